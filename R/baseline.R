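#' Maximum-likelihood-only baseline classifier
#'
#' Classifies every interaction independently from the noise model alone,
#' with no MRF prior: an interaction is active iff its active-hypothesis
#' likelihood exceeds its non-active-hypothesis likelihood
#' (ties go to non-active). The reported posterior is the normalized
#' likelihood ratio \code{l1 / (l1 + l0)}. Classification of one
#' interaction never depends on any other, so the result is invariant to
#' the network topology.
#'
#' @param corr a \linkS4class{CorrelationData}.
#' @param rAlpha active-class correlation parameter (default 0.7).
#' @param n sample size; defaults to \code{sampleSize(corr)}.
#' @param negativeMode "signed" or "absolute".
#' @return An \linkS4class{EmResult} with \code{method = "ml"} and no
#'   MRF parameters.
#' @export
#' @examples
#' corr <- correlationData(c(a = 0.9, b = 0.1), n = 5)
#' activeStates(mlClassify(corr))
mlClassify <- function(corr, rAlpha = 0.7, n = sampleSize(corr),
                       negativeMode = "signed") {
  ids <- names(corr@values)
  keep <- !is.na(corr@values)
  if (!all(keep)) {
    warning("excluding ", sum(!keep),
            " interaction(s) with missing correlations")
    ids <- ids[keep]
  }
  r <- corr@values[ids]
  l1 <- likelihoodActive(r, rAlpha, n, negativeMode = negativeMode,
                         log = TRUE)
  l0 <- likelihoodInactive(r, n, negativeMode = negativeMode, log = TRUE)
  post <- setNames(plogis(l1 - l0), ids)
  ## active iff l1 > l0; ties (posterior exactly 0.5) go to non-active
  states <- setNames(as.integer(post > 0.5), ids)
  theta <- noiseParams(rAlpha, n, negativeMode = negativeMode)
  new("EmResult", posteriors = post, states = states, theta = theta,
      psi = NULL, iterations = 1L, converged = TRUE,
      runaway = length(unique(states)) == 1L,
      trace = data.frame(iteration = 1L,
                         stateChanges = NA_integer_,
                         F = NA_real_, rAlpha = rAlpha),
      method = "ml")
}
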