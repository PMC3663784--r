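#' Fisher z-transform
#'
#' \code{fisherZ(r) = artanh(r) = 0.5 * log((1+r)/(1-r))}; its inverse is
#' \code{inverseFisherZ = tanh}. For a sample correlation over n
#' observations the transform is approximately Gaussian with standard
#' error \code{1/sqrt(n-3)}.
#'
#' @param r correlation value(s), strictly inside (-1, 1).
#' @return Transformed value(s).
#' @export
#' @examples
#' fisherZ(0.7)          # 0.8673
#' inverseFisherZ(fisherZ(0.3))
fisherZ <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("fisherZ requires |r| < 1")
  atanh(r)
}

#' @rdname fisherZ
#' @param z Fisher-z value(s).
#' @export
inverseFisherZ <- function(z) tanh(z)

#' Likelihood of a correlation under the active hypothesis
#'
#' Under H1 (interaction active) the Fisher-transformed correlation is
#' Gaussian with mean \code{artanh(rAlpha)} and sd \code{1/sqrt(n-3)}; the
#' likelihood term is the left-tail probability \code{Pr(Z < z_obs)}, which
#' equals 0.5 exactly at \code{r = rAlpha} and increases with r (signed
#' mode). In absolute mode the magnitude \code{|artanh(r)|} is used, so
#' anti-correlated pairs score like correlated ones.
#'
#' @param r observed correlation(s), |r| < 1.
#' @param rAlpha active-class population correlation estimate in (0, 1).
#' @param n sample size (>= 4).
#' @param negativeMode "signed" (default) or "absolute".
#' @param log return the log probability.
#' @return Probability (or log probability) per input correlation.
#' @export
#' @examples
#' likelihoodActive(0.7, rAlpha = 0.7, n = 5)   # 0.5
likelihoodActive <- function(r, rAlpha, n, negativeMode = "signed",
                             log = FALSE) {
  stopifnot(rAlpha > 0, rAlpha < 1, n >= 4)
  z <- fisherZ(r)
  if (negativeMode == "absolute") z <- abs(z)
  pnorm(z, mean = atanh(rAlpha), sd = 1 / sqrt(n - 3), log.p = log)
}

#' Likelihood of a correlation under the non-active hypothesis
#'
#' Under H0 (interaction not active) the population correlation is 0; the
#' observed r is converted to \code{t = r * sqrt((n-2)/(1-r^2))} and the
#' likelihood term is the one-tailed survival probability
#' \code{Pr(T > t_obs)} under Student t with n-2 degrees of freedom. It
#' equals 0.5 at r = 0 and decreases as r grows (signed mode).
#'
#' @inheritParams likelihoodActive
#' @return Probability (or log probability) per input correlation.
#' @export
#' @examples
#' likelihoodInactive(0, n = 5)    # 0.5
#' likelihoodInactive(0.5, n = 5)  # 0.1955
likelihoodInactive <- function(r, n, negativeMode = "signed", log = FALSE) {
  stopifnot(n >= 4, all(abs(r) < 1, na.rm = TRUE))
  if (negativeMode == "absolute") r <- abs(r)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  pt(tstat, df = n - 2, lower.tail = FALSE, log.p = log)
}

#' Estimate the active-class correlation parameter
#'
#' The M-step estimator for the noise model: the posterior-weighted mean of
#' the Fisher-z values, mapped back through tanh. With
#' \code{weighting = "rank"} the weights are the ranks of the posteriors
#' (average ranks for ties), a variant that stabilizes the estimate when
#' many interactions carry large posteriors. The result is clamped to
#' [0.05, 0.99] so the active and non-active hypotheses remain
#' distinguishable.
#'
#' @param z per-interaction Fisher-z values.
#' @param activePosteriors per-interaction posterior probabilities of the
#'   active state; at least one must be positive.
#' @param weighting "posterior" or "rank".
#' @param clamp length-2 numeric bounds on the returned correlation.
#' @return The estimated correlation in (0, 1).
#' @export
estimateRAlpha <- function(z, activePosteriors,
                           weighting = c("posterior", "rank"),
                           clamp = c(0.05, 0.99)) {
  weighting <- match.arg(weighting)
  stopifnot(length(z) == length(activePosteriors),
            all(activePosteriors >= 0))
  if (all(activePosteriors == 0))
    stop("all active posteriors are zero; rAlpha is undefined")
  w <- if (weighting == "rank") rank(activePosteriors) else activePosteriors
  est <- tanh(sum(w * z) / sum(w))
  min(max(est, clamp[1L]), clamp[2L])
}
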