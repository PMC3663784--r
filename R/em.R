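#' EM configuration
#'
#' Collects the tunable settings of the heuristic-EM algorithm. Defaults
#' follow the standard initialization: single model Psi (1, 1, 2); full
#' model all biases 1 and couplings 2 on the mechanism diagonal (slight
#' encouragement for same-mechanism neighbour pairs to share a state), 0
#' elsewhere.
#'
#' @param model "single" or "full" MRF parameterization.
#' @param biasMode "global" or "per_mechanism" bias terms (full model);
#'   NULL picks "global" for networks under 500 interactions and
#'   "per_mechanism" otherwise.
#' @param maxIter maximum EM iterations (default 50).
#' @param initAlpha significance level of the correlation t-test used to
#'   initialize states (default 0.05).
#' @param psiInit initial MRF parameters or NULL for the defaults above.
#' @param rAlphaInit initial active-class correlation (default 0.7).
#' @param weighting "posterior" or "rank" weights in the rAlpha M-step.
#' @param negativeMode "signed" or "absolute" treatment of negative
#'   correlations in the noise model.
#' @param damping fraction in [0, 1) of the previous posterior retained at
#'   each update (default 0, fully synchronous replacement). Independently
#'   of this setting, \code{runEM} raises the damping to at least 0.5 as
#'   soon as it detects a period-2 state cycle (the characteristic failure
#'   of synchronous updates under strong coupling); damping leaves the
#'   fixed points unchanged while suppressing the cycles.
#' @param freezeBeta hold couplings at their initial values (no coupling
#'   fit); with a zero initial beta this removes the MRF prior entirely.
#' @param estimateTheta re-estimate rAlpha in the M-step (default TRUE).
#' @param bounds box bounds for the Psi fit.
#' @param mMin sparse mechanism-pair freezing threshold (full model).
#' @param seed integer seed recorded for provenance (the EM itself is
#'   deterministic).
#' @return A list of class \code{emConfig}.
#' @export
emConfig <- function(model = c("single", "full"), biasMode = NULL,
                     maxIter = 50L, initAlpha = 0.05, psiInit = NULL,
                     rAlphaInit = 0.7, weighting = "posterior",
                     negativeMode = "signed", damping = 0,
                     freezeBeta = FALSE, estimateTheta = TRUE,
                     bounds = c(-10, 10), mMin = 5L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(maxIter >= 1L, damping >= 0, damping < 1,
            initAlpha > 0, initAlpha < 1)
  structure(list(model = model, biasMode = biasMode,
                 maxIter = as.integer(maxIter), initAlpha = initAlpha,
                 psiInit = psiInit, rAlphaInit = rAlphaInit,
                 weighting = weighting, negativeMode = negativeMode,
                 damping = damping, freezeBeta = freezeBeta,
                 estimateTheta = estimateTheta, bounds = bounds,
                 mMin = as.integer(mMin), seed = as.integer(seed)),
            class = "emConfig")
}

#' Initialize activity states from a correlation test
#'
#' An interaction starts active iff the one-sided correlation t-test
#' (t = r * sqrt((n-2)/(1-r^2)), df = n-2) rejects at level \code{alpha};
#' in absolute mode the test uses |r|.
#'
#' @param corr a \linkS4class{CorrelationData}.
#' @param alpha significance level (default 0.05).
#' @param negativeMode "signed" or "absolute".
#' @return Named integer vector of 0/1 states.
#' @export
initializeStates <- function(corr, alpha = 0.05, negativeMode = "signed") {
  r <- corr@values
  p <- likelihoodInactive(r, corr@n, negativeMode = negativeMode)
  setNames(as.integer(!is.na(p) & p < alpha), names(r))
}

## log-likelihood pieces of the noise model, aligned to ids
.noiseLogLik <- function(corr, theta, ids) {
  r <- corr@values[ids]
  list(l1 = likelihoodActive(r, theta@rAlpha, theta@n,
                             negativeMode = theta@negativeMode, log = TRUE),
       l0 = likelihoodInactive(r, theta@n,
                               negativeMode = theta@negativeMode, log = TRUE))
}

#' Heuristic E-step
#'
#' Updates every interaction's active-state posterior synchronously: the
#' new posterior is proportional to
#' \code{likelihoodActive(r) * exp(psi1)} against
#' \code{likelihoodInactive(r) * exp(psi0)}, where the potentials are
#' evaluated at the expected neighbour counts computed from the incoming
#' posteriors (the belief-propagation-style shortcut that replaces the sum
#' over neighbour configurations). Optional damping blends old and new
#' posteriors.
#'
#' @param posteriors named numeric incoming posteriors.
#' @param corr a \linkS4class{CorrelationData}.
#' @param theta a \linkS4class{NoiseParams}.
#' @param psi MRF parameters.
#' @param net an \linkS4class{InteractionNetwork}.
#' @param damping fraction of the old posterior retained.
#' @return Named numeric vector of updated posteriors.
#' @export
eStep <- function(posteriors, corr, theta, psi, net, damping = 0) {
  ctx <- .mrfContext(net)
  p <- .alignTo(posteriors, ctx$ids)
  pot <- .mrfPotentials(psi, p, ctx)
  nl <- .noiseLogLik(corr, theta, ctx$ids)
  pNew <- plogis((nl$l1 + pot$psi1) - (nl$l0 + pot$psi0))
  setNames((1 - damping) * pNew + damping * p, ctx$ids)
}

#' M-step
#'
#' Re-estimates the noise parameter rAlpha (posterior- or rank-weighted
#' Fisher-z mean) and refits the MRF parameters by pseudo-likelihood
#' maximization at the current posteriors.
#'
#' @param posteriors named numeric posteriors.
#' @param corr a \linkS4class{CorrelationData}.
#' @param net an \linkS4class{InteractionNetwork}.
#' @param config an \code{\link{emConfig}}.
#' @param theta current \linkS4class{NoiseParams}.
#' @param psi current MRF parameters (used as the optimizer start).
#' @return List with elements \code{theta} and \code{psi}.
#' @export
mStep <- function(posteriors, corr, net, config, theta, psi) {
  ids <- net@interactions$id
  p <- .alignTo(posteriors, ids)
  if (config$estimateTheta) {
    z <- fisherZ(corr@values[ids])
    if (theta@negativeMode == "absolute") z <- abs(z)
    rA <- estimateRAlpha(z, p, weighting = config$weighting)
    theta <- noiseParams(rA, theta@n, theta@negativeMode, config$weighting)
  }
  biasMode <- .resolveBiasMode(config, net)
  psiFit <- fitPsi(p, net, model = config$model, biasMode = biasMode,
                   bounds = config$bounds, init = psi,
                   freezeBeta = config$freezeBeta, mMin = config$mMin)
  list(theta = theta, psi = psiFit)
}

.resolveBiasMode <- function(config, net) {
  if (!is.null(config$biasMode)) return(config$biasMode)
  if (nrow(net@interactions) < 500L) "global" else "per_mechanism"
}

.defaultPsi <- function(config, net) {
  if (!is.null(config$psiInit)) return(config$psiInit)
  if (config$model == "single") singleParamPsi()
  else fullParamPsi(sort(unique(net@interactions$mechanism)),
                    biasMode = .resolveBiasMode(config, net))
}

#' Expected complete-data log-likelihood
#'
#' The EM objective: the posterior-weighted sum over interactions and both
#' activity states of the log noise likelihood plus the log normalized MRF
#' conditional of that state, with expected neighbour counts taken from
#' the supplied posteriors.
#'
#' @inheritParams eStep
#' @return Numeric scalar.
#' @export
completeDataLogLik <- function(posteriors, corr, theta, psi, net) {
  ctx <- .mrfContext(net)
  p <- .alignTo(posteriors, ctx$ids)
  pot <- .mrfPotentials(psi, p, ctx)
  nl <- .noiseLogLik(corr, theta, ctx$ids)
  d <- pot$psi1 - pot$psi0
  sum(p * (nl$l1 + .logSigmoid(d)) + (1 - p) * (nl$l0 + .logSigmoid(-d)))
}

#' Run the heuristic-EM active-subnetwork recovery
#'
#' Alternates the heuristic E-step with the M-step from a
#' correlation-test state initialization until the thresholded state
#' vector stops changing (with a secondary stop when the largest posterior
#' change falls below 1e-4), or \code{maxIter} is reached. If all
#' interactions collapse to one state the run is flagged as runaway
#' reinforcement and stopped; the result is still returned so the caller
#' can decide to exclude or restart it.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param corr a \linkS4class{CorrelationData}; interactions with missing
#'   correlations are excluded with a warning.
#' @param config an \code{\link{emConfig}}.
#' @param verbose log one line per iteration (iteration index, state
#'   changes, objective value F and rAlpha) to the message stream.
#' @return An \linkS4class{EmResult}.
#' @export
runEM <- function(net, corr, config = emConfig(), verbose = FALSE) {
  ids <- net@interactions$id
  stopifnot(all(ids %in% names(corr@values)))
  miss <- ids[is.na(corr@values[ids])]
  if (length(miss)) {
    warning("excluding ", length(miss),
            " interaction(s) with missing correlations")
    net <- .subsetNetwork(net, setdiff(ids, miss))
    ids <- net@interactions$id
    corr <- correlationData(corr@values[ids], corr@n)
  }
  theta <- noiseParams(config$rAlphaInit, corr@n,
                       negativeMode = config$negativeMode,
                       weighting = config$weighting)
  psi <- .defaultPsi(config, net)
  states <- initializeStates(corr, config$initAlpha,
                             config$negativeMode)[ids]
  p <- setNames(as.numeric(states), ids)
  trace <- data.frame(iteration = integer(0L), stateChanges = integer(0L),
                      F = numeric(0L), rAlpha = numeric(0L))
  converged <- FALSE
  runaway <- FALSE
  iter <- 0L
  damping <- config$damping
  prevPrevStates <- NULL
  repeat {
    iter <- iter + 1L
    pNew <- eStep(p, corr, theta, psi, net, damping = damping)
    newStates <- setNames(as.integer(pNew > 0.5), ids)
    Fval <- completeDataLogLik(pNew, corr, theta, psi, net)
    trace <- rbind(trace, data.frame(
      iteration = iter, stateChanges = sum(newStates != states),
      F = Fval, rAlpha = theta@rAlpha))
    if (verbose)
      message(sprintf("iter %3d: %4d state changes, F = %.3f, rAlpha = %.4f",
                      iter, sum(newStates != states), Fval, theta@rAlpha))
    maxDelta <- max(abs(pNew - p))
    stateStable <- all(newStates == states)
    ## oscillation guard: an exact period-2 state cycle, or failure to
    ## stabilize within 20 iterations, escalates the damping (0.5, then
    ## 0.75, 0.875, ... capped at 0.95) until the cycle breaks; the fixed
    ## points are unchanged by damping
    if (!stateStable &&
        (iter >= 20L ||
         (!is.null(prevPrevStates) && all(newStates == prevPrevStates))))
      damping <- if (damping < 0.5) 0.5 else min(0.95, (1 + damping) / 2)
    prevPrevStates <- states
    states <- newStates
    p <- pNew
    if (length(unique(states)) == 1L) {
      runaway <- TRUE
      converged <- stateStable
      break
    }
    if (stateStable || maxDelta < 1e-4) {
      converged <- TRUE
      break
    }
    if (iter >= config$maxIter) break
    upd <- mStep(p, corr, net, config, theta, psi)
    theta <- upd$theta
    psi <- upd$psi
  }
  new("EmResult", posteriors = p, states = states, theta = theta,
      psi = psi, iterations = iter, converged = converged,
      runaway = runaway, trace = trace, method = config$model)
}
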