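#' Simulation configuration
#'
#' Defines one benchmark instance: a synthetic mechanism-structured network
#' (a connected pathway core plus preferentially attached expansion
#' interactions), the 90/10 activity rule over two mechanism classes, and
#' Fisher-space correlation replicates. Defaults reproduce the standard
#' benchmark conditions: activity retention probability 0.9, active-class
#' mean correlation 0.7, non-active mean 0, n = 5 time points and N = 5
#' correlation replicates.
#'
#' @param nInteractions total number of interactions.
#' @param nPathway size of the connected pathway core (defaults to 40\% of
#'   the network).
#' @param mechanisms three mechanism codes used in the network.
#' @param class1 subset of \code{mechanisms} forming the first activity
#'   class (pathway-favoured); the complement forms class 2.
#' @param pKeep the 90/10 rule probability (default 0.9).
#' @param meanActive,meanInactive population correlations of active and
#'   non-active interactions (defaults 0.7 and 0).
#' @param nTimepoints samples behind each simulated correlation (default 5).
#' @param nSims number of correlation replicates per benchmark (default 5).
#' @param mixing length-2 numeric: the fraction of interactions carrying
#'   the locally minority class label in the pathway core and in the
#'   expansion (defaults 0.2 and 0.05: pathway maps are largely, not
#'   entirely, class 1, while database expansion is nearly pure class 2;
#'   equal fractions would make the two regions' activity rates coincide
#'   exactly and erase all neighbourhood information).
#' @param seed integer seed.
#' @return A list of class \code{simConfig}.
#' @export
simConfig <- function(nInteractions = 100L, nPathway = NULL,
                      mechanisms = c("M", "TR", "B"),
                      class1 = c("M", "TR"), pKeep = 0.9,
                      meanActive = 0.7, meanInactive = 0,
                      nTimepoints = 5L, nSims = 5L, mixing = c(0.2, 0.05),
                      seed = 1L) {
  mechanisms <- canonicalMechanism(mechanisms)
  class1 <- canonicalMechanism(class1)
  stopifnot(all(class1 %in% mechanisms), length(class1) < length(mechanisms),
            pKeep > 0, pKeep < 1, nTimepoints >= 4L)
  if (length(mixing) == 1L) mixing <- rep(mixing, 2L)
  stopifnot(all(mixing >= 0), all(mixing < 0.5))
  if (is.null(nPathway)) nPathway <- max(2L, round(0.4 * nInteractions))
  stopifnot(nPathway <= nInteractions, nPathway >= 1L)
  structure(list(nInteractions = as.integer(nInteractions),
                 nPathway = as.integer(nPathway),
                 mechanisms = mechanisms, class1 = class1,
                 class2 = setdiff(mechanisms, class1), pKeep = pKeep,
                 meanActive = meanActive, meanInactive = meanInactive,
                 nTimepoints = as.integer(nTimepoints),
                 nSims = as.integer(nSims), mixing = mixing,
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' Benchmark presets at the published network scales
#'
#' Three presets matching the published benchmark network sizes and
#' mechanism sets: \code{"vegf"} (1065 interactions; mechanisms M, B, TR
#' with class 1 \{M, TR\}), \code{"cell_adhesion"} (344 interactions;
#' +P, -P, TR with class 1 \{+P, -P\}) and \code{"blood_coag"}
#' (94 interactions; C, B, +P with class 1 \{C, B\}). Topology is
#' generator-defined (preferential attachment around a connected core).
#'
#' @param preset one of "vegf", "cell_adhesion", "blood_coag".
#' @param seed integer seed.
#' @param ... overrides passed to \code{\link{simConfig}}.
#' @return A \code{simConfig}.
#' @export
simPreset <- function(preset = c("vegf", "cell_adhesion", "blood_coag"),
                      seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    vegf = list(nInteractions = 1065L, mechanisms = c("M", "B", "TR"),
                class1 = c("M", "TR")),
    cell_adhesion = list(nInteractions = 344L,
                         mechanisms = c("+P", "-P", "TR"),
                         class1 = c("+P", "-P")),
    blood_coag = list(nInteractions = 94L, mechanisms = c("C", "B", "+P"),
                      class1 = c("C", "B")))
  do.call(simConfig, c(args, list(seed = seed), list(...)))
}

#' Generate a synthetic mechanism-structured network
#'
#' Builds a connected pathway core of \code{nPathway} interactions, then
#' attaches expansion interactions preferentially to well-connected nodes
#' until \code{nInteractions} is reached. Mechanism labels are drawn so
#' that the pathway core is predominantly class 1 and the expansion
#' predominantly class 2, with a minority-label fraction of
#' \code{mixing}. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{simConfig}}.
#' @return List with \code{network} (an
#'   \linkS4class{InteractionNetwork}) and \code{pathwayIds}.
#' @export
generateNetwork <- function(config) {
  withSeed(config$seed, {
    nI <- config$nInteractions
    src <- tgt <- character(nI)
    nodeDeg <- c(n1 = 1L, n2 = 1L)
    src[1L] <- "n1"; tgt[1L] <- "n2"
    nNodes <- 2L
    ## growth weights: during the core phase every node is eligible;
    ## during expansion only a few core anchor nodes plus nodes touched by
    ## expansion interactions are, so the expansion forms new regions
    ## around the core rather than thickening its hubs.
    growDeg <- nodeDeg
    for (e in seq_len(nI)[-1L]) {
      if (e == config$nPathway + 1L) {
        anchors <- sample(names(nodeDeg),
                          min(3L, length(nodeDeg)))
        growDeg <- setNames(rep(1L, length(anchors)), anchors)
      }
      pool <- names(growDeg)
      anchor <- sample(pool, 1L, prob = growDeg)
      if (runif(1L) < 0.6 || length(pool) < 3L) {
        nNodes <- nNodes + 1L
        other <- paste0("n", nNodes)
        nodeDeg[other] <- 0L
        growDeg[other] <- 0L
      } else {
        others <- setdiff(pool, anchor)
        other <- sample(others, 1L, prob = growDeg[others] + 1)
      }
      src[e] <- anchor; tgt[e] <- other
      nodeDeg[anchor] <- nodeDeg[anchor] + 1L
      nodeDeg[other] <- nodeDeg[other] + 1L
      growDeg[anchor] <- growDeg[anchor] + 1L
      growDeg[other] <- growDeg[other] + 1L
    }
    isPathway <- seq_len(nI) <= config$nPathway
    ## exact minority counts per region (class labels, not activity)
    pickClass <- isPathway
    pw <- which(isPathway); xp <- which(!isPathway)
    nMinP <- round(config$mixing[1L] * length(pw))
    nMinX <- round(config$mixing[2L] * length(xp))
    if (nMinP > 0L) pickClass[sample(pw, nMinP)] <- FALSE
    if (nMinX > 0L) pickClass[sample(xp, nMinX)] <- TRUE
    mech <- character(nI)
    c1 <- config$class1; c2 <- config$class2
    mech[pickClass] <- sample(c1, sum(pickClass), replace = TRUE)
    mech[!pickClass] <- sample(c2, sum(!pickClass), replace = TRUE)
    net <- interactionNetwork(src, tgt, mech,
                              id = sprintf("e%05d", seq_len(nI)))
    list(network = net, pathwayIds = net@interactions$id[isPathway])
  })
}

#' Assign true activity states by the 90/10 rule
#'
#' Pathway-core interactions of class 1 (and expansion interactions of
#' class 2) become active with probability \code{pKeep}; the complementary
#' assignments with probability \code{1 - pKeep}. With the default
#' \code{pKeep = 0.9} this is the "90/10" rule, creating mechanism-mechanism
#' activity correlations in the generated truth.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param pathwayIds interaction ids of the pathway core.
#' @param class1 mechanism codes of the first class; all other mechanisms
#'   form class 2.
#' @param pKeep retention probability (default 0.9).
#' @param seed integer seed.
#' @return A \linkS4class{SimulationTruth}.
#' @export
applyNinetyTenRule <- function(net, pathwayIds, class1, pKeep = 0.9,
                               seed = 1L) {
  df <- net@interactions
  stopifnot(all(pathwayIds %in% df$id), pKeep > 0, pKeep <= 1)
  withSeed(seed, {
    inPathway <- df$id %in% pathwayIds
    inClass1 <- df$mechanism %in% class1
    pActive <- ifelse(inPathway == inClass1, pKeep, 1 - pKeep)
    active <- runif(nrow(df)) < pActive
    new("SimulationTruth", network = net,
        pathwayIds = as.character(pathwayIds),
        trueActive = df$id[active])
  })
}

#' Simulate correlation observations in Fisher space
#'
#' For each interaction, draws z from a Gaussian with mean
#' \code{artanh(meanActive)} (active) or \code{artanh(meanInactive)}
#' (non-active) and sd \code{1/sqrt(nTimepoints - 3)}, and reports
#' \code{r = tanh(z)}. All outputs are strictly inside (-1, 1).
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param meanActive,meanInactive population correlations (defaults 0.7, 0).
#' @param nTimepoints sample size n (default 5).
#' @param seed integer seed.
#' @return A \linkS4class{CorrelationData}.
#' @export
simulateCorrelations <- function(truth, meanActive = 0.7, meanInactive = 0,
                                 nTimepoints = 5L, seed = 1L) {
  stopifnot(nTimepoints >= 4L)
  ids <- truth@network@interactions$id
  active <- ids %in% truth@trueActive
  mu <- ifelse(active, atanh(meanActive), atanh(meanInactive))
  withSeed(seed, {
    z <- rnorm(length(ids), mean = mu, sd = 1 / sqrt(nTimepoints - 3))
    correlationData(setNames(tanh(z), ids), nTimepoints)
  })
}

#' Recovery metrics against the simulation truth
#'
#' Confusion counts of a predicted state vector against the true active
#' set, with sensitivity \code{100*TP/(TP+FN)}, specificity
#' \code{100*TN/(TN+FP)} and percentage correct \code{100*(TP+TN)/total}.
#'
#' @param predicted named 0/1 state vector covering the network (or an
#'   \linkS4class{EmResult}).
#' @param truth a \linkS4class{SimulationTruth}.
#' @return List with tp, fp, tn, fn, sensitivity, specificity,
#'   percentCorrect.
#' @export
evaluateRecovery <- function(predicted, truth) {
  if (is(predicted, "EmResult")) predicted <- predicted@states
  ids <- truth@network@interactions$id
  stopifnot(all(ids %in% names(predicted)))
  pred <- predicted[ids] == 1L
  act <- ids %in% truth@trueActive
  tp <- sum(pred & act); fn <- sum(!pred & act)
  tn <- sum(!pred & !act); fp <- sum(pred & !act)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       percentCorrect = 100 * (tp + tn) / length(ids))
}

#' Consensus network across simulation replicates
#'
#' Interactions called active in at least \code{ceiling(threshold * N)} of
#' the N replicate results (with the default 0.8 threshold and N = 5 this
#' is the 4-of-5 rule).
#'
#' @param results list of named 0/1 state vectors (or
#'   \linkS4class{EmResult}s) over the same network.
#' @param threshold consensus fraction (default 0.8).
#' @return Character vector of consensus-active interaction ids.
#' @export
consensusNetwork <- function(results, threshold = 0.8) {
  stopifnot(length(results) >= 1L)
  states <- lapply(results, function(x)
    if (is(x, "EmResult")) x@states else x)
  ids <- names(states[[1L]])
  stopifnot(all(vapply(states, function(s) identical(names(s), ids),
                       logical(1L))))
  counts <- Reduce(`+`, lapply(states, function(s) as.integer(s == 1L)))
  need <- ceiling(threshold * length(states))
  ids[counts >= max(need, 1L)]
}

#' Run the full simulation benchmark
#'
#' Generates one network and truth from \code{config}, draws
#' \code{config$nSims} correlation replicates, runs each requested method
#' on every replicate, and aggregates recovery metrics as mean (sd) per
#' method. Replicates flagged as runaway reinforcement or non-converged
#' are excluded from the summary and the exclusion counts reported.
#'
#' @param config a \code{\link{simConfig}}.
#' @param methods subset of c("full", "single", "ml").
#' @param emCfg an \code{\link{emConfig}} used (with the matching
#'   \code{model}) for the EM methods.
#' @return List with \code{summary} (a data.frame of per-method mean/sd
#'   metrics), \code{perReplicate}, \code{excluded} (named counts),
#'   \code{truth} and \code{consensus} (per method, over included
#'   replicates).
#' @export
runBenchmark <- function(config, methods = c("full", "single", "ml"),
                         emCfg = emConfig()) {
  methods <- match.arg(methods, several.ok = TRUE)
  gen <- generateNetwork(config)
  seeds <- subSeeds(config$seed, config$nSims + 1L)
  truth <- applyNinetyTenRule(gen$network, gen$pathwayIds, config$class1,
                              config$pKeep, seed = seeds[1L])
  reps <- lapply(seq_len(config$nSims), function(k)
    simulateCorrelations(truth, config$meanActive, config$meanInactive,
                         config$nTimepoints, seed = seeds[k + 1L]))
  runOne <- function(method, corr) {
    if (method == "ml")
      return(mlClassify(corr, rAlpha = config$meanActive,
                        n = config$nTimepoints,
                        negativeMode = emCfg$negativeMode))
    cfg <- emCfg
    cfg$model <- method
    cfg$psiInit <- NULL                  # model-appropriate defaults
    runEM(truth@network, corr, cfg)
  }
  perRep <- list()
  excluded <- setNames(integer(length(methods)), methods)
  summary <- NULL
  consensus <- list()
  for (method in methods) {
    fits <- lapply(reps, function(corr) runOne(method, corr))
    ok <- vapply(fits, function(f) f@converged && !f@runaway, logical(1L))
    excluded[method] <- sum(!ok)
    if (!any(ok))
      stop("all replicates excluded (runaway/non-converged) for method ",
           method)
    mets <- lapply(fits[ok], evaluateRecovery, truth = truth)
    agg <- function(field) {
      v <- vapply(mets, `[[`, numeric(1L), field)
      c(mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0)
    }
    if (excluded[method] > 0L)
      message(excluded[method], " replicate(s) excluded for method ",
              method)
    sens <- agg("sensitivity"); spec <- agg("specificity")
    pc <- agg("percentCorrect")
    summary <- rbind(summary, data.frame(
      method = method, nIncluded = sum(ok),
      sensitivity = sens["mean"], sensitivity_sd = sens["sd"],
      specificity = spec["mean"], specificity_sd = spec["sd"],
      percentCorrect = pc["mean"], percentCorrect_sd = pc["sd"],
      row.names = NULL))
    perRep[[method]] <- mets
    consensus[[method]] <- consensusNetwork(fits[ok])
  }
  if (any(summary$nIncluded == 1L))
    warning("a method has a single included replicate; sd reported as 0")
  list(summary = summary, perReplicate = perRep, excluded = excluded,
       truth = truth, consensus = consensus)
}
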