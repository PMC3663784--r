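#' @rdname InteractionNetwork-class
#' @param object,x an object.
#' @export
setGeneric("interactionIds", function(x) standardGeneric("interactionIds"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("mechanismOf", function(x) standardGeneric("mechanismOf"))

#' @rdname CorrelationData-class
#' @param x an object.
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname CorrelationData-class
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))

#' @rdname EmResult-class
#' @param x an object.
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))

#' @rdname EmResult-class
#' @export
setGeneric("activeStates", function(x) standardGeneric("activeStates"))

#' @rdname SimulationTruth-class
#' @param x an object.
#' @export
setGeneric("trueActive", function(x) standardGeneric("trueActive"))

#' @rdname SimulationTruth-class
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' Extract interaction table
#' @param x an \linkS4class{InteractionNetwork}.
#' @return \code{interactions}: the interaction data.frame;
#'   \code{interactionIds}: character vector of ids; \code{networkNodes}:
#'   node ids; \code{mechanismOf}: named character vector of mechanism codes.
#' @rdname InteractionNetwork-class
#' @export
setMethod("interactions", "InteractionNetwork", function(x) x@interactions)

#' @rdname InteractionNetwork-class
#' @export
setMethod("interactionIds", "InteractionNetwork",
          function(x) x@interactions$id)

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkNodes", "InteractionNetwork", function(x) x@nodes)

#' @rdname InteractionNetwork-class
#' @export
setMethod("mechanismOf", "InteractionNetwork", function(x)
  setNames(x@interactions$mechanism, x@interactions$id))

#' @rdname CorrelationData-class
#' @export
setMethod("corValues", "CorrelationData", function(x) x@values)

#' @rdname CorrelationData-class
#' @export
setMethod("sampleSize", "CorrelationData", function(x) x@n)

#' @rdname EmResult-class
#' @export
setMethod("posteriors", "EmResult", function(x) x@posteriors)

#' @rdname EmResult-class
#' @export
setMethod("activeStates", "EmResult", function(x) x@states)

#' @rdname SimulationTruth-class
#' @export
setMethod("trueActive", "SimulationTruth", function(x) x@trueActive)

#' @rdname SimulationTruth-class
#' @export
setMethod("pathwayIds", "SimulationTruth", function(x) x@pathwayIds)

#' @rdname SimulationTruth-class
#' @export
setGeneric("simNetwork", function(x) standardGeneric("simNetwork"))

#' @rdname SimulationTruth-class
#' @export
setMethod("simNetwork", "SimulationTruth", function(x) x@network)

setMethod("show", "InteractionNetwork", function(object) {
  df <- object@interactions
  cat("InteractionNetwork with", length(object@nodes), "nodes and",
      nrow(df), "interactions\n")
  tab <- table(df$mechanism)
  cat("mechanisms:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "CorrelationData", function(object) {
  v <- object@values
  cat("CorrelationData:", length(v), "interactions, n =", object@n, "\n")
  cat("range:", sprintf("[%.3f, %.3f]", min(v, na.rm = TRUE),
      max(v, na.rm = TRUE)),
      if (anyNA(v)) sprintf("(%d missing)", sum(is.na(v))) else "", "\n")
})

setMethod("show", "NoiseParams", function(object) {
  cat(sprintf("NoiseParams: rAlpha = %.4f (zAlpha = %.4f), n = %d, %s, %s\n",
              object@rAlpha, atanh(object@rAlpha), object@n,
              object@negativeMode, object@weighting))
})

setMethod("show", "SingleParamPsi", function(object) {
  cat(sprintf(
    "SingleParamPsi: gamma0 = %.4f, gamma1 = %.4f, beta = %.4f\n",
    object@gamma0, object@gamma1, object@beta))
  if (any(object@atBound))
    cat("at bound:", paste(names(which(object@atBound)), collapse = ", "), "\n")
})

setMethod("show", "FullParamPsi", function(object) {
  cat("FullParamPsi (", object@biasMode, " bias) over mechanisms: ",
      paste(rownames(object@beta), collapse = ", "), "\n", sep = "")
  cat("gamma:\n"); print(round(object@gamma, 4))
  cat("beta:\n"); print(round(object@beta, 4))
  if (any(object@frozen[upper.tri(object@frozen, diag = TRUE)]))
    cat("frozen couplings held at 0 (sparse mechanism pairs)\n")
  if (length(object@atBound))
    cat("at bound:", paste(object@atBound, collapse = ", "), "\n")
})

setMethod("show", "EmResult", function(object) {
  cat(sprintf(
    "EmResult (%s): %d interactions, %d active; %d iteration(s), %s%s\n",
    object@method, length(object@states), sum(object@states),
    object@iterations,
    if (object@converged) "converged" else "not converged",
    if (object@runaway) ", RUNAWAY reinforcement" else ""))
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", nrow(object@network@interactions),
      "interactions (", length(object@trueActive), "active,",
      length(object@pathwayIds), "in pathway core )\n")
})
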