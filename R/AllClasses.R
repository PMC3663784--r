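#' InteractionNetwork: a mechanism-annotated interaction network
#'
#' Stores a molecular interaction network as a set of nodes plus a table of
#' interactions (edges), each carrying a mechanism annotation from the
#' ten-symbol controlled vocabulary (see \code{\link{mechanismCodes}}), and
#' an interaction-adjacency (line-graph) view: two interactions are
#' neighbours iff they share at least one node. Parallel interactions
#' between the same node pair (with distinct mechanisms) are allowed and are
#' neighbours of each other.
#'
#' @slot nodes character vector of node identifiers.
#' @slot interactions data.frame with columns \code{id}, \code{source},
#'   \code{target}, \code{mechanism}.
#' @slot adjacency named list mapping each interaction id to the character
#'   vector of neighbouring interaction ids (symmetric, never self).
#' @export
setClass("InteractionNetwork",
  representation(nodes = "character",
                 interactions = "data.frame",
                 adjacency = "list"))

setValidity("InteractionNetwork", function(object) {
  df <- object@interactions
  need <- c("id", "source", "target", "mechanism")
  if (!all(need %in% names(df)))
    return(paste("interactions must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(df$id))
    return("interaction ids must be unique")
  if (length(bad <- setdiff(unique(df$mechanism), .MECHANISMS)))
    return(paste("unknown mechanism code(s):", paste(bad, collapse = ", ")))
  if (!all(c(df$source, df$target) %in% object@nodes))
    return("interaction endpoints must appear in nodes")
  adj <- object@adjacency
  if (!identical(sort(names(adj)), sort(df$id)))
    return("adjacency must be keyed by the interaction ids")
  for (id in names(adj)) {
    nb <- adj[[id]]
    if (id %in% nb) return(paste("interaction", id, "is its own neighbour"))
    if (!all(vapply(nb, function(j) id %in% adj[[j]], logical(1L))))
      return("adjacency is not symmetric")
  }
  TRUE
})

## internal: incident interaction ids per node -> neighbour lists
.buildAdjacency <- function(df) {
  inc <- split(rep(df$id, 2L), c(df$source, df$target))
  adj <- lapply(seq_len(nrow(df)), function(i) {
    nb <- unique(c(inc[[df$source[i]]], inc[[df$target[i]]]))
    nb[nb != df$id[i]]
  })
  names(adj) <- df$id
  adj
}

#' Construct an InteractionNetwork
#'
#' @param source,target character vectors of endpoint node ids (parallel
#'   vectors, one entry per interaction).
#' @param mechanism character vector of mechanism codes (\code{"Tr"} is
#'   accepted and canonicalized to \code{"TR"}).
#' @param id optional interaction ids; defaults to
#'   \code{source|mechanism|target} keys, disambiguated if duplicated.
#' @param nodes optional node universe; defaults to the endpoint union
#'   (extra isolated nodes may be supplied).
#' @param allowSelfLoops logical; self interactions are rejected unless TRUE.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
#' @examples
#' net <- interactionNetwork(c("A", "B"), c("B", "C"), c("TR", "M"))
#' interactionNeighbors(net, interactionIds(net)[1])
interactionNetwork <- function(source, target, mechanism, id = NULL,
                               nodes = NULL, allowSelfLoops = FALSE) {
  source <- as.character(source)
  target <- as.character(target)
  mechanism <- canonicalMechanism(mechanism)
  stopifnot(length(source) == length(target),
            length(source) == length(mechanism))
  if (!allowSelfLoops && any(source == target))
    stop("self-interactions are not allowed (source == target)")
  if (is.null(id)) {
    id <- paste(source, mechanism, target, sep = "|")
    if (anyDuplicated(id))
      id <- make.unique(id, sep = "#")
  }
  id <- as.character(id)
  df <- data.frame(id = id, source = source, target = target,
                   mechanism = mechanism, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  allNodes <- unique(c(source, target, as.character(nodes)))
  new("InteractionNetwork", nodes = allNodes, interactions = df,
      adjacency = .buildAdjacency(df))
}

#' CorrelationData: per-interaction correlation observations
#'
#' Holds one observed correlation coefficient per interaction, together with
#' the common sample size n (number of time points) used to compute each
#' correlation; n >= 4 so the Fisher standard error 1/sqrt(n-3) is defined.
#' Values may be NA for interactions whose correlation was undefined
#' (constant expression profile); such interactions are excluded from the
#' likelihood downstream.
#'
#' @slot values named numeric vector in [-1, 1] (names = interaction ids).
#' @slot n integer sample size.
#' @export
setClass("CorrelationData",
  representation(values = "numeric", n = "integer"))

setValidity("CorrelationData", function(object) {
  v <- object@values
  if (is.null(names(v)) || anyDuplicated(names(v)))
    return("values must be uniquely named by interaction id")
  if (any(abs(v) > 1, na.rm = TRUE))
    return("correlations must lie in [-1, 1]")
  if (length(object@n) != 1L || object@n < 4L)
    return("sample size n must be a single integer >= 4")
  TRUE
})

#' Construct CorrelationData
#' @param values named numeric vector of correlations (names = interaction ids).
#' @param n integer sample size (>= 4).
#' @return A \linkS4class{CorrelationData}.
#' @export
correlationData <- function(values, n) {
  new("CorrelationData", values = values, n = as.integer(n))
}

#' ExpressionData: expression matrix plus identifier maps
#'
#' A measured-unit (probe or gene) by sample expression matrix together with
#' the two many-to-many maps needed to tie network nodes to expression rows:
#' a probe-to-gene map and a network-object-to-gene map.
#'
#' @slot exprs numeric matrix (rows = measured units, columns = samples).
#' @slot probeMap data.frame with columns \code{probe}, \code{gene}.
#' @slot objectMap data.frame with columns \code{node}, \code{gene}.
#' @export
setClass("ExpressionData",
  representation(exprs = "matrix", probeMap = "data.frame",
                 objectMap = "data.frame"))

setValidity("ExpressionData", function(object) {
  if (is.null(rownames(object@exprs)))
    return("exprs must have row names (measured unit ids)")
  if (anyDuplicated(colnames(object@exprs)) > 0L)
    return("sample (column) names must be unique")
  if (!all(c("probe", "gene") %in% names(object@probeMap)))
    return("probeMap needs columns probe, gene")
  if (!all(c("node", "gene") %in% names(object@objectMap)))
    return("objectMap needs columns node, gene")
  TRUE
})

#' Construct ExpressionData
#' @param exprs numeric matrix with row names.
#' @param probeMap data.frame (probe, gene); defaults to identity on rows.
#' @param objectMap data.frame (node, gene); defaults to identity on genes.
#' @return An \linkS4class{ExpressionData}.
#' @export
expressionData <- function(exprs, probeMap = NULL, objectMap = NULL) {
  exprs <- as.matrix(exprs)
  if (is.null(probeMap))
    probeMap <- data.frame(probe = rownames(exprs), gene = rownames(exprs),
                           stringsAsFactors = FALSE)
  if (is.null(objectMap))
    objectMap <- data.frame(node = unique(probeMap$gene),
                            gene = unique(probeMap$gene),
                            stringsAsFactors = FALSE)
  new("ExpressionData", exprs = exprs,
      probeMap = as.data.frame(probeMap), objectMap = as.data.frame(objectMap))
}

#' NoiseParams: parameters of the correlation noise model
#'
#' @slot rAlpha estimate of the active-class population correlation, in (0,1).
#' @slot n integer sample size.
#' @slot negativeMode \code{"signed"} or \code{"absolute"} handling of
#'   negative correlations.
#' @slot weighting \code{"posterior"} or \code{"rank"} weighting used when
#'   re-estimating rAlpha.
#' @export
setClass("NoiseParams",
  representation(rAlpha = "numeric", n = "integer",
                 negativeMode = "character", weighting = "character"))

setValidity("NoiseParams", function(object) {
  if (object@rAlpha <= 0 || object@rAlpha >= 1)
    return("rAlpha must lie in (0, 1)")
  if (object@n < 4L) return("n must be >= 4")
  if (!object@negativeMode %in% c("signed", "absolute"))
    return("negativeMode must be 'signed' or 'absolute'")
  if (!object@weighting %in% c("posterior", "rank"))
    return("weighting must be 'posterior' or 'rank'")
  TRUE
})

#' Construct NoiseParams
#' @param rAlpha active-class correlation estimate in (0,1).
#' @param n sample size (>= 4).
#' @param negativeMode "signed" or "absolute".
#' @param weighting "posterior" or "rank".
#' @return A \linkS4class{NoiseParams}.
#' @export
noiseParams <- function(rAlpha, n, negativeMode = "signed",
                        weighting = "posterior") {
  new("NoiseParams", rAlpha = rAlpha, n = as.integer(n),
      negativeMode = negativeMode, weighting = weighting)
}

#' MrfParams: virtual parent of MRF parameter sets
#' @export
setClass("MrfParams", representation("VIRTUAL"))

#' SingleParamPsi: Ising-style single-coupling MRF parameters
#'
#' The two-colour (active/non-active) potential with bias terms gamma0,
#' gamma1 and a single disagreement penalty beta shared by all neighbour
#' pairs.
#'
#' @slot gamma0,gamma1,beta numeric scalars.
#' @slot frozen named logical: parameters held fixed during fitting.
#' @slot atBound named logical: parameters clipped at a box bound by the fit.
#' @export
setClass("SingleParamPsi", contains = "MrfParams",
  representation(gamma0 = "numeric", gamma1 = "numeric", beta = "numeric",
                 frozen = "logical", atBound = "logical"))

#' Construct SingleParamPsi
#' @param gamma0,gamma1 state bias terms (defaults 1, 1).
#' @param beta disagreement coupling (default 2).
#' @param frozen,atBound named logical flags over c("gamma0","gamma1","beta").
#' @return A \linkS4class{SingleParamPsi}.
#' @export
singleParamPsi <- function(gamma0 = 1, gamma1 = 1, beta = 2,
                           frozen = NULL, atBound = NULL) {
  nm <- c("gamma0", "gamma1", "beta")
  if (is.null(frozen)) frozen <- setNames(rep(FALSE, 3L), nm)
  if (is.null(atBound)) atBound <- setNames(rep(FALSE, 3L), nm)
  new("SingleParamPsi", gamma0 = gamma0, gamma1 = gamma1, beta = beta,
      frozen = frozen, atBound = atBound)
}

#' FullParamPsi: mechanism-pair MRF parameters (reduced form)
#'
#' Bias terms per (mechanism, activity) pair -- or a single pair of global
#' biases when \code{biasMode = "global"} -- plus a symmetric coupling matrix
#' beta indexed by unordered mechanism pairs. The coupling penalizes
#' neighbouring interactions in opposite activity states; couplings across
#' activity levels carry no parameters of their own (the reduced
#' parameterization).
#'
#' @slot gamma numeric matrix, mechanisms x c("0","1") (rows identical in
#'   global bias mode).
#' @slot beta symmetric numeric matrix, mechanisms x mechanisms.
#' @slot biasMode \code{"global"} or \code{"per_mechanism"}.
#' @slot frozen logical matrix matching beta: couplings held at zero.
#' @slot atBound character vector of parameter labels clipped at a bound.
#' @export
setClass("FullParamPsi", contains = "MrfParams",
  representation(gamma = "matrix", beta = "matrix", biasMode = "character",
                 frozen = "matrix", atBound = "character"))

setValidity("FullParamPsi", function(object) {
  b <- object@beta
  if (!isTRUE(all.equal(b, t(b))))
    return("beta must be symmetric")
  if (!identical(dim(object@frozen), dim(b)))
    return("frozen must match beta's dimensions")
  if (!identical(colnames(object@gamma), c("0", "1")))
    return("gamma must have columns '0' and '1'")
  if (!identical(rownames(object@gamma), rownames(b)))
    return("gamma and beta must be indexed by the same mechanisms")
  if (!object@biasMode %in% c("global", "per_mechanism"))
    return("biasMode must be 'global' or 'per_mechanism'")
  TRUE
})

#' Construct FullParamPsi
#'
#' Defaults reproduce the standard initialization: every bias 1, couplings 2
#' on the diagonal (slight encouragement for same-mechanism neighbour pairs
#' to share a state) and 0 off the diagonal.
#'
#' @param mechanisms character vector of mechanism codes present.
#' @param gamma bias matrix (mechanisms x 2) or NULL for all-1.
#' @param beta symmetric coupling matrix or NULL for diag 2.
#' @param biasMode "global" or "per_mechanism".
#' @param frozen logical matrix or NULL (nothing frozen).
#' @return A \linkS4class{FullParamPsi}.
#' @export
fullParamPsi <- function(mechanisms, gamma = NULL, beta = NULL,
                         biasMode = "per_mechanism", frozen = NULL) {
  mechanisms <- canonicalMechanism(mechanisms)
  k <- length(mechanisms)
  if (is.null(gamma))
    gamma <- matrix(1, k, 2L, dimnames = list(mechanisms, c("0", "1")))
  if (is.null(beta)) {
    beta <- diag(2, k)
    dimnames(beta) <- list(mechanisms, mechanisms)
  }
  if (is.null(frozen))
    frozen <- matrix(FALSE, k, k, dimnames = dimnames(beta))
  new("FullParamPsi", gamma = gamma, beta = beta, biasMode = biasMode,
      frozen = frozen, atBound = character(0L))
}

#' EmResult: output of active-subnetwork inference
#'
#' @slot posteriors named numeric: posterior probability of the active state
#'   per interaction.
#' @slot states named integer in \{0,1\}: thresholded activity calls
#'   (posterior > 0.5 is active).
#' @slot theta \linkS4class{NoiseParams} at termination.
#' @slot psi fitted MRF parameters (NULL for the ML baseline).
#' @slot iterations integer iteration count.
#' @slot converged,runaway logical flags; runaway reinforcement means all
#'   interactions collapsed to one state.
#' @slot trace data.frame with per-iteration expected complete-data
#'   log-likelihood, state-change counts and rAlpha.
#' @slot method character label ("full", "single" or "ml").
#' @export
setClass("EmResult",
  representation(posteriors = "numeric", states = "integer",
                 theta = "NoiseParams", psi = "ANY",
                 iterations = "integer", converged = "logical",
                 runaway = "logical", trace = "data.frame",
                 method = "character"))

setValidity("EmResult", function(object) {
  p <- object@posteriors
  if (any(p < 0 | p > 1)) return("posteriors must lie in [0, 1]")
  if (!identical(names(p), names(object@states)))
    return("posteriors and states must share names")
  if (!identical(unname(object@states), as.integer(unname(p) > 0.5)))
    return("states must equal as.integer(posteriors > 0.5)")
  TRUE
})

#' SimulationTruth: a generated benchmark instance
#'
#' @slot network the generated \linkS4class{InteractionNetwork}.
#' @slot pathwayIds interaction ids forming the pathway core (the remainder
#'   are expansion interactions).
#' @slot trueActive interaction ids of the true active subnetwork I*.
#' @export
setClass("SimulationTruth",
  representation(network = "InteractionNetwork", pathwayIds = "character",
                 trueActive = "character"))

setValidity("SimulationTruth", function(object) {
  ids <- object@network@interactions$id
  if (!all(object@pathwayIds %in% ids))
    return("pathwayIds must be interaction ids of the network")
  if (!all(object@trueActive %in% ids))
    return("trueActive must be interaction ids of the network")
  TRUE
})
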