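#' Neighbouring interactions
#'
#' Returns the ids of all interactions sharing a source or target node with
#' the given interaction (the line-graph neighbourhood), excluding the
#' interaction itself.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param id an interaction id present in \code{net}.
#' @return Character vector of neighbouring interaction ids.
#' @export
interactionNeighbors <- function(net, id) {
  if (!id %in% names(net@adjacency))
    stop("unknown interaction id: ", id)
  net@adjacency[[id]]
}

## Ordered neighbour-pair index: one row (i, j) per directed neighbour pair,
## as integer positions into the interaction table.
.pairIndex <- function(net) {
  ids <- net@interactions$id
  deg <- lengths(net@adjacency[ids])
  i <- rep(seq_along(ids), deg)
  j <- match(unlist(net@adjacency[ids], use.names = FALSE), ids)
  cbind(i = i, j = j)
}

## Keep a subset of interactions (by id), rebuilding adjacency.
.subsetNetwork <- function(net, keepIds) {
  df <- net@interactions
  df <- df[df$id %in% keepIds, , drop = FALSE]
  rownames(df) <- NULL
  new("InteractionNetwork", nodes = net@nodes, interactions = df,
      adjacency = .buildAdjacency(df))
}

#' Per-interaction Spearman correlations from expression data
#'
#' Computes, for every interaction, the Spearman rank correlation between
#' the expression profiles of its two endpoints. Network nodes map to genes
#' through the object map and genes to expression rows through the probe
#' map; multi-mapping is resolved by \code{\link{aggregateEdgeCorrelation}}:
#' a gene with several candidate rows is represented by the row with the
#' largest mean correlation against the other candidate rows in the
#' network, and a node matching several genes contributes the mean of the
#' per-gene-pair correlations. Interactions whose endpoints have a constant
#' profile (undefined rank correlation) get NA and are reported.
#'
#' @param expr an \linkS4class{ExpressionData}.
#' @param net an \linkS4class{InteractionNetwork}.
#' @param absolute logical; if TRUE, probe selection uses absolute
#'   correlations (default FALSE, signed).
#' @return A \linkS4class{CorrelationData} with n = number of samples.
#' @export
edgeCorrelations <- function(expr, net, absolute = FALSE) {
  if (ncol(expr@exprs) < 4L)
    stop("need at least 4 samples/time points")
  om <- expr@objectMap
  pm <- expr@probeMap
  nodes <- unique(c(net@interactions$source, net@interactions$target))
  geneSets <- lapply(setNames(nodes, nodes),
                     function(v) unique(om$gene[om$node == v]))
  if (any(none <- lengths(geneSets) == 0L))
    stop("network node(s) with no mapped gene: ",
         paste(nodes[none], collapse = ", "))
  genes <- unique(unlist(geneSets))
  rowSets <- lapply(setNames(genes, genes), function(g) {
    p <- unique(pm$probe[pm$gene == g])
    p[p %in% rownames(expr@exprs)]
  })
  if (any(none <- lengths(rowSets) == 0L))
    stop("gene(s) with no expression row: ",
         paste(genes[none], collapse = ", "))
  allRows <- unique(unlist(rowSets))
  constant <- vapply(allRows,
                     function(p) sd(expr@exprs[p, ]) == 0, logical(1L))
  cm <- suppressWarnings(
    cor(t(expr@exprs[allRows, , drop = FALSE]), method = "spearman"))
  agg <- aggregateEdgeCorrelation(rowSets, cm, absolute = absolute)
  reprRow <- agg$representative                       # gene -> selected row
  ints <- net@interactions
  vals <- vapply(seq_len(nrow(ints)), function(i) {
    gu <- geneSets[[ints$source[i]]]
    gv <- geneSets[[ints$target[i]]]
    ru <- reprRow[gu]; rv <- reprRow[gv]
    if (any(constant[ru]) || any(constant[rv])) return(NA_real_)
    mean(cm[ru, rv, drop = FALSE])
  }, numeric(1L))
  names(vals) <- ints$id
  if (anyNA(vals))
    warning("undefined Spearman correlation (constant profile) for ",
            sum(is.na(vals)), " interaction(s); flagged as missing")
  correlationData(vals, ncol(expr@exprs))
}

#' Representative-row selection and edge aggregation
#'
#' For each gene with multiple candidate expression rows, selects the row
#' maximizing the mean correlation against all other candidate rows in the
#' network; single-row genes are selected unconditionally. Used to resolve
#' probe-level multi-mapping before per-edge correlations are formed.
#'
#' @param candidateRows named list: gene id -> character vector of candidate
#'   row ids.
#' @param corrMatrix square correlation matrix over all candidate rows.
#' @param absolute logical; rank rows by absolute mean correlation.
#' @return List with \code{representative} (named character: gene ->
#'   selected row) and \code{edgeValue}, a function(genesU, genesV) giving
#'   the mean correlation over the selected per-gene-pair values.
#' @export
aggregateEdgeCorrelation <- function(candidateRows, corrMatrix,
                                     absolute = FALSE) {
  if (any(lengths(candidateRows) == 0L))
    stop("empty candidate row set for gene(s): ",
         paste(names(candidateRows)[lengths(candidateRows) == 0L],
               collapse = ", "))
  allRows <- unique(unlist(candidateRows))
  stopifnot(all(allRows %in% rownames(corrMatrix)),
            identical(rownames(corrMatrix), colnames(corrMatrix)))
  reprRow <- vapply(candidateRows, function(p) {
    if (length(p) == 1L) return(p)
    others <- setdiff(allRows, p)
    score <- vapply(p, function(pr) {
      v <- corrMatrix[pr, others]
      if (absolute) v <- abs(v)
      mean(v)
    }, numeric(1L))
    p[which.max(score)]
  }, character(1L))
  edgeValue <- function(genesU, genesV)
    mean(corrMatrix[reprRow[genesU], reprRow[genesV], drop = FALSE])
  list(representative = reprRow, edgeValue = edgeValue)
}

#' Artificial correlation score from significance calls
#'
#' Scores an interaction from the binary significance vectors of its two
#' endpoint genes over the time points: if neither gene is significant at
#' any time point the score is 0; otherwise the score is
#' \code{0.4 + subscore/10}, where subscore counts the time points at which
#' both genes are significant. With 4 time points the score ladder is
#' \{0\} union \{0.4, 0.5, ..., 0.8\}.
#'
#' @param sigA,sigB binary (0/1 or logical) vectors of equal length.
#' @return Numeric score.
#' @export
#' @examples
#' artificialCorrelationScore(c(1, 1, 0, 0), c(1, 1, 1, 0))  # 0.6
artificialCorrelationScore <- function(sigA, sigB) {
  if (length(sigA) != length(sigB))
    stop("significance vectors must have equal length")
  a <- as.integer(as.logical(sigA))
  b <- as.integer(as.logical(sigB))
  if (!all(a %in% 0:1) || !all(b %in% 0:1) || anyNA(a) || anyNA(b))
    stop("significance vectors must be binary")
  if (all(a == 0L) && all(b == 0L)) return(0)
  0.4 + sum(a & b) / 10
}
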