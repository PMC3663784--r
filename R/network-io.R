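#' Read a SIF network with edge mechanism attributes
#'
#' Reads a Cytoscape-style SIF file (whitespace-delimited
#' \code{source relation target} lines; a single-token line declares an
#' isolated node) together with an edge attribute table assigning each
#' interaction one of the ten mechanism codes. Every SIF edge must be
#' covered by the attribute table; uncovered edges raise an error naming
#' the offending edge keys.
#'
#' The attribute file is either (a) a tab-separated table with a header and
#' columns \code{source}, \code{target}, \code{mechanism} (an optional
#' \code{relation} column is ignored for matching), or (b) the Cytoscape
#' \code{.eda} dialect of lines \code{source (relation) target = VALUE}.
#' A node pair listed k times in the SIF (parallel interactions) may carry
#' either a single attribute row (applied to all k) or exactly k rows
#' (matched in order). The same edge key listed twice with conflicting
#' mechanisms while the SIF has a single such edge is an error.
#'
#' @param sifPath path to the SIF file.
#' @param mechanismAttrPath path to the mechanism attribute file.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
readNetwork <- function(sifPath, mechanismAttrPath) {
  lines <- readLines(sifPath)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[ \t]+")
  nt <- lengths(toks)
  if (any(bad <- !(nt %in% c(1L, 3L))))
    stop("malformed SIF line(s) (expected 1 or 3 tokens): ",
         paste(lines[bad], collapse = "; "))
  iso <- vapply(toks[nt == 1L], `[[`, character(1L), 1L)
  et <- toks[nt == 3L]
  src <- vapply(et, `[[`, character(1L), 1L)
  rel <- vapply(et, `[[`, character(1L), 2L)
  tgt <- vapply(et, `[[`, character(1L), 3L)

  attrs <- readEdgeAttributes(mechanismAttrPath)
  key <- paste(src, tgt, sep = "\r")
  akey <- paste(attrs$source, attrs$target, sep = "\r")

  missing <- setdiff(key, akey)
  if (length(missing))
    stop("edge(s) missing from the mechanism attribute file: ",
         paste(gsub("\r", "-", unique(missing)), collapse = ", "))

  mech <- character(length(src))
  for (k in unique(key)) {
    ei <- which(key == k)
    ai <- which(akey == k)
    mk <- unique(attrs$mechanism[ai])
    if (length(mk) == 1L) {
      mech[ei] <- mk
      next
    }
    if (length(ei) == 1L)
      stop("duplicate edge key with conflicting mechanisms: ",
           gsub("\r", "-", k))
    ## parallel SIF edges: prefer the relation column when it names the
    ## mechanisms, otherwise pair attribute rows to edges in order
    relMech <- tryCatch(canonicalMechanism(rel[ei]),
                        error = function(e) NULL)
    if (!is.null(relMech) && all(relMech %in% mk)) {
      mech[ei] <- relMech
    } else if (length(mk) == length(ei)) {
      mech[ei] <- mk
    } else {
      stop("cannot match ", length(mk), " attribute rows to ", length(ei),
           " SIF edges for ", gsub("\r", "-", k))
    }
  }
  interactionNetwork(src, tgt, mech, nodes = iso)
}

#' Read an edge mechanism attribute table
#'
#' Accepts the tab-separated (source, target, mechanism) table or the
#' Cytoscape \code{.eda} dialect \code{source (relation) target = VALUE};
#' the dialect is auto-detected. Mechanisms are canonicalized
#' (\code{"Tr"} to \code{"TR"}) and validated.
#'
#' @param path path to the attribute file.
#' @return data.frame with columns source, target, mechanism.
#' @export
readEdgeAttributes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  edaLike <- grepl("\\(.*\\).* = ", lines)
  if (length(lines) > 1L && all(edaLike[-1L])) {
    ## .eda dialect; first line may be a title such as "mechanism"
    body <- if (edaLike[1L]) lines else lines[-1L]
    m <- regmatches(body,
        regexec("^\\s*(\\S+)\\s+\\((.*)\\)\\s+(\\S+)\\s*=\\s*(\\S+)\\s*$",
                body))
    bad <- lengths(m) != 5L
    if (any(bad))
      stop("malformed .eda line(s): ", paste(body[bad], collapse = "; "))
    df <- data.frame(source = vapply(m, `[[`, character(1L), 2L),
                     target = vapply(m, `[[`, character(1L), 4L),
                     mechanism = vapply(m, `[[`, character(1L), 5L),
                     stringsAsFactors = FALSE)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "",
                     quote = "")
    need <- c("source", "target", "mechanism")
    if (!all(need %in% names(df)))
      stop("attribute table needs columns: ", paste(need, collapse = ", "))
    df <- df[, need]
  }
  df$mechanism <- canonicalMechanism(df$mechanism)
  dup <- paste(df$source, df$target, df$mechanism)
  df <- df[!duplicated(dup), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a network as SIF plus mechanism attribute table
#'
#' The relation column of the SIF carries the mechanism code, so
#' \code{readNetwork(writeNetwork(net))} round-trips the interaction set,
#' mechanisms and adjacency.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param sifPath,attrPath output paths.
#' @return Invisibly, \code{net}.
#' @export
writeNetwork <- function(net, sifPath, attrPath) {
  df <- net@interactions
  writeLines(c(paste(df$source, df$mechanism, df$target),
               setdiff(net@nodes, c(df$source, df$target))), sifPath)
  write.table(df[, c("source", "target", "mechanism")], attrPath,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(net)
}

#' Read a per-interaction correlation table
#'
#' Reads a tab-separated table with header columns \code{source},
#' \code{target}, \code{r} and matches rows to the interactions of
#' \code{net} by node pair (a pair with parallel interactions applies its
#' value to each of them).
#'
#' @param path path to the TSV file.
#' @param net the \linkS4class{InteractionNetwork} the values belong to.
#' @param n sample size (number of time points) behind each correlation.
#' @return A \linkS4class{CorrelationData} covering all interactions of
#'   \code{net} (unmatched interactions get NA with a warning).
#' @export
readCorrelations <- function(path, net, n) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "")
  need <- c("source", "target", "r")
  if (!all(need %in% names(df)))
    stop("correlation table needs columns: ", paste(need, collapse = ", "))
  ints <- net@interactions
  key <- paste(ints$source, ints$target, sep = "\r")
  akey <- paste(df$source, df$target, sep = "\r")
  vals <- setNames(df$r[match(key, akey)], ints$id)
  if (anyNA(vals))
    warning(sum(is.na(vals)),
            " interaction(s) without a correlation value; flagged as missing")
  correlationData(vals, n)
}

#' Read an expression matrix and identifier maps
#'
#' The matrix is a TSV whose first column holds the measured-unit (probe or
#' gene) ids and whose remaining columns are samples/time points. Maps are
#' two-column TSVs with headers.
#'
#' @param exprsPath path to the expression TSV.
#' @param probeMapPath optional path to a (probe, gene) TSV.
#' @param objectMapPath optional path to a (node, gene) TSV.
#' @return An \linkS4class{ExpressionData}.
#' @export
readExpressionMatrix <- function(exprsPath, probeMapPath = NULL,
                                 objectMapPath = NULL) {
  df <- read.table(exprsPath, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "",
                   check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  readMap <- function(p, cols) {
    x <- read.table(p, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
    stats::setNames(x[, seq_len(2L)], cols)
  }
  expressionData(m,
    probeMap = if (!is.null(probeMapPath))
      readMap(probeMapPath, c("probe", "gene")) else NULL,
    objectMap = if (!is.null(objectMapPath))
      readMap(objectMapPath, c("node", "gene")) else NULL)
}

#' Write inference results as a states table
#'
#' Writes the standard per-interaction output schema: source, target,
#' mechanism, r, posterior_active, state.
#'
#' @param result an \linkS4class{EmResult}.
#' @param net the \linkS4class{InteractionNetwork} analysed.
#' @param corr the \linkS4class{CorrelationData} analysed.
#' @param path output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
writeStatesTable <- function(result, net, corr, path) {
  df <- net@interactions
  df <- df[match(names(result@states), df$id), ]
  out <- data.frame(source = df$source, target = df$target,
                    mechanism = df$mechanism,
                    r = unname(corr@values[df$id]),
                    posterior_active = unname(result@posteriors),
                    state = unname(result@states),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
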