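#' @import methods
#' @importFrom stats cor optim pnorm pt rnorm runif plogis rbinom sd setNames
#' @importFrom utils read.table write.table
NULL

## Controlled vocabulary of interaction mechanisms (Metacore symbols).
.MECHANISMS <- c("B", "C", "CM", "+P", "-P", "T", "Tn", "Z", "TR", "M")

#' Interaction mechanism vocabulary
#'
#' The ten-symbol controlled vocabulary for interaction mechanisms used
#' throughout the package: binding (B), cleavage (C), covalent modification
#' (CM), phosphorylation (+P), dephosphorylation (-P), transformation (T),
#' transport (Tn), catalysis (Z), transcription regulation (TR) and
#' microRNA binding (M).
#'
#' @return Character vector of the ten mechanism codes.
#' @export
#' @examples
#' mechanismCodes()
mechanismCodes <- function() .MECHANISMS

#' Canonicalize mechanism codes
#'
#' Maps the alternative spelling \code{"Tr"} to \code{"TR"} and validates
#' codes against the ten-element mechanism vocabulary.
#'
#' @param x character vector of mechanism codes.
#' @return Character vector of canonical codes.
#' @export
canonicalMechanism <- function(x) {
  x <- as.character(x)
  x[x == "Tr"] <- "TR"
  bad <- setdiff(unique(x), .MECHANISMS)
  if (length(bad))
    stop("unknown mechanism code(s): ", paste(bad, collapse = ", "))
  x
}

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## k reproducible child seeds (kept below 2^31) derived from one seed.
subSeeds <- function(seed, k) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

## Sum `v` grouped by integer index `idx` into a length-n vector (zeros for
## empty groups).
.groupSum <- function(v, idx, n) {
  out <- numeric(n)
  if (length(v)) {
    s <- rowsum(v, idx)
    out[as.integer(rownames(s))] <- s
  }
  out
}

## log(1 / (1 + exp(-x))), branch-free and safe for large |x|:
## log sigma(x) = min(x, 0) - log1p(exp(-|x|)).
.logSigmoid <- function(x) {
  pmin(x, 0) - log1p(exp(-abs(x)))
}

## sum_i p_i log sigma(d_i) + (1 - p_i) log sigma(-d_i), using
## log sigma(-d) = log sigma(d) - d.
.bernLogLik <- function(p, d) {
  ls <- .logSigmoid(d)
  sum(ls) - sum((1 - p) * d)
}
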