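# Internal indexing conventions
#
# A vertex X_ih (variable i in layer h) is stored as the integer
# vid = (h - 1) * nVars + i, 1-based.  A configuration over nV vertices with
# nS labels is stored as the integer m in 1..nS^nV, little-endian mixed
# radix: the label index of vertex v in configuration m is
# ((m - 1) %/% nS^(v - 1)) %% nS + 1.  All arithmetic is done in doubles,
# which is exact for the enumerable spaces this package admits (<= 2^20
# configurations).

.vid <- function(var, layer, nVars) (layer - 1L) * nVars + var

.vidVar <- function(vid, nVars) (vid - 1L) %% nVars + 1L

.vidLayer <- function(vid, nVars) (vid - 1L) %/% nVars + 1L

#' @noRd
.configLabels <- function(m, v, nS) {
  # label indices (1..nS) of vertex v in configuration(s) m (vectorised in m)
  ((m - 1) %/% nS^(v - 1)) %% nS + 1
}

#' Index vector mapping each full configuration to its restriction
#'
#' For a vertex subset, returns for every full configuration index
#' m = 1..nS^nV the index (1..nS^|subset|) of the restricted configuration,
#' with the subset's own little-endian ordering.
#' @noRd
.restrictionIndex <- function(nV, nS, subset) {
  m <- seq_len(nS^nV)
  if (length(subset) == 0L) return(rep(1, length(m)))
  idx <- rep(1, length(m))
  for (t in seq_along(subset)) {
    idx <- idx + (.configLabels(m, subset[t], nS) - 1) * nS^(t - 1)
  }
  idx
}

#' Marginal probability vector of a subset, by exact summation
#' @noRd
.marginal <- function(prob, nV, nS, subset) {
  if (length(subset) == 0L) return(sum(prob))
  idx <- .restrictionIndex(nV, nS, subset)
  as.vector(rowsum(prob, idx))
}

#' Enumerate restricted configurations of a subset as a |subset| x nS^|subset|
#' matrix of label indices
#' @noRd
.restrictedConfigs <- function(nS, k) {
  if (k == 0L) return(matrix(integer(0), nrow = 0, ncol = 1))
  m <- seq_len(nS^k)
  out <- matrix(0L, nrow = k, ncol = length(m))
  for (t in seq_len(k)) out[t, ] <- as.integer(.configLabels(m, t, nS))
  out
}

.logSumExp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Deterministic substream seeds derived from one scenario seed
#'
#' Streams: 1 graph, 2 potentials, 3 sampling, 4 noise, 5 permutations.
#' Kept below 2^31 so they are valid R integer seeds.
#' @noRd
.subSeeds <- function(seed, n = 5L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run an expression under a temporary RNG seed, restoring global RNG state
#' @noRd
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
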