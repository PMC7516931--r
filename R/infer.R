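#' One-call mutual-information network inference
#'
#' Discretises a multilayer sample tensor, computes the off-diagonal MI
#' hypermatrix, picks the significance threshold (a fixed `i0` or a
#' permutation-null quantile) and emits the adjacency and strength
#' hypermatrices, i.e. the inferred neighbourhood law of the tensor Markov
#' field underlying the data.
#'
#' @param data a [SampleTensor-class].
#' @param nBins discretisation bins (default 10).
#' @param i0 fixed MI threshold in bits; give either `i0` or `alpha`.
#' @param alpha permutation-null significance level (used when `i0` is NULL).
#' @param nPerm permutations for the null (default 100).
#' @param seed integer seed for the permutation null.
#' @return list with `mi`, `adjacency`, `strength` ([Hypermatrix-class]
#'   objects), `threshold` (bits) and `graph` (the inferred
#'   [MultilayerGraph-class]).
#' @examples
#' sc <- makeScenario(nSamples = 500, seed = 3)
#' fit <- inferNetwork(scenarioSamples(sc), alpha = 0.05, nPerm = 50, seed = 3)
#' fit$threshold
#' @export
inferNetwork <- function(data, nBins = 10L, i0 = NULL, alpha = 0.05,
                         nPerm = 100L, seed = 1L) {
  if (!is.null(i0) && !missing(alpha) && !is.null(alpha)) {
    .stopf("give either a fixed threshold i0 or a permutation level alpha, not both")
  }
  mi <- miMatrix(data, nBins = nBins)
  thr <- if (!is.null(i0)) {
    as.numeric(i0)
  } else {
    permutationThreshold(data, nPerm = nPerm, alpha = alpha, nBins = nBins,
                         seed = seed)
  }
  adj <- adjacencyHypermatrix(mi, thr)
  list(mi = mi, adjacency = adj, strength = strengthHypermatrix(adj, mi),
       threshold = thr, graph = graphFromHypermatrix(adj))
}

#' F1 score of a recovered edge set against a planted truth
#'
#' Harmonic mean of edge precision and recall.  Two graphs with empty edge
#' sets score 1 (nothing to recover, nothing invented).
#'
#' @param truth,inferred [MultilayerGraph-class] objects on the same vertex
#'   set.
#' @return numeric in [0, 1].
#' @export
edgeRecoveryF1 <- function(truth, inferred) {
  key <- function(g) paste(g@edges[, 1L], g@edges[, 2L])
  kt <- key(truth)
  ki <- key(inferred)
  tp <- sum(ki %in% kt)
  if (length(kt) == 0L && length(ki) == 0L) return(1)
  if (tp == 0L) return(0)
  2 * tp / (2 * tp + (length(ki) - tp) + (length(kt) - tp))
}
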