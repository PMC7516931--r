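# Plug-in (maximum-likelihood) mutual information in bits, on discrete codes
.miCodes <- function(x, y) {
  nx <- max(x)
  ny <- max(y)
  n <- length(x)
  jm <- matrix(tabulate((y - 1L) * nx + x, nx * ny), nx, ny) / n
  px <- rowSums(jm)
  py <- colSums(jm)
  nz <- jm > 0
  sum(jm[nz] * log2(jm[nz] / outer(px, py)[nz]))
}

#' Plug-in mutual information of two discrete sample vectors
#'
#' The maximum-likelihood estimate, in bits:
#' sum over observed joint cells of p(x, y) log2[ p(x, y) / (p(x) p(y)) ].
#' Exactly zero when the empirical joint factorises; symmetric in its
#' arguments; invariant under relabelling of the codes.
#'
#' @param x,y equal-length vectors of discrete values (any codes; factors of
#'   the unique values are taken).
#' @return non-negative numeric, bits.
#' @examples
#' x <- rep(c(0, 1), each = 5)
#' mutualInformation(x, x)  # H(X) = 1 bit
#' @export
mutualInformation <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (length(x) < 2L) .stopf("need at least two samples")
  .miCodes(match(x, sort(unique(x))), match(y, sort(unique(y))))
}

#' Equal-frequency discretisation
#'
#' Bins a real vector into `nBins` classes of (as near as possible) equal
#' occupancy, by rank; ties are broken by stable sample order, so the codes
#' are invariant under any strictly increasing transform of the data.
#' Inputs that already take at most `nBins` distinct values are relabelled
#' to 1..k preserving value order (a constant vector yields a single bin,
#' with a warning).
#'
#' @param x numeric vector.
#' @param nBins number of bins (>= 2).
#' @return integer codes in 1..nBins.
#' @export
discretize <- function(x, nBins = 10L) {
  nBins <- as.integer(nBins)
  if (nBins < 2L) .stopf("nBins must be >= 2")
  u <- sort(unique(x))
  if (length(u) == 1L) {
    warning("constant vector: single-bin output", call. = FALSE)
    return(rep(1L, length(x)))
  }
  if (length(u) <= nBins) return(match(x, u))
  as.integer(ceiling(rank(x, ties.method = "first") * nBins / length(x)))
}

.hypermatrix <- function(values, kind, varNames, layerNames) {
  new("Hypermatrix", values = values, kind = kind,
      varNames = varNames, layerNames = layerNames)
}

#' @name hypermatrix-values
#' @title Raw 4-index array of a hypermatrix
#' @param x a [Hypermatrix-class].
#' @return numeric array, dim c(N, N, L, L); entry `[i, j, h, k]` refers to
#'   the vertex pair (variable i, layer h) -- (variable j, layer k).
NULL

#' @rdname hypermatrix-values
#' @export
setMethod("hmValues", "Hypermatrix", function(x) x@values)

#' @rdname MultilayerGraph-accessors
#' @export
setMethod("nVars", "Hypermatrix", function(x) dim(x@values)[1L])
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("nLayers", "Hypermatrix", function(x) dim(x@values)[3L])
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("varNames", "Hypermatrix", function(x) x@varNames)
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("layerNames", "Hypermatrix", function(x) x@layerNames)

setMethod("show", "Hypermatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("Hypermatrix (%s): %d variables x %d layers, %d nonzero entry pairs\n",
              object@kind, d[1L], d[3L], sum(object@values != 0) / 2))
})

#' Off-diagonal mutual-information hypermatrix
#'
#' Computes the plug-in mutual information (bits) between every unordered
#' pair of vertex columns of a sample tensor, after equal-frequency
#' discretisation, mirrors it by the tensor symmetry
#' `I[i,j,h,k] = I[j,i,k,h]`, and forces the bi-diagonal `I[i,i,h,h]` to
#' zero (self-information is discarded; cross-layer pairs of the same
#' variable index are NOT masked).
#'
#' @param data a [SampleTensor-class].
#' @param nBins discretisation bins (default 10).
#' @return a [Hypermatrix-class] of kind `"mi"`.
#' @export
miMatrix <- function(data, nBins = 10L) {
  N <- nVars(data)
  L <- nLayers(data)
  nV <- N * L
  codes <- lapply(seq_len(nV), function(v) {
    discretize(data@values[, .vidVar(v, N), .vidLayer(v, N)], nBins)
  })
  arr <- array(0, dim = c(N, N, L, L))
  if (nV >= 2L) {
    for (a in seq_len(nV - 1L)) {
      for (b in (a + 1L):nV) {
        mi <- .miCodes(codes[[a]], codes[[b]])
        i <- .vidVar(a, N); h <- .vidLayer(a, N)
        j <- .vidVar(b, N); k <- .vidLayer(b, N)
        arr[i, j, h, k] <- mi
        arr[j, i, k, h] <- mi
      }
    }
  }
  .hypermatrix(arr, "mi", data@varNames, data@layerNames)
}

#' Threshold a mutual-information hypermatrix into an adjacency hypermatrix
#'
#' Applies the Heaviside rule `A[i,j,h,k] = 1 iff I[i,j,h,k] > i0` (strict
#' exceedance: an entry exactly at the threshold is excluded, so the rule is
#' deterministic and raising `i0` never adds edges).
#'
#' @param mi a [Hypermatrix-class] of kind `"mi"` (or any non-negative one).
#' @param i0 significance threshold for mutual information, bits (>= 0).
#' @return a binary [Hypermatrix-class] of kind `"adjacency"`.
#' @export
adjacencyHypermatrix <- function(mi, i0) {
  if (i0 < 0) .stopf("i0 must be non-negative")
  .hypermatrix((mi@values > i0) + 0, "adjacency", mi@varNames, mi@layerNames)
}

#' Strength hypermatrix: MI restricted to the adjacency support
#'
#' Elementwise product `W = A * I`, i.e. the weighted neighbourhood law that
#' keeps each surviving pair's mutual information as its edge strength.
#'
#' @param a a binary adjacency [Hypermatrix-class].
#' @param mi the matching MI [Hypermatrix-class].
#' @return a [Hypermatrix-class] of kind `"strength"`.
#' @export
strengthHypermatrix <- function(a, mi) {
  if (!identical(dim(a@values), dim(mi@values))) {
    .stopf("adjacency and MI hypermatrices have different shapes")
  }
  .hypermatrix(a@values * mi@values, "strength", mi@varNames, mi@layerNames)
}

#' Permutation null threshold for mutual-information significance
#'
#' Builds an empirical null of independence by recomputing the MI of every
#' unordered column pair after independently permuting the sample order of
#' one column, `nPerm` times, and returns the (1 - alpha) quantile of the
#' pooled null values.  An edge whose MI exceeds this threshold is unlikely
#' under column independence at level alpha.
#'
#' @param data a [SampleTensor-class].
#' @param nPerm number of permutations per pair (>= 20, default 100).
#' @param alpha significance level in (0, 1) (default 0.05).
#' @param nBins discretisation bins (default 10).
#' @param seed integer seed (reproducible threshold).
#' @return non-negative numeric threshold, bits.
#' @export
permutationThreshold <- function(data, nPerm = 100L, alpha = 0.05,
                                 nBins = 10L, seed = 1L) {
  if (nPerm < 20L) .stopf("nPerm must be at least 20")
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must be in (0, 1)")
  N <- nVars(data)
  nV <- N * nLayers(data)
  codes <- lapply(seq_len(nV), function(v) {
    discretize(data@values[, .vidVar(v, N), .vidLayer(v, N)], nBins)
  })
  n <- nSamples(data)
  .withSeed(seed, {
    null <- numeric(0)
    for (a in seq_len(nV - 1L)) {
      for (b in (a + 1L):nV) {
        vals <- vapply(seq_len(nPerm), function(r) {
          .miCodes(codes[[a]], codes[[b]][sample.int(n)])
        }, numeric(1L))
        null <- c(null, vals)
      }
    }
    as.numeric(stats::quantile(null, 1 - alpha))
  })
}

#' Write inferred edges as a weighted TSV edge list
#'
#' One row per unordered vertex pair in canonical order, columns
#' `var_a layer_a var_b layer_b mi adjacency`; by default only pairs present
#' in the adjacency hypermatrix are written.
#'
#' @param mi MI [Hypermatrix-class].
#' @param adj adjacency [Hypermatrix-class].
#' @param path output file.
#' @param all write all pairs (TRUE) or only adjacent ones (FALSE, default).
#' @return `path`, invisibly.
#' @export
writeMIEdges <- function(mi, adj, path, all = FALSE) {
  N <- nVars(mi)
  nV <- N * nLayers(mi)
  rows <- list()
  for (a in seq_len(max(nV - 1L, 0L))) {
    for (b in (a + 1L):nV) {
      i <- .vidVar(a, N); h <- .vidLayer(a, N)
      j <- .vidVar(b, N); k <- .vidLayer(b, N)
      if (!all && adj@values[i, j, h, k] == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        var_a = mi@varNames[i], layer_a = mi@layerNames[h],
        var_b = mi@varNames[j], layer_b = mi@layerNames[k],
        mi = mi@values[i, j, h, k],
        adjacency = adj@values[i, j, h, k],
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(var_a = character(0), layer_a = character(0),
               var_b = character(0), layer_b = character(0),
               mi = numeric(0), adjacency = numeric(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dump a hypermatrix as 5-column coordinate text
#'
#' Nonzero entries only, columns `i j h k value`, canonical (i, j, h, k)
#' order, 1-based indices.
#'
#' @param hm a [Hypermatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHypermatrixCoords <- function(hm, path) {
  nz <- which(hm@values != 0, arr.ind = TRUE)
  df <- data.frame(i = nz[, 1L], j = nz[, 2L], h = nz[, 3L], k = nz[, 4L],
                   value = hm@values[nz])
  df <- df[order(df$i, df$j, df$h, df$k), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
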