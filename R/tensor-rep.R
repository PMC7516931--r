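# Adjacency 4-tensor summaries.  The hypermatrix with its declared index
# roles (i, j over variables; h, k over layers) IS the multilayer adjacency
# tensor: contractions with all-ones tensors are implemented directly, so no
# unit tensor is ever materialised.  Each undirected edge contributes 1 to
# the contraction at each of its endpoints (intra- and inter-layer edges are
# counted alike).

#' Multidegree centrality vector
#'
#' Full contraction of the adjacency tensor over the partner variable and
#' both layer indices: `K[i] = sum_{j,h,k} A[i,j,h,k]`, the total
#' connectivity of variable i across all layers.  Weighted tensors are
#' allowed and yield strength totals.
#'
#' @param a a [Hypermatrix-class].
#' @return numeric vector of length N, named by variable.
#' @export
multidegreeCentrality <- function(a) {
  stats::setNames(apply(a@values, 1L, sum), a@varNames)
}

#' Layer-pair connectivity degree vector
#'
#' `k[i](h, k) = sum_j A[i,j,h,k]`: the connections that variable i has in
#' layer h towards any variable in layer k.  Summing over all ordered layer
#' pairs recovers the multidegree centrality exactly.
#'
#' @param a a [Hypermatrix-class].
#' @param h,k layer indices or names.
#' @return numeric vector of length N, named by variable.
#' @export
layerPairDegree <- function(a, h, k) {
  if (is.character(h)) h <- match(h, a@layerNames)
  if (is.character(k)) k <- match(k, a@layerNames)
  L <- nLayers(a)
  if (is.na(h) || is.na(k) || h < 1L || h > L || k < 1L || k > L) {
    .stopf("layer index out of range [1, %d]", L)
  }
  N <- nVars(a)
  stats::setNames(rowSums(matrix(a@values[, , h, k], N, N)), a@varNames)
}

#' Neighbourhood (Markov blanket) size of one vertex
#'
#' `|N(X_ih)| = sum_{j,k} A[i,j,h,k]` for a binary adjacency tensor; equals
#' the Markov-blanket size of the corresponding multilayer-graph vertex.
#' Weighted tensors are refused (sizes are counts).
#'
#' @param a a binary adjacency [Hypermatrix-class].
#' @param v vertex id (see [nodeId()]).
#' @return non-negative integer.
#' @export
neighborhoodSize <- function(a, v) {
  if (!all(a@values %in% c(0, 1))) {
    .stopf("neighbourhood sizes are counts; supply a binary adjacency tensor")
  }
  N <- nVars(a)
  i <- .vidVar(v, N)
  h <- .vidLayer(v, N)
  as.integer(sum(a@values[i, , h, ]))
}

#' Convert between multilayer graphs and adjacency hypermatrices
#'
#' Mutually inverse bijections: an undirected edge
#' (variable i, layer h) -- (variable j, layer k) corresponds to the entry
#' pair `A[i,j,h,k] = A[j,i,k,h] = 1`.  `graphFromHypermatrix` validates
#' symmetry and an all-zero bi-diagonal before converting.
#'
#' @param a a binary [Hypermatrix-class].
#' @param g a [MultilayerGraph-class].
#' @return a [MultilayerGraph-class] / a [Hypermatrix-class].
#' @export
graphFromHypermatrix <- function(a) {
  if (!all(a@values %in% c(0, 1))) .stopf("hypermatrix must be binary")
  N <- nVars(a)
  L <- nLayers(a)
  nz <- which(a@values != 0, arr.ind = TRUE)
  edges <- if (nrow(nz)) {
    va <- .vid(nz[, 1L], nz[, 3L], N)
    vb <- .vid(nz[, 2L], nz[, 4L], N)
    if (any(va == vb)) .stopf("hypermatrix has self-loop entries")
    cbind(va, vb)
  } else NULL
  mlGraph(N, L, edges = edges, varNames = a@varNames, layerNames = a@layerNames)
}

#' @rdname graphFromHypermatrix
#' @export
hypermatrixFromGraph <- function(g) {
  N <- nVars(g)
  L <- nLayers(g)
  arr <- array(0, dim = c(N, N, L, L))
  e <- edgeSet(g)
  for (r in seq_len(nrow(e))) {
    i <- .vidVar(e[r, 1L], N); h <- .vidLayer(e[r, 1L], N)
    j <- .vidVar(e[r, 2L], N); k <- .vidLayer(e[r, 2L], N)
    arr[i, j, h, k] <- 1
    arr[j, i, k, h] <- 1
  }
  .hypermatrix(arr, "adjacency", varNames(g), layerNames(g))
}

#' Write a centrality report TSV
#'
#' Columns: `var`, `multidegree`, then one `k_<h>_<k>` column per ordered
#' layer pair.
#'
#' @param a a [Hypermatrix-class].
#' @param path output file.
#' @return the report data.frame, invisibly (after writing).
#' @export
writeCentralityReport <- function(a, path) {
  L <- nLayers(a)
  df <- data.frame(var = a@varNames,
                   multidegree = as.numeric(multidegreeCentrality(a)),
                   stringsAsFactors = FALSE)
  for (h in seq_len(L)) for (k in seq_len(L)) {
    df[[paste0("k_", a@layerNames[h], "_", a@layerNames[k])]] <-
      as.numeric(layerPairDegree(a, h, k))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
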