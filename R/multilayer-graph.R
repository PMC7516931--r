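#' Construct a multilayer graph
#'
#' Builds the vertex set \{X_ih : i = 1..nVars, h = 1..nLayers\} together
#' with an undirected edge set.  Edges may be given as a two-column matrix
#' of vertex ids (see [nodeId()]) or as a four-column matrix /
#' data.frame `(var_a, layer_a, var_b, layer_b)`; either endpoint order is
#' accepted and duplicates are removed.
#'
#' @param nVars number of variables per layer (N >= 1).
#' @param nLayers number of layers (L >= 1).
#' @param edges edge specification (may be NULL for an edgeless graph).
#' @param varNames,layerNames optional name registries; defaults are
#'   `V1..VN` and Roman numerals `I, II, ...`.
#' @return a [MultilayerGraph-class] object.
#' @examples
#' g <- mlGraph(4, 2, edges = rbind(
#'   c(2, 1, 3, 1), c(3, 1, 4, 1), c(2, 1, 4, 1), c(3, 1, 3, 2)))
#' neighborsOf(g, nodeId(g, 3, 1))
#' @export
mlGraph <- function(nVars, nLayers, edges = NULL,
                    varNames = paste0("V", seq_len(nVars)),
                    layerNames = as.character(utils::as.roman(seq_len(nLayers)))) {
  nVars <- as.integer(nVars)
  nLayers <- as.integer(nLayers)
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) == 4L) {
      a <- .vid(as.integer(edges[, 1L]), as.integer(edges[, 2L]), nVars)
      b <- .vid(as.integer(edges[, 3L]), as.integer(edges[, 4L]), nVars)
      em <- cbind(a, b)
    } else if (ncol(edges) == 2L) {
      em <- cbind(as.integer(edges[, 1L]), as.integer(edges[, 2L]))
    } else {
      .stopf("edges must have 2 (vertex ids) or 4 (var/layer pairs) columns")
    }
    em <- .canonicalEdges(em)
  }
  new("MultilayerGraph", nVars = nVars, nLayers = nLayers, edges = em,
      varNames = varNames, layerNames = layerNames)
}

.canonicalEdges <- function(em) {
  if (nrow(em) == 0L) return(matrix(integer(0), ncol = 2L))
  em <- cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
  em <- unique(em)
  em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  storage.mode(em) <- "integer"
  dimnames(em) <- NULL
  em
}

#' Vertex id of a (variable, layer) pair
#'
#' Variables and layers may be given by 1-based index or by registered name.
#'
#' @param g a MultilayerGraph (or any object with var/layer registries).
#' @param var variable index or name.
#' @param layer layer index or name.
#' @return integer vertex id, usable everywhere a vertex is expected.
#' @export
nodeId <- function(g, var, layer) {
  if (is.character(var)) var <- match(var, varNames(g))
  if (is.character(layer)) layer <- match(layer, layerNames(g))
  var <- as.integer(var)
  layer <- as.integer(layer)
  if (anyNA(var) || any(var < 1L) || any(var > nVars(g))) {
    .stopf("variable index out of range [1, %d]", nVars(g))
  }
  if (anyNA(layer) || any(layer < 1L) || any(layer > nLayers(g))) {
    .stopf("layer index out of range [1, %d]", nLayers(g))
  }
  .vid(var, layer, nVars(g))
}

#' Human-readable vertex labels
#'
#' @param g a MultilayerGraph.
#' @param vids integer vertex ids.
#' @return character labels like `"V3:I"`.
#' @export
nodeLabel <- function(g, vids) {
  paste0(varNames(g)[.vidVar(vids, nVars(g))], ":",
         layerNames(g)[.vidLayer(vids, nVars(g))])
}

#' @name MultilayerGraph-accessors
#' @title Accessors for multilayer objects
#' @description Shape, name registries and canonical edge matrix.
#' @param x the object.
#' @return `nVars`/`nLayers`: integers; `varNames`/`layerNames`: character;
#'   `edgeSet`: two-column integer matrix of vertex ids in canonical order.
NULL

#' @rdname MultilayerGraph-accessors
#' @export
setMethod("nVars", "MultilayerGraph", function(x) x@nVars)
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("nLayers", "MultilayerGraph", function(x) x@nLayers)
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("varNames", "MultilayerGraph", function(x) x@varNames)
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("layerNames", "MultilayerGraph", function(x) x@layerNames)
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("edgeSet", "MultilayerGraph", function(x) x@edges)

setMethod("show", "MultilayerGraph", function(object) {
  cat(sprintf("MultilayerGraph: %d variables x %d layers (%d vertices), %d edges\n",
              object@nVars, object@nLayers,
              object@nVars * object@nLayers, nrow(object@edges)))
  cat("layers:", paste(object@layerNames, collapse = ", "), "\n")
  if (nrow(object@edges) > 0L) {
    shown <- utils::head(seq_len(nrow(object@edges)), 10L)
    cat("edges:",
        paste(nodeLabel(object, object@edges[shown, 1L]),
              nodeLabel(object, object@edges[shown, 2L]), sep = "--",
              collapse = ", "),
        if (nrow(object@edges) > 10L) "..." else "", "\n")
  }
})

.checkVertex <- function(g, v) {
  nV <- g@nVars * g@nLayers
  if (anyNA(v) || any(v < 1L) || any(v > nV)) {
    .stopf("vertex id out of range [1, %d]", nV)
  }
  invisible(as.integer(v))
}

# igraph conversion keeping isolated vertices
.toIgraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g@nVars * g@nLayers, directed = FALSE)
  if (nrow(g@edges) > 0L) ig <- igraph::add_edges(ig, t(g@edges))
  ig
}

#' Neighbours of a vertex
#'
#' The set N(X_ih) of vertices sharing an edge with `v`, in any layer; `v`
#' itself is excluded.  In a tensor Markov field this set is also the
#' vertex's Markov blanket.
#'
#' @param g a MultilayerGraph.
#' @param v a vertex id.
#' @return sorted integer vector of vertex ids.
#' @export
setMethod("neighborsOf", "MultilayerGraph", function(g, v) {
  v <- .checkVertex(g, v)
  stopifnot(length(v) == 1L)
  e <- g@edges
  sort(unique(c(e[e[, 1L] == v, 2L], e[e[, 2L] == v, 1L])))
})

#' Is a vertex subset a clique?
#'
#' A subset is a clique when every pair of its members is an edge; the empty
#' set and singletons are cliques.  Cliques (in this all-complete-subsets
#' sense) carry the non-unit potentials of a nearest-neighbour Gibbs field.
#'
#' @param g a MultilayerGraph.
#' @param s integer vector of vertex ids.
#' @return logical.
#' @export
setMethod("isClique", "MultilayerGraph", function(g, s) {
  s <- unique(.checkVertex(g, s))
  k <- length(s)
  if (k <= 1L) return(TRUE)
  need <- t(utils::combn(sort(s), 2L))
  key <- function(m) paste(m[, 1L], m[, 2L])
  all(key(need) %in% key(g@edges))
})

#' Enumerate all cliques of a multilayer graph
#'
#' Every complete vertex subset, including the empty set and all singletons,
#' each exactly once, ordered by size then lexicographically by vertex id.
#' This is the index set of the Gibbs product, hence the unrestricted
#' (non-maximal) enumeration.
#'
#' @param g a MultilayerGraph.
#' @param maxVertices capacity guard; enumeration refuses graphs with more
#'   vertices than this (default 24).
#' @return list of integer vectors; the first element is `integer(0)`.
#' @export
setMethod("enumerateCliques", "MultilayerGraph", function(g, maxVertices = 24L) {
  nV <- g@nVars * g@nLayers
  if (nV > maxVertices) {
    .stopf("clique enumeration refused: %d vertices exceeds the guard of %d",
           nV, maxVertices)
  }
  cl <- igraph::cliques(.toIgraph(g), min = 1L)
  cl <- lapply(cl, function(x) sort(as.integer(x)))
  sizes <- lengths(cl)
  key <- vapply(cl, function(x) paste(sprintf("%06d", x), collapse = ""), "")
  cl <- cl[order(sizes, key)]
  c(list(integer(0)), cl)
})

#' Graph separation (global Markov relation)
#'
#' Tests whether every path from a vertex of `a` to a vertex of `b` passes
#' through `c`: after deleting the vertices of `c` (and incident edges) no
#' component contains members of both `a` and `b`.
#'
#' @param g a MultilayerGraph.
#' @param a,b,c pairwise disjoint integer vectors of vertex ids (`c` may be
#'   empty).
#' @return logical.
#' @export
setMethod("separates", "MultilayerGraph", function(g, a, b, c) {
  a <- unique(.checkVertex(g, a))
  b <- unique(.checkVertex(g, b))
  c <- if (length(c)) unique(.checkVertex(g, c)) else integer(0)
  if (length(intersect(a, b)) || length(intersect(a, c)) ||
      length(intersect(b, c))) {
    .stopf("a, b and c must be pairwise disjoint")
  }
  if (length(a) == 0L || length(b) == 0L) return(TRUE)
  ig <- .toIgraph(g)
  if (length(c)) ig <- igraph::delete_vertices(ig, c)
  # vertex ids shift after deletion; map survivors
  keep <- setdiff(seq_len(g@nVars * g@nLayers), c)
  d <- igraph::distances(ig, v = match(a, keep), to = match(b, keep))
  all(is.infinite(d))
})

#' Markov blanket of a vertex
#'
#' In a tensor Markov field the Markov blanket equals the set of first
#' neighbours: conditioning on them renders the vertex independent of the
#' remainder of the multilayer graph.
#'
#' @param g a MultilayerGraph.
#' @param v a vertex id.
#' @return sorted integer vector of vertex ids.
#' @export
setMethod("markovBlanket", "MultilayerGraph", function(g, v) {
  neighborsOf(g, v)
})

#' Write / read a multilayer graph as a TSV edge list
#'
#' Four columns `var_a  layer_a  var_b  layer_b`, layer names as registered
#' strings, one edge per line in canonical order.  The reader accepts either
#' endpoint order and deduplicates.
#'
#' @param g a MultilayerGraph.
#' @param path file path.
#' @param nVars,nLayers,varNames,layerNames shape of the graph being read
#'   (an edge list alone does not determine isolated vertices).
#' @return `writeEdgeList` returns `path` invisibly; `readEdgeList` returns a
#'   MultilayerGraph.
#' @export
writeEdgeList <- function(g, path) {
  e <- edgeSet(g)
  df <- data.frame(
    var_a = varNames(g)[.vidVar(e[, 1L], nVars(g))],
    layer_a = layerNames(g)[.vidLayer(e[, 1L], nVars(g))],
    var_b = varNames(g)[.vidVar(e[, 2L], nVars(g))],
    layer_b = layerNames(g)[.vidLayer(e[, 2L], nVars(g))],
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path, nVars, nLayers,
                         varNames = paste0("V", seq_len(nVars)),
                         layerNames = as.character(utils::as.roman(seq_len(nLayers)))) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  g0 <- mlGraph(nVars, nLayers, varNames = varNames, layerNames = layerNames)
  if (nrow(df) == 0L) return(g0)
  a <- .vid(match(df$var_a, varNames), match(df$layer_a, layerNames), nVars)
  b <- .vid(match(df$var_b, varNames), match(df$layer_b, layerNames), nVars)
  if (anyNA(a) || anyNA(b)) .stopf("edge list refers to unregistered names")
  mlGraph(nVars, nLayers, edges = cbind(a, b),
          varNames = varNames, layerNames = layerNames)
}

#' Test two multilayer graphs for equality of shape and edge set
#' @param g1,g2 MultilayerGraph objects.
#' @return logical.
#' @export
sameGraph <- function(g1, g2) {
  isTRUE(g1@nVars == g2@nVars) && isTRUE(g1@nLayers == g2@nLayers) &&
    identical(dim(g1@edges), dim(g2@edges)) &&
    all(g1@edges == g2@edges)
}
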