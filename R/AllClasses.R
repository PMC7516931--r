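#' Multilayer graph of tensor-indexed vertices
#'
#' A vertex is a pair (variable i, layer h), i in 1..nVars, h in 1..nLayers,
#' stored internally as the integer id (h-1)*nVars + i.  Edges are undirected
#' and may join vertices within one layer (intra-layer) or across layers
#' (inter-layer); self-loops are forbidden, but distinct copies of the same
#' variable in two layers may be joined.  Edges are kept in canonical form:
#' each pair ordered by id, rows sorted, no duplicates.
#'
#' @slot nVars number of variables per layer (N).
#' @slot nLayers number of layers (L).
#' @slot edges two-column integer matrix of vertex ids, canonical order.
#' @slot varNames character vector of length N.
#' @slot layerNames character vector of length L.
#'
#' @exportClass MultilayerGraph
setClass("MultilayerGraph",
  representation(
    nVars = "integer",
    nLayers = "integer",
    edges = "matrix",
    varNames = "character",
    layerNames = "character"
  )
)

setValidity("MultilayerGraph", function(object) {
  N <- object@nVars
  L <- object@nLayers
  if (length(N) != 1L || N < 1L) return("nVars must be a single integer >= 1")
  if (length(L) != 1L || L < 1L) return("nLayers must be a single integer >= 1")
  if (length(object@varNames) != N) return("varNames must have length nVars")
  if (length(object@layerNames) != L) return("layerNames must have length nLayers")
  if (anyDuplicated(object@layerNames)) return("layerNames must be unique")
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have two columns")
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > N * L)) return("edge endpoint outside vertex set")
    if (any(e[, 1L] == e[, 2L])) return("self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L])) return("edges are not in canonical order")
    if (anyDuplicated(e)) return("duplicate edges")
  }
  TRUE
})

#' Finite label set of a Gibbs field
#'
#' The ordered set S of labels a vertex can take, plus a designated default
#' label playing the role of the reference ("0") state in the
#' Moebius-inversion construction of candidate potentials.
#'
#' @slot labels character vector, the ordered label set S (|S| >= 2).
#' @slot defaultLabel one element of S.
#'
#' @exportClass LabelSet
setClass("LabelSet",
  representation(labels = "character", defaultLabel = "character")
)

setValidity("LabelSet", function(object) {
  if (length(object@labels) < 2L) return("need at least two labels")
  if (anyDuplicated(object@labels)) return("labels must be unique")
  if (length(object@defaultLabel) != 1L ||
      !(object@defaultLabel %in% object@labels)) {
    return("defaultLabel must be one of the labels")
  }
  TRUE
})

#' Nearest-neighbour Gibbs field on a multilayer graph
#'
#' Strictly positive clique potentials phi_C on a MultilayerGraph; the
#' induced measure is P(omega) = prod_C phi_C(omega_C) / Z with the product
#' over all cliques.  Subsets without a stored potential are implicitly the
#' constant 1.  Potentials are stored as log tables (one array per clique,
#' one dimension per member vertex) so products accumulate without
#' underflow.
#'
#' @slot graph a MultilayerGraph.
#' @slot labels a LabelSet.
#' @slot potentials list of entries, each `list(vertices = <sorted integer
#'   vids>, logTable = <numeric array, dim rep(|S|, k)>)`.
#'
#' @exportClass GibbsField
setClass("GibbsField",
  representation(
    graph = "MultilayerGraph",
    labels = "LabelSet",
    potentials = "list"
  )
)

setValidity("GibbsField", function(object) {
  nS <- length(object@labels@labels)
  nV <- object@graph@nVars * object@graph@nLayers
  for (p in object@potentials) {
    v <- p$vertices
    if (length(v) > 0L) {
      if (is.unsorted(v, strictly = TRUE)) return("potential vertices must be strictly sorted")
      if (any(v < 1L) || any(v > nV)) return("potential vertex outside graph")
      if (!isClique(object@graph, v)) {
        return("a non-unit potential is stored on a subset that is not a clique")
      }
    }
    want <- nS^length(v)
    if (length(p$logTable) != want) return("potential table has wrong size")
    if (any(!is.finite(p$logTable))) {
      return("potential values must be strictly positive (finite log)")
    }
  }
  TRUE
})

#' Explicit joint probability table over all configurations
#'
#' Stores P(omega) for every one of |S|^(N*L) configurations of a multilayer
#' vertex set.  Configurations are indexed little-endian: the label of
#' vertex v in configuration m is `((m-1) %/% |S|^(v-1)) %% |S| + 1`.  The
#' table must be strictly positive (the hypothesis of the
#' Hammersley-Clifford theorem) and sum to one.
#'
#' @slot nVars,nLayers vertex-set shape (N variables, L layers).
#' @slot labels a LabelSet.
#' @slot prob numeric vector of length |S|^(N*L), strictly positive, sums to 1.
#' @slot varNames,layerNames name registries.
#'
#' @exportClass JointTable
setClass("JointTable",
  representation(
    nVars = "integer",
    nLayers = "integer",
    labels = "LabelSet",
    prob = "numeric",
    varNames = "character",
    layerNames = "character"
  )
)

setValidity("JointTable", function(object) {
  nS <- length(object@labels@labels)
  nV <- object@nVars * object@nLayers
  if (length(object@prob) != nS^nV) return("prob has wrong length")
  if (any(object@prob <= 0)) return("joint table must be strictly positive")
  if (abs(sum(object@prob) - 1) > 1e-9) return("probabilities must sum to 1")
  TRUE
})

#' Multilayer sample data: samples x variables x layers
#'
#' Observations of every tensor-indexed variable X_ih across shared samples,
#' e.g. expression of N genes measured in L omic layers.  Values may be
#' discrete codes or continuous levels; no missing entries.
#'
#' @slot values numeric array, dim c(nSamples, nVars, nLayers).
#' @slot varNames,layerNames,sampleIds name registries.
#'
#' @exportClass SampleTensor
setClass("SampleTensor",
  representation(
    values = "array",
    varNames = "character",
    layerNames = "character",
    sampleIds = "character"
  )
)

setValidity("SampleTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-d array (samples x vars x layers)")
  if (any(!is.finite(object@values))) return("missing or non-finite entries are not allowed")
  if (length(object@varNames) != d[2L]) return("varNames must match dim 2")
  if (length(object@layerNames) != d[3L]) return("layerNames must match dim 3")
  if (length(object@sampleIds) != d[1L]) return("sampleIds must match dim 1")
  TRUE
})

#' Four-index hypermatrix A[i,j,h,k] / W[i,j,h,k]
#'
#' The neighbourhood law of a tensor Markov field in tensor form: entry
#' [i, j, h, k] refers to the (unordered) vertex pair (variable i, layer h)
#' -- (variable j, layer k).  Symmetry [i,j,h,k] = [j,i,k,h] holds and the
#' bi-diagonal [i,i,h,h] is zero.  `kind` is one of "mi" (off-diagonal
#' mutual information, bits), "adjacency" (binary) or "strength"
#' (MI restricted to the adjacency support).
#'
#' @slot values numeric array, dim c(N, N, L, L).
#' @slot kind character flag.
#' @slot varNames,layerNames name registries.
#'
#' @exportClass Hypermatrix
setClass("Hypermatrix",
  representation(
    values = "array",
    kind = "character",
    varNames = "character",
    layerNames = "character"
  )
)

setValidity("Hypermatrix", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L || d[1L] != d[2L] || d[3L] != d[4L]) {
    return("values must be an N x N x L x L array")
  }
  if (!object@kind %in% c("mi", "adjacency", "strength")) {
    return("kind must be 'mi', 'adjacency' or 'strength'")
  }
  if (any(object@values < 0)) return("entries must be non-negative")
  if (object@kind == "adjacency" && !all(object@values %in% c(0, 1))) {
    return("adjacency entries must be 0/1")
  }
  v <- object@values
  if (max(abs(v - aperm(v, c(2L, 1L, 4L, 3L)))) > 1e-12) {
    return("hypermatrix must satisfy [i,j,h,k] = [j,i,k,h]")
  }
  for (i in seq_len(d[1L])) for (h in seq_len(d[3L])) {
    if (v[i, i, h, h] != 0) return("bi-diagonal entries [i,i,h,h] must be zero")
  }
  if (length(object@varNames) != d[1L]) return("varNames must match N")
  if (length(object@layerNames) != d[3L]) return("layerNames must match L")
  TRUE
})

#' One conditional-independence statement and its evidence
#'
#' Records the tested relation left _||_ right | given, whether it was
#' accepted, and the measured deviation (for exact joint tables: the maximal
#' normalised deviation of the product-form identity; for empirical tests:
#' the conditional mutual information) together with the decision threshold.
#'
#' @slot left,right vertex ids of the tested pair.
#' @slot given integer vector of conditioning vertex ids.
#' @slot holds logical decision.
#' @slot deviation measured statistic.
#' @slot threshold decision threshold (tolerance or permutation quantile).
#'
#' @exportClass CIStatement
setClass("CIStatement",
  representation(
    left = "integer",
    right = "integer",
    given = "integer",
    holds = "logical",
    deviation = "numeric",
    threshold = "numeric"
  )
)

setValidity("CIStatement", function(object) {
  if (object@left == object@right) return("left and right must differ")
  if (object@left %in% object@given || object@right %in% object@given) {
    return("tested vertices cannot appear in the conditioning set")
  }
  TRUE
})

#' Conditional kernel C_A(B) = P(B | A) as an explicit table
#'
#' @slot conditioning integer vids of A; @slot target integer vids of B.
#' @slot table matrix, rows = configurations of A (little-endian over the
#'   sorted conditioning set), cols = configurations of B; each row sums to 1.
#' @slot nLabels size of the label set.
#'
#' @exportClass ConditionalKernel
setClass("ConditionalKernel",
  representation(
    conditioning = "integer",
    target = "integer",
    table = "matrix",
    nLabels = "integer"
  )
)

setValidity("ConditionalKernel", function(object) {
  rs <- rowSums(object@table)
  if (max(abs(rs - 1)) > 1e-10) return("kernel rows must sum to 1")
  TRUE
})

#' A planted multilayer scenario: graph, field, exact joint, samples
#'
#' The synthetic stand-in for a multi-omic corpus: a known multilayer
#' dependency structure, a strictly positive Gibbs field on it, the exact
#' joint table, and exact samples from that joint, all derived from one
#' seed through named substreams.
#'
#' @slot graph,field,joint the planted structure and its measure.
#' @slot samples SampleTensor of exact draws (possibly 0 samples).
#' @slot seed the scenario seed.
#'
#' @exportClass PlantedScenario
setClass("PlantedScenario",
  representation(
    graph = "MultilayerGraph",
    field = "GibbsField",
    joint = "JointTable",
    samples = "SampleTensor",
    seed = "integer"
  )
)
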