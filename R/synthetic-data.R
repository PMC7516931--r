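# Planted-structure generators.  All randomness flows from one scenario seed
# through named substreams (graph / potentials / sampling / noise), so each
# component can be regenerated independently and scenarios are bit-identical
# across runs with the same seed.

#' Random multilayer graph (planted structure)
#'
#' Each intra-layer vertex pair becomes an edge independently with
#' probability `pIntra`, each inter-layer pair with probability `pInter`
#' (including cross-layer pairs of the same variable index).
#'
#' @param nVars,nLayers shape (N variables, L layers).
#' @param pIntra,pInter edge probabilities in [0, 1].
#' @param seed integer seed.
#' @param varNames,layerNames optional name registries.
#' @return a [MultilayerGraph-class].
#' @export
randomMultilayerGraph <- function(nVars, nLayers, pIntra = 0.25, pInter = 0.15,
                                  seed = 1L,
                                  varNames = paste0("V", seq_len(nVars)),
                                  layerNames = as.character(utils::as.roman(seq_len(nLayers)))) {
  if (pIntra < 0 || pIntra > 1 || pInter < 0 || pInter > 1) {
    .stopf("edge probabilities must lie in [0, 1]")
  }
  nV <- as.integer(nVars) * as.integer(nLayers)
  edges <- NULL
  if (nV >= 2L) {
    prs <- t(utils::combn(nV, 2L))
    sameLayer <- .vidLayer(prs[, 1L], nVars) == .vidLayer(prs[, 2L], nVars)
    pEdge <- ifelse(sameLayer, pIntra, pInter)
    keep <- .withSeed(seed, stats::runif(nrow(prs)) < pEdge)
    edges <- prs[keep, , drop = FALSE]
  }
  mlGraph(nVars, nLayers, edges = edges, varNames = varNames,
          layerNames = layerNames)
}

#' Random strictly positive Gibbs field on a planted graph
#'
#' Places one pairwise potential on every edge, with log-potential entries
#' drawn uniformly from the two-sided band
#' `[-strength, -0.2*strength] U [0.2*strength, strength]` -- bounded away
#' from zero so no planted interaction is degenerate (near-unity potentials
#' would make an edge statistically invisible).  All other potentials are
#' unit, so the field is strictly positive by construction.
#'
#' @param g a [MultilayerGraph-class].
#' @param labels a [LabelSet-class] (default binary).
#' @param strength positive scale of the log-potentials (default 1).
#' @param seed integer seed.
#' @return a [GibbsField-class].
#' @export
randomGibbsField <- function(g, labels = binaryLabels(), strength = 1.0,
                             seed = 1L) {
  if (strength <= 0) .stopf("strength must be positive")
  nS <- nLabels(labels)
  e <- edgeSet(g)
  pots <- .withSeed(seed, lapply(seq_len(nrow(e)), function(r) {
    mag <- stats::runif(nS * nS, 0.2 * strength, strength)
    sgn <- sample(c(-1, 1), nS * nS, replace = TRUE)
    potential(e[r, ], array(exp(mag * sgn), dim = c(nS, nS)))
  }))
  gibbsField(g, labels, pots)
}

#' Build a complete planted scenario
#'
#' Chains the generators: planted graph, random Gibbs field on it, exact
#' joint table, and `nSamples` exact draws -- the synthetic stand-in for a
#' multilayer (e.g. gene x miRNA expression) corpus with known ground-truth
#' dependency structure.  Substream seeds for the graph, the potentials and
#' the sampling are derived deterministically from `seed`.
#'
#' @param nVars,nLayers shape (defaults 4 variables, 2 layers: a 256-
#'   configuration binary space, fully enumerable).
#' @param pIntra,pInter planted edge probabilities (defaults 0.25 / 0.15:
#'   inter-layer coupling sparser than intra-layer, as in multi-omic
#'   regulatory layers).
#' @param nSamples exact draws (default 2000).
#' @param strength interaction scale (default 1).
#' @param labels label set (default binary).
#' @param seed scenario seed.
#' @param maxConfigs enumeration guard.
#' @return a [PlantedScenario-class].
#' @examples
#' sc <- makeScenario(nSamples = 100, seed = 7)
#' sc
#' @export
makeScenario <- function(nVars = 4L, nLayers = 2L, pIntra = 0.25,
                         pInter = 0.15, nSamples = 2000L, strength = 1.0,
                         labels = binaryLabels(), seed = 1L,
                         maxConfigs = 2^20) {
  ss <- .subSeeds(seed)
  g <- randomMultilayerGraph(nVars, nLayers, pIntra, pInter, seed = ss[1L])
  field <- randomGibbsField(g, labels = labels, strength = strength,
                            seed = ss[2L])
  joint <- toJointTable(field, maxConfigs = maxConfigs)
  samples <- sampleJoint(joint, nSamples, seed = ss[3L])
  new("PlantedScenario", graph = g, field = field, joint = joint,
      samples = samples, seed = as.integer(seed))
}

setMethod("show", "PlantedScenario", function(object) {
  cat(sprintf("PlantedScenario (seed %d): %d x %d vertices, %d edges, %d labels, %d samples\n",
              object@seed, object@graph@nVars, object@graph@nLayers,
              nrow(object@graph@edges), nLabels(object@field@labels),
              nSamples(object@samples)))
})

#' @name PlantedScenario-accessors
#' @title Accessors for planted scenarios
#' @param x a [PlantedScenario-class].
#' @return the respective component.
NULL

#' @rdname PlantedScenario-accessors
#' @export
scenarioGraph <- function(x) x@graph
#' @rdname PlantedScenario-accessors
#' @export
scenarioField <- function(x) x@field
#' @rdname PlantedScenario-accessors
#' @export
scenarioJoint <- function(x) x@joint
#' @rdname PlantedScenario-accessors
#' @export
scenarioSamples <- function(x) x@samples

#' Continuous (omics-like) emulation of a discrete scenario
#'
#' Maps each discrete label to an evenly spaced real level and adds
#' independent Gaussian noise, preserving the planted dependency structure
#' up to noise; used to exercise discretisation and MI inference on
#' continuous data.
#'
#' @param s a [PlantedScenario-class].
#' @param noiseSd positive noise standard deviation (the label levels are
#'   one unit apart).
#' @param seed integer seed; defaults to the scenario's noise substream.
#' @return a real-valued [SampleTensor-class].
#' @export
gaussianize <- function(s, noiseSd = 0.3, seed = NULL) {
  if (noiseSd <= 0) .stopf("noiseSd must be positive")
  if (is.null(seed)) seed <- .subSeeds(s@seed)[4L]
  v <- s@samples@values
  noise <- .withSeed(seed, stats::rnorm(length(v), sd = noiseSd))
  sampleTensor(v + array(noise, dim = dim(v)),
               varNames = s@samples@varNames,
               layerNames = s@samples@layerNames,
               sampleIds = s@samples@sampleIds)
}

#' Dump / load a planted scenario as a plain-text directory
#'
#' Writes the graph edge list (TSV), the field document, one samples TSV per
#' layer plus a layer manifest, and a run manifest recording the seed and
#' shape.  `readScenario` restores everything except the joint table, which
#' is recomputed exactly from the field.
#'
#' @param s a [PlantedScenario-class].
#' @param dir directory (created if needed).
#' @return `writeScenario`: `dir`, invisibly; `readScenario`: a
#'   [PlantedScenario-class].
#' @export
writeScenario <- function(s, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEdgeList(s@graph, file.path(dir, "graph.tsv"))
  writeGibbsField(s@field, file.path(dir, "field.txt"))
  writeLayerMatrices(s@samples, dir)
  writeLines(c("# tensorMRF PlantedScenario v1",
               paste0("seed\t", s@seed),
               paste0("nVars\t", s@graph@nVars),
               paste0("nLayers\t", s@graph@nLayers),
               paste0("nSamples\t", nSamples(s@samples))),
             file.path(dir, "scenario.txt"))
  invisible(dir)
}

#' @rdname writeScenario
#' @export
readScenario <- function(dir) {
  man <- utils::read.table(file.path(dir, "scenario.txt"), sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  kv <- stats::setNames(man[[2L]], man[[1L]])
  field <- readGibbsField(file.path(dir, "field.txt"))
  g <- field@graph
  samples <- readLayerMatrices(file.path(dir, "layers.tsv"))
  new("PlantedScenario", graph = g, field = field,
      joint = toJointTable(field), samples = samples,
      seed = as.integer(kv[["seed"]]))
}
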