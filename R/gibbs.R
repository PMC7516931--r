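#' Construct a label set
#'
#' @param labels character (or coercible) vector of at least two distinct
#'   labels, in order.
#' @param defaultLabel the designated reference state used by the
#'   Moebius-inversion construction; defaults to the first label.
#' @return a [LabelSet-class].
#' @examples
#' binaryLabels()
#' labelSet(c("low", "mid", "high"), defaultLabel = "low")
#' @export
labelSet <- function(labels, defaultLabel = labels[1L]) {
  new("LabelSet", labels = as.character(labels),
      defaultLabel = as.character(defaultLabel))
}

#' @rdname labelSet
#' @export
binaryLabels <- function() labelSet(c("0", "1"))

#' @rdname labelSet
#' @export
nLabels <- function(x) {
  if (is(x, "LabelSet")) length(x@labels) else length(x@labels@labels)
}

setMethod("show", "LabelSet", function(object) {
  cat(sprintf("LabelSet: {%s}, default '%s'\n",
              paste(object@labels, collapse = ", "), object@defaultLabel))
})

#' Build a potential entry for a Gibbs field
#'
#' @param vertices integer vertex ids the potential acts on (a clique of the
#'   field's graph); the empty vector gives a constant potential.
#' @param table strictly positive numeric array of dim `rep(|S|, k)` giving
#'   phi on every restricted configuration; dimension t runs over the labels
#'   of the t-th vertex in sorted id order.
#' @return list usable in [gibbsField()]'s `potentials`.
#' @export
potential <- function(vertices, table) {
  vertices <- sort(as.integer(vertices))
  table <- as.array(table)
  if (any(table <= 0)) .stopf("potential values must be strictly positive")
  list(vertices = vertices, logTable = log(table))
}

#' Construct a nearest-neighbour Gibbs field
#'
#' @param graph a [MultilayerGraph-class].
#' @param labels a [LabelSet-class].
#' @param potentials list of entries from [potential()]; every subset with a
#'   non-unit potential must be a clique of `graph`.
#' @return a [GibbsField-class].
#' @examples
#' g <- mlGraph(2, 1, edges = cbind(1, 2))
#' f <- gibbsField(g, binaryLabels(),
#'   list(potential(c(1, 2), matrix(c(exp(1), 1, 1, exp(1)), 2))))
#' partitionFunction(f)
#' @export
gibbsField <- function(graph, labels, potentials = list()) {
  new("GibbsField", graph = graph, labels = labels, potentials = potentials)
}

setMethod("show", "GibbsField", function(object) {
  cat(sprintf("GibbsField: %d vertices, %d labels, %d stored potentials\n",
              object@graph@nVars * object@graph@nLayers,
              nLabels(object@labels), length(object@potentials)))
})

.fieldShape <- function(field) {
  nV <- field@graph@nVars * field@graph@nLayers
  list(nV = nV, nS = nLabels(field@labels), K = nLabels(field@labels)^nV)
}

.checkGuard <- function(K, maxConfigs) {
  if (K > maxConfigs) {
    .stopf(paste0("configuration space of size %.0f exceeds the exact ",
                  "enumeration guard of %.0f; use gibbsSample() for ",
                  "approximate draws"), K, maxConfigs)
  }
}

#' Coerce a configuration to label indices
#'
#' Accepts an integer vector of label indices (1..|S|) or a character vector
#' of labels, of length nV; NA entries are allowed only where the caller
#' permits partial configurations.
#' @noRd
.asConfig <- function(field, config, allowPartial = FALSE) {
  sh <- .fieldShape(field)
  if (is.character(config)) config <- match(config, field@labels@labels)
  config <- as.integer(config)
  if (length(config) != sh$nV) {
    .stopf("configuration must assign all %d vertices", sh$nV)
  }
  bad <- is.na(config) | config < 1L | config > sh$nS
  if (allowPartial) bad <- bad & !is.na(config)
  if (any(bad)) .stopf("configuration contains labels outside the label set")
  if (!allowPartial && anyNA(config)) {
    .stopf("configuration must assign all %d vertices", sh$nV)
  }
  config
}

# sum of log-potentials of a single full configuration
.logWeightOf <- function(field, config) {
  s <- 0
  nS <- nLabels(field@labels)
  for (p in field@potentials) {
    k <- length(p$vertices)
    if (k == 0L) { s <- s + p$logTable[1L]; next }
    idx <- 1 + sum((config[p$vertices] - 1) * nS^(seq_len(k) - 1))
    s <- s + p$logTable[idx]
  }
  s
}

# vector of log prod_C phi_C over all K configurations (log-domain)
.logWeights <- function(field, maxConfigs = 2^20) {
  sh <- .fieldShape(field)
  .checkGuard(sh$K, maxConfigs)
  lw <- numeric(sh$K)
  for (p in field@potentials) {
    if (length(p$vertices) == 0L) { lw <- lw + p$logTable[1L]; next }
    ridx <- .restrictionIndex(sh$nV, sh$nS, p$vertices)
    lw <- lw + p$logTable[ridx]
  }
  lw
}

#' @name gibbs-measure
#' @title Energy, partition function and exact Gibbs measure
#' @description
#' `energy` evaluates the dimensionless energy U(omega) = -sum_C log
#' phi_C(omega_C) over the field's stored potentials.  `partitionFunction`
#' computes Z = sum_omega prod_C phi_C(omega_C) by exact enumeration (log
#' domain), `gibbsProbability` the normalised measure P(omega) =
#' prod_C phi_C / Z, and `toJointTable` materialises the whole measure as a
#' [JointTable-class].  Exact operations refuse configuration spaces larger
#' than `maxConfigs` rather than approximating.
#' @param field a [GibbsField-class].
#' @param config a full configuration: integer label indices or character
#'   labels, one per vertex.
#' @param maxConfigs enumeration guard (default 2^20 configurations).
#' @return `energy`/`partitionFunction`/`gibbsProbability`: numbers;
#'   `toJointTable`: a [JointTable-class].
NULL

#' @rdname gibbs-measure
#' @export
setMethod("energy", "GibbsField", function(field, config) {
  config <- .asConfig(field, config)
  -.logWeightOf(field, config)
})

#' @rdname gibbs-measure
#' @export
setMethod("partitionFunction", "GibbsField", function(field, maxConfigs = 2^20) {
  exp(.logSumExp(.logWeights(field, maxConfigs)))
})

#' @rdname gibbs-measure
#' @export
setMethod("gibbsProbability", "GibbsField",
          function(field, config, maxConfigs = 2^20) {
  config <- .asConfig(field, config)
  lw <- .logWeights(field, maxConfigs)
  exp(.logWeightOf(field, config) - .logSumExp(lw))
})

#' @rdname gibbs-measure
#' @export
setMethod("toJointTable", "GibbsField", function(field, maxConfigs = 2^20) {
  lw <- .logWeights(field, maxConfigs)
  lz <- .logSumExp(lw)
  jointTable(exp(lw - lz), field@graph@nVars, field@graph@nLayers,
             field@labels, varNames = field@graph@varNames,
             layerNames = field@graph@layerNames)
})

#' Local characteristic of one vertex
#'
#' The conditional distribution P(X_v = s | rest), computed using only the
#' potentials of cliques containing `v` (the Markov property makes the other
#' factors cancel); the configuration's own value at `v` is ignored, and
#' vertices outside the neighbourhood of `v` never influence the result.
#'
#' @param field a [GibbsField-class].
#' @param v a vertex id.
#' @param config configuration defined at least on all vertices except `v`
#'   (NA allowed at `v`).
#' @return named numeric vector over the labels, summing to 1.
#' @export
setMethod("localCharacteristic", "GibbsField", function(field, v, config) {
  sh <- .fieldShape(field)
  v <- .checkVertex(field@graph, v)
  config <- .asConfig(field, config, allowPartial = TRUE)
  if (anyNA(config[-v])) {
    .stopf("configuration must be defined on every vertex except possibly %d", v)
  }
  touching <- Filter(function(p) v %in% p$vertices, field@potentials)
  logp <- numeric(sh$nS)
  for (s in seq_len(sh$nS)) {
    cfg <- config
    cfg[v] <- s
    for (p in touching) {
      k <- length(p$vertices)
      idx <- 1 + sum((cfg[p$vertices] - 1) * sh$nS^(seq_len(k) - 1))
      logp[s] <- logp[s] + p$logTable[idx]
    }
  }
  pr <- exp(logp - .logSumExp(logp))
  stats::setNames(pr / sum(pr), field@labels@labels)
})

#' Exact sampling from an enumerable Gibbs field
#'
#' Materialises the joint table and draws independent configurations from
#' the resulting categorical distribution; reproducible given `seed`.
#'
#' @param field a [GibbsField-class].
#' @param n number of draws (>= 0).
#' @param seed integer seed.
#' @param maxConfigs enumeration guard.
#' @return a [SampleTensor-class] of label codes (1..|S|), dim
#'   `c(n, nVars, nLayers)`.
#' @export
setMethod("exactSample", "GibbsField", function(field, n, seed, maxConfigs = 2^20) {
  joint <- toJointTable(field, maxConfigs = maxConfigs)
  sampleJoint(joint, n, seed)
})

#' Draw exact samples from a joint table
#'
#' @param joint a [JointTable-class].
#' @param n number of draws.
#' @param seed integer seed.
#' @return a [SampleTensor-class] of label codes.
#' @export
sampleJoint <- function(joint, n, seed) {
  n <- as.integer(n)
  nS <- nLabels(joint@labels)
  nV <- joint@nVars * joint@nLayers
  m <- if (n > 0L) {
    .withSeed(seed, sample.int(length(joint@prob), n, replace = TRUE,
                               prob = joint@prob))
  } else integer(0)
  vals <- array(0, dim = c(n, joint@nVars, joint@nLayers))
  for (v in seq_len(nV)) {
    vals[, .vidVar(v, joint@nVars), .vidLayer(v, joint@nVars)] <-
      .configLabels(m, v, nS)
  }
  sampleTensor(vals, varNames = joint@varNames, layerNames = joint@layerNames)
}

#' Single-site heat-bath Gibbs sampler (approximate)
#'
#' For fields whose configuration space exceeds the exact-enumeration guard.
#' Runs `burnIn` full sweeps of sequential heat-bath updates (each site
#' redrawn from its local characteristic), then records one configuration
#' per `thin` further sweeps.  Draws are a Markov chain, not independent;
#' intended for fixture generation, never as an exactness oracle.
#'
#' @param field a [GibbsField-class].
#' @param n number of recorded configurations.
#' @param seed integer seed.
#' @param burnIn burn-in sweeps (default 100 * number of vertices).
#' @param thin sweeps between recorded configurations (default 1).
#' @return a [SampleTensor-class] of label codes.
#' @export
gibbsSample <- function(field, n, seed, burnIn = NULL, thin = 1L) {
  sh <- .fieldShape(field)
  if (is.null(burnIn)) burnIn <- 100L * sh$nV
  .withSeed(seed, {
    config <- sample.int(sh$nS, sh$nV, replace = TRUE)
    sweep1 <- function(cfg) {
      for (v in seq_len(sh$nV)) {
        pr <- localCharacteristic(field, v, cfg)
        cfg[v] <- sample.int(sh$nS, 1L, prob = pr)
      }
      cfg
    }
    for (i in seq_len(burnIn)) config <- sweep1(config)
    out <- matrix(0L, nrow = n, ncol = sh$nV)
    for (r in seq_len(n)) {
      for (t in seq_len(thin)) config <- sweep1(config)
      out[r, ] <- config
    }
    vals <- array(0, dim = c(n, field@graph@nVars, field@graph@nLayers))
    for (v in seq_len(sh$nV)) {
      vals[, .vidVar(v, field@graph@nVars), .vidLayer(v, field@graph@nVars)] <-
        out[, v]
    }
    sampleTensor(vals, varNames = field@graph@varNames,
                 layerNames = field@graph@layerNames)
  })
}

#' Serialise / restore a Gibbs field as a plain-text document
#'
#' Tab-separated key-value document listing the shape, label set, default
#' label and per-clique potential tables (values written with full
#' precision, little-endian over each clique's sorted vertex ids);
#' round-trip stable.
#'
#' @param field a [GibbsField-class].
#' @param path file path.
#' @return `writeGibbsField`: `path`, invisibly; `readGibbsField`: a
#'   [GibbsField-class].
#' @export
writeGibbsField <- function(field, path) {
  g <- field@graph
  lines <- c(
    "# tensorMRF GibbsField v1",
    paste0("nVars\t", g@nVars),
    paste0("nLayers\t", g@nLayers),
    paste0("varNames\t", paste(g@varNames, collapse = ",")),
    paste0("layerNames\t", paste(g@layerNames, collapse = ",")),
    paste0("labels\t", paste(field@labels@labels, collapse = ",")),
    paste0("defaultLabel\t", field@labels@defaultLabel),
    paste0("edges\t", paste(apply(g@edges, 1L, paste, collapse = "-"),
                            collapse = ","))
  )
  for (p in field@potentials) {
    lines <- c(lines, paste0(
      "potential\t", paste(p$vertices, collapse = ","), "\t",
      paste(sprintf("%.17g", exp(p$logTable)), collapse = ",")
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGibbsField
#' @export
readGibbsField <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kv <- function(key) {
    hit <- Filter(function(p) p[[1L]] == key, parts)
    if (!length(hit)) .stopf("field document missing key '%s'", key)
    hit[[1L]][2L]
  }
  nVars <- as.integer(kv("nVars"))
  nLayers <- as.integer(kv("nLayers"))
  edgesStr <- {
    hit <- Filter(function(p) p[[1L]] == "edges", parts)[[1L]]
    if (length(hit) < 2L) "" else hit[2L]
  }
  edges <- if (nzchar(edgesStr)) {
    do.call(rbind, lapply(strsplit(strsplit(edgesStr, ",")[[1L]], "-"),
                          as.integer))
  } else NULL
  g <- mlGraph(nVars, nLayers, edges = edges,
               varNames = strsplit(kv("varNames"), ",")[[1L]],
               layerNames = strsplit(kv("layerNames"), ",")[[1L]])
  labels <- labelSet(strsplit(kv("labels"), ",")[[1L]], kv("defaultLabel"))
  nS <- nLabels(labels)
  pots <- lapply(Filter(function(p) p[[1L]] == "potential", parts), function(p) {
    verts <- if (nzchar(p[2L])) as.integer(strsplit(p[2L], ",")[[1L]]) else integer(0)
    vals <- as.numeric(strsplit(p[3L], ",")[[1L]])
    potential(verts, array(vals, dim = rep(nS, length(verts))))
  })
  gibbsField(g, labels, pots)
}

#' Construct a joint probability table
#'
#' @param prob strictly positive numeric vector over all |S|^(N*L)
#'   configurations (little-endian vertex order); normalised to sum to 1.
#' @param nVars,nLayers vertex-set shape.
#' @param labels a [LabelSet-class].
#' @param varNames,layerNames name registries.
#' @return a [JointTable-class].
#' @export
jointTable <- function(prob, nVars, nLayers, labels,
                       varNames = paste0("V", seq_len(nVars)),
                       layerNames = as.character(utils::as.roman(seq_len(nLayers)))) {
  prob <- as.numeric(prob)
  if (any(prob <= 0)) {
    .stopf("joint table must be strictly positive (min entry %.3g)", min(prob))
  }
  new("JointTable", nVars = as.integer(nVars), nLayers = as.integer(nLayers),
      labels = labels, prob = prob / sum(prob),
      varNames = varNames, layerNames = layerNames)
}

setMethod("show", "JointTable", function(object) {
  cat(sprintf("JointTable: %d variables x %d layers, %d labels, %d configurations\n",
              object@nVars, object@nLayers, nLabels(object@labels),
              length(object@prob)))
})

#' @rdname MultilayerGraph-accessors
#' @export
setMethod("nVars", "JointTable", function(x) x@nVars)
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("nLayers", "JointTable", function(x) x@nLayers)
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("varNames", "JointTable", function(x) x@varNames)
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("layerNames", "JointTable", function(x) x@layerNames)

#' Probabilities of a joint table
#' @param p a [JointTable-class].
#' @return numeric vector over configurations (little-endian vertex order).
#' @export
jointProb <- function(p) p@prob

#' Exact marginal of a vertex subset
#'
#' @param p a [JointTable-class].
#' @param subset integer vertex ids (may be empty: returns 1).
#' @return numeric vector over the restricted configurations of `subset`
#'   (little-endian over the subset in the given order).
#' @export
marginalProbability <- function(p, subset) {
  nV <- p@nVars * p@nLayers
  .marginal(p@prob, nV, nLabels(p@labels), as.integer(subset))
}

#' Construct a sample tensor
#'
#' @param values numeric array `c(nSamples, nVars, nLayers)` (a matrix is
#'   treated as a single layer).
#' @param varNames,layerNames,sampleIds name registries.
#' @return a [SampleTensor-class].
#' @export
sampleTensor <- function(values,
                         varNames = paste0("V", seq_len(dim(values)[2L])),
                         layerNames = as.character(utils::as.roman(seq_len(dim(values)[3L]))),
                         sampleIds = if (dim(values)[1L] > 0)
                           paste0("S", seq_len(dim(values)[1L])) else character(0)) {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  new("SampleTensor", values = values, varNames = varNames,
      layerNames = layerNames, sampleIds = sampleIds)
}

setMethod("show", "SampleTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("SampleTensor: %d samples x %d variables x %d layers\n",
              d[1L], d[2L], d[3L]))
})

#' @rdname stValues
#' @export
setMethod("stValues", "SampleTensor", function(x) x@values)

#' @name stValues
#' @title Raw values of a sample tensor
#' @param x a [SampleTensor-class].
#' @return the underlying `samples x vars x layers` array.
NULL

#' @rdname MultilayerGraph-accessors
#' @export
setMethod("nVars", "SampleTensor", function(x) dim(x@values)[2L])
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("nLayers", "SampleTensor", function(x) dim(x@values)[3L])
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("varNames", "SampleTensor", function(x) x@varNames)
#' @rdname MultilayerGraph-accessors
#' @export
setMethod("layerNames", "SampleTensor", function(x) x@layerNames)

#' Number of samples in a sample tensor
#' @param x a [SampleTensor-class].
#' @return integer.
#' @export
nSamples <- function(x) dim(x@values)[1L]

#' Column of one vertex across samples
#' @param x a [SampleTensor-class].
#' @param var,layer variable and layer (index or name).
#' @return numeric vector of length nSamples.
#' @export
vertexColumn <- function(x, var, layer) {
  if (is.character(var)) var <- match(var, x@varNames)
  if (is.character(layer)) layer <- match(layer, x@layerNames)
  x@values[, var, layer]
}
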