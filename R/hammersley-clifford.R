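# Moebius-inversion candidate potentials
#
# For a strictly positive joint P over the multilayer vertex set and a
# designated default label "0", the candidate potential of a subset sigma is
#
#   f_sigma(x_sigma) = prod_{zeta subseteq sigma}
#                      P(X_zeta = x_zeta, X_rest = 0)^((-1)^(|sigma|-|zeta|))
#
# with the product over ALL subsets zeta including the empty set and sigma
# itself.  Two facts make these proper clique potentials: (i) the product of
# f_sigma over all subsets telescopes back to P, and (ii) f_sigma is
# identically 1 whenever sigma is not a clique of any graph with respect to
# which P is Markov.  Both are verified numerically here; all accumulation
# is in log space with integer sign bookkeeping.

.checkPositivity <- function(p) {
  if (min(p@prob) <= 1e-300) {
    .stopf("joint table violates strict positivity (min %.3g)", min(p@prob))
  }
  invisible(TRUE)
}

.defaultLabelIndex <- function(p) {
  match(p@labels@defaultLabel, p@labels@labels)
}

# log f_sigma over all nS^|sigma| restricted configurations (little-endian
# over sigma's sorted order)
.moebiusLogF <- function(prob, nV, nS, sigma, dflt) {
  w <- nS^(seq_len(nV) - 1)
  k <- length(sigma)
  baseIdx <- 1 + (dflt - 1) * sum(w)
  if (k == 0L) return(log(prob[baseIdx]))
  labs <- .restrictedConfigs(nS, k)
  M <- ncol(labs)
  bits <- 2^(seq_len(k) - 1)
  logf <- numeric(M)
  for (mask in 0:(2^k - 1)) {
    zeta <- which(bitwAnd(mask, bits) > 0)
    sgn <- if ((k - length(zeta)) %% 2 == 0) 1 else -1
    idx <- rep(baseIdx, M)
    for (t in zeta) idx <- idx + (labs[t, ] - dflt) * w[sigma[t]]
    logf <- logf + sgn * log(prob[idx])
  }
  logf
}

#' Moebius-inversion candidate potential of a vertex subset
#'
#' Computes the inclusion-exclusion product of default-pinned joint
#' probabilities that reconstructs a clique potential from a strictly
#' positive joint distribution.  The designated default label of the joint
#' table's label set plays the role of the reference state.
#'
#' @param p a strictly positive [JointTable-class].
#' @param sigma integer vector of vertex ids (may be empty).
#' @param maxSize capacity guard on |sigma| (default 20; the inner product
#'   enumerates 2^|sigma| subsets).
#' @return list with `vertices` (sorted ids) and `values`, a numeric vector
#'   of f_sigma over the subset's restricted configurations (little-endian),
#'   named by the label combinations.
#' @examples
#' f <- gibbsField(mlGraph(2, 1, cbind(1, 2)), binaryLabels(),
#'   list(potential(c(1, 2), matrix(c(2, 1, 1, 2), 2))))
#' moebiusPotential(toJointTable(f), c(1, 2))
#' @export
moebiusPotential <- function(p, sigma, maxSize = 20L) {
  .checkPositivity(p)
  sigma <- sort(unique(as.integer(sigma)))
  nV <- p@nVars * p@nLayers
  if (length(sigma) && (min(sigma) < 1L || max(sigma) > nV)) {
    .stopf("sigma contains vertex ids outside [1, %d]", nV)
  }
  if (length(sigma) > maxSize) {
    .stopf("|sigma| = %d exceeds the guard of %d", length(sigma), maxSize)
  }
  nS <- nLabels(p@labels)
  vals <- exp(.moebiusLogF(p@prob, nV, nS, sigma, .defaultLabelIndex(p)))
  if (length(sigma)) {
    labs <- .restrictedConfigs(nS, length(sigma))
    names(vals) <- apply(labs, 2L, function(cl)
      paste(p@labels@labels[cl], collapse = ","))
  }
  list(vertices = sigma, values = vals)
}

.allSubsetLogF <- function(p, maxVertices) {
  .checkPositivity(p)
  nV <- p@nVars * p@nLayers
  if (nV > maxVertices) {
    .stopf("factorization check refused: %d vertices exceeds the guard of %d",
           nV, maxVertices)
  }
  nS <- nLabels(p@labels)
  dflt <- .defaultLabelIndex(p)
  bits <- 2^(seq_len(nV) - 1)
  subsets <- lapply(0:(2^nV - 1), function(mask) which(bitwAnd(mask, bits) > 0))
  logf <- lapply(subsets, function(s) .moebiusLogF(p@prob, nV, nS, s, dflt))
  list(subsets = subsets, logf = logf, nV = nV, nS = nS)
}

#' Verify the factorization condition of the candidate potentials
#'
#' Recomputes every candidate potential f_sigma and checks that their
#' product over all subsets of the vertex set reproduces the joint table:
#' max relative deviation below `tol`.
#'
#' @param p a strictly positive [JointTable-class].
#' @param tol relative tolerance (default 1e-8).
#' @param maxVertices guard: 2^nV subsets are enumerated (default 10).
#' @return list with `pass` (logical), `maxRelError`, and `worstConfig`
#'   (index of the worst configuration).
#' @export
verifyFactorization <- function(p, tol = 1e-8, maxVertices = 10L) {
  dec <- .allSubsetLogF(p, maxVertices)
  tot <- numeric(length(p@prob))
  for (s in seq_along(dec$subsets)) {
    ridx <- .restrictionIndex(dec$nV, dec$nS, dec$subsets[[s]])
    tot <- tot + dec$logf[[s]][ridx]
  }
  rel <- abs(exp(tot) - p@prob) / p@prob
  list(pass = max(rel) < tol, maxRelError = max(rel),
       worstConfig = which.max(rel))
}

#' Verify that candidate potentials vanish off the cliques
#'
#' Checks that for every subset sigma that is NOT a clique of `g`, the
#' candidate potential f_sigma is identically 1 (within `tol`).  This is the
#' graphical half of turning a Markov measure into a Gibbs factorization: it
#' holds when `p` satisfies the Markov property with respect to `g`, and
#' fails (reporting the worst offending subset) when `p` carries an
#' interaction that `g` does not draw.
#'
#' @param p a strictly positive [JointTable-class].
#' @param g a [MultilayerGraph-class] on the same vertex set.
#' @param tol absolute tolerance on |f - 1| (default 1e-8).
#' @param maxVertices guard (default 10).
#' @return list with `pass`, `maxDeviation`, `worstSubset` (integer ids).
#' @export
verifyCliqueSupport <- function(p, g, tol = 1e-8, maxVertices = 10L) {
  nV <- p@nVars * p@nLayers
  if (nV != g@nVars * g@nLayers) .stopf("graph and joint table shapes differ")
  dec <- .allSubsetLogF(p, maxVertices)
  adj <- matrix(FALSE, nV, nV)
  if (nrow(g@edges) > 0L) {
    adj[g@edges] <- TRUE
    adj[g@edges[, 2:1, drop = FALSE]] <- TRUE
  }
  isCl <- function(s) {
    if (length(s) <= 1L) return(TRUE)
    all(adj[t(utils::combn(s, 2L))])
  }
  worst <- 0
  worstSubset <- integer(0)
  for (i in seq_along(dec$subsets)) {
    s <- dec$subsets[[i]]
    if (length(s) < 2L || isCl(s)) next
    dev <- max(abs(exp(dec$logf[[i]]) - 1))
    if (dev > worst) {
      worst <- dev
      worstSubset <- s
    }
  }
  list(pass = worst < tol, maxDeviation = worst, worstSubset = worstSubset)
}

#' Minimal independence map of a strictly positive joint
#'
#' Draws an edge between two vertices exactly when they are NOT
#' conditionally independent given all remaining vertices (the pairwise
#' Markov relation, tested in product form on the exact joint).  For a
#' strictly positive measure this graph is the unique minimal I-map.
#'
#' @param p a strictly positive [JointTable-class].
#' @param tol tolerance for classifying a pair as conditionally independent
#'   (default 1e-6 on the normalised product-form deviation).
#' @return a [MultilayerGraph-class] with `p`'s shape and name registries.
#' @export
ciGraphFromJoint <- function(p, tol = 1e-6) {
  .checkPositivity(p)
  nV <- p@nVars * p@nLayers
  edges <- matrix(integer(0), ncol = 2L)
  if (nV >= 2L) {
    prs <- t(utils::combn(nV, 2L))
    keep <- vapply(seq_len(nrow(prs)), function(r) {
      u <- prs[r, 1L]; v <- prs[r, 2L]
      dev <- .ciDeviation(p, u, v, setdiff(seq_len(nV), c(u, v)))
      dev >= tol
    }, logical(1L))
    edges <- prs[keep, , drop = FALSE]
  }
  mlGraph(p@nVars, p@nLayers, edges = edges,
          varNames = p@varNames, layerNames = p@layerNames)
}
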