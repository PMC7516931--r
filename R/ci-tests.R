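# Conditional independence on exact joint tables is tested in product form,
#
#   | P(u, v, S) * P(S)  -  P(u, S) * P(v, S) |  /  P(S)^2  <  tol
#
# (maximised over all configurations), which avoids dividing by small
# marginals and works directly with joint and marginal probabilities.

# generalised set version: A _||_ B | C
.ciSetDeviation <- function(p, aSet, bSet, cSet) {
  nV <- p@nVars * p@nLayers
  nS <- nLabels(p@labels)
  aSet <- sort(as.integer(aSet))
  bSet <- sort(as.integer(bSet))
  cSet <- sort(as.integer(cSet))
  abc <- sort(c(aSet, bSet, cSet))
  Pabc <- .marginal(p@prob, nV, nS, abc)
  m <- seq_along(Pabc)
  idxOf <- function(sub) {
    if (!length(sub)) return(rep(1, length(m)))
    i <- rep(1, length(m))
    for (t in seq_along(sub)) {
      i <- i + (.configLabels(m, match(sub[t], abc), nS) - 1) * nS^(t - 1)
    }
    i
  }
  ac <- sort(c(aSet, cSet))
  bc <- sort(c(bSet, cSet))
  Pc <- .marginal(p@prob, nV, nS, cSet)
  Pac <- .marginal(p@prob, nV, nS, ac)
  Pbc <- .marginal(p@prob, nV, nS, bc)
  pcm <- Pc[idxOf(cSet)]
  max(abs(Pabc * pcm - Pac[idxOf(ac)] * Pbc[idxOf(bc)]) / pcm^2)
}

.ciDeviation <- function(p, u, v, s) .ciSetDeviation(p, u, v, s)

#' Conditional kernel C_A(B) = P(B | A) from an exact joint
#'
#' Materialises the conditional distribution of the target set given every
#' configuration of the conditioning set, by exact marginal summation.  The
#' kernels satisfy the recursion C_A(D | C) = C_A(C, D) / C_A(C), which the
#' test suite exercises on random joints.
#'
#' @param p a strictly positive [JointTable-class].
#' @param a integer vertex ids of the conditioning set (may be empty, giving
#'   the marginal of `b`).
#' @param b integer vertex ids of the target set, disjoint from `a`.
#' @return a [ConditionalKernel-class]; rows index configurations of `a`
#'   (little-endian over sorted ids), columns configurations of `b`.
#' @export
conditionalKernel <- function(p, a, b) {
  .checkPositivity(p)
  a <- sort(unique(as.integer(a)))
  b <- sort(unique(as.integer(b)))
  if (length(intersect(a, b))) .stopf("conditioning and target sets overlap")
  if (!length(b)) .stopf("target set must be non-empty")
  nV <- p@nVars * p@nLayers
  nS <- nLabels(p@labels)
  ab <- sort(c(a, b))
  Pab <- .marginal(p@prob, nV, nS, ab)
  m <- seq_along(Pab)
  idxOf <- function(sub) {
    if (!length(sub)) return(rep(1, length(m)))
    i <- rep(1, length(m))
    for (t in seq_along(sub)) {
      i <- i + (.configLabels(m, match(sub[t], ab), nS) - 1) * nS^(t - 1)
    }
    i
  }
  tab <- matrix(0, nrow = nS^length(a), ncol = nS^length(b))
  tab[cbind(idxOf(a), idxOf(b))] <- Pab
  tab <- tab / rowSums(tab)
  new("ConditionalKernel", conditioning = a, target = b, table = tab,
      nLabels = as.integer(nS))
}

setMethod("show", "ConditionalKernel", function(object) {
  cat(sprintf("ConditionalKernel: P(B|A), |A| = %d, |B| = %d (%d x %d table)\n",
              length(object@conditioning), length(object@target),
              nrow(object@table), ncol(object@table)))
})

#' Kernel table accessor
#' @param k a [ConditionalKernel-class].
#' @return the row-stochastic matrix.
#' @export
kernelTable <- function(k) k@table

.ciStatement <- function(u, v, s, dev, tol) {
  new("CIStatement", left = as.integer(u), right = as.integer(v),
      given = sort(as.integer(s)), holds = dev < tol,
      deviation = dev, threshold = tol)
}

setMethod("show", "CIStatement", function(object) {
  cat(sprintf("CIStatement: %d _||_ %d | {%s}: %s (deviation %.3g, threshold %.3g)\n",
              object@left, object@right,
              paste(object@given, collapse = ","),
              if (object@holds) "holds" else "fails",
              object@deviation, object@threshold))
})

#' @name CIStatement-accessors
#' @title Accessors for CI statements
#' @param x a [CIStatement-class].
#' @return `ciHolds`: logical; `ciDeviation`: the measured statistic.
NULL

#' @rdname CIStatement-accessors
#' @export
ciHolds <- function(x) x@holds

#' @rdname CIStatement-accessors
#' @export
ciDeviation <- function(x) x@deviation

#' Conditional independence of two vertices given a set (exact joint)
#'
#' Tests u _||_ v | s on an exact joint table via the cross-multiplied
#' product form (never via explicit conditional tables).
#'
#' @param p a strictly positive [JointTable-class].
#' @param u,v vertex ids, not in `s`.
#' @param s integer vector of conditioning vertex ids (may be empty).
#' @param tol tolerance on the normalised deviation (default 1e-6).
#' @return a [CIStatement-class].
#' @export
ciGivenSet <- function(p, u, v, s = integer(0), tol = 1e-6) {
  .checkPositivity(p)
  u <- as.integer(u); v <- as.integer(v); s <- as.integer(s)
  if (u == v || u %in% s || v %in% s) {
    .stopf("u and v must be distinct and outside the conditioning set")
  }
  .ciStatement(u, v, s, .ciDeviation(p, u, v, s), tol)
}

#' Pairwise Markov test: CI given all remaining vertices
#'
#' @param p a strictly positive [JointTable-class].
#' @param u,v distinct vertex ids.
#' @param tol tolerance (default 1e-6).
#' @return a [CIStatement-class].
#' @export
ciGivenRest <- function(p, u, v, tol = 1e-6) {
  nV <- p@nVars * p@nLayers
  ciGivenSet(p, u, v, setdiff(seq_len(nV), c(u, v)), tol = tol)
}

#' Number of pairwise conditional-independence tests
#'
#' The count of unordered vertex pairs of an N-variable, L-layer field:
#' choose(NL, 2), one test per potential edge.
#'
#' @param nVars,nLayers field shape.
#' @return integer count.
#' @export
countPairwiseTests <- function(nVars, nLayers) {
  nV <- as.integer(nVars) * as.integer(nLayers)
  (nV * (nV - 1L)) %/% 2L
}

#' Is a graph an independence map of a joint distribution?
#'
#' Checks the global Markov property: every graph separation (A, B | C) must
#' correspond to a conditional independence of `p`.  For small vertex sets
#' all disjoint subset triples are enumerated; above `exhaustiveLimit`
#' vertices a documented reduced check is used instead (all pairwise
#' relations given the rest, plus all single-vertex separators), which under
#' strict positivity is what the pairwise-implies-global theorem licenses.
#'
#' @param g a [MultilayerGraph-class].
#' @param p a strictly positive [JointTable-class] on the same vertex set.
#' @param tol CI tolerance (default 1e-6).
#' @param exhaustiveLimit largest vertex count for full triple enumeration
#'   (default 6).
#' @param maxVertices hard capacity guard (default 10).
#' @return list with `pass`, `mode` ("exhaustive" or "reduced") and, on
#'   failure, `counterexample = list(a, b, c, deviation)`.
#' @export
isIndependenceMap <- function(g, p, tol = 1e-6, exhaustiveLimit = 6L,
                              maxVertices = 10L) {
  nV <- p@nVars * p@nLayers
  if (nV != g@nVars * g@nLayers) .stopf("graph and joint table shapes differ")
  if (nV > maxVertices) {
    .stopf("I-map check refused: %d vertices exceeds the guard of %d",
           nV, maxVertices)
  }
  .checkPositivity(p)
  fail <- function(a, b, c, dev) {
    list(pass = FALSE, mode = mode,
         counterexample = list(a = a, b = b, c = c, deviation = dev))
  }
  if (nV <= exhaustiveLimit) {
    mode <- "exhaustive"
    for (code in 0:(4^nV - 1)) {
      digits <- (code %/% 4^(seq_len(nV) - 1)) %% 4
      a <- which(digits == 1)
      b <- which(digits == 2)
      c <- which(digits == 3)
      if (!length(a) || !length(b) || min(a) > min(b)) next
      if (!separates(g, a, b, c)) next
      dev <- .ciSetDeviation(p, a, b, c)
      if (dev >= tol) return(fail(a, b, c, dev))
    }
  } else {
    mode <- "reduced"
    prs <- t(utils::combn(nV, 2L))
    adjKey <- paste(g@edges[, 1L], g@edges[, 2L])
    for (r in seq_len(nrow(prs))) {
      u <- prs[r, 1L]; v <- prs[r, 2L]
      if (paste(u, v) %in% adjKey) next
      dev <- .ciDeviation(p, u, v, setdiff(seq_len(nV), c(u, v)))
      if (dev >= tol) return(fail(u, v, setdiff(seq_len(nV), c(u, v)), dev))
    }
    for (r in seq_len(nrow(prs))) {
      u <- prs[r, 1L]; v <- prs[r, 2L]
      if (paste(u, v) %in% adjKey) next
      for (w in setdiff(seq_len(nV), c(u, v))) {
        if (separates(g, u, v, w)) {
          dev <- .ciDeviation(p, u, v, w)
          if (dev >= tol) return(fail(u, v, w, dev))
        }
      }
    }
  }
  list(pass = TRUE, mode = mode, counterexample = NULL)
}

#' Is a graph a perfect map of a joint distribution?
#'
#' True when the graph is an independence map AND the pairwise-Markov
#' minimal I-map recovered from `p` equals the graph, i.e. the graph encodes
#' exactly the distribution's CI structure.
#'
#' @inheritParams isIndependenceMap
#' @return logical.
#' @export
isPerfectMap <- function(g, p, tol = 1e-6, exhaustiveLimit = 6L,
                         maxVertices = 10L) {
  im <- isIndependenceMap(g, p, tol = tol, exhaustiveLimit = exhaustiveLimit,
                          maxVertices = maxVertices)
  im$pass && sameGraph(ciGraphFromJoint(p, tol = tol), g)
}

#' Empirical conditional-independence test on multilayer samples
#'
#' Estimates the conditional mutual information I(u; v | s) by plug-in on
#' discretised data (summing stratum-wise mutual informations weighted by
#' stratum frequency) and compares it against a stratified permutation null:
#' `v`'s column is permuted within each stratum of the conditioning
#' variables, preserving the (u, s) and (v, s) margins while breaking any
#' conditional association.  Strata with fewer than two samples are skipped
#' with a warning.
#'
#' @param data a [SampleTensor-class].
#' @param u,v vertex ids (see [nodeId()]), distinct and outside `s`.
#' @param s integer vector of conditioning vertex ids, small (default empty;
#'   sizes above `maxGiven` are refused so cells stay populated).
#' @param nBins discretisation bins for continuous columns (default 10).
#' @param alpha test level (default 0.05).
#' @param nPerm number of permutations (default 200).
#' @param seed integer seed.
#' @param maxGiven guard on |s| (default 3).
#' @return a [CIStatement-class]; `deviation` is the CMI estimate (bits),
#'   `threshold` the (1 - alpha) null quantile.
#' @export
empiricalCITest <- function(data, u, v, s = integer(0), nBins = 10L,
                            alpha = 0.05, nPerm = 200L, seed = 1L,
                            maxGiven = 3L) {
  if (length(s) > maxGiven) {
    .stopf("|s| = %d exceeds the guard of %d conditioning vertices",
           length(s), maxGiven)
  }
  N <- nVars(data)
  col <- function(vid) {
    discretize(data@values[, .vidVar(vid, N), .vidLayer(vid, N)], nBins)
  }
  xu <- col(u)
  xv <- col(v)
  strata <- if (length(s)) {
    key <- rep(1, nSamples(data))
    mult <- 1
    for (w in s) {
      cw <- col(w)
      key <- key + (cw - 1) * mult
      mult <- mult * max(cw)
    }
    as.integer(factor(key))
  } else rep(1L, nSamples(data))
  cmiOf <- function(xv2) {
    tot <- 0
    n <- length(xu)
    for (st in unique(strata)) {
      idx <- strata == st
      ns <- sum(idx)
      if (ns < 2L) {
        warning(sprintf("stratum %d has %d sample(s); skipped", st, ns),
                call. = FALSE)
        next
      }
      tot <- tot + ns / n * .miCodes(xu[idx], xv2[idx])
    }
    tot
  }
  est <- cmiOf(xv)
  null <- .withSeed(seed, vapply(seq_len(nPerm), function(r) {
    xp <- xv
    for (st in unique(strata)) {
      idx <- which(strata == st)
      if (length(idx) > 1L) xp[idx] <- xv[sample(idx)]
    }
    cmiOf(xp)
  }, numeric(1L)))
  thr <- as.numeric(stats::quantile(null, 1 - alpha))
  new("CIStatement", left = as.integer(u), right = as.integer(v),
      given = sort(as.integer(s)), holds = est < thr,
      deviation = est, threshold = thr)
}
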