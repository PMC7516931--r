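# Brute-force oracles, written independently of the package internals:
# everything here works by direct enumeration over edge lists, subsets,
# paths or full probability vectors.

`%||%` <- function(a, b) if (is.null(a)) b else a

# the worked multilayer example: N = 4 variables, L = 2 layers (I, II);
# intra-layer triangle {X2I, X3I, X4I} plus the inter-layer edge X3I--X3II
fig3Graph <- function() {
  mlGraph(4, 2, edges = rbind(
    c(2, 1, 3, 1), c(3, 1, 4, 1), c(2, 1, 4, 1), c(3, 1, 3, 2)))
}

vidOf <- function(var, layer, nVars = 4L) (layer - 1L) * nVars + var

bruteNeighbors <- function(g, v) {
  e <- edgeSet(g)
  out <- integer(0)
  for (r in seq_len(nrow(e))) {
    if (e[r, 1L] == v) out <- c(out, e[r, 2L])
    if (e[r, 2L] == v) out <- c(out, e[r, 1L])
  }
  sort(unique(out))
}

bruteIsClique <- function(g, s) {
  s <- sort(unique(s))
  if (length(s) <= 1L) return(TRUE)
  e <- edgeSet(g)
  ek <- paste(e[, 1L], e[, 2L])
  for (i in seq_len(length(s) - 1L)) {
    for (j in (i + 1L):length(s)) {
      if (!(paste(s[i], s[j]) %in% ek)) return(FALSE)
    }
  }
  TRUE
}

# all complete subsets by filtering the power set
bruteCliques <- function(g) {
  nV <- nVars(g) * nLayers(g)
  out <- list(integer(0))
  for (mask in 1:(2^nV - 1)) {
    s <- which(bitwAnd(mask, 2^(0:(nV - 1))) > 0)
    if (bruteIsClique(g, s)) out[[length(out) + 1L]] <- s
  }
  out
}

# does any path avoid c?  depth-first search over vertices not in c
bruteSeparates <- function(g, a, b, c) {
  nV <- nVars(g) * nLayers(g)
  allowed <- setdiff(seq_len(nV), c)
  adj <- lapply(seq_len(nV), function(v) bruteNeighbors(g, v))
  seen <- rep(FALSE, nV)
  stack <- intersect(a, allowed)
  seen[stack] <- TRUE
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v %in% b) return(FALSE)
    nxt <- setdiff(intersect(adj[[v]], allowed), which(seen))
    seen[nxt] <- TRUE
    stack <- c(stack, nxt)
  }
  TRUE
}

# joint table of a Gibbs field by direct per-configuration products
# (plain multiplication, no log domain)
bruteJoint <- function(field) {
  g <- scenarioLikeGraph <- field@graph
  nV <- nVars(g) * nLayers(g)
  nS <- nLabels(field@labels)
  K <- nS^nV
  w <- numeric(K)
  for (m in seq_len(K)) {
    cfg <- integer(nV)
    rem <- m - 1
    for (v in seq_len(nV)) {
      cfg[v] <- rem %% nS + 1
      rem <- rem %/% nS
    }
    prod <- 1
    for (p in field@potentials) {
      k <- length(p$vertices)
      idx <- if (k == 0L) 1L else 1 + sum((cfg[p$vertices] - 1) * nS^(seq_len(k) - 1))
      prod <- prod * exp(p$logTable[idx])
    }
    w[m] <- prod
  }
  w / sum(w)
}

# conditional P(X_v = s | rest = cfg[-v]) from a probability vector
bruteConditional <- function(prob, nV, nS, v, cfg) {
  lab <- function(m, vv) ((m - 1) %/% nS^(vv - 1)) %% nS + 1
  m <- seq_along(prob)
  restOk <- rep(TRUE, length(prob))
  for (vv in setdiff(seq_len(nV), v)) restOk <- restOk & lab(m, vv) == cfg[vv]
  num <- vapply(seq_len(nS), function(s) sum(prob[restOk & lab(m, v) == s]),
                numeric(1L))
  num / sum(num)
}

# strictly positive random joint table on nV binary vertices
randomJoint <- function(nV, seed, nVars = nV, nLayers = 1L) {
  set.seed(seed)
  w <- exp(stats::rnorm(2^nV))
  jointTable(w, nVars, nLayers, binaryLabels())
}

# random binary Gibbs field on a random multilayer graph
randomField <- function(nVarsN, nLayersL, seed, strength = 1.0,
                        pIntra = 0.4, pInter = 0.3) {
  g <- randomMultilayerGraph(nVarsN, nLayersL, pIntra, pInter, seed = seed)
  randomGibbsField(g, strength = strength, seed = seed + 7919L)
}

expect_same_graph <- function(g1, g2) {
  expect_true(sameGraph(g1, g2),
              label = sprintf("edge sets differ: {%s} vs {%s}",
                              paste(apply(edgeSet(g1), 1, paste, collapse = "-"),
                                    collapse = ","),
                              paste(apply(edgeSet(g2), 1, paste, collapse = "-"),
                                    collapse = ",")))
}
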