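# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths (pruning, Cholesky GLS, closed-form lens).

# Dense multivariate-normal log-density via determinant() + solve().
dense_mvn_loglik <- function(x, mean, V) {
  n <- length(x)
  r <- x - mean
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% solve(V, r)))
}

# Brute-force Mk likelihood: sum over all internal (and ambiguous-tip)
# state assignments of prior x product of edge transition probabilities.
enum_mk_loglik <- function(tree, tip_states, model) {
  k <- length(model$states)
  q <- model$q
  P <- function(t) {
    e <- exp(-k * q * t)
    M <- matrix((1 - e) / k, k, k)
    diag(M) <- (1 + (k - 1) * e) / k
    M
  }
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  obs <- tip_states[tree$tip.label]
  tipgrids <- lapply(seq_len(ntip), function(i) {
    if (is.na(obs[i])) seq_len(k) else match(obs[i], model$states)
  })
  intgrid <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
  tipgrid <- as.matrix(expand.grid(tipgrids))
  Pe <- lapply(tree$edge.length, P)
  tot <- 0
  st <- integer(nn)
  for (r in seq_len(nrow(intgrid))) {
    st[(ntip + 1L):nn] <- intgrid[r, ]
    for (rr in seq_len(nrow(tipgrid))) {
      st[seq_len(ntip)] <- tipgrid[rr, ]
      pr <- model$prior[st[ntip + 1L]]
      for (e in seq_len(nrow(tree$edge))) {
        pr <- pr * Pe[[e]][st[tree$edge[e, 1L]], st[tree$edge[e, 2L]]]
      }
      tot <- tot + pr
    }
  }
  unname(log(tot))
}

# Brute-force BM covariance entry: sum of lengths of edges shared by the
# two root-to-tip paths.
path_shared_length <- function(tree, tip_i, tip_j) {
  pe <- function(tip) {
    nodes <- oculoevo:::root_path(tree, tip)
    cbind(nodes[-length(nodes)], nodes[-1L])
  }
  ei <- pe(tip_i); ej <- pe(tip_j)
  key <- function(m) paste(m[, 1L], m[, 2L])
  shared <- intersect(key(ei), key(ej))
  if (!length(shared)) return(0)
  ekey <- paste(tree$edge[, 1L], tree$edge[, 2L])
  sum(tree$edge.length[match(shared, ekey)])
}

# Monte-Carlo lens volume: uniform sampling in the tight bounding box of
# the intersection region (axis through both centers, spheres at 0 and d).
mc_lens_volume <- function(r1, r2, d, n = 2e6) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  xlo <- d - r2; xhi <- r1
  a2 <- (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2) /
    (4 * d^2)
  a <- sqrt(a2)
  x <- runif(n, xlo, xhi)
  y <- runif(n, -a, a)
  z <- runif(n, -a, a)
  inside <- (x^2 + y^2 + z^2 <= r1^2) & ((x - d)^2 + y^2 + z^2 <= r2^2)
  (xhi - xlo) * (2 * a)^2 * mean(inside)
}

# Monte-Carlo boolean volume for points inside sphere A (center 0, radius
# rA) satisfying `cond(x, y, z)`; samples uniformly within sphere A.
mc_sphere_boolean <- function(rA, cond, n = 2e6) {
  m <- ceiling(n / 0.5)
  x <- runif(m, -rA, rA); y <- runif(m, -rA, rA); z <- runif(m, -rA, rA)
  keep <- x^2 + y^2 + z^2 <= rA^2
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  4 / 3 * pi * rA^3 * mean(cond(x, y, z))
}

# Random non-ultrametric tree with positive branch lengths.
rand_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}
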