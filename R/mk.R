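#' Equal-rates Mk model
#'
#' Continuous-time Markov model of a k-state discrete character in which
#' every transition between distinct states occurs at the same rate `q`
#' (the "equal rates" matrix). The root prior defaults to the flat
#' distribution 1/k ("equal root node prior"); analyses such as the
#' mammalian capillarization reconstruction may override it (e.g. 1:0:0).
#'
#' @param states Character vector of state labels (k >= 2).
#' @param q Transition rate (per Myr), > 0.
#' @param prior Optional root prior over states (recycled/normalized);
#'   default flat.
#' @return Object of class `"mk_model"`: `states`, `q`, rate matrix `Q`,
#'   `prior`.
#' @export
mk_model <- function(states, q, prior = NULL) {
  states <- as.character(states)
  k <- length(states)
  stopifnot(k >= 2L, q > 0)
  Q <- matrix(q, k, k, dimnames = list(states, states))
  diag(Q) <- -(k - 1) * q
  if (is.null(prior)) prior <- rep(1 / k, k)
  stopifnot(length(prior) == k, all(prior >= 0), sum(prior) > 0)
  prior <- prior / sum(prior)
  structure(list(states = states, q = q, Q = Q,
                 prior = stats::setNames(prior, states)),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat("Equal-rates Mk model, k =", length(x$states),
      "states:", paste(x$states, collapse = ", "), "\n")
  cat("  q =", format(x$q, digits = 6), "per Myr; root prior:",
      paste(format(x$prior, digits = 3), collapse = ":"), "\n")
  invisible(x)
}

# Transition probability matrix of the ER model over time t (closed form:
# eigenvalues 0 and -k q).
.p_er <- function(t, k, q) {
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- (1 + (k - 1) * e) / k
  P
}

# Tip partial-likelihood matrix: one-hot rows; NA/ambiguous -> all ones.
.tip_partials <- function(tree, tip_states, states) {
  ntip <- length(tree$tip.label)
  k <- length(states)
  L <- matrix(1, ntip, k)
  obs <- tip_states[tree$tip.label]
  bad <- setdiff(unique(obs[!is.na(obs)]), states)
  if (length(bad)) stop("states not in model: ", paste(bad, collapse = ", "))
  for (i in seq_len(ntip)) {
    if (!is.na(obs[i])) {
      L[i, ] <- 0
      L[i, match(obs[i], states)] <- 1
    }
  }
  L
}

# Felsenstein pruning: returns log-likelihood plus the per-node conditional
# partials and per-edge messages needed for marginal ASR and mapping.
.mk_prune <- function(tree, tip_states, model) {
  states <- model$states; k <- length(states); q <- model$q
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  if (any(!is.finite(po$edge.length))) stop("non-finite branch length")
  D <- matrix(1, nn, k)
  D[seq_len(ntip), ] <- .tip_partials(tree, tip_states, states)
  logscale <- 0
  msg <- matrix(NA_real_, nrow(po$edge), k)   # msg[e, i] = sum_j P_ij D_child(j)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    P <- .p_er(po$edge.length[e], k, q)
    m <- as.vector(P %*% D[ch, ])
    sc <- max(m)
    if (sc <= 0) stop("zero likelihood on edge to node ", ch)
    msg[e, ] <- m
    D[p, ] <- D[p, ] * (m / sc)
    logscale <- logscale + log(sc)
  }
  lik_root <- sum(model$prior * D[ntip + 1L, ])
  list(loglik = log(lik_root) + logscale, D = D, msg = msg, po = po)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' @param tree A `"phylo"` tree.
#' @param tip_states Named character vector of tip states; `NA` (or absent
#'   species) are treated as fully ambiguous, not pruned.
#' @param model An `"mk_model"`.
#' @return Log-likelihood (numeric scalar).
#' @export
mk_loglik <- function(tree, tip_states, model) {
  validate_tree(tree)
  .mk_prune(tree, tip_states, model)$loglik
}

#' Fit the equal-rates Mk model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over the single transition rate by
#' bounded search on log(q) in [-15, 5] (q in 1/Myr). If only one state is
#' observed among the tips the likelihood is maximized at the lower search
#' bound and a degeneracy flag is set.
#'
#' @param tree A `"phylo"` tree.
#' @param tip_states Named character vector of tip states (`NA` ambiguous).
#' @param states Optional state set (default: sorted observed states).
#' @param prior Optional root prior (default flat).
#' @return Object of class `"mk_fit"`: fitted `"mk_model"` as `model`,
#'   `loglik`, `q`, and `degenerate` flag.
#' @export
fit_mk_er <- function(tree, tip_states, states = NULL, prior = NULL) {
  obs <- tip_states[!is.na(tip_states)]
  if (is.null(states)) states <- sort(unique(as.character(obs)))
  if (length(states) < 2L) {
    stop("state set must contain >= 2 states (supply `states` explicitly ",
         "for characters observed in one state only)")
  }
  degenerate <- length(unique(obs)) < 2L
  obj <- function(lq) {
    -mk_loglik(tree, tip_states, mk_model(states, exp(lq), prior))
  }
  if (degenerate) {
    lq <- -15
  } else {
    o <- stats::optimize(obj, c(-15, 5), tol = 1e-10)
    lq <- o$minimum
  }
  q <- exp(lq)
  model <- mk_model(states, q, prior)
  structure(list(model = model, q = q,
                 loglik = mk_loglik(tree, tip_states, model),
                 degenerate = degenerate),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("ML equal-rates Mk fit: q =", format(x$q, digits = 6),
      "per Myr, logL =", format(x$loglik, digits = 8), "\n")
  if (x$degenerate) cat("  [single observed state: q at lower search bound]\n")
  invisible(x)
}

#' Marginal ancestral state probabilities under an Mk model
#'
#' Exact marginal conditional probability of each state at every node given
#' the tip data, by a root-to-tip pass over the pruning partials. Serves as
#' the analytic reference that stochastic-map node frequencies converge to.
#'
#' @inheritParams mk_loglik
#' @return Matrix (nodes x states) of posterior probabilities; rows are ape
#'   node ids, each row sums to 1.
#' @export
mk_marginal <- function(tree, tip_states, model) {
  pr <- .mk_prune(tree, tip_states, model)
  states <- model$states; k <- length(states); q <- model$q
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- pr$po
  root <- ntip + 1L
  U <- matrix(NA_real_, nn, k)
  U[root, ] <- model$prior
  # child edges of each parent, in postorder edge indexing
  for (e in rev(seq_len(nrow(po$edge)))) {   # preorder
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    sib <- which(po$edge[, 1L] == p & seq_len(nrow(po$edge)) != e)
    above <- U[p, ]
    for (s in sib) above <- above * pr$msg[s, ]
    P <- .p_er(po$edge.length[e], k, q)
    u <- as.vector(above %*% P)
    U[ch, ] <- u / max(u)
  }
  post <- U * pr$D
  post <- post / rowSums(post)
  dimnames(post) <- list(as.character(seq_len(nn)), states)
  post
}
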