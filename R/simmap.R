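# Forward CTMC path under the ER model from state i for time t.
# Returns list(states, times) of jump targets and jump times (possibly empty).
.forward_path <- function(i, t, k, q) {
  rate <- (k - 1) * q
  st <- integer(0); tm <- numeric(0)
  cur <- i; now <- 0
  repeat {
    now <- now + stats::rexp(1L, rate)
    if (now >= t) break
    cur <- sample.int(k - 1L, 1L)
    cur <- if (cur >= i) cur + 1L else cur   # uniform over states != previous
    i <- cur
    st <- c(st, cur); tm <- c(tm, now)
  }
  list(states = st, times = tm)
}

# (R^n)_{ij} for the uniformized jump chain of the ER model with
# lambda = (k-1) q: R is uniform over the other k-1 states (zero diagonal),
# eigenvalues 1 and -1/(k-1).
.rn_er <- function(n, same, k) {
  if (n == 0L) return(as.numeric(same))
  v <- (-1 / (k - 1))^n
  if (same) (1 + (k - 1) * v) / k else (1 - v) / k
}

# Endpoint-conditioned path sampling: rejection with a forced first jump
# when the endpoints differ, falling back to uniformization after
# `max_tries` rejections. Uses lambda = (k-1)q so every uniformized jump is
# a real state change (no virtual jumps to collapse).
.sample_path_cond <- function(i, j, t, k, q, max_tries = 1000L) {
  rate <- (k - 1) * q
  if (t <= 0) {
    if (i != j) stop("state change on zero-length branch")
    return(list(states = integer(0), times = numeric(0)))
  }
  for (try in seq_len(max_tries)) {
    if (i == j) {
      p <- .forward_path(i, t, k, q)
    } else {
      # first jump time from the exponential truncated to (0, t)
      u <- stats::runif(1L)
      tau <- -log(1 - u * (1 - exp(-rate * t))) / rate
      s1 <- sample.int(k - 1L, 1L)
      s1 <- if (s1 >= i) s1 + 1L else s1
      rest <- .forward_path(s1, t - tau, k, q)
      p <- list(states = c(s1, rest$states), times = c(tau, rest$times + tau))
    }
    end <- if (length(p$states)) p$states[length(p$states)] else i
    if (end == j) return(p)
  }
  .sample_path_unif(i, j, t, k, q)
}

# Uniformization sampler (exact), used as the fallback.
.sample_path_unif <- function(i, j, t, k, q) {
  lambda <- (k - 1) * q
  e <- exp(-k * q * t)
  pij <- if (i == j) (1 + (k - 1) * e) / k else (1 - e) / k
  u <- stats::runif(1L) * pij
  nmax <- max(50L, ceiling(10 * lambda * t + 50))
  cum <- 0; n <- -1L
  for (m in 0L:nmax) {
    cum <- cum + stats::dpois(m, lambda * t) * .rn_er(m, i == j, k)
    if (cum >= u) { n <- m; break }
  }
  if (n < 0L) n <- nmax   # numerically saturated tail; nmax is far out
  if (n == 0L) return(list(states = integer(0), times = numeric(0)))
  states <- integer(n)
  cur <- i
  for (m in seq_len(n)) {
    rem <- n - m
    w <- vapply(seq_len(k), function(s) {
      if (s == cur) 0 else .rn_er(rem, s == j, k)
    }, 0)
    if (sum(w) <= 0) { states[m:n] <- j; break }
    cur <- sample.int(k, 1L, prob = w)
    states[m] <- cur
  }
  states[n] <- j
  times <- sort(stats::runif(n, 0, t))
  keep <- c(TRUE, states[-1L] != states[-n])   # defensive; should all differ
  list(states = states[keep], times = times[keep])
}

#' Stochastic character mapping under the equal-rates Mk model
#'
#' Draws full character histories on the tree conditional on the tip states
#' and the model: node states are sampled root-to-tip from their conditional
#' distributions over the pruning partials, and each branch interior is
#' sampled conditional on its endpoint states by rejection sampling of
#' Markov paths (retry cap 1000), with an exact uniformization fallback.
#'
#' @param tree A `"phylo"` tree.
#' @param tip_states Named character vector of tip states (`NA` ambiguous).
#' @param model An `"mk_model"`; if `NULL`, fitted by [fit_mk_er()].
#' @param n_maps Number of maps (the study battery uses 10,000).
#' @param seed Integer seed (mandatory).
#' @return Object of class `"simmap_set"`: `maps` (each with integer
#'   `node_states` over all nodes and `segments`, a per-edge list of
#'   `states`/`times` jump records), plus `tree`, `model`, `n_maps`.
#' @export
simmap_sample <- function(tree, tip_states, model = NULL, n_maps = 100L,
                          seed) {
  if (missing(seed)) stop("seed is mandatory")
  validate_tree(tree)
  if (is.null(model)) model <- fit_mk_er(tree, tip_states)$model
  pr <- .mk_prune(tree, tip_states, model)
  k <- length(model$states); q <- model$q
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- pr$po
  pre <- rev(seq_len(nrow(po$edge)))
  root <- ntip + 1L
  root_w <- model$prior * pr$D[root, ]
  Ps <- lapply(po$edge.length, .p_er, k = k, q = q)
  set.seed(as.integer(seed))
  maps <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    ns <- integer(nn)
    ns[root] <- sample.int(k, 1L, prob = root_w)
    segs <- vector("list", nrow(po$edge))
    for (e in pre) {
      p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
      w <- Ps[[e]][ns[p], ] * pr$D[ch, ]
      ns[ch] <- sample.int(k, 1L, prob = w)
      path <- .sample_path_cond(ns[p], ns[ch], po$edge.length[e], k, q)
      if (length(path$states)) segs[[e]] <- path
    }
    maps[[m]] <- list(node_states = ns, segments = segs)
  }
  structure(list(maps = maps, tree = tree, model = model,
                 n_maps = as.integer(n_maps), edge = po$edge,
                 edge.length = po$edge.length),
            class = "simmap_set")
}

#' @export
print.simmap_set <- function(x, ...) {
  cat("Stochastic character maps:", x$n_maps, "samples,",
      length(x$model$states), "states, q =",
      format(x$model$q, digits = 5), "\n")
  invisible(x)
}

# Piecewise-constant segments (state, dwell) of edge e in map m,
# reconstructing constant branches from the endpoint states.
.edge_segments <- function(set, map, e) {
  t <- set$edge.length[e]
  start <- map$node_states[set$edge[e, 1L]]
  sg <- map$segments[[e]]
  if (is.null(sg)) {
    return(list(states = start, dwell = t))
  }
  states <- c(start, sg$states)
  bounds <- c(0, sg$times, t)
  list(states = states, dwell = diff(bounds))
}

#' Summarize a set of stochastic maps
#'
#' Empirical node posteriors (state frequencies across maps), mean
#' per-branch time-in-state fractions, and gain/loss counts for a
#' designated "present" state: distributional counts (mean, median, 95%
#' interval over maps, per branch and total) alongside the headline counts
#' on the modal node reconstruction via [detect_transitions()].
#'
#' @param set A `"simmap_set"`.
#' @param present State label counted as "present" for gain/loss direction;
#'   default the last state in the model's state set.
#' @return Object of class `"simmap_summary"`: `posterior` (node x state
#'   matrix), `time_in_state` (edge x state), `gains`/`losses` summaries,
#'   `per_branch` mean counts, `modal` transition table, and bookkeeping
#'   fields.
#' @export
simmap_summarize <- function(set, present = NULL) {
  stopifnot(inherits(set, "simmap_set"))
  states <- set$model$states; k <- length(states)
  if (is.null(present)) present <- states[k]
  pi_idx <- match(present, states)
  if (is.na(pi_idx)) stop("unknown state: ", present)
  nn <- length(set$maps[[1L]]$node_states)
  ne <- nrow(set$edge)
  nmap <- set$n_maps
  post <- matrix(0, nn, k, dimnames = list(as.character(seq_len(nn)), states))
  tis <- matrix(0, ne, k, dimnames = list(NULL, states))
  gains_b <- losses_b <- matrix(0, ne, nmap)
  for (m in seq_len(nmap)) {
    ns <- set$maps[[m]]$node_states
    post[cbind(seq_len(nn), ns)] <- post[cbind(seq_len(nn), ns)] + 1
    for (e in seq_len(ne)) {
      sg <- .edge_segments(set, set$maps[[m]], e)
      for (s in seq_along(sg$states)) {
        tis[e, sg$states[s]] <- tis[e, sg$states[s]] + sg$dwell[s]
      }
      if (length(sg$states) > 1L) {
        from <- sg$states[-length(sg$states)]; to <- sg$states[-1L]
        gains_b[e, m] <- sum(from != pi_idx & to == pi_idx)
        losses_b[e, m] <- sum(from == pi_idx & to != pi_idx)
      }
    }
  }
  post <- post / nmap
  tl <- ifelse(set$edge.length > 0, set$edge.length, 1)
  tis <- tis / (nmap * tl)
  gt <- colSums(gains_b); lt <- colSums(losses_b)
  summ <- function(v) {
    c(mean = mean(v), median = stats::median(v),
      q2.5 = unname(stats::quantile(v, 0.025)),
      q97.5 = unname(stats::quantile(v, 0.975)))
  }
  modal <- detect_transitions(post, set$tree, present = present,
                              edge = set$edge)
  structure(list(
    posterior = post, time_in_state = tis,
    gains = summ(gt), losses = summ(lt),
    per_branch = data.frame(parent = set$edge[, 1L], child = set$edge[, 2L],
                            gains = rowMeans(gains_b),
                            losses = rowMeans(losses_b)),
    modal = modal, states = states, present = present,
    n_maps = nmap, tree = set$tree
  ), class = "simmap_summary")
}

#' @export
print.simmap_summary <- function(x, ...) {
  cat("Stochastic-map summary over", x$n_maps, "maps; 'present' state:",
      x$present, "\n")
  cat(sprintf("  gains : mean %.2f, median %g, 95%% [%g, %g]\n",
              x$gains["mean"], x$gains["median"], x$gains["q2.5"],
              x$gains["q97.5"]))
  cat(sprintf("  losses: mean %.2f, median %g, 95%% [%g, %g]\n",
              x$losses["mean"], x$losses["median"], x$losses["q2.5"],
              x$losses["q97.5"]))
  cat("  modal-reconstruction transition branches:", nrow(x$modal), "\n")
  invisible(x)
}

#' Branches on which a character most likely transitioned
#'
#' Flags a branch when the posterior probability of the "present" state
#' crosses 0.5 between its parent and child nodes (strict inequalities on
#' both sides; a probability of exactly 0.5 at either end does not count as
#' a crossing). Direction is "gain" when probability rises above 0.5
#' tip-ward, "loss" when it falls below. With interior evaluation points
#' supplied, each sign change along the sequence parent-interior-child
#' counts once.
#'
#' @param posterior Node x state probability matrix (rows = ape node ids),
#'   e.g. from [simmap_summarize()] or [mk_marginal()].
#' @param tree The `"phylo"` tree the posteriors live on.
#' @param present State label whose probability is tracked.
#' @param interior Optional list (indexed by edge row) of numeric vectors of
#'   P(present) at ordered interior points along each branch.
#' @param edge Optional edge matrix (defaults to `tree$edge`).
#' @return Data frame with `parent`, `child`, `direction`, `n_crossings`.
#' @export
detect_transitions <- function(posterior, tree, present, interior = NULL,
                               edge = NULL) {
  if (is.null(edge)) edge <- tree$edge
  p_present <- posterior[, present]
  out <- list()
  for (e in seq_len(nrow(edge))) {
    seqp <- c(p_present[edge[e, 1L]], interior[[e]], p_present[edge[e, 2L]])
    above <- seqp > 0.5
    below <- seqp < 0.5
    crossings <- 0L; direction <- NA_character_
    for (i in seq_len(length(seqp) - 1L)) {
      if ((below[i] && above[i + 1L]) || (above[i] && below[i + 1L])) {
        crossings <- crossings + 1L
        direction <- if (above[i + 1L]) "gain" else "loss"
      }
    }
    if (crossings > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        parent = edge[e, 1L], child = edge[e, 2L],
        direction = direction, n_crossings = crossings)
    }
  }
  if (!length(out)) {
    return(data.frame(parent = integer(0), child = integer(0),
                      direction = character(0), n_crossings = integer(0)))
  }
  do.call(rbind, out)
}
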