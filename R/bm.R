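#' Simulate Brownian motion on a tree
#'
#' Evolves a continuous trait from the root value `z0` along every branch
#' with independent Gaussian increments of variance `sigma2 * branch length`.
#' Both tip values and the true internal-node values are returned so that
#' estimator-recovery tests can compare against ground truth. Multiple
#' independent replicates can be drawn in one call.
#'
#' @param tree A `"phylo"` tree.
#' @param sigma2 Rate (trait units squared per Myr), >= 0.
#' @param z0 Root state.
#' @param seed Integer seed (mandatory: simulation is reproducible by
#'   contract).
#' @param n Number of independent replicates.
#' @return List with `tips` (Ntip x n matrix, rownames = tip labels) and
#'   `nodes` (Nnode x n matrix, rownames = internal node ids).
#' @export
simulate_bm <- function(tree, sigma2, z0 = 0, seed, n = 1L) {
  validate_tree(tree)
  stopifnot(sigma2 >= 0, n >= 1L)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  sims <- .simulate_bm_raw(tree, sigma2, z0, n)
  ntip <- length(tree$tip.label)
  tips <- sims[seq_len(ntip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  nodes <- sims[(ntip + 1L):nrow(sims), , drop = FALSE]
  rownames(nodes) <- as.character((ntip + 1L):(ntip + tree$Nnode))
  list(tips = tips, nodes = nodes)
}

# Core simulator without seed handling; used internally where the RNG
# stream is already positioned (e.g. the pAOV null).
.simulate_bm_raw <- function(tree, sigma2, z0, n) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  lens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  vals <- matrix(NA_real_, nn, n)
  vals[ntip + 1L, ] <- z0
  sds <- sqrt(sigma2 * lens)
  for (e in seq_len(nrow(edges))) {
    vals[edges[e, 2L], ] <- vals[edges[e, 1L], ] + stats::rnorm(n, 0, sds[e])
  }
  vals
}

#' Fit a Brownian-motion model to tip data by maximum likelihood
#'
#' Estimates the root state `z0` (the GLS mean under the BM covariance) and
#' the rate `sigma2`. The ML rate uses the 1/n convention; the REML rate
#' (1/(n-1)) is reported alongside. Species with missing values are dropped
#' and the tree pruned to the complete cases.
#'
#' @param tree A `"phylo"` tree.
#' @param x Named numeric vector of tip values (names = tip labels; `NA`
#'   allowed and dropped).
#' @return Object of class `"bm_fit"`: `z0`, `sigma2` (ML), `sigma2_reml`,
#'   `loglik`, `n`, the pruned `tree`, and a `degenerate` flag set when all
#'   tip values are identical.
#' @export
fit_bm <- function(tree, x) {
  d <- .match_trait(tree, x)
  tree <- d$tree; x <- d$x
  n <- length(x)
  C <- ape::vcv(tree)[names(x), names(x)]
  R <- chol(C)
  logdetC <- 2 * sum(log(diag(R)))
  ones <- rep(1, n)
  Cix <- backsolve(R, forwardsolve(t(R), x))
  Ci1 <- backsolve(R, forwardsolve(t(R), ones))
  z0 <- sum(Cix) / sum(Ci1)
  r <- x - z0
  Q <- sum(r * backsolve(R, forwardsolve(t(R), r)))
  degenerate <- Q < 1e-12 * max(1, sum(x^2))
  sigma2 <- Q / n
  loglik <- if (degenerate) Inf else {
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetC + n)
  }
  structure(list(
    z0 = z0, sigma2 = sigma2, sigma2_reml = Q / (n - 1),
    loglik = loglik, n = n, tree = tree, degenerate = degenerate,
    data = x
  ), class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat("Brownian-motion ML fit (", x$n, " tips)\n", sep = "")
  cat("  root state z0:", format(x$z0, digits = 6), "\n")
  cat("  rate sigma2  :", format(x$sigma2, digits = 6),
      "(ML); ", format(x$sigma2_reml, digits = 6), "(REML)\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8), "\n")
  if (x$degenerate) cat("  [degenerate fit: all tip values identical]\n")
  invisible(x)
}

#' @export
logLik.bm_fit <- function(object, ...) {
  structure(object$loglik, df = 2, class = "logLik")
}

#' @export
coef.bm_fit <- function(object, ...) {
  c(z0 = object$z0, sigma2 = object$sigma2)
}

#' Maximum-likelihood ancestral states of a continuous trait
#'
#' Marginal ML reconstruction under Brownian motion: each internal node's
#' estimate is the conditional (GLS) expectation of the node state given the
#' tip data, with the root state estimated as the GLS mean. The root
#' estimate therefore equals [fit_bm()]'s `z0` exactly, and all estimates
#' are invariant to rescaling branch lengths or to affine transformation of
#' the data. Estimation variances use the plug-in ML rate and account for
#' the estimation of the root state.
#'
#' @param tree A `"phylo"` tree.
#' @param x Named numeric vector of tip values (`NA` dropped, tree pruned).
#' @return Object of class `"bm_asr"`: `nodes` data frame (`node`, `age`,
#'   `estimate`, `variance`), tip observations, the underlying `"bm_fit"`,
#'   and the pruned tree.
#' @export
asr_ml <- function(tree, x) {
  fit <- fit_bm(tree, x)
  tree <- fit$tree
  x <- fit$data
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  internal <- (ntip + 1L):nn
  d <- ape::node.depth.edgelength(tree)  # depths relative to the (new) root
  M <- ape::mrca(tree, full = TRUE)
  tip_idx <- match(names(x), tree$tip.label)
  # cross-covariance (unit rate): shared depth of internal node k and tip i
  Cnt <- matrix(d[M[internal, tip_idx]], nrow = length(internal))
  C <- ape::vcv(tree)[names(x), names(x)]
  R <- chol(C)
  r <- x - fit$z0
  Cir <- backsolve(R, forwardsolve(t(R), r))
  Ci1 <- backsolve(R, forwardsolve(t(R), rep(1, ntip)))
  est <- fit$z0 + as.vector(Cnt %*% Cir)
  CiCt <- backsolve(R, forwardsolve(t(R), t(Cnt)))
  cond <- d[internal] - colSums(t(Cnt) * CiCt)
  mean_adj <- (1 - as.vector(Cnt %*% Ci1))^2 / sum(Ci1)
  vars <- fit$sigma2 * pmax(cond + mean_adj, 0)
  ages <- node_ages(tree)
  nodes <- data.frame(node = internal, age = ages[internal],
                      estimate = est, variance = vars)
  structure(list(nodes = nodes, tips = x, fit = fit, tree = tree),
            class = "bm_asr")
}

#' @export
print.bm_asr <- function(x, ...) {
  cat("ML ancestral state reconstruction (BM), ", length(x$tips),
      " tips, ", nrow(x$nodes), " internal nodes\n", sep = "")
  cat("  root estimate:", format(x$nodes$estimate[1L], digits = 6),
      " (age", format(x$nodes$age[1L], digits = 5), "Myr)\n")
  invisible(x)
}

# Map every node of a pruned tree to its id in the full tree: tips by label,
# internal nodes as the MRCA (in the full tree) of their descendant tips.
map_nodes_to <- function(sub, full) {
  ntip_s <- length(sub$tip.label)
  nn_s <- ntip_s + sub$Nnode
  po <- ape::reorder.phylo(sub, "postorder")
  clades <- vector("list", nn_s)
  for (i in seq_len(ntip_s)) clades[[i]] <- sub$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    clades[[p]] <- c(clades[[p]], clades[[ch]])
  }
  out <- integer(nn_s)
  out[seq_len(ntip_s)] <- match(sub$tip.label, full$tip.label)
  for (k in (ntip_s + 1L):nn_s) out[k] <- ape::getMRCA(full, clades[[k]])
  out
}

#' Per-layer ancestral reconstruction of retinal layer thicknesses
#'
#' Applies [asr_ml()] independently to each retinal layer column
#' (complete cases per layer), then reports the stacked sum of layer
#' reconstructions at every node of the input tree alongside the
#' independently reconstructed total thickness, with their discrepancy
#' made explicit rather than hidden: the two need not agree when
#' missingness differs between layers and total.
#'
#' @param tree A `"phylo"` tree.
#' @param layers Data frame of per-species layer thicknesses (um); species
#'   in `rownames` or a `species` column; canonical columns are PEPRL, ONL,
#'   OPL, INL, IPL, GCL, NFL but any set is accepted.
#' @param total Optional named vector of independently measured total
#'   thickness for its own reconstruction.
#' @return Object of class `"asr_layers"`: `per_layer` (named list of
#'   `"bm_asr"`), `n_per_layer`, and `stacked` data frame (`node`, `age`,
#'   `stacked`, `total`, `discrepancy`) on the input tree's node ids.
#' @export
asr_layers <- function(tree, layers, total = NULL) {
  layers <- as.data.frame(layers)
  if ("species" %in% names(layers)) {
    rownames(layers) <- layers$species
    layers$species <- NULL
  }
  per_layer <- list()
  n_per_layer <- integer(0)
  node_est <- list()
  for (nm in names(layers)) {
    x <- stats::setNames(as.numeric(layers[[nm]]), rownames(layers))
    x <- x[!is.na(x)]
    if (length(x) < 2L) next
    a <- asr_ml(tree, x)
    per_layer[[nm]] <- a
    n_per_layer[nm] <- length(a$tips)
    ids <- map_nodes_to(a$tree, tree)
    ntip_s <- length(a$tree$tip.label)
    node_est[[nm]] <- stats::setNames(a$nodes$estimate,
                                      ids[a$nodes$node])
  }
  if (!length(per_layer)) stop("no layer has >= 2 observed species")
  common <- Reduce(intersect, lapply(node_est, names))
  stacked_sum <- rowSums(sapply(node_est, function(v) v[common]))
  ages <- node_ages(tree)[as.integer(common)]
  stacked <- data.frame(node = as.integer(common), age = ages,
                        stacked = as.numeric(stacked_sum),
                        total = NA_real_, discrepancy = NA_real_)
  total_asr <- NULL
  if (!is.null(total)) {
    total_asr <- asr_ml(tree, total[!is.na(total)])
    ids <- map_nodes_to(total_asr$tree, tree)
    tot <- stats::setNames(total_asr$nodes$estimate, ids[total_asr$nodes$node])
    m <- match(stacked$node, as.integer(names(tot)))
    stacked$total <- as.numeric(tot[m])
    stacked$discrepancy <- stacked$stacked - stacked$total
  }
  structure(list(per_layer = per_layer, n_per_layer = n_per_layer,
                 stacked = stacked, total_asr = total_asr),
            class = "asr_layers")
}

#' @export
print.asr_layers <- function(x, ...) {
  cat("Per-layer ancestral reconstruction:",
      paste(names(x$per_layer), collapse = ", "), "\n")
  cat("  species per layer:",
      paste(sprintf("%s=%d", names(x$n_per_layer), x$n_per_layer),
            collapse = ", "), "\n")
  if (!all(is.na(x$stacked$discrepancy))) {
    cat("  max |stacked - total| discrepancy:",
        format(max(abs(x$stacked$discrepancy), na.rm = TRUE), digits = 4), "\n")
  }
  invisible(x)
}

# Align a named trait vector with tree tips; drop NAs, prune, preserve order.
.match_trait <- function(tree, x) {
  if (is.null(names(x))) stop("trait vector must be named by species")
  x <- x[!is.na(x)]
  unknown <- setdiff(names(x), tree$tip.label)
  if (length(unknown)) {
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(x) < 2L) stop("need >= 2 species with data")
  if (length(x) < length(tree$tip.label)) {
    tree <- prune_to_taxa(tree, names(x))
  }
  x <- x[tree$tip.label]
  list(tree = tree, x = x)
}
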