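# One-way F statistics for each column of Y given a grouping factor.
.f_stats <- function(Y, g) {
  N <- nrow(Y); k <- nlevels(g)
  ng <- tabulate(g, k)
  grand <- colMeans(Y)
  gm <- rowsum(Y, g) / ng
  ssb <- colSums(ng * (sweep(gm, 2L, grand))^2)
  sst <- colSums(sweep(Y, 2L, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  (ssb / (k - 1)) / (ssw / (N - k))
}

#' Simulation-based phylogenetic analysis of variance
#'
#' Tests for a difference in a continuous trait between groups of species
#' while accounting for phylogenetic non-independence. The observed
#' statistic is the classical one-way ANOVA F on the species values; its
#' null distribution is built by simulating the trait under Brownian motion
#' on the tree (rate estimated from the observed trait by [fit_bm()],
#' ignoring groups) `n_sim` times and recomputing F on every replicate.
#' The phylogenetic p-value is `(1 + #\{F_sim >= F_obs\}) / (1 + n_sim)`.
#'
#' @param tree A `"phylo"` tree.
#' @param y Named numeric trait vector (names = species).
#' @param groups Named factor or character vector of group labels.
#' @param n_sim Number of Brownian null replicates (the study battery uses
#'   50,000).
#' @param seed Integer seed (mandatory).
#' @return Object of class `"phylo_anova"`: `F`, `p.value`, `n_sim`,
#'   `group_means`, `n_per_group`, `sigma2` used for the null, the null
#'   F sample, and a `degenerate` flag when within-group variance is zero.
#' @export
phylo_anova <- function(tree, y, groups, n_sim = 50000L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  groups <- stats::setNames(as.character(groups), names(groups))
  common <- intersect(names(y)[!is.na(y)], names(groups)[!is.na(groups)])
  y <- y[common]; groups <- factor(groups[common])
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(tabulate(groups) < 2L)) stop("every group needs >= 2 species")
  fit <- fit_bm(tree, y)
  tr <- fit$tree
  g <- groups[tr$tip.label]
  yv <- fit$data
  ntip <- length(tr$tip.label)
  Fobs <- .f_stats(matrix(yv, ncol = 1L), g)
  degenerate <- !is.finite(Fobs)
  set.seed(as.integer(seed))
  Fsim <- numeric(0)
  left <- as.integer(n_sim)
  while (left > 0L) {
    m <- min(left, 10000L)
    Y <- .simulate_bm_raw(tr, fit$sigma2, 0, m)[seq_len(ntip), , drop = FALSE]
    Fsim <- c(Fsim, .f_stats(Y, g))
    left <- left - m
  }
  p <- if (degenerate) 1 / (1 + n_sim) else (1 + sum(Fsim >= Fobs)) / (1 + n_sim)
  structure(list(
    F = Fobs, p.value = p, n_sim = as.integer(n_sim),
    group_means = tapply(yv, g, mean), n_per_group = table(g),
    sigma2 = fit$sigma2, null_F = Fsim, degenerate = degenerate,
    n = length(yv)
  ), class = "phylo_anova")
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat("Phylogenetic ANOVA (Brownian simulation null, n_sim = ",
      x$n_sim, ")\n", sep = "")
  cat("  F = ", format(x$F, digits = 5), ", p = ",
      format(x$p.value, digits = 4), ", n = ", x$n, "\n", sep = "")
  cat("  group means:\n")
  print(round(x$group_means, 4))
  if (x$degenerate) cat("  [zero within-group variance: F infinite]\n")
  invisible(x)
}

#' One-way ANOVA with Student-Newman-Keuls posthoc letters
#'
#' Classical one-way ANOVA followed by the SNK stepwise studentized-range
#' procedure at a fixed alpha: ordered group means are compared over
#' decreasing range spans, a non-significant range protects all its
#' sub-ranges, and groups sharing a letter are not distinguished. Unequal
#' group sizes are handled with the pairwise harmonic mean (Tukey-Kramer
#' style) and flagged.
#'
#' @param values Numeric response vector.
#' @param groups Factor (or coercible) of group labels, same length.
#' @param alpha Familywise level of the range tests.
#' @return Object of class `"snk_anova"`: `F`, `df`, `p.value`,
#'   `group_means`, `n_per_group`, `letters` (named by group), and
#'   `unequal_n` flag.
#' @export
oneway_anova_snk <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(factor(groups[ok]))
  k <- nlevels(groups); N <- length(values)
  if (k < 2L) stop("need >= 2 groups")
  if (any(tabulate(groups) == 0L)) stop("empty group")
  if (N <= k) stop("need total n > number of groups")
  ng <- tabulate(groups, k)
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(ng * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1L; df2 <- N - k
  mse <- ssw / df2
  Fv <- (ssb / df1) / mse
  pv <- stats::pf(Fv, df1, df2, lower.tail = FALSE)

  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; n_ord <- ng[ord]
  ns <- matrix(FALSE, k, k)    # TRUE when range [i, j] declared homogeneous
  test_range <- function(i, j) {
    if (j <= i || ns[i, j]) return(invisible())
    r <- j - i + 1L
    se <- sqrt(mse / 2 * (1 / n_ord[i] + 1 / n_ord[j]))
    cd <- stats::qtukey(1 - alpha, r, df2) * se
    if (abs(m[i] - m[j]) > cd) {
      test_range(i + 1L, j)
      test_range(i, j - 1L)
    } else {
      for (a in i:j) for (b in a:j) ns[a, b] <<- TRUE
    }
  }
  test_range(1L, k)
  diag(ns) <- TRUE
  # maximal homogeneous intervals -> letters
  intervals <- list()
  for (i in seq_len(k)) {
    j <- max(which(ns[i, ]))
    intervals[[i]] <- c(i, j)
  }
  intervals <- unique(intervals)
  keep <- vapply(intervals, function(iv) {
    !any(vapply(intervals, function(o) {
      (o[1] <= iv[1] && o[2] >= iv[2]) && !identical(o, iv)
    }, TRUE))
  }, TRUE)
  intervals <- intervals[keep]
  intervals <- intervals[order(vapply(intervals, `[`, 0, 1))]
  letts <- rep("", k)
  for (h in seq_along(intervals)) {
    iv <- intervals[[h]]
    letts[iv[1]:iv[2]] <- paste0(letts[iv[1]:iv[2]], letters[h])
  }
  letters_out <- stats::setNames(letts[order(ord)], levels(groups))
  structure(list(
    F = Fv, df = c(df1, df2), p.value = pv,
    group_means = means, n_per_group = stats::setNames(ng, levels(groups)),
    letters = letters_out, alpha = alpha, mse = mse,
    unequal_n = length(unique(ng)) > 1L
  ), class = "snk_anova")
}

#' @export
print.snk_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p.value))
  tab <- data.frame(mean = round(x$group_means, 4),
                    n = as.integer(x$n_per_group),
                    SNK = x$letters[names(x$group_means)])
  print(tab)
  if (x$unequal_n) {
    cat("  [unequal group sizes: pairwise harmonic-mean n used in SNK]\n")
  }
  invisible(x)
}
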