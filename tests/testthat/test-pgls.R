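test_that("PGLS on a star tree reproduces OLS exactly", {
  star <- ape::stree(12, "star")
  star$edge.length <- rep(1, 12)
  set.seed(3)
  d <- data.frame(x = rnorm(12), row.names = star$tip.label)
  d$y <- 1 + 0.5 * d$x + rnorm(12, 0, 0.3)
  p <- pgls_fit(y ~ x, d, star, structure = "BM")
  o <- lm(y ~ x, d)
  so <- summary(o)$coefficients
  expect_equal(unname(coef(p)), unname(coef(o)), tolerance = 1e-9)
  expect_equal(unname(p$se), unname(so[, 2]), tolerance = 1e-9)
  expect_equal(unname(p$t), unname(so[, 3]), tolerance = 1e-9)
  expect_equal(unname(residuals(p)), unname(residuals(o)), tolerance = 1e-9)
})

test_that("PGLS recovers exact coefficients in the noiseless limit", {
  tr <- generate_tree(20, 10, seed = 5)
  set.seed(6)
  d <- data.frame(x = rnorm(20), row.names = tr$tip.label)
  d$y <- 2 * d$x + 1 + simulate_bm(tr, 1e-14, 0, seed = 7)$tips[, 1]
  p <- pgls_fit(y ~ x, d, tr, structure = "BM")
  expect_equal(unname(coef(p)), c(1, 2), tolerance = 1e-6)
})

test_that("PGLS (BM) agrees with nlme::gls under corBrownian", {
  skip_if_not_installed("nlme")
  tr <- generate_tree(25, 50, seed = 8)
  d <- data.frame(x = simulate_bm(tr, 1, 0, seed = 9)$tips[, 1])
  rownames(d) <- tr$tip.label
  d$y <- 3 + 0.5 * d$x + simulate_bm(tr, 0.5, 0, seed = 10)$tips[, 1]
  p <- pgls_fit(y ~ x, d, tr, structure = "BM")
  d$sp <- rownames(d)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corBrownian(1, tr, form = ~sp),
                 method = "ML")
  expect_equal(unname(coef(p)), unname(coef(g)), tolerance = 1e-7)
  expect_equal(p$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
  expect_equal(unname(p$se), unname(sqrt(diag(g$varBeta))), tolerance = 1e-6)
})

test_that("GLS normal equations hold and singular designs are named", {
  tr <- generate_tree(18, 40, seed = 12)
  set.seed(13)
  d <- data.frame(x = rnorm(18), row.names = tr$tip.label)
  d$y <- d$x + simulate_bm(tr, 1, 0, seed = 14)$tips[, 1]
  p <- pgls_fit(y ~ x, d, tr, structure = "BM")
  V <- ape::vcv(prune_to_taxa(tr, rownames(d)))[p$species, p$species]
  X <- cbind(1, d[p$species, "x"])
  expect_lt(max(abs(t(X) %*% solve(V, residuals(p)))), 1e-8)

  d$x2 <- 2 * d$x
  expect_error(pgls_fit(y ~ x + x2, d, tr, structure = "BM"), "x2")
})

test_that("automatic structure choice reports both fits with weights summing to 1", {
  tr <- generate_tree(30, 100, seed = 15)
  d <- data.frame(x = simulate_bm(tr, 1, 0, seed = 16)$tips[, 1])
  rownames(d) <- tr$tip.label
  d$y <- 1 + d$x + simulate_bm(tr, 2, 0, seed = 17)$tips[, 1]
  p <- pgls_fit(y ~ x, d, tr, structure = "auto")
  expect_named(p$fits, c("BM", "OU"))
  w <- vapply(p$fits, `[[`, 0, "weight")
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(p$structure %in% c("BM", "OU"))
  expect_gte(p$fits$OU$loglik, p$fits$BM$loglik - 1e-6)  # BM nested in OU limit
})

test_that("akaike_weights matches closed forms and is shift invariant", {
  aw <- akaike_weights(c(-10, -10), c(3, 3), n = 30)
  expect_equal(unname(aw$weights), c(0.5, 0.5))

  # identical k: delta = (0, 20) means loglik gap of 10
  aw2 <- akaike_weights(c(0, -10), c(3, 3), n = 50)
  expect_equal(unname(aw2$weights),
               c(1 / (1 + exp(-10)), exp(-10) / (1 + exp(-10))),
               tolerance = 1e-12)

  aw3 <- akaike_weights(c(-5, -6, -9), c(2, 3, 4), n = 40)
  expect_equal(sum(aw3$weights), 1, tolerance = 1e-12)
  aw3b <- akaike_weights(c(-5, -6, -9) + 100, c(2, 3, 4), n = 40)
  expect_equal(aw3$weights, aw3b$weights, tolerance = 1e-12)

  expect_warning(aw4 <- akaike_weights(c(-1, -2), c(3, 4), n = 4), "AIC")
  expect_true(aw4$fallback)
})

test_that("phylo_residuals are zero for exact fits and V-weighted centered", {
  tr <- generate_tree(20, 50, seed = 18)
  x <- simulate_bm(tr, 1, 2, seed = 19)$tips[, 1]
  y_exact <- 0.8 * x - 1
  r <- phylo_residuals(tr, y_exact, x, structure = "BM")
  expect_lt(max(abs(r)), 1e-9)

  y <- y_exact + simulate_bm(tr, 0.3, 0, seed = 20)$tips[, 1]
  r2 <- phylo_residuals(tr, y, x, structure = "BM")
  fit <- attr(r2, "fit")
  V <- ape::vcv(tr)[fit$species, fit$species]
  expect_lt(abs(sum(solve(V, r2[fit$species]))), 1e-8)

  star <- ape::stree(10, "star"); star$edge.length <- rep(1, 10)
  set.seed(21)
  xs <- setNames(rnorm(10), star$tip.label)
  ys <- 2 * xs + rnorm(10, 0, 0.5)
  ro <- phylo_residuals(star, ys, xs, structure = "BM")
  expect_equal(unname(ro[names(xs)]),
               unname(residuals(lm(ys ~ xs))), tolerance = 1e-9)
})

test_that("residual sign recovers planted species deviations", {
  tr <- generate_tree(40, 100, seed = 22)
  set.seed(23)
  x <- simulate_bm(tr, 0.02, 1, seed = 24)$tips[, 1]
  dev <- setNames(sample(c(-0.4, 0.4), 40, replace = TRUE), tr$tip.label)
  hits <- 0
  for (i in 1:5) {
    noise <- simulate_bm(tr, 0.1^2 / 100, 0, seed = 30 + i)$tips[, 1]
    y <- -2.6 + 0.77 * x + dev + noise
    r <- phylo_residuals(tr, y, x, structure = "BM")
    hits <- hits + mean(sign(r[names(dev)]) == sign(dev))
  }
  expect_gte(hits / 5, 0.95)
})
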