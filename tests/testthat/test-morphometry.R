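test_that("eye volume follows the sphere formula", {
  expect_equal(eye_volume(1), 4 / 3 * pi, tolerance = 1e-9)
  expect_equal(eye_volume(0.5), 4 / 3 * pi / 8, tolerance = 1e-9)
  expect_equal(eye_volume(2) / eye_volume(1), 8, tolerance = 1e-12)
})

test_that("lens volume handles all regimes, symmetry and continuity", {
  expect_equal(lens_volume(1, 0.8, 1.8), 0)            # tangent
  expect_equal(lens_volume(1, 0.8, 0), 4 / 3 * pi * 0.8^3)  # containment
  expect_equal(lens_volume(1, 0.8, 0.5), lens_volume(0.8, 1, 0.5))
  # continuity at the containment boundary d = |r1 - r2|
  eps <- 1e-8
  expect_equal(lens_volume(1, 0.6, 0.4 + eps), lens_volume(1, 0.6, 0.4),
               tolerance = 1e-6)
  # continuity at tangency
  expect_lt(lens_volume(1, 0.6, 1.6 - eps), 1e-12)
  expect_error(lens_volume(-1, 1, 0.5), "radii")
})

test_that("lens volume matches Monte-Carlo rejection integration", {
  set.seed(50)
  v <- lens_volume(1, 0.8, 0.5)
  mc <- mc_lens_volume(1, 0.8, 0.5, n = 2e6)
  expect_equal(v, mc, tolerance = 0.003)
})

test_that("retina volume: containment shell, r_retina -> 0, and the exact identity", {
  g <- eye_geometry(r_eye = 1, r_retina = 0.8, d_eye_retina = 0.1)
  # d < r_eye - r_retina: containment, shell volume
  expect_equal(retina_volume(g), 4 / 3 * pi * (1 - 0.8^3), tolerance = 1e-12)

  g2 <- eye_geometry(1, 1e-9, 0.5)
  expect_equal(retina_volume(g2), eye_volume(1), tolerance = 1e-6)

  g3 <- eye_geometry(1.2, 0.9, 0.35)
  expect_equal(retina_volume(g3) + lens_volume(1.2, 0.9, 0.35),
               eye_volume(1.2), tolerance = 1e-12)
  expect_error(eye_geometry(1, 1.5, 0.1), "smaller")
})

test_that("CRM volume reduces to a hemisphere when nothing is subtracted", {
  g <- eye_geometry(1, 0.8, 0.1, r_crm = 1, r_no = 1e-12,
                    d_eye_crm = 10, d_crm_no = 0.5)
  expect_equal(crm_volume(g), 4 / 3 * pi / 2, tolerance = 1e-9)
  g2 <- eye_geometry(1, 0.8, 0.1, r_crm = 0.5, r_no = 0.1,
                     d_eye_crm = 10, d_crm_no = 10)
  expect_equal(crm_volume(g2), 4 / 3 * pi * 0.5^3 / 2, tolerance = 1e-12)
})

test_that("quadratic average matches closed forms and the two-pass oracle", {
  stack <- array(3, dim = c(4, 4, 10))
  expect_true(all(quadratic_average(stack) == 0))

  m <- 5; a <- 1.25; N <- 8
  alt <- array(rep(c(m + a, m - a), each = 1, times = N / 2 * 16),
               dim = c(4, 4, N))
  for (i in 1:4) for (j in 1:4) alt[i, j, ] <- m + a * rep(c(1, -1), N / 2)
  expect_equal(as.vector(quadratic_average(alt)), rep(a, 16),
               tolerance = 1e-12)

  set.seed(51)
  st <- array(rnorm(5 * 6 * 20), dim = c(5, 6, 20))
  D <- quadratic_average(st)
  for (i in 1:5) for (j in 1:6) {
    v <- st[i, j, ]
    expect_equal(D[i, j], sqrt(sum((v - mean(v))^2) / 20), tolerance = 1e-10)
  }
  # invariance to a per-pixel temporal constant
  shift <- array(rep(matrix(1:30, 5, 6), 20), dim = c(5, 6, 20))
  expect_equal(quadratic_average(st + shift), D, tolerance = 1e-10)
  expect_error(quadratic_average(array(1, dim = c(3, 3, 1))), "N >= 2")
})

test_that("Cavalieri estimator is exact on aligned cubes and unbiased on spheres", {
  expect_equal(cavalieri_volume(0.5, 0.01, c(0, 0, 0)), 0)
  expect_error(cavalieri_volume(0.5, 0.01, c(3)), "sections")

  # cube side 1, sections every 0.1 (10 sections), grid 0.05 -> 400 pts/section
  expect_equal(cavalieri_volume(0.1, 0.0025, rep(400, 10)), 1,
               tolerance = 1e-12)

  # sphere with random grid offsets: mean over offsets approaches 4*pi*r^3/3
  set.seed(52)
  r <- 1; spacing <- 0.15; gp <- 0.1
  est <- replicate(200, {
    z0 <- runif(1, 0, spacing); x0 <- runif(1, 0, gp); y0 <- runif(1, 0, gp)
    zs <- seq(z0 - r - spacing, r + spacing, by = spacing)
    hits <- vapply(zs, function(z) {
      if (abs(z) >= r) return(0L)
      rho <- sqrt(r^2 - z^2)
      xs <- seq(x0 - r - gp, r + gp, by = gp)
      ys <- seq(y0 - r - gp, r + gp, by = gp)
      sum(outer(xs^2, ys^2, "+") <= rho^2)
    }, 0L)
    cavalieri_volume(spacing, gp^2, hits)
  })
  expect_equal(mean(est), 4 / 3 * pi, tolerance = 0.02)
})

test_that("surface-area estimator is linear and recovers a sphere's area", {
  expect_equal(surface_area_estimate(2, 10, 0), 0)
  expect_equal(surface_area_estimate(2, 10, 6),
               2 * surface_area_estimate(2, 20, 6), tolerance = 1e-12)

  # vertical test lines through a bounding cube, reference volume the cube
  set.seed(53)
  r <- 0.8; R <- 1
  est <- replicate(500, {
    n_lines <- 60
    x <- runif(n_lines, -R, R); y <- runif(n_lines, -R, R)
    I_int <- 2L * sum(x^2 + y^2 < r^2)
    surface_area_estimate(V = 8 * R^3, L = n_lines * 2 * R, I_int = I_int)
  })
  expect_equal(mean(est), 4 * pi * r^2, tolerance = 0.05 * 4 * pi * r^2)
})

test_that("pre-retinal capillarization density follows its definition", {
  expect_equal(preretinal_capillarization(0, SA_retina = 3), 0)
  d <- preretinal_capillarization(SA_retina = 4, density = 0.1, V_retina = 2)
  expect_equal(attr(d, "V_prc"), 0.2)
  expect_equal(as.numeric(d), 0.05)
  expect_error(preretinal_capillarization(1, SA_retina = 0), "SA_retina")

  # shell phantom: binomial point counts recover a known capillary fraction
  set.seed(54)
  f_true <- 0.12; V_ret <- 2.4; n_pts <- 200000
  hits <- rbinom(1, n_pts, f_true)
  d2 <- preretinal_capillarization(SA_retina = 5, density = hits / n_pts,
                                   V_retina = V_ret)
  expect_equal(attr(d2, "V_prc"), f_true * V_ret, tolerance = 0.03)
})

make_basis <- function() {
  wl <- seq(480, 700, by = 0.2)
  g <- function(mu, s) exp(-(wl - mu)^2 / (2 * s^2))
  data.frame(wavelength = wl,
             oxy = 0.9 * g(542, 12) + 0.95 * g(577, 10),
             deoxy = 1.1 * g(555, 16),
             met = 0.5 * g(500, 15) + 0.6 * g(630, 12))
}

test_that("Root effect: trivial endpoints and noisy mixture recovery", {
  b <- make_basis()
  B <- as.matrix(b[, c("oxy", "deoxy", "met")])
  same <- B %*% c(0.5, 0.4, 0.1)
  expect_equal(as.numeric(root_effect(same, same, b)), 0, tolerance = 1e-9)

  expect_equal(as.numeric(root_effect(B[, "deoxy"], B[, "oxy"], b)), 100,
               tolerance = 1e-9)

  set.seed(55)
  mix <- function(s) B %*% c(s * 0.9, (1 - s) * 0.9, 0.1)
  noisy <- function(y) y * (1 + rnorm(length(y), 0, 0.01))
  re <- root_effect(noisy(mix(0.57)), noisy(mix(0.95)), b)
  expect_equal(as.numeric(re), 100 * (0.95 - 0.57) / 0.95, tolerance = 2)

  re_diff <- root_effect(noisy(mix(0.57)), noisy(mix(0.95)), b,
                         form = "difference")
  expect_equal(as.numeric(re_diff), 100 * (0.95 - 0.57), tolerance = 2)

  b_bad <- b; b_bad$met <- b$oxy * 2
  expect_error(root_effect(same, same, b_bad), "collinear")
})

test_that("thickness conventions: positional maximum and layer scaling", {
  expect_equal(max_retinal_thickness(c(310, 295, NA, 330, 301, 290)), 330)
  expect_true(is.na(max_retinal_thickness(c(NA, NA))))
  lt <- layer_thickness_absolute(300, c(PEPRL = 2, ONL = 1, NFL = 1))
  expect_equal(unname(lt), c(150, 75, 75))
  expect_equal(sum(lt), 300)
})
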