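test_that("maps are constant with zero transitions in the no-change limit", {
  tr <- generate_tree(8, 5, seed = 30)
  ts <- setNames(rep("s1", 8), tr$tip.label)
  m <- mk_model(c("s1", "s2"), q = 1e-9)
  sm <- simmap_sample(tr, ts, m, n_maps = 20, seed = 31)
  ss <- simmap_summarize(sm, present = "s1")
  expect_true(all(vapply(sm$maps, function(mp) all(mp$node_states == 1L), TRUE)))
  expect_equal(unname(ss$gains["mean"] + ss$losses["mean"]), 0)
  expect_true(all(ss$posterior[, "s1"] == 1))
})

test_that("map histories are internally consistent", {
  tr <- generate_tree(15, 20, seed = 32)
  set.seed(33)
  ts <- setNames(sample(c("absent", "present"), 15, replace = TRUE),
                 tr$tip.label)
  sm <- simmap_sample(tr, ts, n_maps = 50, seed = 34)
  total_len <- sum(tr$edge.length)
  for (mp in sm$maps[1:10]) {
    tot <- 0
    for (e in seq_len(nrow(sm$edge))) {
      sg <- oculoevo:::.edge_segments(sm, mp, e)
      # dwell times sum to the branch length
      expect_equal(sum(sg$dwell), sm$edge.length[e], tolerance = 1e-9)
      # adjacent segment states differ
      if (length(sg$states) > 1L) {
        expect_true(all(diff(sg$states) != 0))
      }
      # endpoints agree with the node states
      expect_identical(sg$states[1L], mp$node_states[sm$edge[e, 1L]])
      expect_identical(sg$states[length(sg$states)],
                       mp$node_states[sm$edge[e, 2L]])
      tot <- tot + sum(sg$dwell)
    }
    expect_equal(tot, total_len, tolerance = 1e-6 * total_len)
  }
  # observed tips carry their observed state in every map
  idx <- match(ts[tr$tip.label], sm$model$states)
  for (mp in sm$maps) {
    expect_identical(mp$node_states[seq_len(15)], idx)
  }
})

test_that("node posteriors converge to the analytic marginals", {
  tr <- generate_tree(20, 10, seed = 35)
  sim <- oculoevo:::.simulate_mk_forward(tr, q = 0.15, k = 2, root_state = 1L)
  ts <- setNames(c("absent", "present")[sim$node_states[1:20]], tr$tip.label)
  f <- fit_mk_er(tr, ts)
  marg <- mk_marginal(tr, ts, f$model)
  err <- function(n_maps, seed) {
    sm <- simmap_sample(tr, ts, f$model, n_maps = n_maps, seed = seed)
    ss <- simmap_summarize(sm)
    max(abs(ss$posterior[21:39, ] - marg[21:39, ]))
  }
  e3 <- err(3000, 36)
  expect_lt(e3, 0.05)
})

test_that("rejection and uniformization path samplers agree on dwell statistics", {
  # same endpoint-conditioned law from two independent algorithms
  k <- 2; q <- 0.8; t <- 2.5
  set.seed(37)
  n <- 4000
  rej <- replicate(n, length(oculoevo:::.sample_path_cond(1L, 2L, t, k, q,
                                                          max_tries = 1e6)$states))
  uni <- replicate(n, length(oculoevo:::.sample_path_unif(1L, 2L, t, k, q)$states))
  expect_equal(mean(rej), mean(uni), tolerance = 0.05)
  expect_true(all(rej %% 2 == 1))  # odd number of changes for unequal endpoints
  expect_true(all(uni %% 2 == 1))

  same_r <- replicate(n, length(oculoevo:::.sample_path_cond(1L, 1L, t, k, q,
                                                             max_tries = 1e6)$states))
  same_u <- replicate(n, length(oculoevo:::.sample_path_unif(1L, 1L, t, k, q)$states))
  expect_equal(mean(same_r), mean(same_u), tolerance = 0.05)
})

test_that("transition branches are detected by the strict 0.5-crossing rule", {
  tr <- read_newick("(A:1,B:1);")
  post <- rbind("1" = c(absent = 0.9, present = 0.1),
                "2" = c(absent = 0.3, present = 0.7),
                "3" = c(absent = 0.1, present = 0.9))
  res <- detect_transitions(post, tr, present = "present")
  expect_equal(nrow(res), 1L)
  expect_equal(res$child, 1L)
  expect_equal(res$direction, "loss")

  post2 <- rbind("1" = c(absent = 0.4, present = 0.6),
                 "2" = c(absent = 0.3, present = 0.7),
                 "3" = c(absent = 0.35, present = 0.65))
  expect_equal(nrow(detect_transitions(post2, tr, present = "present")), 0L)

  # exactly 0.5 at one end: not a crossing
  post3 <- rbind("1" = c(absent = 0.1, present = 0.9),
                 "2" = c(absent = 0.3, present = 0.7),
                 "3" = c(absent = 0.5, present = 0.5))
  expect_equal(nrow(detect_transitions(post3, tr, present = "present")), 0L)

  # interior points count each sign change once
  res4 <- detect_transitions(post2, tr, present = "present",
                             interior = list(c(0.4, 0.8), NULL))
  expect_equal(res4$n_crossings, 2L)
})

test_that("a single simulated clade origin is recovered as one gain on its branch", {
  # draw Mk histories at a moderate rate, keep those with exactly one gain
  # (an internal-branch origin of a clade of >= 3 tips) and no losses, and
  # ask the modal stochastic-map reconstruction for that gain branch
  recovered <- 0; n_cases <- 0; s <- 0
  while (n_cases < 10 && s < 200) {
    s <- s + 1
    tr <- generate_tree(40, 100, seed = 400 + s)
    q_sim <- 2 / sum(tr$edge.length)
    set.seed(900 + s)
    sim <- oculoevo:::.simulate_mk_forward(tr, q_sim, 2, 1L)
    changed <- which(!vapply(sim$segments, is.null, TRUE))
    if (length(changed) != 1L) next
    sg <- sim$segments[[changed]]
    if (length(sg$states) != 1L || sg$states != 2L) next
    origin <- sim$edge[changed, 2L]
    if (origin <= 40L ||
        length(ape::extract.clade(tr, origin)$tip.label) < 3L) next
    n_cases <- n_cases + 1
    ts <- setNames(c("absent", "present")[sim$node_states[1:40]],
                   tr$tip.label)
    sm <- simmap_sample(tr, ts, n_maps = 200, seed = 500 + s)
    ss <- simmap_summarize(sm, present = "present")
    gains <- ss$modal[ss$modal$direction == "gain", ]
    if (nrow(gains) == 1L && gains$child == origin &&
        !any(ss$modal$direction == "loss")) recovered <- recovered + 1
  }
  expect_equal(n_cases, 10L)
  expect_gte(recovered / n_cases, 0.9)
})
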