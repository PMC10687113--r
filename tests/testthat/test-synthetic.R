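count_modes <- function(d) {
  # local maxima of the density, ignoring near-zero ripples
  p <- d$p
  keep <- p > 0.02 * max(p)
  sum(diff(sign(diff(p))) == -2 & keep[-c(1, length(p))])
}

test_that("make_synthetic_system is seed-deterministic and well-formed", {
  a <- make_synthetic_system(n_states = 2, seed = 7, n_residues = 20,
                             body_radius = 7, n_label_pairs = 3)
  b <- make_synthetic_system(n_states = 2, seed = 7, n_residues = 20,
                             body_radius = 7, n_label_pairs = 3)
  expect_identical(a$system$stationary$atoms, b$system$stationary$atoms)
  expect_identical(lapply(a$truth$states, `[[`, "pair_distances"),
                   lapply(b$truth$states, `[[`, "pair_distances"))

  expect_equal(sum(a$truth$weights), 1, tolerance = 1e-9)
  # every truth state is clash-free
  for (st in a$truth$states) {
    expect_equal(confspace:::conformer_steric(a$system, st), 0)
  }
  # labels sit on different bodies for every pair
  for (i in seq_len(nrow(a$system$pairs))) {
    expect_false(a$system$labels[[a$system$pairs$a[i]]]$body ==
                   a$system$labels[[a$system$pairs$b[i]]]$body)
  }
})

test_that("forward-simulated distributions reflect the truth states", {
  one <- make_synthetic_system(n_states = 1, seed = 3, n_residues = 20,
                               body_radius = 7, n_label_pairs = 3)
  d1 <- simulate_distributions(one$truth, one$system)
  for (nm in names(d1)) {
    expect_equal(trapz_oracle(d1[[nm]]$r, d1[[nm]]$p), 1, tolerance = 1e-9)
    expect_equal(count_modes(d1[[nm]]), 1)
    # peak at the single truth distance
    mu <- one$truth$states[[1]]$pair_distances[[nm]]
    expect_lt(abs(d1[[nm]]$r[which.max(d1[[nm]]$p)] - mu), 0.5)
  }

  two <- make_synthetic_system(n_states = 2, seed = 11, n_residues = 20,
                               body_radius = 7, n_label_pairs = 3)
  d2 <- simulate_distributions(two$truth, two$system)
  expect_gte(max(vapply(d2, count_modes, 0L)), 2)

  # noiseless simulation is deterministic
  d2b <- simulate_distributions(two$truth, two$system)
  expect_identical(lapply(d2, `[[`, "p"), lapply(d2b, `[[`, "p"))
})

test_that("gaussian mixtures carry the specified component masses", {
  d <- gaussian_mixture_distribution(c(25, 45), c(0.3, 0.7), sigma = 2.5,
                                     step = 0.05)
  # mass below/above the midpoint splits 0.3 : 0.7 (tails negligible)
  below <- d$r <= 35
  expect_equal(trapz_oracle(d$r[below], d$p[below]), 0.3, tolerance = 2e-3)
  expect_equal(trapz_oracle(d$r[!below], d$p[!below]), 0.7, tolerance = 2e-3)
})

test_that("ensemble_distribution accumulates equal-area Gaussians", {
  ts <- tiny_system()
  ens <- fake_ensemble(list(fake_conformer(c(pair1 = 35)),
                            fake_conformer(c(pair1 = 35))), ts$system, "pair1")
  d <- ensemble_distribution(ens, "pair1")
  expect_equal(trapz_oracle(d$r, d$p), 1, tolerance = 1e-9)
  expect_lt(abs(d$r[which.max(d$p)] - 35), 0.5)

  ens2 <- fake_ensemble(list(fake_conformer(c(pair1 = 20)),
                             fake_conformer(c(pair1 = 60))), ts$system, "pair1")
  d2 <- ensemble_distribution(ens2, "pair1")
  p20 <- d2$p[which.min(abs(d2$r - 20))]
  p60 <- d2$p[which.min(abs(d2$r - 60))]
  expect_equal(p20, p60, tolerance = 1e-9)
  expect_equal(count_modes(d2), 2)
})

test_that("distribution_overlap is the histogram intersection", {
  g1 <- gaussian_restraint(30)
  expect_equal(distribution_overlap(g1, g1), 1, tolerance = 1e-9)

  g_far <- gaussian_restraint(90)
  expect_equal(distribution_overlap(g1, g_far), 0)

  # fine-grid quadrature oracle for two Gaussians 2.5 A apart
  g2 <- gaussian_restraint(32.5)
  got <- distribution_overlap(g1, g2)
  xx <- seq(10, 55, by = 5e-4)
  y1 <- approx(g1$r, g1$p, xout = xx, yleft = 0, yright = 0)$y
  y2 <- approx(g2$r, g2$p, xout = xx, yleft = 0, yright = 0)$y
  expect_equal(got, trapz_oracle(xx, pmin(y1, y2)), tolerance = 1e-6)
  # and close to the closed-form value 2 * pnorm(-delta / (2 sigma)); the
  # 0.5 A piecewise-linear discretization biases the intersection by ~2e-3
  expect_equal(got, 2 * pnorm(-2.5 / (2 * 2.5)), tolerance = 5e-3)
})

test_that("leave_one_out validates its inputs and reports scores in [0, 1]", {
  ts <- tiny_system(seed = 5, n_states = 1, pairs = 2, linker = 4)
  dists <- simulate_distributions(ts$truth, ts$system)
  cfg <- protocol_config(n_iterations = 3, n_calculated = 4, n_selected = 1,
                         rng_seed = 2, anneal_steps = 200)

  expect_error(leave_one_out(dists["pair1"], 1, ts$system, cfg), "at least 2")
  expect_error(leave_one_out(dists, "nope", ts$system, cfg), "does not name")

  rep <- leave_one_out(dists, 1, ts$system, cfg)
  expect_gte(rep$held_out_overlap, 0)
  expect_lte(rep$held_out_overlap, 1)
  expect_gte(rep$free_overlap, 0)
  expect_lte(rep$free_overlap, 1)
  expect_identical(rep$pair, "pair1")
})
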