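test_that("cohorts are age-stratified, sex-balanced and seed-deterministic", {
  coh <- simulate_cohort(30, seed = 1)
  expect_equal(nrow(coh), 180)
  expect_true(all(coh$age >= 20 & coh$age < 80))
  dec <- cut(coh$age, seq(20, 80, 10), right = FALSE)
  expect_equal(unname(table(dec)), rep(30L, 6), ignore_attr = TRUE)
  sex_by_dec <- table(dec, coh$sex)
  expect_true(all(sex_by_dec == 15))
  expect_identical(coh, simulate_cohort(30, seed = 1))
  expect_false(identical(coh$age, simulate_cohort(30, seed = 2)$age))
  expect_equal(nrow(simulate_cohort(1, seed = 3)), 6)
  expect_error(simulate_cohort(0), "n_per_decade")
})

test_that("D1DR means are continuous piecewise-linear in age", {
  # closed form: intercept is the mean at the breakpoint
  v60 <- simulate_d1dr(60, intercept = 2.4, slope_young = 0,
                       slope_old = -0.02, noise_sd = 0)
  expect_equal(v60, 2.0)
  # continuity at the knot: approaching from both sides agrees
  ages <- c(40 - 1e-9, 40, 40 + 1e-9)
  v <- simulate_d1dr(ages, intercept = 1.9, slope_young = -0.01,
                     slope_old = -0.03, noise_sd = 0)
  expect_equal(max(v) - min(v), 0, tolerance = 1e-7)
  # noiseless values sit exactly on the two line segments
  v2 <- simulate_d1dr(c(20, 30, 50, 70), intercept = 2, slope_young = -0.005,
                      slope_old = -0.012, noise_sd = 0)
  expect_equal(v2, c(2 + 0.005 * 20, 2 + 0.005 * 10, 2 - 0.012 * 10,
                     2 - 0.012 * 30))
  # truncation at zero
  v3 <- simulate_d1dr(rep(75, 50), intercept = 0.01, slope_young = 0,
                      slope_old = 0, noise_sd = 1, seed = 5)
  expect_true(all(v3 >= 0))
  expect_error(simulate_d1dr(50, noise_sd = -1), "noise_sd")
})

test_that("noiseless planted effects appear exactly in affected edges", {
  coh <- toy_cohort(3, seed = 2)
  part <- toy_partition(c(3, 3))
  sp <- effect_spec(base_within_z = 0, base_between_z = 0,
                    beta_age_within = 1, beta_d1_within = 0,
                    beta_age_between = 0, beta_d1_between = 0,
                    latent_within = 0, latent_between = 0,
                    noise_sd = 0, affected_fraction = 1)
  sim <- simulate_connectomes(coh, part, sp, seed = 3)
  z_age <- (coh$age - mean(coh$age)) / sd(coh$age)
  within <- part$network[sim$edges$edge_index$i] ==
    part$network[sim$edges$edge_index$j]
  for (e in which(within))
    expect_equal(sim$edges$values[, e], z_age, ignore_attr = TRUE)
  expect_true(all(sim$edges$values[, !within] == 0))
})

test_that("the null generator yields edge-age correlations centered on zero", {
  coh <- toy_cohort(30, seed = 7)
  part <- simulate_partition(47, 5)   # 1081 edges
  sim <- simulate_connectomes(coh, part, null_effect_spec(noise_sd = 1),
                              seed = 8)
  r <- cor(coh$age, sim$edges$values)
  n <- nrow(coh)
  expect_lt(abs(mean(r)), 0.01)              # signed correlations center on 0
  # |r| has null expectation sqrt(2/pi)/sqrt(n-1) ~ 0.060 at n = 180
  expect_lt(mean(abs(r)), 1 / sqrt(n - 1))
  expect_gt(mean(abs(r)), 0.5 * sqrt(2 / pi) / sqrt(n - 1))
})

test_that("effect signs follow the dedifferentiation pattern at high SNR", {
  coh <- toy_cohort(30, seed = 9)
  part <- simulate_partition(30, 4)
  sp <- effect_spec(noise_sd = 0.01)
  sim <- simulate_connectomes(coh, part, sp, seed = 10)
  within <- sim$truth$is_within
  aff <- sim$truth$affected_edges
  aw <- intersect(aff, which(within))
  ab <- intersect(aff, which(!within))
  r_age <- cor(coh$age, sim$edges$values)
  r_d1 <- cor(coh$d1dr_bpnd, sim$edges$values)
  expect_true(all(r_age[aw] < 0))
  expect_true(all(r_d1[aw] > 0))
  expect_true(all(r_age[ab] > 0))
  expect_true(all(r_d1[ab] < 0))
})

test_that("planted truth is unit-norm, supported on affected edges, scale-invariant", {
  coh <- toy_cohort(10, seed = 11)
  part <- simulate_partition(20, 4)
  sp <- effect_spec()
  sim <- simulate_connectomes(coh, part, sp, seed = 12)
  tr <- sim$truth
  expect_equal(sqrt(sum(tr$true_salience^2)), 1, tolerance = 1e-12)
  expect_true(all(tr$true_salience[tr$affected_edges] != 0))
  expect_true(all(tr$true_salience[-tr$affected_edges] == 0))
  expect_gt(tr$true_latent_corr_d1, 0)    # receptor-positive orientation
  expect_lt(tr$true_latent_corr_age, 0)

  # doubling all betas (and loadings) leaves the salience direction unchanged
  sp2 <- effect_spec(beta_age_within = 2 * sp$beta_age_within,
                     beta_d1_within = 2 * sp$beta_d1_within,
                     beta_age_between = 2 * sp$beta_age_between,
                     beta_d1_between = 2 * sp$beta_d1_between,
                     latent_within = 2 * sp$latent_within,
                     latent_between = 2 * sp$latent_between)
  sim2 <- simulate_connectomes(coh, part, sp2, seed = 12)
  expect_equal(sim2$truth$true_salience, tr$true_salience, tolerance = 1e-10)
})

test_that("working-memory scores respect ranges and couple to the planted score", {
  st <- simulate_study(n_per_decade = 30, n_nodes = 30, n_networks = 4,
                       seed = 13)
  expect_true(all(st$subjects$wm_letter >= 0 & st$subjects$wm_letter <= 48))
  expect_true(all(st$subjects$wm_number >= 0 & st$subjects$wm_number <= 108))
  expect_true(all(st$subjects$wm_spatial >= 0 & st$subjects$wm_spatial <= 30))
  comp <- wm_composite(st$subjects$wm_letter, st$subjects$wm_number,
                       st$subjects$wm_spatial)
  expect_gt(cor(comp, st$truth$true_score), 0.1)
  wm1 <- simulate_wm_scores(st$truth$true_score, seed = 14)
  wm2 <- simulate_wm_scores(st$truth$true_score, seed = 14)
  expect_identical(wm1, wm2)
})

test_that("timeseries reproduce their target correlations", {
  z <- matrix(0, 2, 2); z[1, 2] <- z[2, 1] <- 0.5493  # tanh = 0.5
  sim <- simulate_timeseries(z, 5000, seed = 15)
  expect_equal(cor(sim$ts[1, ], sim$ts[2, ]), 0.5, tolerance = 0.05)

  z0 <- matrix(0, 8, 8)
  sim0 <- simulate_timeseries(z0, 5000, seed = 16)
  r <- cor(t(sim0$ts))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.05)

  expect_identical(simulate_timeseries(z, 50, seed = 17),
                   simulate_timeseries(z, 50, seed = 17))
  expect_error(simulate_timeseries(z, 9), "n_volumes")
})
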