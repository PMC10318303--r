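# small labeled dataset shared by the PLS oracle tests
pls_toy <- function(n = 6, n_nodes = 4, seed = 31) {
  set.seed(seed)
  tab <- validate_subject_table(data.frame(
    subject_id = sprintf("s%d", 1:n),
    age = runif(n, 20, 80),
    d1dr_bpnd = runif(n, 1, 3)))
  edges <- edge_matrix(matrix(rnorm(n * n_nodes * (n_nodes - 1) / 2), n),
                       n_nodes, subject_ids = tab$subject_id)
  list(tab = tab, design = build_design(tab), edges = edges)
}

test_that("design matrices are z-scored with the sample SD and validated", {
  toy <- pls_toy()
  d <- toy$design
  expect_equal(colMeans(d$values), c(0, 0), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(apply(d$values, 2, sd), c(1, 1), ignore_attr = TRUE,
               tolerance = 1e-12)
  tab <- toy$tab; tab$d1dr_bpnd <- 2
  expect_error(build_design(tab), "d1dr_bpnd")
  expect_error(build_design(toy$tab, c("age", "height")), "height")
})

test_that("cross-correlation matches a hand Pearson oracle edge by edge", {
  toy <- pls_toy()
  r <- cross_correlate(toy$design, toy$edges)
  for (v in 1:2) for (e in seq_len(ncol(toy$edges$values)))
    expect_equal(unname(r[v, e]),
                 pearson_loop(toy$design$values[, v], toy$edges$values[, e]),
                 tolerance = 1e-12)

  # edge equal to a design variable: r = 1; orthogonal edge: r = 0
  x <- toy$edges
  x$values[, 1] <- toy$design$values[, 1]
  ctr <- rep(c(-1, 1), 3)
  x$values[, 2] <- ctr - toy$design$values %*%
    solve(crossprod(toy$design$values), crossprod(toy$design$values, ctr))
  r2 <- cross_correlate(toy$design, x)
  expect_equal(unname(r2[1, 1]), 1, tolerance = 1e-12)
  expect_equal(unname(r2[, 2]), c(0, 0), tolerance = 1e-10)

  # zero-variance edge: r forced to 0 with a message, indexing preserved
  x$values[, 3] <- 5
  expect_message(r3 <- cross_correlate(toy$design, x), "zero-variance")
  expect_equal(unname(r3[, 3]), c(0, 0))

  # near-linear 4-subject example
  v4 <- c(-1.16, -0.39, 0.39, 1.16)
  expect_gt(pearson_loop(v4, 1:4), 0.999)
})

test_that("the PLS fit matches an independent SVD and conserves energy", {
  toy <- pls_toy(n = 8, n_nodes = 5, seed = 32)
  fit <- fit_pls(toy$design, toy$edges)

  # oracle: hand correlation matrix + base svd
  r <- matrix(0, 2, ncol(toy$edges$values))
  for (v in 1:2) for (e in seq_len(ncol(r)))
    r[v, e] <- pearson_loop(toy$design$values[, v], toy$edges$values[, e])
  sv <- svd(r)
  expect_equal(fit$singular_values, sv$d, tolerance = 1e-8)
  for (l in 1:2) {
    cs <- sum(fit$brain_saliences[, l] * sv$v[, l])
    expect_equal(abs(cs), 1, tolerance = 1e-8)
    expect_equal(fit$brain_saliences[, l], sign(cs) * sv$v[, l],
                 tolerance = 1e-8)
  }

  expect_equal(sum(fit$singular_values^2), sum(r^2), tolerance = 1e-8)
  expect_equal(crossprod(fit$brain_saliences), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(fit$design_saliences), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(fit$crossblock_fraction), 1, tolerance = 1e-12)
  # sign convention: largest-|.| design-salience entry positive
  for (l in 1:2) {
    ds <- fit$design_saliences[, l]
    expect_gt(ds[which.max(abs(ds))], 0)
  }

  # rank-1 case: every edge proportional to variable 1
  prop <- toy$edges
  set.seed(33)
  prop$values <- outer(toy$design$values[, 1], rnorm(ncol(prop$values)))
  fit1 <- fit_pls(toy$design, prop)
  expect_equal(fit1$crossblock_fraction[1], 1, tolerance = 1e-8)
})

test_that("brain scores equal the explicit per-subject loop", {
  toy <- pls_toy(n = 5, n_nodes = 5, seed = 34)
  x <- toy$edges$values
  w <- rnorm(ncol(x))
  oracle <- vapply(1:5, function(s) {
    acc <- 0
    for (e in seq_len(ncol(x))) acc <- acc + w[e] * x[s, e]
    acc
  }, numeric(1))
  expect_equal(compute_brain_scores(w, toy$edges), oracle, tolerance = 1e-12)

  one_hot <- replace(numeric(ncol(x)), 3, 1)
  expect_equal(compute_brain_scores(one_hot, toy$edges), x[, 3])
  expect_equal(compute_brain_scores(numeric(ncol(x)), toy$edges), rep(0, 5))
  expect_error(compute_brain_scores(w[-1], toy$edges), "length")
})

test_that("permutation p-values are exact under exhaustive enumeration", {
  toy <- pls_toy(n = 5, n_nodes = 4, seed = 35)
  res <- permutation_test(toy$design, toy$edges, exhaustive = TRUE)

  # independent oracle: recursive permutation enumeration + base svd
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms_of(v[-i]), function(p) c(v[i], p)))
    out
  }
  svals <- function(idx) {
    r <- matrix(0, 2, ncol(toy$edges$values))
    for (v in 1:2) for (e in seq_len(ncol(r)))
      r[v, e] <- pearson_loop(toy$design$values[idx, v],
                              toy$edges$values[, e])
    svd(r)$d
  }
  all_p <- perms_of(1:5)
  expect_length(all_p, 120)
  sp <- vapply(all_p, svals, numeric(2))
  obs <- svals(1:5)
  expect_equal(res$p, rowSums(sp >= obs) / 120, tolerance = 1e-12)
  expect_equal(res$n_perm, 120)
})

test_that("permutation p is invariant to joint relabeling and bounded for strong effects", {
  # exact invariance under joint subject relabeling (exhaustive enumeration;
  # a Monte-Carlo draw would map the relabeled data to different random
  # permutations)
  set.seed(36)
  n <- 5
  tab <- validate_subject_table(data.frame(
    subject_id = sprintf("s%d", 1:n),
    age = runif(n, 20, 80), d1dr_bpnd = runif(n, 1, 3)))
  edges <- edge_matrix(matrix(rnorm(n * 6), n), 4,
                       subject_ids = tab$subject_id)
  des <- build_design(tab)
  p1 <- permutation_test(des, edges, exhaustive = TRUE)$p

  perm <- c(3, 1, 5, 2, 4)
  des2 <- des
  des2$values <- des$values[perm, ]
  des2$subject_ids <- des$subject_ids[perm]
  ed2 <- edges
  ed2$values <- ed2$values[perm, ]
  ed2$subject_ids <- ed2$subject_ids[perm]
  p2 <- permutation_test(des2, ed2, exhaustive = TRUE)$p
  expect_equal(p1, p2, tolerance = 1e-12)

  # near-noiseless planted effect: smallest attainable p for LV1
  coh <- toy_cohort(5, seed = 36)
  part <- toy_partition(c(4, 4))
  sim0 <- simulate_connectomes(coh, part, effect_spec(noise_sd = 1e-4),
                               seed = 40)
  p0 <- permutation_test(build_design(coh), sim0$edges, n_perm = 99,
                         seed = 41)$p
  expect_equal(p0[1], 1 / 100, tolerance = 1e-12)
})

test_that("bootstrap ratios match a direct resampling oracle and flip with the data", {
  coh <- toy_cohort(5, seed = 42)
  part <- toy_partition(c(4, 4))
  sim <- simulate_connectomes(coh, part, effect_spec(), seed = 43)
  des <- build_design(coh)
  bs <- bootstrap_bsr(des, sim$edges, n_boot = 40, seed = 44)

  # direct indexed oracle following the same RNG stream
  n <- nrow(des$values)
  fit <- fit_pls(des, sim$edges)
  vs0 <- fit$brain_saliences %*% diag(fit$singular_values)
  sum_v <- 0; sum_v2 <- 0
  set.seed(44)
  for (b in 1:40) {
    idx <- sample.int(n, replace = TRUE)
    zd <- scale(des$values[idx, ])
    ze <- scale(sim$edges$values[idx, ])
    r <- crossprod(zd, ze) / (n - 1)
    sv <- svd(r)
    vb <- sv$v %*% diag(sv$d)
    flip <- sign(colSums(vb * vs0)); flip[flip == 0] <- 1
    vb <- vb * rep(flip, each = nrow(vb))
    sum_v <- sum_v + vb; sum_v2 <- sum_v2 + vb^2
  }
  se_oracle <- sqrt(pmax(sum_v2 / 40 - (sum_v / 40)^2, 0) * 40 / 39)
  expect_equal(bs$boot_se, se_oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(bs$bsr, vs0 / se_oracle, tolerance = 1e-10, ignore_attr = TRUE)

  # negating every edge flips BSR signs, magnitudes unchanged
  neg <- sim$edges
  neg$values <- -neg$values
  bs_neg <- bootstrap_bsr(des, neg, n_boot = 40, seed = 44)
  expect_equal(bs_neg$bsr, -bs$bsr, tolerance = 1e-10)
})

test_that("latent correlations and LV reorientation behave as documented", {
  toy <- pls_toy(n = 10, n_nodes = 4, seed = 45)
  scores <- toy$design$values[, 1]
  r <- latent_correlations(scores, toy$design)
  expect_equal(r[1, 1], 1, tolerance = 1e-12)

  fit <- fit_pls(toy$design, toy$edges)
  fo <- orient_lv(fit, "d1dr_bpnd")
  expect_true(all(fo$design_saliences[2, ] >= 0))
  expect_equal(abs(fo$brain_saliences), abs(fit$brain_saliences))
  expect_equal(abs(fo$latent_corr), abs(fit$latent_corr))
  # flipped LVs flip scores together with saliences
  flipped <- which(fit$design_saliences[2, ] < 0)
  for (l in flipped)
    expect_equal(fo$brain_scores[, l], -fit$brain_scores[, l])
})
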