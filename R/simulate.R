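# Synthetic cohort generator: age-stratified subjects, age-dependent D1
# receptor availability, block-structured connectomes with planted covariate
# effects, working-memory scores coupled to the planted pattern, and
# timeseries fixtures. Every generator is a pure function of its parameters
# and seed.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate an age-stratified cohort
#'
#' Draws subjects stratified by decade between `age_min` and `age_max`
#' (default six decades, 20--80 years), with ages uniform within each decade
#' and the sex ratio balanced per decade. Education (years) and mean
#' frame-wise displacement (mm) are drawn as plausible nuisance phenotypes.
#'
#' @param n_per_decade Subjects per decade bin (default 30).
#' @param age_min,age_max Cohort age bounds; `(age_max - age_min)` must be a
#'   positive multiple of 10.
#' @param sex_balance Fraction of females per decade (default 0.5).
#' @param seed Integer seed.
#' @return A `subject_table` with columns `subject_id`, `age`, `sex`,
#'   `education`, `fd_mean`.
#' @export
simulate_cohort <- function(n_per_decade = 30, age_min = 20, age_max = 80,
                            sex_balance = 0.5, seed = NULL) {
  if (n_per_decade < 1) stop("n_per_decade must be >= 1")
  span <- age_max - age_min
  if (span <= 0 || span %% 10 != 0)
    stop("age bounds must span a positive multiple of 10 years")
  n_dec <- span / 10
  with_seed(seed, {
    lo <- age_min + 10 * (seq_len(n_dec) - 1)
    age <- unlist(lapply(lo, function(l) stats::runif(n_per_decade, l, l + 10)))
    n_f <- round(sex_balance * n_per_decade)
    sex <- unlist(lapply(seq_len(n_dec), function(d)
      sample(c(rep("F", n_f), rep("M", n_per_decade - n_f)))))
    n <- n_dec * n_per_decade
    edu <- pmin(pmax(round(stats::rnorm(n, 14, 2.5)), 9), 22)
    fd  <- exp(stats::rnorm(n, log(0.12) + 0.004 * (age - 50), 0.3))
    validate_subject_table(data.frame(
      subject_id = sprintf("sub%04d", seq_len(n)),
      age = age, sex = sex, education = edu, fd_mean = round(fd, 4),
      stringsAsFactors = FALSE))
  })
}

#' Simulate D1-receptor availability with a mid-life regime shift
#'
#' Mean binding potential is continuous piecewise-linear in age with a knot
#' at `breakpoint` (default 40 years): a shallow developmental slope before
#' the knot and a steeper aging slope after it, plus additive Gaussian noise.
#' `intercept` is the mean binding potential at the breakpoint age. Values
#' are truncated at zero (binding potentials cannot be negative).
#'
#' @param ages Numeric vector of ages in years.
#' @param intercept Mean BPND at `breakpoint` (default 1.95).
#' @param slope_young Slope (per year) for `age <= breakpoint` (default -0.008).
#' @param slope_old Slope (per year) for `age > breakpoint` (default -0.011).
#' @param breakpoint Knot age in years (default 40).
#' @param noise_sd SD of additive Gaussian noise (default 0.2; must be >= 0).
#' @param seed Integer seed.
#' @return Numeric vector of non-negative binding potentials.
#' @export
simulate_d1dr <- function(ages, intercept = 1.95, slope_young = -0.008,
                          slope_old = -0.011, breakpoint = 40,
                          noise_sd = 0.2, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  mu <- ifelse(ages <= breakpoint,
               intercept + slope_young * (ages - breakpoint),
               intercept + slope_old * (ages - breakpoint))
  with_seed(seed, pmax(mu + stats::rnorm(length(ages), 0, noise_sd), 0))
}

#' Build an evenly sized synthetic network partition
#'
#' Assigns `n_nodes` nodes to `n_networks` labeled networks with sizes as
#' even as possible (e.g. 264 nodes in 14 networks: twelve networks of 19
#' nodes and two of 18).
#'
#' @param n_nodes Number of nodes (default 264).
#' @param n_networks Number of networks (default 14).
#' @return A `network_partition`.
#' @export
simulate_partition <- function(n_nodes = 264, n_networks = 14) {
  if (n_networks < 2 || n_networks > n_nodes)
    stop("need 2 <= n_networks <= n_nodes")
  base <- n_nodes %/% n_networks
  sizes <- rep(base, n_networks)
  extra <- n_nodes - base * n_networks
  if (extra > 0) sizes[seq_len(extra)] <- base + 1
  labels <- sprintf("net%02d", seq_len(n_networks))
  network_partition(default_node_ids(n_nodes), rep(labels, times = sizes))
}

#' Planted connectome effect specification
#'
#' Defines the block baselines and per-standard-deviation covariate slopes of
#' the connectome generator. Affected within-network edges carry a negative
#' age slope and a positive D1DR slope; affected between-network edges carry
#' the mirrored signs (the dedifferentiation pattern: weaker within- and
#' stronger between-network coupling with age and receptor loss). In addition
#' to the covariate slopes, affected edges load (via `latent_within` /
#' `latent_between`) on a shared subject-level factor representing
#' individual differences in expression of the pattern not explained by age
#' or D1DR; this places the planted latent correlations strictly inside the
#' feasible region of the two-variable design. The defaults are calibrated
#' so that, under the default cohort, the planted pattern has latent
#' correlations of about -0.8 with age and +0.6 with D1DR.
#'
#' @param base_within_z,base_between_z Fisher-z edge-mean baselines for
#'   within- and between-network edges (defaults 0.6 and 0.3).
#' @param beta_age_within,beta_d1_within Slopes (Fisher-z per SD of the
#'   covariate) on affected within-network edges.
#' @param beta_age_between,beta_d1_between Slopes on affected between-network
#'   edges.
#' @param latent_within,latent_between Loadings of the shared subject factor
#'   on affected within-/between-network edges.
#' @param noise_sd SD of independent Gaussian edge noise (>= 0; default 0.1).
#' @param affected_fraction Fraction of edges in each class carrying effects
#'   (in `[0, 1]`; default 0.25).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(base_within_z = 0.6, base_between_z = 0.3,
                        beta_age_within = -0.0627, beta_d1_within = 0.0110,
                        beta_age_between = 0.0401, beta_d1_between = -0.0070,
                        latent_within = 0.0518, latent_between = -0.0332,
                        noise_sd = 0.1, affected_fraction = 0.25) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (affected_fraction < 0 || affected_fraction > 1)
    stop("affected_fraction must lie in [0, 1]")
  structure(list(base_within_z = base_within_z,
                 base_between_z = base_between_z,
                 beta_age_within = beta_age_within,
                 beta_d1_within = beta_d1_within,
                 beta_age_between = beta_age_between,
                 beta_d1_between = beta_d1_between,
                 latent_within = latent_within,
                 latent_between = latent_between,
                 noise_sd = noise_sd,
                 affected_fraction = affected_fraction),
            class = "effect_spec")
}

#' A null effect specification (no planted effects)
#'
#' Convenience wrapper: all covariate slopes and latent loadings zero, so
#' edges are pure baseline-plus-noise. Used for type-I-error and bootstrap
#' calibration studies.
#'
#' @param noise_sd Edge noise SD (default 0.1).
#' @param ... Passed to [effect_spec()] (e.g. baselines).
#' @export
null_effect_spec <- function(noise_sd = 0.1, ...) {
  effect_spec(beta_age_within = 0, beta_d1_within = 0,
              beta_age_between = 0, beta_d1_between = 0,
              latent_within = 0, latent_between = 0,
              noise_sd = noise_sd, ...)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

#' Simulate block-structured connectomes with planted covariate effects
#'
#' Each subject's canonical edge vector is
#' `baseline + beta_age * z(age) + beta_d1 * z(D1DR) + latent_loading * eta +
#' noise`, where `z()` denotes within-cohort z-scoring, `eta` is a standard
#' normal subject factor shared across affected edges, and the betas/loadings
#' are nonzero only on the randomly chosen affected edges of each class.
#' Returns the ground truth needed for parameter-recovery tests: the
#' unit-norm planted salience (the population design-covariance pattern over
#' edges, which is invariant to rescaling all betas), the planned latent
#' correlations of the pattern with age and D1DR (closed form, including
#' latent- and edge-noise attenuation), the affected edge indices, and each
#' subject's noiseless expression of the pattern (`true_score`).
#'
#' @param cohort A `subject_table` with `age` and `d1dr_bpnd`.
#' @param partition A `network_partition` (>= 2 networks).
#' @param spec An [effect_spec()].
#' @param seed Integer seed.
#' @return List with `edges` (an `edge_matrix`) and `truth` (a
#'   `planted_truth` list: `true_salience`, `true_latent_corr_age`,
#'   `true_latent_corr_d1`, `affected_edges`, `true_score`, `is_within`).
#' @export
simulate_connectomes <- function(cohort, partition, spec = effect_spec(),
                                 seed = NULL) {
  stopifnot(inherits(partition, "network_partition"))
  if (!all(c("age", "d1dr_bpnd") %in% names(cohort)))
    stop("cohort must contain age and d1dr_bpnd")
  n <- nrow(cohort)
  n_nodes <- length(partition$node_ids)
  ei <- edge_index(n_nodes, partition$node_ids)
  is_within <- partition$network[ei$i] == partition$network[ei$j]
  ne <- nrow(ei)

  z_age <- zscore(cohort$age)
  z_d1  <- zscore(cohort$d1dr_bpnd)

  with_seed(seed, {
    idx_w <- which(is_within); idx_b <- which(!is_within)
    aff_w <- sort(sample(idx_w, round(spec$affected_fraction * length(idx_w))))
    aff_b <- sort(sample(idx_b, round(spec$affected_fraction * length(idx_b))))

    beta_age <- beta_d1 <- lam <- numeric(ne)
    beta_age[aff_w] <- spec$beta_age_within
    beta_d1[aff_w]  <- spec$beta_d1_within
    lam[aff_w]      <- spec$latent_within
    beta_age[aff_b] <- spec$beta_age_between
    beta_d1[aff_b]  <- spec$beta_d1_between
    lam[aff_b]      <- spec$latent_between

    base <- ifelse(is_within, spec$base_within_z, spec$base_between_z)
    eta <- stats::rnorm(n)
    signal <- outer(z_age, beta_age) + outer(z_d1, beta_d1) + outer(eta, lam)
    x <- sweep(signal, 2, base, "+") +
      matrix(stats::rnorm(n * ne, 0, spec$noise_sd), n, ne)

    truth <- planted_truth(beta_age, beta_d1, lam, z_age, z_d1, eta,
                           spec$noise_sd, c(aff_w, aff_b), is_within)
    list(edges = edge_matrix(x, n_nodes, subject_ids = cohort$subject_id,
                             node_ids = partition$node_ids),
         truth = truth)
  })
}

# Ground truth of the planted pattern. The salience direction is the
# unit-normalized top singular vector (edge side) of the edges-by-design
# covariance pattern B %*% Sigma, where B holds the per-edge betas and Sigma
# the sample covariance of the z-scored design; this direction is exactly
# invariant to rescaling all betas. The planned latent correlations follow in
# closed form from cov(score, z_v) and var(score).
planted_truth <- function(beta_age, beta_d1, lam, z_age, z_d1, eta,
                          noise_sd, affected, is_within) {
  B <- cbind(beta_age, beta_d1)
  Sigma <- stats::cov(cbind(z_age, z_d1))
  cov_pattern <- B %*% Sigma                       # edges x 2
  if (sum(cov_pattern^2) == 0 && sum(lam^2) == 0) {
    u <- numeric(length(beta_age))
    r <- c(age = NA_real_, d1 = NA_real_)
    score <- numeric(length(z_age))
  } else {
    aff <- sort(affected)
    u <- numeric(nrow(cov_pattern))
    if (sum(cov_pattern^2) > 0) {
      u[aff] <- svd(cov_pattern[aff, , drop = FALSE], nu = 1, nv = 1)$u[, 1]
    } else {
      u <- lam / sqrt(sum(lam^2))
    }
    cc <- drop(crossprod(B, u))                   # design-side effect of the pattern
    lam_u <- sum(lam * u)
    v_score <- drop(crossprod(cc, Sigma %*% cc)) + lam_u^2 + noise_sd^2
    r <- drop(Sigma %*% cc) / sqrt(v_score)
    names(r) <- c("age", "d1")
    score <- drop(cbind(z_age, z_d1) %*% cc) + lam_u * eta
    # report the pattern in the receptor-positive orientation (higher true
    # score = more D1DR / more youth-like connectivity)
    if (!is.na(r["d1"]) && r["d1"] < 0) {
      u <- -u; r <- -r; score <- -score
    }
  }
  structure(list(true_salience = u,
                 true_latent_corr_age = unname(r["age"]),
                 true_latent_corr_d1 = unname(r["d1"]),
                 affected_edges = sort(affected),
                 true_score = score,
                 is_within = is_within),
            class = "planted_truth")
}

#' Simulate working-memory task scores coupled to the planted pattern
#'
#' A latent working-memory ability is generated as `gamma` times the
#' standardized true pattern score plus independent noise; each of the three
#' updating tasks measures that ability with reliability `reliability` and is
#' mapped onto its documented integer range (letter 0--48, number 0--108,
#' spatial 0--30).
#'
#' @param true_score Per-subject noiseless pattern expression
#'   (`truth$true_score` from [simulate_connectomes()]), or any numeric
#'   vector with nonzero variance.
#' @param gamma Correlation between latent working memory and the pattern
#'   score (default 0.35).
#' @param reliability Per-task loading on the latent ability (default 0.6).
#' @param seed Integer seed.
#' @return Data frame with integer columns `wm_letter`, `wm_number`,
#'   `wm_spatial`.
#' @export
simulate_wm_scores <- function(true_score, gamma = 0.35, reliability = 0.6,
                               seed = NULL) {
  if (abs(gamma) > 1) stop("gamma must lie in [-1, 1]")
  n <- length(true_score)
  with_seed(seed, {
    base <- if (stats::sd(true_score) > 0) zscore(true_score) else numeric(n)
    ability <- gamma * base + sqrt(1 - gamma^2) * stats::rnorm(n)
    task <- function(center, sd, max) {
      z <- sqrt(reliability) * ability + sqrt(1 - reliability) * stats::rnorm(n)
      pmin(pmax(round(center + sd * z), 0), max)
    }
    data.frame(wm_letter  = task(28, 7, 48),
               wm_number  = task(60, 16, 108),
               wm_spatial = task(17, 4.5, 30))
  })
}

#' Simulate multivariate-Gaussian timeseries with a target connectivity
#'
#' Draws zero-mean node-by-time Gaussian series whose population correlation
#' matrix is `tanh()` of the Fisher-z target (repaired to the nearest
#' positive-semidefinite correlation matrix by eigenvalue clipping when
#' needed), plus an optional six-parameter motion trace with displacement
#' spikes injected at chosen volumes.
#'
#' @param target A `connectivity_matrix` (Fisher-z) or symmetric matrix with
#'   zero diagonal.
#' @param n_volumes Number of time points (>= 10).
#' @param seed Integer seed.
#' @param spike_volumes Integer volumes at which a translation step of
#'   `spike_size` mm is injected into the motion trace.
#' @param spike_size Step size in mm (default 1).
#' @param motion_sd Per-volume SD of the random-walk increments of the
#'   translation parameters, in mm (rotations scaled down by the 50 mm
#'   conversion radius).
#' @return List with `ts` (node x time matrix) and `motion`
#'   (volumes x 6 matrix: three translations in mm, three rotations in rad).
#' @export
simulate_timeseries <- function(target, n_volumes, seed = NULL,
                                spike_volumes = integer(0), spike_size = 1,
                                motion_sd = 0.01) {
  if (n_volumes < 10) stop("n_volumes must be >= 10")
  z <- as_conn_values(target)
  r <- tanh(z); diag(r) <- 1
  e <- eigen(r, symmetric = TRUE)
  vals <- pmax(e$values, 1e-10)                  # nearest-PSD repair (clip)
  r <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(r)); r <- r / tcrossprod(d)     # back to unit diagonal
  n <- nrow(r)
  with_seed(seed, {
    cf <- chol(r + diag(1e-12, n))
    ts <- t(matrix(stats::rnorm(n_volumes * n), n_volumes, n) %*% cf)
    motion <- apply(matrix(stats::rnorm(n_volumes * 6, 0,
                                        rep(c(motion_sd, motion_sd / 50),
                                            each = 3 * n_volumes)),
                           n_volumes, 6), 2, cumsum)
    for (v in spike_volumes)
      motion[v:n_volumes, 1] <- motion[v:n_volumes, 1] + spike_size
    list(ts = ts, motion = motion)
  })
}

#' Simulate a complete synthetic study
#'
#' Runs the whole generator: age-stratified cohort, age-dependent D1DR,
#' block-structured connectomes with planted effects, and working-memory
#' scores coupled to the planted pattern.
#'
#' @param n_per_decade Subjects per decade (default 30; six decades 20--80).
#' @param n_nodes,n_networks Graph size (defaults 264 nodes, 14 networks).
#' @param spec An [effect_spec()].
#' @param gamma Working-memory coupling (see [simulate_wm_scores()]).
#' @param seed Integer seed; sub-generators use offsets of it.
#' @return List with `subjects` (a `subject_table` including `d1dr_bpnd` and
#'   WM scores), `partition`, `edges`, `truth`.
#' @export
simulate_study <- function(n_per_decade = 30, n_nodes = 264, n_networks = 14,
                           spec = effect_spec(), gamma = 0.35, seed = 1) {
  subjects <- simulate_cohort(n_per_decade, seed = seed)
  subjects$d1dr_bpnd <- simulate_d1dr(subjects$age, seed = seed + 1)
  partition <- simulate_partition(n_nodes, n_networks)
  sim <- simulate_connectomes(subjects, partition, spec, seed = seed + 2)
  wm <- simulate_wm_scores(sim$truth$true_score, gamma = gamma, seed = seed + 3)
  subjects <- validate_subject_table(cbind(subjects, wm))
  list(subjects = subjects, partition = partition,
       edges = sim$edges, truth = sim$truth)
}
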