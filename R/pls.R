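# Behavioral PLS on the variables-by-edges correlation matrix: SVD into
# design and brain saliences, brain scores, permutation test on the singular
# values, bootstrap ratios, and latent correlations.

# z-score columns; zero-variance columns are returned as all-zero and
# reported, so edge indexing is preserved.
zscore_cols <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  xc <- x - rep(m, each = n)
  s <- sqrt(colSums(xc^2) / (n - 1))
  zero <- s == 0 | !is.finite(s)
  s[zero] <- 1
  list(z = xc / rep(s, each = n), zero = zero)
}

#' Build a z-scored design matrix of variables of interest
#'
#' Stacks the named subject-table columns (by default D1DR availability and
#' age) and z-scores each with the sample SD (n - 1 divisor).
#'
#' @param table A `subject_table`.
#' @param variables Character vector of column names (default
#'   `c("age", "d1dr_bpnd")`).
#' @return A `design_matrix`: list with `values` (subjects x variables,
#'   columns mean 0 / SD 1), `variable_names`, `subject_ids`.
#' @export
build_design <- function(table, variables = c("age", "d1dr_bpnd")) {
  miss <- setdiff(variables, names(table))
  if (length(miss)) stop("design variable(s) not in table: ",
                         paste(miss, collapse = ", "))
  if (nrow(table) < 3) stop("need at least 3 subjects")
  x <- as.matrix(as.data.frame(table)[variables])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-finite design values")
  zc <- zscore_cols(x)
  if (any(zc$zero))
    stop("constant design column(s): ",
         paste(variables[zc$zero], collapse = ", "))
  structure(list(values = zc$z, variable_names = variables,
                 subject_ids = as.character(table$subject_id)),
            class = "design_matrix")
}

#' Cross-correlate design variables with connectome edges
#'
#' Entry (v, e) is the Pearson correlation across subjects between design
#' variable v and edge e. Zero-variance edges get r = 0 (with a message)
#' rather than being dropped, preserving the canonical edge indexing.
#'
#' @param design A `design_matrix`.
#' @param edges An `edge_matrix` over the same subjects in the same order.
#' @return Variables x edges numeric matrix.
#' @export
cross_correlate <- function(design, edges) {
  check_same_subjects(design, edges)
  n <- nrow(design$values)
  ze <- zscore_cols(edges$values)
  if (any(ze$zero))
    message(sum(ze$zero), " zero-variance edge(s); correlations set to 0")
  r <- crossprod(design$values, ze$z) / (n - 1)
  rownames(r) <- design$variable_names
  r
}

check_same_subjects <- function(design, edges) {
  if (nrow(design$values) != nrow(edges$values) ||
      !identical(design$subject_ids, edges$subject_ids))
    stop("design and edge matrices cover different subjects (or order differs)")
  invisible(TRUE)
}

# Singular value decomposition of a wide V x E matrix via the small-side
# Gram matrix: eigenvalues of R R' give the squared singular values, the
# eigenvectors the design-side singular vectors, and the edge-side vectors
# follow as R'u/s. With V = 2 this is orders of magnitude cheaper than a
# full SVD over tens of thousands of edges.
svd_wide <- function(r, values_only = FALSE, tol = 1e-12) {
  ee <- eigen(tcrossprod(r), symmetric = TRUE)
  d <- sqrt(pmax(ee$values, 0))
  if (values_only) return(d)
  u <- ee$vectors
  v <- crossprod(r, u)
  pos <- d > tol * max(d, tol)
  v[, pos] <- v[, pos, drop = FALSE] / rep(d[pos], each = nrow(v))
  v[, !pos] <- 0
  list(d = d, u = u, v = v)
}

# Orientation rule applied to every fit, permutation and bootstrap
# replicate: the design-salience entry of largest magnitude is positive.
fix_signs <- function(u, v) {
  for (l in seq_len(ncol(u))) {
    if (u[which.max(abs(u[, l])), l] < 0) {
      u[, l] <- -u[, l]
      v[, l] <- -v[, l]
    }
  }
  list(u = u, v = v)
}

#' Fit behavioral PLS (point estimates)
#'
#' Decomposes the variables-by-edges correlation matrix by SVD. Edge-side
#' singular vectors are the brain saliences and variable-side vectors the
#' design saliences, regardless of storage orientation. Each latent
#' variable's sign is fixed so that its largest-magnitude design-salience
#' entry is positive. The cross-block variance fraction of LV i is
#' `s_i^2 / sum(s^2)`; brain scores are the dot products of each subject's
#' canonical edge vector with the brain saliences.
#'
#' @param design A `design_matrix`.
#' @param edges An `edge_matrix` (same subjects, same order).
#' @return A `pls_result`: list with `brain_saliences` (edges x LVs,
#'   unit-norm columns), `design_saliences` (variables x LVs),
#'   `singular_values` (descending), `crossblock_fraction`, `brain_scores`
#'   (subjects x LVs), `latent_corr` (variables x LVs), `variable_names`,
#'   `edge_index`, `n`.
#' @export
fit_pls <- function(design, edges) {
  n <- nrow(design$values)
  if (n < ncol(design$values) + 2)
    stop("need at least 2 more subjects than design variables")
  r <- cross_correlate(design, edges)
  if (any(!is.finite(r))) stop("non-finite correlation matrix")
  sv <- svd_wide(r)
  fs <- fix_signs(sv$u, sv$v)
  lv_names <- paste0("LV", seq_along(sv$d))
  dimnames(fs$u) <- list(design$variable_names, lv_names)
  colnames(fs$v) <- lv_names
  scores <- edges$values %*% fs$v
  rownames(scores) <- edges$subject_ids
  structure(list(brain_saliences = fs$v,
                 design_saliences = fs$u,
                 singular_values = sv$d,
                 crossblock_fraction = sv$d^2 / sum(sv$d^2),
                 brain_scores = scores,
                 latent_corr = latent_correlations(scores, design),
                 variable_names = design$variable_names,
                 edge_index = edges$edge_index,
                 n = n),
            class = "pls_result")
}

#' Reorient latent variables so a chosen variable's salience is positive
#'
#' The sign of each latent variable is a pure convention: flipping a
#' salience pair and its scores leaves the model unchanged. [fit_pls()]
#' orients each LV so its largest-magnitude design-salience entry is
#' positive; this helper instead flips LVs so that the design salience of a
#' named variable (typically the receptor availability, so that higher brain
#' scores mean more youth-like, segregated connectivity) is positive.
#' Saliences, brain scores, latent correlations, bootstrap ratios and CIs
#' are flipped together.
#'
#' @param fit A `pls_result`.
#' @param variable Design variable whose salience should be positive
#'   (default `"d1dr_bpnd"`).
#' @return The reoriented `pls_result`.
#' @export
orient_lv <- function(fit, variable = "d1dr_bpnd") {
  iv <- match(variable, fit$variable_names)
  if (is.na(iv)) stop("variable '", variable, "' not in the design")
  flip <- which(fit$design_saliences[iv, ] < 0)
  for (l in flip) {
    fit$design_saliences[, l] <- -fit$design_saliences[, l]
    fit$brain_saliences[, l] <- -fit$brain_saliences[, l]
    fit$brain_scores[, l] <- -fit$brain_scores[, l]
    fit$latent_corr[, l] <- -fit$latent_corr[, l]
    if (!is.null(fit$bsr)) fit$bsr[, l] <- -fit$bsr[, l]
    if (!is.null(fit$latent_ci)) {
      lo <- fit$latent_ci[, l, "lower"]
      fit$latent_ci[, l, "lower"] <- -fit$latent_ci[, l, "upper"]
      fit$latent_ci[, l, "upper"] <- -lo
    }
  }
  fit
}

#' @export
print.pls_result <- function(x, ...) {
  k <- length(x$singular_values)
  cat("Behavioral PLS:", x$n, "subjects,", nrow(x$brain_saliences),
      "edges,", k, "latent variable(s)\n")
  tab <- data.frame(singular_value = round(x$singular_values, 4),
                    crossblock_pct = round(100 * x$crossblock_fraction, 2))
  if (!is.null(x$perm_p)) tab$perm_p <- signif(x$perm_p, 3)
  rownames(tab) <- paste0("LV", seq_len(k))
  print(tab)
  cat("latent correlations:\n")
  print(round(x$latent_corr, 3))
  invisible(x)
}

#' Brain scores: subject-level expression of a salience pattern
#'
#' `score[s] = sum_e salience[e] * edges[s, e]` over the canonical
#' upper-triangle edge vector.
#'
#' @param saliences Edge-length numeric vector or edges x LVs matrix.
#' @param edges An `edge_matrix` (or plain subjects x edges matrix).
#' @return Subjects x LVs matrix (or vector for a single salience vector).
#' @export
compute_brain_scores <- function(saliences, edges) {
  x <- if (inherits(edges, "edge_matrix")) edges$values else as.matrix(edges)
  s <- as.matrix(saliences)
  if (nrow(s) != ncol(x))
    stop("salience length ", nrow(s), " != edge count ", ncol(x))
  sc <- x %*% s
  if (ncol(sc) == 1) drop(sc) else sc
}

#' Pearson correlations of design variables with brain scores
#'
#' @param scores Subjects x LVs brain-score matrix (or vector).
#' @param design A `design_matrix` over the same subjects.
#' @return Variables x LVs correlation matrix.
#' @export
latent_correlations <- function(scores, design) {
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(design$values)) stop("subject count mismatch")
  if (any(apply(scores, 2, stats::sd) == 0)) stop("constant brain scores")
  r <- stats::cor(design$values, scores)
  rownames(r) <- design$variable_names
  colnames(r) <- paste0("LV", seq_len(ncol(scores)))
  r
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Permutation test on the PLS singular values
#'
#' Rows of the design matrix are permuted (edges fixed) and the PLS refit;
#' each latent variable's observed singular value is compared with the
#' permutation distribution of the same-ranked singular value (default), or
#' of the permuted maximum with `compare = "max"`. Monte-Carlo p-values use
#' the add-one estimator `(1 + #exceedances) / (n_perm + 1)`, so p = 0 is
#' never reported. With `exhaustive = TRUE` all `n!` permutations (identity
#' included) are enumerated and the p-value is the exact proportion of
#' permutations whose singular value reaches the observed one.
#'
#' @param design A `design_matrix`.
#' @param edges An `edge_matrix`.
#' @param n_perm Number of Monte-Carlo permutations (default 1000).
#' @param seed Integer seed.
#' @param compare `"per_rank"` (default) or `"max"`.
#' @param exhaustive Enumerate all permutations (requires n <= 8).
#' @return List with `p` (per LV), `observed` singular values, `n_perm`,
#'   `compare`.
#' @export
permutation_test <- function(design, edges, n_perm = 1000, seed = NULL,
                             compare = c("per_rank", "max"),
                             exhaustive = FALSE) {
  compare <- match.arg(compare)
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  check_same_subjects(design, edges)
  n <- nrow(design$values)
  ze <- zscore_cols(edges$values)$z
  zd <- design$values
  obs <- svd_wide(crossprod(zd, ze) / (n - 1), values_only = TRUE)
  perm_svals <- function(idx)
    svd_wide(crossprod(zd[idx, , drop = FALSE], ze) / (n - 1),
             values_only = TRUE)
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    sp <- vapply(all_permutations(n), perm_svals, numeric(length(obs)))
    denom <- ncol(sp)
    count <- count_exceed(sp, obs, compare)
    p <- count / denom
  } else {
    sp <- with_seed(seed,
      vapply(seq_len(n_perm), function(b) perm_svals(sample.int(n)),
             numeric(length(obs))))
    p <- (1 + count_exceed(sp, obs, compare)) / (n_perm + 1)
  }
  list(p = p, observed = obs,
       n_perm = if (exhaustive) factorial(n) else n_perm,
       compare = compare, exhaustive = exhaustive)
}

count_exceed <- function(sp, obs, compare) {
  sp <- matrix(sp, nrow = length(obs))
  if (compare == "max") {
    mx <- apply(sp, 2, max)
    vapply(obs, function(o) sum(mx >= o), numeric(1))
  } else {
    rowSums(sp >= obs)
  }
}

#' Bootstrap ratios and latent-correlation confidence intervals
#'
#' Subjects are resampled with replacement `n_boot` times and the PLS refit
#' on each replicate. The bootstrapped quantity is the singular-value-scaled
#' brain salience (`v * s`, the projection of the correlation matrix onto
#' the design direction), whose per-edge bootstrap SE consistently estimates
#' sampling variability; replicates are aligned to the original fit by
#' per-LV sign flip (dot-product sign; `align = "procrustes"` instead
#' applies an orthogonal rotation, useful when several LVs are close in
#' strength). The bootstrap ratio of an edge is its original scaled salience
#' divided by that SE; BSRs are approximately standard normal, so
#' `|BSR| > 2.8` corresponds to two-tailed p of about 0.005. Latent-correlation 95% confidence intervals are
#' percentile intervals over the replicates. Replicates in which a design
#' variable becomes constant are redrawn (and counted).
#'
#' @param design A `design_matrix`.
#' @param edges An `edge_matrix`.
#' @param n_boot Number of bootstrap replicates (default 1000, >= 2).
#' @param seed Integer seed.
#' @param align `"sign"` (default) or `"procrustes"`.
#' @return List with `bsr` (edges x LVs), `boot_se` (edges x LVs, on the
#'   singular-value-scaled salience scale),
#'   `latent_ci` (variables x LVs x c(lower, upper)), `n_boot`, `n_redrawn`.
#' @export
bootstrap_bsr <- function(design, edges, n_boot = 1000, seed = NULL,
                          align = c("sign", "procrustes")) {
  align <- match.arg(align)
  if (n_boot < 2) stop("n_boot must be >= 2")
  check_same_subjects(design, edges)
  n <- nrow(design$values)
  fit <- fit_pls(design, edges)
  k <- ncol(fit$brain_saliences)
  v0 <- fit$brain_saliences *
    rep(fit$singular_values[seq_len(k)], each = nrow(fit$brain_saliences))
  nv <- length(fit$variable_names)
  x <- edges$values
  x2 <- x^2                              # for resampled edge variances
  sum_v <- matrix(0, nrow(v0), k)
  sum_v2 <- matrix(0, nrow(v0), k)
  lat <- array(NA_real_, c(nv, k, n_boot))
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        zd <- zscore_cols(design$values[idx, , drop = FALSE])
        if (!any(zd$zero)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100 * n_boot) stop("too many degenerate replicates")
      }
      # replicate cross-correlations without materializing x[idx, ]:
      # aggregate the z-scored design draws per original subject (weights)
      w <- tabulate(idx, nbins = n)
      a <- rowsum(zd$z, idx, reorder = FALSE)
      aw <- matrix(0, n, ncol(a))
      aw[as.integer(rownames(a)), ] <- a
      mu <- drop(crossprod(w, x)) / n
      ss <- drop(crossprod(w, x2))
      sd_b <- sqrt(pmax((ss - n * mu^2) / (n - 1), 0))
      sd_b[sd_b == 0] <- 1
      rb <- crossprod(aw, x) / (n - 1) / rep(sd_b, each = ncol(aw))
      sv <- svd_wide(rb)
      vb <- sv$v[, seq_len(k), drop = FALSE] *
        rep(sv$d[seq_len(k)], each = nrow(sv$v))
      if (align == "procrustes") {
        pr <- svd(crossprod(vb, v0))
        vb <- vb %*% (pr$u %*% t(pr$v))
      } else {
        flip <- sign(colSums(vb * v0))
        flip[flip == 0] <- 1
        vb <- vb * rep(flip, each = nrow(vb))
      }
      sum_v <- sum_v + vb
      sum_v2 <- sum_v2 + vb^2
      sc <- (x %*% vb)[idx, , drop = FALSE]
      lat[, , b] <- stats::cor(design$values[idx, , drop = FALSE], sc)
    }
  })
  se <- sqrt(pmax(sum_v2 / n_boot - (sum_v / n_boot)^2, 0) *
               n_boot / (n_boot - 1))
  bsr <- v0 / se
  bsr[se == 0] <- NA_real_
  ci <- apply(lat, c(1, 2), stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  latent_ci <- aperm(ci, c(2, 3, 1))
  dimnames(latent_ci) <- list(fit$variable_names,
                              paste0("LV", seq_len(k)),
                              c("lower", "upper"))
  list(bsr = bsr, boot_se = se, latent_ci = latent_ci,
       n_boot = n_boot, n_redrawn = n_redrawn, align = align)
}

#' Run the full PLS inference
#'
#' Convenience wrapper combining [fit_pls()], [permutation_test()] and
#' [bootstrap_bsr()]; the returned `pls_result` gains `perm_p`, `bsr`,
#' `boot_se` and `latent_ci` fields.
#'
#' @inheritParams permutation_test
#' @inheritParams bootstrap_bsr
#' @return A `pls_result` with inference fields filled in.
#' @export
run_pls <- function(design, edges, n_perm = 1000, n_boot = 1000, seed = NULL,
                    compare = "per_rank", align = "sign") {
  fit <- fit_pls(design, edges)
  pt <- permutation_test(design, edges, n_perm = n_perm, seed = seed,
                         compare = compare)
  bs <- bootstrap_bsr(design, edges, n_boot = n_boot,
                      seed = if (is.null(seed)) NULL else seed + 1,
                      align = align)
  fit$perm_p <- pt$p
  fit$bsr <- bs$bsr
  fit$boot_se <- bs$boot_se
  fit$latent_ci <- bs$latent_ci
  fit$n_perm <- pt$n_perm
  fit$n_boot <- bs$n_boot
  fit
}
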