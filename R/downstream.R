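# Downstream analyses: working-memory composite scoring, partial regressions
# of brain scores, the deterministic two-group split on age-adjusted D1DR,
# and covariate-adjusted group comparisons.

#' T-score standardization (mean 50, SD 10)
#'
#' Z-scores with the sample SD (n - 1 divisor), then rescales to mean 50 and
#' SD 10.
#'
#' @param scores Numeric vector with at least two distinct values.
#' @return Numeric vector of T-scores.
#' @export
standardize_t <- function(scores) {
  if (any(!is.finite(scores))) stop("non-finite scores")
  s <- stats::sd(scores)
  if (s == 0) stop("cannot standardize a constant vector")
  (scores - mean(scores)) / s * 10 + 50
}

#' Working-memory composite score
#'
#' Each task is T-standardized (mean 50, SD 10) across the sample and the
#' composite is the per-subject mean of the three T-scores. Complete cases
#' only: any subject missing a task must be excluded beforehand.
#'
#' @param letter,number,spatial Raw task-score vectors of equal length.
#' @return Numeric composite vector.
#' @export
wm_composite <- function(letter, number, spatial) {
  n <- length(letter)
  if (length(number) != n || length(spatial) != n)
    stop("task score vectors must have equal length")
  if (anyNA(letter) || anyNA(number) || anyNA(spatial))
    stop("missing task scores; use complete cases")
  (standardize_t(letter) + standardize_t(number) + standardize_t(spatial)) / 3
}

#' Multiple regression with standardized betas and drop-one adjusted R-squared
#'
#' Ordinary least squares of `response` on the focal predictors plus
#' covariates, with two-sided t-tests per coefficient. Standardized betas
#' come from refitting with the z-scored response and predictors. For each
#' focal predictor, `delta_r2_adj` is the drop-one increment: adjusted
#' R-squared of the full model minus that of the model without the
#' predictor — one of several conventions for a per-predictor
#' "adjusted R-squared", reported as such.
#'
#' @param response Numeric response vector.
#' @param predictors Data frame (or named list) of focal predictors.
#' @param covariates Optional data frame of nuisance covariates.
#' @return A `regression_report`: list with `coefficients` (data frame:
#'   estimate, se, t, p, std_beta, delta_r2_adj), `r_squared`,
#'   `adj_r_squared`, `n`, `df_residual`.
#' @export
fit_ols <- function(response, predictors, covariates = NULL) {
  predictors <- as.data.frame(predictors)
  dat <- cbind(data.frame(.y = response), predictors)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  if (anyNA(dat)) stop("missing values; use complete cases")
  k <- ncol(dat) - 1L
  if (nrow(dat) <= k + 1L) stop("insufficient observations for ", k, " terms")
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  sm <- summary(fit)
  co <- sm$coefficients

  # standardized betas: z-score response and numeric terms, refit
  datz <- dat
  for (nm in names(datz))
    if (is.numeric(datz[[nm]]) && stats::sd(datz[[nm]]) > 0)
      datz[[nm]] <- (datz[[nm]] - mean(datz[[nm]])) / stats::sd(datz[[nm]])
  coz <- stats::coef(stats::lm(.y ~ ., data = datz))

  adj_full <- sm$adj.r.squared
  terms_all <- names(dat)[-1]
  focal <- names(predictors)
  d_r2 <- vapply(focal, function(tr) {
    keep <- setdiff(terms_all, tr)
    f <- if (length(keep))
      stats::reformulate(keep, response = ".y") else stats::formula(.y ~ 1)
    adj_full - summary(stats::lm(f, data = dat))$adj.r.squared
  }, numeric(1))

  rows <- rownames(co)[-1]
  tab <- data.frame(term = rows,
                    estimate = co[-1, 1], se = co[-1, 2],
                    t = co[-1, 3], p = co[-1, 4],
                    std_beta = coz[rows],
                    delta_r2_adj = d_r2[rows],
                    row.names = NULL)
  structure(list(coefficients = tab,
                 r_squared = sm$r.squared,
                 adj_r_squared = adj_full,
                 n = nrow(dat),
                 df_residual = fit$df.residual,
                 model = fit),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, digits = 4, ...) {
  cat("OLS regression: n =", x$n, ", residual df =", x$df_residual, "\n")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  cat("R2 =", signif(x$r_squared, digits),
      " adjusted R2 =", signif(x$adj_r_squared, digits), "\n")
  invisible(x)
}

#' Age-adjust a variable by linear regression
#'
#' Residuals of the OLS regression of `values` on `age` (intercept included):
#' mean zero, sample correlation with age zero.
#'
#' @param values Numeric vector.
#' @param age Numeric, non-constant.
#' @return Residual vector.
#' @export
age_adjust <- function(values, age) {
  if (stats::sd(age) == 0) stop("age is constant; cannot adjust")
  unname(stats::resid(stats::lm(values ~ age)))
}

#' Optimal two-group split of one-dimensional values
#'
#' Exhaustively scans the sorted-split thresholds and picks the partition
#' minimizing the within-cluster sum of squares — the global optimum of
#' two-cluster k-means in one dimension, but deterministic. The cluster with
#' the higher center is labeled `"high"`.
#'
#' @param adjusted Numeric vector (>= 2 distinct values), e.g. age-adjusted
#'   D1DR residuals.
#' @return A `group_split`: list with `labels` (character, "high"/"low"),
#'   `centers` (named), `split_value` (boundary between the groups), `wss`.
#' @export
split_two_groups <- function(adjusted) {
  n <- length(adjusted)
  if (n < 2 || length(unique(adjusted)) < 2)
    stop("need at least 2 distinct values")
  o <- order(adjusted)
  x <- adjusted[o]
  csum <- cumsum(x); csq <- cumsum(x^2)
  tot_s <- csum[n]; tot_q <- csq[n]
  m <- seq_len(n - 1)
  wss <- (csq[m] - csum[m]^2 / m) +
    ((tot_q - csq[m]) - (tot_s - csum[m])^2 / (n - m))
  valid <- x[m] < x[m + 1]                 # ties cannot straddle the boundary
  wss[!valid] <- Inf
  best <- which.min(wss)
  labels <- rep("low", n)
  labels[o[(best + 1):n]] <- "high"
  centers <- c(low = mean(x[seq_len(best)]), high = mean(x[(best + 1):n]))
  structure(list(labels = labels, centers = centers,
                 split_value = mean(x[best + 0:1]), wss = wss[best]),
            class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat("two-group split: n(high) =", sum(x$labels == "high"),
      ", n(low) =", sum(x$labels == "low"), "\n")
  cat("centers:", paste(names(x$centers), round(x$centers, 4),
                        collapse = ", "), "\n")
  invisible(x)
}

#' ANCOVA: group comparison adjusted for covariates
#'
#' OLS of the response on a group indicator plus covariates; the group effect
#' is tested with a partial F-test on 1 and n - k - 1 degrees of freedom.
#' Adjusted group means are model predictions at the covariate means.
#'
#' @param response Numeric response.
#' @param group Character/factor group labels (exactly 2 non-empty levels),
#'   or a `group_split`.
#' @param covariates Optional data frame of covariates.
#' @return List with `F`, `p`, `df`, `adjusted_means` (named by group),
#'   `model`.
#' @export
ancova <- function(response, group, covariates = NULL) {
  if (inherits(group, "group_split")) group <- group$labels
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("group must have exactly 2 non-empty levels")
  dat <- data.frame(.y = response, .grp = group)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  full <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(full)))) stop("rank-deficient design")
  reduced <- stats::lm(.y ~ . - .grp, data = dat)
  rss1 <- sum(stats::resid(full)^2)
  rss0 <- sum(stats::resid(reduced)^2)
  df1 <- full$df.residual
  Fstat <- (rss0 - rss1) / (rss1 / df1)
  p <- stats::pf(Fstat, 1, df1, lower.tail = FALSE)
  nd <- dat[c(1, 1), -1, drop = FALSE]
  nd$.grp <- factor(levels(group), levels = levels(group))
  for (nm in names(nd))
    if (is.numeric(nd[[nm]])) nd[[nm]] <- rep(mean(dat[[nm]]), 2)
  adj <- stats::predict(full, newdata = nd)
  names(adj) <- levels(group)
  list(F = Fstat, p = p, df = c(1, df1), adjusted_means = adj, model = full)
}
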