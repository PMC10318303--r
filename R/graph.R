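# Timeseries cleaning and graph construction: RMS displacement and spike
# flags, one simultaneous nuisance + band-pass regression, and Fisher-z
# Pearson connectivity matrices.

#' Cleaning configuration
#'
#' @param band Pass band in Hz, `c(low, high)` with
#'   `0 < low < high < 1/(2*tr)` (default 0.008--0.09 Hz).
#' @param tr Repetition time in seconds (default 2).
#' @param spike_threshold RMS-displacement threshold in mm above which a
#'   volume receives a spike regressor (default 0.25).
#' @param include_global_signal Include the whole-brain mean signal among the
#'   nuisance regressors (default `TRUE`; set `FALSE` to mirror a no-GSR
#'   sensitivity pipeline).
#' @param rotation_radius Radius in mm at which rotations are converted to
#'   arc length for the displacement summary (default 50).
#' @return A `cleaning_config` list.
#' @export
cleaning_config <- function(band = c(0.008, 0.09), tr = 2,
                            spike_threshold = 0.25,
                            include_global_signal = TRUE,
                            rotation_radius = 50) {
  nyq <- 1 / (2 * tr)
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] || band[2] >= nyq)
    stop("band must satisfy 0 < low < high < Nyquist = ", nyq, " Hz")
  if (spike_threshold <= 0) stop("spike_threshold must be > 0")
  structure(list(band = band, tr = tr, spike_threshold = spike_threshold,
                 include_global_signal = include_global_signal,
                 rotation_radius = rotation_radius),
            class = "cleaning_config")
}

#' Volume-to-volume RMS displacement and motion-spike flags
#'
#' For each volume, takes the backward difference of the six rigid-body
#' parameters (rotations first converted to arc length at
#' `rotation_radius`), and summarizes them as the root of the mean of the six
#' squared differences. The first volume has displacement 0 by convention.
#'
#' @param motion Volumes x 6 matrix: three translations (mm) then three
#'   rotations (radians).
#' @param spike_threshold Displacement threshold in mm (default 0.25).
#' @param rotation_radius Conversion radius in mm (default 50).
#' @return List with `displacement` (mm, per volume) and `spike` (logical).
#' @export
rms_displacement <- function(motion, spike_threshold = 0.25,
                             rotation_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion trace must have 6 columns")
  if (nrow(motion) < 2) stop("need at least 2 volumes")
  if (any(!is.finite(motion))) stop("non-finite motion parameters")
  mm <- motion
  mm[, 4:6] <- mm[, 4:6] * rotation_radius
  d <- diff(mm)
  disp <- c(0, sqrt(rowMeans(d^2)))
  list(displacement = disp, spike = disp > spike_threshold)
}

# sine/cosine regressors at every DFT frequency of the run that lies outside
# the pass band; regressing these out in the joint model is equivalent to
# band-pass filtering without re-introducing nuisance signal.
spectral_regressors <- function(n_volumes, tr, band) {
  k <- seq_len(floor(n_volumes / 2))
  f <- k / (n_volumes * tr)
  out <- k[f < band[1] | f > band[2]]
  if (!length(out)) return(NULL)
  t_idx <- seq_len(n_volumes) - 1
  cols <- lapply(out, function(kk) {
    w <- 2 * pi * kk * t_idx / n_volumes
    if (2 * kk == n_volumes) cbind(cos(w)) else cbind(sin(w), cos(w))
  })
  x <- do.call(cbind, cols)
  colnames(x) <- NULL
  x
}

expand_confounds <- function(x) {
  x <- as.matrix(x)
  d <- rbind(0, diff(x))
  cbind(x, x^2, d, d^2)
}

#' Simultaneous nuisance and band-pass regression
#'
#' Removes, in a single joint least-squares regression per node: linear and
#' quadratic trends; the supplied base nuisance signals (e.g. tissue means
#' and motion parameters) expanded with their squares, backward-difference
#' derivatives and squared derivatives; the whole-brain mean signal (same
#' expansion) when `cfg$include_global_signal` is set; one-hot spike
#' regressors for volumes whose RMS displacement exceeds the threshold; and
#' sine/cosine regressors at all discrete Fourier frequencies of the run
#' outside the pass band. Fitting everything at once avoids re-introducing
#' nuisance variance that a sequential filter-then-regress pipeline would.
#'
#' @param ts Node x time matrix.
#' @param motion Optional volumes x 6 motion trace (spike regressors and
#'   motion confounds are derived from it).
#' @param nuisance Optional volumes x k matrix of base nuisance signals.
#' @param cfg A [cleaning_config()].
#' @return List with `residuals` (node x time), `spike` (logical per volume),
#'   `n_regressors`.
#' @export
clean_timeseries <- function(ts, motion = NULL, nuisance = NULL,
                             cfg = cleaning_config()) {
  ts <- as.matrix(ts)
  nv <- ncol(ts)
  t_idx <- seq_len(nv)
  lin <- scale(t_idx)[, 1]
  X <- cbind(1, lin, lin^2)
  base <- NULL
  if (!is.null(motion)) base <- cbind(base, as.matrix(motion))
  if (!is.null(nuisance)) base <- cbind(base, as.matrix(nuisance))
  if (isTRUE(cfg$include_global_signal)) base <- cbind(base, colMeans(ts))
  if (!is.null(base)) {
    ec <- expand_confounds(base)
    ec <- ec[, apply(ec, 2, stats::var) > 0, drop = FALSE]  # drop constants
    X <- cbind(X, ec)
  }
  spike <- rep(FALSE, nv)
  if (!is.null(motion)) {
    spike <- rms_displacement(motion, cfg$spike_threshold,
                              cfg$rotation_radius)$spike
    if (any(spike)) {
      oh <- matrix(0, nv, sum(spike))
      oh[cbind(which(spike), seq_len(sum(spike)))] <- 1
      X <- cbind(X, oh)
    }
  }
  X <- cbind(X, spectral_regressors(nv, cfg$tr, cfg$band))
  if (ncol(X) >= nv)
    stop("rank-deficient cleaning design: ", ncol(X), " regressors for ",
         nv, " volumes")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient cleaning design (collinear regressors)")
  res <- t(qr.resid(qx, t(ts)))
  dimnames(res) <- dimnames(ts)
  list(residuals = res, spike = spike, n_regressors = ncol(X))
}

#' Build a Fisher-z connectivity matrix from node timeseries
#'
#' Pairwise Pearson correlations across time, clipped to
#' `+/-(1 - 1e-7)` so the Fisher transform stays finite for degenerate
#' pairs, then `atanh()`; the main diagonal is set to zero.
#'
#' @param ts Node x time matrix (>= 3 volumes; every node series must have
#'   nonzero variance).
#' @param node_ids Optional node identifiers (defaults to rownames).
#' @return A `connectivity_matrix`.
#' @export
build_connectivity <- function(ts, node_ids = NULL) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stop("need at least 3 volumes")
  v <- apply(ts, 1, stats::var)
  if (any(v == 0))
    stop("constant node series (zero variance): node(s) ",
         paste(which(v == 0), collapse = ", "))
  r <- stats::cor(t(ts))
  cap <- 1 - 1e-7
  n_clip <- sum(abs(r[upper.tri(r)]) > cap)
  if (n_clip > 0)
    message("clipped ", n_clip, " edge correlation(s) at |r| = ", cap)
  r <- pmin(pmax(r, -cap), cap)
  z <- atanh(r)
  diag(z) <- 0
  if (is.null(node_ids)) node_ids <- rownames(ts)
  connectivity_matrix(z, node_ids = node_ids, tol = 1e-6)
}
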