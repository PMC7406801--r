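#' Fractional anisotropy and mean diffusivity from tensor eigenvalues
#'
#' FA is the standard scalar anisotropy of the diffusion tensor,
#' `sqrt(3/2) * sqrt(sum((lambda_i - <lambda>)^2) / sum(lambda_i^2))`,
#' which lies in \[0, 1\]; MD is the eigenvalue mean `<lambda>`. Voxels with
#' all-zero eigenvalues get FA = 0 by convention.
#'
#' @param eigs A 4D array (X, Y, Z, 3) of eigenvalues sorted decreasingly,
#'   or an n x 3 matrix (one row per voxel).
#' @return A list with elements `fa` and `md` (3D arrays, or vectors when
#'   `eigs` is a matrix), each carrying a `metric_name` attribute.
#' @export
compute_fa_md <- function(eigs) {
  was_array <- length(dim(eigs)) == 4L
  lam <- if (was_array) matrix(eigs, ncol = 3L) else as.matrix(eigs)
  if (ncol(lam) != 3L) stop("'eigs' must have three eigenvalues per voxel")
  neg <- which(lam < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative eigenvalue at voxel %d (eigenvalue %d)",
                 neg[1, 1], neg[1, 2]))
  }
  if (any(lam[, 1] < lam[, 2] | lam[, 2] < lam[, 3])) {
    stop("eigenvalues must be sorted decreasingly (lambda1 >= lambda2 >= lambda3)")
  }
  md <- rowMeans(lam)
  ss <- rowSums(lam^2)
  dev <- rowSums((lam - md)^2)
  fa <- ifelse(ss > 0, sqrt(1.5 * dev / ss), 0)
  fa <- pmin(pmax(fa, 0), 1)
  if (was_array) {
    sp <- dim(eigs)[1:3]
    fa <- array(fa, sp); md <- array(md, sp)
  }
  attr(fa, "metric_name") <- "FA"
  attr(md, "metric_name") <- "MD"
  list(fa = fa, md = md)
}

# frequency of DFT bin k (0-based) for T samples at sampling interval tr
.bin_freqs <- function(Tn, tr) {
  k <- seq_len(Tn) - 1L
  pmin(k, Tn - k) / (Tn * tr)
}

#' Preprocess a 4D BOLD time series
#'
#' Drops initial time points, removes the per-voxel linear trend, optionally
#' band-passes with an ideal (frequency-domain mask) filter, and optionally
#' smooths spatially with a Gaussian kernel of the given FWHM.
#'
#' @param vol 4D array (X, Y, Z, T); `tr_seconds` taken from its attribute
#'   unless given.
#' @param tr_seconds Repetition time in seconds.
#' @param drop_initial Number of initial volumes to discard (default 10).
#' @param band_hz Optional `c(low, high)` pass band in Hz; bins with
#'   frequency outside the band (including DC) are zeroed.
#' @param fwhm_mm Optional Gaussian smoothing FWHM in mm
#'   (sigma = FWHM / (2 sqrt(2 ln 2)) per axis).
#' @param voxel_size_mm Voxel size used to convert FWHM to voxel units.
#' @return The preprocessed 4D array, with attributes preserved.
#' @export
preprocess_timeseries <- function(vol, tr_seconds = attr(vol, "tr_seconds"),
                                  drop_initial = 10L, band_hz = NULL,
                                  fwhm_mm = NULL,
                                  voxel_size_mm = attr(vol, "voxel_size_mm") %||% c(1, 1, 1)) {
  d <- dim(vol)
  stopifnot(length(d) == 4L)
  if (is.null(tr_seconds)) stop("'tr_seconds' is required")
  Tn <- d[4] - drop_initial
  if (Tn < 20) stop("fewer than 20 time points would remain after removal")
  x <- matrix(vol, prod(d[1:3]), d[4])
  if (drop_initial > 0) x <- x[, -(seq_len(drop_initial)), drop = FALSE]
  # linear detrend, closed form against [1, t]
  t <- seq_len(Tn)
  tc <- t - mean(t)
  slope <- (x %*% tc) / sum(tc^2)
  x <- x - rowMeans(x) - tcrossprod(slope, tc)
  if (!is.null(band_hz)) {
    nyq <- 1 / (2 * tr_seconds)
    if (band_hz[1] <= 0 && band_hz[2] <= 0 || band_hz[2] > nyq + 1e-12) {
      stop(sprintf("band (%g, %g) Hz must lie within (0, Nyquist = %g]",
                   band_hz[1], band_hz[2], nyq))
    }
    f <- .bin_freqs(Tn, tr_seconds)
    keep <- f >= band_hz[1] & f <= band_hz[2]
    X <- stats::mvfft(t(x))
    X[!keep, ] <- 0
    x <- t(Re(stats::mvfft(X, inverse = TRUE)) / Tn)
  }
  out <- array(x, c(d[1:3], Tn))
  if (!is.null(fwhm_mm)) {
    sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size_mm
    for (tt in seq_len(Tn)) {
      out[, , , tt] <- gaussian_smooth3d(out[, , , tt], sigma_vox)
    }
  }
  attr(out, "tr_seconds") <- tr_seconds
  attr(out, "voxel_size_mm") <- voxel_size_mm
  out
}

#' Separable 3D Gaussian smoothing
#'
#' Truncated (3 sigma) separable Gaussian convolution with edge
#' renormalization, applied axis by axis.
#'
#' @param vol 3D numeric array.
#' @param sigma_vox Gaussian SD per axis, in voxel units (scalar or triple);
#'   axes with sigma 0 are left untouched.
#' @return The smoothed array.
#' @export
gaussian_smooth3d <- function(vol, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  d <- dim(vol)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-r:r, sd = s)
    n <- d[ax]
    # banded weight matrix with renormalized rows at the edges
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      wi <- w[j - i + r + 1L]
      W[i, j] <- wi / sum(wi)
    }
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    v <- aperm(vol, perm)
    v <- array(W %*% matrix(v, d[ax]), dim(v))
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Amplitude of low-frequency fluctuations (ALFF and fALFF)
#'
#' Per voxel, the one-sided discrete Fourier amplitude spectrum
#' (2 |X_k| / T, DC bin excluded) is computed on the (already detrended)
#' series. ALFF is the mean amplitude over bins inside `low_band`; fALFF is
#' the summed low-band amplitude as a fraction of the summed amplitude over
#' the full band, whose upper limit is capped at Nyquist.
#'
#' @param vol 4D array (X, Y, Z, T).
#' @param tr_seconds Repetition time in seconds.
#' @param low_band Low-frequency band in Hz (default 0.01-0.08).
#' @param full_band Full spectrum band in Hz (default 0-0.25; the upper
#'   limit is reduced to Nyquist when the sampling rate cannot resolve it).
#' @return A list with 3D arrays `alff` and `falff` (fALFF in \[0, 1\]);
#'   attribute `band_hz` records the effective bands, and
#'   `n_zero_spectrum` counts voxels whose total amplitude was zero (their
#'   fALFF is defined as 0, with a warning).
#' @export
compute_alff_falff <- function(vol, tr_seconds = attr(vol, "tr_seconds"),
                               low_band = c(0.01, 0.08),
                               full_band = c(0, 0.25)) {
  d <- dim(vol)
  stopifnot(length(d) == 4L)
  if (is.null(tr_seconds)) stop("'tr_seconds' is required")
  Tn <- d[4]
  nyq <- 1 / (2 * tr_seconds)
  full_hi <- min(full_band[2], nyq)
  x <- matrix(vol, prod(d[1:3]), Tn)
  X <- stats::mvfft(t(x))
  half <- 2:(floor(Tn / 2) + 1L)          # positive-frequency bins, DC excluded
  f <- (half - 1L) / (Tn * tr_seconds)
  amp <- 2 * Mod(X[half, , drop = FALSE]) / Tn
  in_low <- f >= low_band[1] & f <= low_band[2]
  in_full <- f > max(full_band[1], 0) & f <= full_hi + 1e-12
  if (!any(in_low)) stop("no frequency bin falls inside 'low_band'")
  alff <- colMeans(amp[in_low, , drop = FALSE])
  low_sum <- colSums(amp[in_low, , drop = FALSE])
  full_sum <- colSums(amp[in_full, , drop = FALSE])
  zero <- full_sum <= 0
  if (any(zero)) warning(sprintf("%d voxel(s) with zero total amplitude; fALFF set to 0", sum(zero)))
  falff <- ifelse(zero, 0, pmin(low_sum / ifelse(zero, 1, full_sum), 1))
  sp <- d[1:3]
  alff <- array(alff, sp); falff <- array(falff, sp)
  attr(alff, "metric_name") <- "ALFF"
  attr(falff, "metric_name") <- "fALFF"
  attr(alff, "band_hz") <- low_band
  attr(falff, "band_hz") <- c(max(full_band[1], 0), full_hi)
  attr(falff, "n_zero_spectrum") <- sum(zero)
  list(alff = alff, falff = falff)
}

#' Kendall's coefficient of concordance
#'
#' Agreement among m series ranked over T time points:
#' `W = 12 * sum_t (R_t - m (T + 1) / 2)^2 / (m^2 (T^3 - T))`, where `R_t`
#' is the sum across series of the time-point ranks (average ranks on
#' ties). W = 1 means perfect concordance, 0 none.
#'
#' @param x An m x T matrix, one series per row.
#' @return W in \[0, 1\].
#' @export
kendall_w <- function(x) {
  x <- as.matrix(x)
  m <- nrow(x); Tn <- ncol(x)
  if (m < 2 || Tn < 2) stop("need at least 2 series of length 2")
  rk <- t(apply(x, 1L, rank, ties.method = "average"))
  R <- colSums(rk)
  S <- sum((R - m * (Tn + 1) / 2)^2)
  12 * S / (m^2 * (Tn^3 - Tn))
}

.neighborhood_offsets <- function(neighborhood) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  manh <- rowSums(abs(off))
  switch(as.character(neighborhood),
         "7"  = off[manh <= 1, , drop = FALSE],
         "19" = off[manh <= 2, , drop = FALSE],
         "27" = off,
         stop("'neighborhood' must be one of 7, 19, 27"))
}

#' Regional homogeneity (Kendall's coefficient of concordance)
#'
#' For every interior voxel, Kendall's W is computed over the time series of
#' the voxel and its neighbors (m = 7, 19 or 27 series): each series is
#' ranked over time (average ranks on ties), the ranks are summed across
#' series at each time point, and
#' `W = 12 * sum_t (R_t - m (T + 1) / 2)^2 / (m^2 (T^3 - T))`.
#' Boundary voxels with an incomplete neighborhood are set to 0 and flagged
#' in the returned `interior_mask` attribute. A fully constant neighborhood
#' yields W = 0 (with a warning).
#'
#' @param vol 4D array (X, Y, Z, T) of detrended series.
#' @param neighborhood Cluster size: 7 (faces), 19 (faces + edges) or 27
#'   (full cube).
#' @return A 3D array of W values in \[0, 1\] with attributes
#'   `metric_name = "ReHo"` and `interior_mask`.
#' @export
compute_reho <- function(vol, neighborhood = 27L) {
  d <- dim(vol)
  stopifnot(length(d) == 4L)
  Tn <- d[4]
  off <- .neighborhood_offsets(neighborhood)
  m <- nrow(off)
  # rank every voxel's series over time (ties -> average ranks)
  x <- matrix(vol, prod(d[1:3]), Tn)
  rk <- t(apply(x, 1L, rank, ties.method = "average"))
  const <- .row_vars(x) == 0
  rk4 <- array(rk, c(d[1:3], Tn))
  sp <- d[1:3]
  xi <- 2:(sp[1] - 1L); yi <- 2:(sp[2] - 1L); zi <- 2:(sp[3] - 1L)
  if (any(sp < 3)) stop("volume too small for a full neighborhood")
  Rsum <- array(0, c(length(xi), length(yi), length(zi), Tn))
  nconst <- array(0L, c(length(xi), length(yi), length(zi)))
  const3 <- array(const, sp)
  for (k in seq_len(m)) {
    Rsum <- Rsum + rk4[xi + off[k, 1], yi + off[k, 2], zi + off[k, 3], , drop = FALSE]
    nconst <- nconst + const3[xi + off[k, 1], yi + off[k, 2], zi + off[k, 3]]
  }
  dev <- Rsum - m * (Tn + 1) / 2
  S <- apply(dev^2, 1:3, sum)
  W <- 12 * S / (m^2 * (Tn^3 - Tn))
  all_const <- nconst == m
  if (any(all_const)) {
    warning(sprintf("%d fully constant neighborhood(s); W set to 0", sum(all_const)))
    W[all_const] <- 0
  }
  out <- array(0, sp)
  out[xi, yi, zi] <- W
  interior <- array(FALSE, sp); interior[xi, yi, zi] <- TRUE
  attr(out, "metric_name") <- "ReHo"
  attr(out, "interior_mask") <- interior
  out
}

# row variances, closed form
.row_vars <- function(x) {
  n <- ncol(x)
  (rowSums(x^2) - rowSums(x)^2 / n) / (n - 1)
}
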