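#' Specification for synthetic 4D volumes
#'
#' Geometry and timing for the synthetic resting-state and diffusion
#' volumes. Defaults follow a typical 3 T resting-state acquisition
#' (TR = 3 s, 140 time points).
#'
#' @param shape Integer triple (X, Y, Z) of voxel dimensions.
#' @param n_timepoints Number of time points (must exceed 20).
#' @param tr_seconds Repetition time in seconds.
#' @param voxel_size_mm Numeric triple of voxel edge lengths in mm.
#' @param effect_region List with integer triples `lo` and `hi`: the
#'   voxel-coordinate box carrying the group effect (inclusive, 1-based).
#'   Default: the central third of the volume.
#' @return An object of class `volume_spec`.
#' @export
volume_spec <- function(shape = c(12L, 12L, 12L), n_timepoints = 140L,
                        tr_seconds = 3.0, voxel_size_mm = c(3, 3, 3),
                        effect_region = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (n_timepoints <= 20) stop("'n_timepoints' must exceed 20")
  if (tr_seconds <= 0) stop("'tr_seconds' must be positive")
  if (is.null(effect_region)) {
    lo <- pmax(1L, floor(shape / 3) + 1L)
    hi <- pmin(shape, floor(2 * shape / 3))
    effect_region <- list(lo = lo, hi = hi)
  }
  lo <- as.integer(effect_region$lo); hi <- as.integer(effect_region$hi)
  if (any(lo < 1) || any(hi > shape) || any(lo > hi)) {
    stop("'effect_region' must be a non-empty box inside 'shape'")
  }
  structure(list(shape = shape, n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, voxel_size_mm = voxel_size_mm,
                 effect_region = list(lo = lo, hi = hi)),
            class = "volume_spec")
}

.region_mask <- function(spec) {
  m <- array(FALSE, spec$shape)
  r <- spec$effect_region
  m[r$lo[1]:r$hi[1], r$lo[2]:r$hi[2], r$lo[3]:r$hi[3]] <- TRUE
  m
}

#' Generate a synthetic BOLD-like 4D time-series volume
#'
#' Every voxel carries AR(1) noise; voxels inside the spec's effect region
#' additionally carry a sinusoid of the given frequency and amplitude,
#' emulating a low-frequency fluctuation confined to a region.
#'
#' @param spec A [volume_spec()].
#' @param amplitude Sinusoid amplitude (0 for pure noise), in units of the
#'   AR(1) innovation SD (which is 1).
#' @param frequency_hz Sinusoid frequency; must not exceed Nyquist
#'   (1 / (2 TR)).
#' @param ar Lag-1 autoregressive coefficient of the noise.
#' @param seed Integer seed; identical seeds give identical volumes.
#' @return A 4D array (X, Y, Z, T) with attributes `tr_seconds`,
#'   `voxel_size_mm` and `effect_mask`.
#' @export
generate_timeseries_volume <- function(spec, amplitude = 0, frequency_hz = 0.05,
                                       ar = 0.3, seed = 1L) {
  stopifnot(inherits(spec, "volume_spec"))
  nyq <- 1 / (2 * spec$tr_seconds)
  if (frequency_hz > nyq) {
    stop(sprintf("frequency %.4f Hz exceeds Nyquist %.4f Hz", frequency_hz, nyq))
  }
  nvox <- prod(spec$shape); Tn <- spec$n_timepoints
  with_seed(seed, {
    innov <- matrix(stats::rnorm(Tn * nvox), Tn, nvox)
    x <- stats::filter(innov, ar, method = "recursive")
    x <- matrix(as.numeric(x), Tn, nvox)
  })
  if (amplitude != 0) {
    s <- amplitude * sin(2 * pi * frequency_hz * spec$tr_seconds * seq_len(Tn))
    in_region <- which(.region_mask(spec))
    x[, in_region] <- x[, in_region] + s
  }
  vol <- array(t(x), c(spec$shape, Tn))
  attr(vol, "tr_seconds") <- spec$tr_seconds
  attr(vol, "voxel_size_mm") <- spec$voxel_size_mm
  attr(vol, "effect_mask") <- .region_mask(spec)
  vol
}

# axially symmetric eigenvalue triple with exact fractional anisotropy `fa`
# and mean diffusivity `md`: (md(1+2d), md(1-d), md(1-d))
.eigs_for_fa <- function(fa, md = 1) {
  if (fa < 0 || fa >= 1) stop("FA target must lie in [0, 1)")
  d <- fa * sqrt(1 / (3 - 2 * fa^2))
  md * c(1 + 2 * d, 1 - d, 1 - d)
}

#' Generate a synthetic diffusion-tensor eigenvalue volume
#'
#' Each voxel holds the three eigenvalues of an axially symmetric diffusion
#' tensor whose noise-free fractional anisotropy equals the target of its
#' compartment (effect region vs background) and whose mean diffusivity is
#' `md`. Optional multiplicative noise perturbs the eigenvalues, which are
#' then re-sorted so the ordering invariant holds.
#'
#' @param spec A [volume_spec()] (the time dimension is ignored).
#' @param fa_region FA target inside the effect region, in \[0, 1).
#' @param fa_background FA target elsewhere, in \[0, 1).
#' @param md Mean diffusivity (arbitrary common scale).
#' @param noise_sd SD of multiplicative log-normal eigenvalue noise
#'   (0 = noise-free).
#' @param seed Integer seed.
#' @return A 4D array (X, Y, Z, 3) of eigenvalues, sorted decreasingly along
#'   the fourth margin, with attribute `effect_mask`.
#' @export
generate_tensor_volume <- function(spec, fa_region = 0.7, fa_background = 0.3,
                                   md = 1, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(spec, "volume_spec"))
  if (fa_region >= 1 || fa_background >= 1) {
    stop("FA targets of 1 or above are rejected (they require a zero eigenvalue)")
  }
  mask <- .region_mask(spec)
  nvox <- prod(spec$shape)
  lam <- matrix(rep(.eigs_for_fa(fa_background, md), each = nvox), nvox, 3)
  lam[mask, ] <- matrix(rep(.eigs_for_fa(fa_region, md), each = sum(mask)),
                        sum(mask), 3)
  if (noise_sd > 0) {
    with_seed(seed, {
      lam <- lam * exp(matrix(stats::rnorm(nvox * 3, sd = noise_sd), nvox, 3))
    })
    lam <- t(apply(lam, 1, sort, decreasing = TRUE))
  }
  vol <- array(lam, c(spec$shape, 3L))
  attr(vol, "effect_mask") <- mask
  vol
}

#' Write a 3D/4D volume as NIfTI-1
#'
#' @param vol A numeric array (3D metric map or 4D series).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel edge lengths written to the header (defaults
#'   to the array's `voxel_size_mm` attribute, else 1 mm isotropic).
#' @return Invisibly, `path`.
#' @export
write_volume_nifti <- function(vol, path, voxel_size_mm = NULL) {
  vs <- voxel_size_mm %||% attr(vol, "voxel_size_mm") %||% c(1, 1, 1)
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- c(vs[1:3], rep(1, max(0, length(dim(vol)) - 3)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A numeric array with a `voxel_size_mm` attribute.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}
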