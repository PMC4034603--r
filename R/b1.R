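# Transmit-field (B1) mapping from the actual flip-angle imaging (AFI)
# acquisition: two interleaved TRs whose signal ratio yields the actual
# excitation angle via cos(a) = (r*n - 1)/(n - r), n = TR2/TR1.

#' Actual flip angle from the AFI volume pair
#'
#' @param S1,S2 the two AFI `vol3d` volumes (TR1 and TR2 acquisitions).
#' @param TR1_ms,TR2_ms the alternating TR pair, ms (`TR2 > TR1`).
#' @param noise_sigma voxels with `S1 < 3 * noise_sigma` are masked (`NA`);
#'   0 disables masking.
#' @return a `vol3d` of flip angles in degrees; the `clipped` attribute
#'   counts voxels whose arccos argument fell outside [-1, 1].
#' @export
afi_flip_angle <- function(S1, S2, TR1_ms = 50, TR2_ms = 150,
                           noise_sigma = 0) {
  if (TR2_ms <= TR1_ms) stop("afi_flip_angle: need TR2 > TR1 (n > 1)")
  stop_if_grid_mismatch(S1, S2, "afi_flip_angle")
  n <- TR2_ms / TR1_ms
  r <- S2$data / S1$data
  arg <- (r * n - 1) / (n - r)
  clipped <- sum(arg < -1 | arg > 1, na.rm = TRUE)
  arg <- pmin(pmax(arg, -1), 1)
  a <- acos(arg) * 180 / pi
  a[!is.finite(a)] <- NA_real_
  if (noise_sigma > 0) a[S1$data < 3 * noise_sigma] <- NA_real_
  out <- vol3d(a, S1$affine)
  attr(out, "clipped") <- clipped
  out
}

#' Express a flip-angle map in percent of nominal
#'
#' @param flip_map `vol3d` of actual flip angles, degrees.
#' @param nominal_deg nominal excitation angle, degrees (> 0).
#' @return a `vol3d` transmit-field map f_T in percent of nominal.
#' @export
to_percent_nominal <- function(flip_map, nominal_deg = 60) {
  if (nominal_deg <= 0) stop("to_percent_nominal: nominal angle must be positive")
  vol3d(100 * flip_map$data / nominal_deg, flip_map$affine)
}

gaussian_kernel_1d <- function(fwhm_mm, voxel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

convolve_axis <- function(arr, k, axis) {
  if (length(k) == 1) return(arr)
  d <- dim(arr)
  r <- (length(k) - 1) / 2
  out <- array(0, d)
  for (m in seq_along(k)) {
    off <- m - 1 - r
    src <- pmin(pmax(seq_len(d[axis]) + off, 1), d[axis]) # replicate edges
    out <- out + k[m] * switch(axis,
                               arr[src, , , drop = FALSE],
                               arr[, src, , drop = FALSE],
                               arr[, , src, drop = FALSE])
  }
  out
}

#' Gaussian smoothing of a volume (separable, edge-replicated)
#'
#' @param v a `vol3d`.
#' @param fwhm_mm kernel full-width at half-maximum, mm (0 disables).
#' @return the smoothed `vol3d`.
#' @export
smooth_gaussian <- function(v, fwhm_mm) {
  if (fwhm_mm <= 0) return(v)
  vd <- voxel_size(v$affine)
  a <- v$data
  for (ax in 1:3) a <- convolve_axis(a, gaussian_kernel_1d(fwhm_mm, vd[ax]), ax)
  vol3d(a, v$affine)
}

fill_nearest <- function(arr) {
  # fill NA voxels by iterative nearest-valid dilation
  while (anyNA(arr)) {
    d <- dim(arr)
    filled <- arr
    na <- is.na(arr)
    if (all(na)) stop("prepare_b1_for_correction: empty valid mask")
    for (shift in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))) {
      src_i <- pmin(pmax(seq_len(d[1]) - shift[1], 1), d[1])
      src_j <- pmin(pmax(seq_len(d[2]) - shift[2], 1), d[2])
      src_k <- pmin(pmax(seq_len(d[3]) - shift[3], 1), d[3])
      nb <- arr[src_i, src_j, src_k, drop = FALSE]
      take <- is.na(filled) & !is.na(nb)
      filled[take] <- nb[take]
    }
    if (identical(filled, arr)) break
    arr <- filled
  }
  arr
}

#' Resample and smooth a B1 map for flip-angle correction
#'
#' The transmit-field map is resampled (trilinear) onto the reference grid
#' under the transform obtained by registering the first AFI volume to the
#' registered T1w volume, masked voxels are filled from their nearest valid
#' neighbours, and the result is smoothed with a Gaussian kernel.
#'
#' @param b1 transmit-field `vol3d`, percent of nominal (may contain `NA`).
#' @param reference `vol3d` defining the output grid.
#' @param t [rigid_transform()] mapping the reference to the B1 grid
#'   (identity by default).
#' @param smoothing_fwhm_mm Gaussian FWHM, mm (default 8; 0 disables).
#' @return the corrected-grid transmit-field `vol3d` (percent).
#' @export
prepare_b1_for_correction <- function(b1, reference, t = rigid_transform(),
                                      smoothing_fwhm_mm = 8) {
  filled <- vol3d(fill_nearest(b1$data), b1$affine)
  M <- rigid_matrix(t, volume_centre(reference))
  Q <- index_map(reference$affine, b1$affine, M)
  pts <- grid_points(dim(reference$data))
  s <- apply_index_map(Q, pts)
  pp <- pad_array(filled$data, 1L)
  vals <- interp_points(pp, s$si, s$sj, s$sk, "linear")
  # out-of-field voxels keep the nearest in-field value rather than 0
  outside <- vals == 0 &
    (s$si < -0.5 | s$si > dim(b1$data)[1] - 0.5 |
     s$sj < -0.5 | s$sj > dim(b1$data)[2] - 0.5 |
     s$sk < -0.5 | s$sk > dim(b1$data)[3] - 0.5)
  v <- array(vals, dim(reference$data))
  v[array(outside, dim(v))] <- NA_real_
  v <- fill_nearest(v)
  smooth_gaussian(vol3d(v, reference$affine), smoothing_fwhm_mm)
}

#' Compute the transmit-field map from an AFI acquisition
#'
#' Convenience wrapper: [afi_flip_angle()] then [to_percent_nominal()].
#'
#' @param S1,S2 AFI volume pair.
#' @param nominal_deg nominal AFI angle, degrees.
#' @param TR1_ms,TR2_ms TR pair, ms.
#' @param noise_sigma see [afi_flip_angle()].
#' @return transmit-field `vol3d` in percent of nominal.
#' @export
compute_b1_map <- function(S1, S2, nominal_deg = 60, TR1_ms = 50,
                           TR2_ms = 150, noise_sigma = 0) {
  to_percent_nominal(afi_flip_angle(S1, S2, TR1_ms, TR2_ms, noise_sigma),
                     nominal_deg)
}
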