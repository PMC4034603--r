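# Interpolation kernels and pull-resampling under rigid transforms.
# All voxel indices are 0-based; sampling outside the field of view yields 0.

SINC_RADIUS <- 3L # 7-voxel support per axis

pad_array <- function(arr, p) {
  if (p == 0L) return(list(a = arr, p = 0L, d = dim(arr)))
  d <- dim(arr)
  a <- array(0, d + 2L * p)
  a[(p + 1):(p + d[1]), (p + 1):(p + d[2]), (p + 1):(p + d[3])] <- arr
  list(a = a, p = p, d = d)
}

interp_pad <- function(method) {
  switch(method, nearest = 1L, linear = 1L, sinc = SINC_RADIUS + 1L,
         stop(sprintf("unknown interpolation method '%s'", method)))
}

hann_sinc <- function(d, radius = SINC_RADIUS + 0.5) {
  w <- ifelse(abs(d) < radius,
              ifelse(abs(d) < 1e-12, 1,
                     sin(pi * d) / (pi * d)) * 0.5 * (1 + cos(pi * d / radius)),
              0)
  w
}

# Sample a padded array at continuous 0-based indices (si, sj, sk).
# The kernels live in src/interp.cpp; per-axis sinc weights are normalised
# so a constant image is reproduced exactly.
interp_points <- function(pp, si, sj, sk, method) {
  code <- switch(method, nearest = 0L, linear = 1L, sinc = 2L,
                 stop(sprintf("unknown interpolation method '%s'", method)))
  cpp_interp_points(pp$a, as.integer(pp$d), as.integer(pp$p),
                    as.numeric(si), as.numeric(sj), as.numeric(sk), code)
}

grid_points <- function(d) {
  i <- rep.int(0:(d[1] - 1), d[2] * d[3])
  j <- rep.int(rep(0:(d[2] - 1), each = d[1]), d[3])
  k <- rep(0:(d[3] - 1), each = d[1] * d[2])
  cbind(i, j, k)
}

# voxel-index mapping for pull-resampling: output index -> source index
index_map <- function(affine_out, affine_in, M) {
  solve(affine_in) %*% M %*% affine_out
}

apply_index_map <- function(Q, pts) {
  # pts: n x 3 (0-based); returns list(si, sj, sk)
  si <- Q[1, 1] * pts[, 1] + Q[1, 2] * pts[, 2] + Q[1, 3] * pts[, 3] + Q[1, 4]
  sj <- Q[2, 1] * pts[, 1] + Q[2, 2] * pts[, 2] + Q[2, 3] * pts[, 3] + Q[2, 4]
  sk <- Q[3, 1] * pts[, 1] + Q[3, 2] * pts[, 2] + Q[3, 3] * pts[, 3] + Q[3, 4]
  list(si = si, sj = sj, sk = sk)
}

#' Resample a volume under a rigid transform
#'
#' Pull-resampling: the output voxel at world position `x` takes the value of
#' the input volume at `T(x)`, where `T` is the rigid map (rotation about the
#' volume centre, then translation). Voxels mapping outside the field of view
#' are set to 0. The windowed-sinc kernel is a Hann-windowed sinc with
#' 7-voxel support per axis.
#'
#' @param v a `vol3d`.
#' @param t a [rigid_transform()].
#' @param interp one of `"sinc"`, `"linear"`, `"nearest"`.
#' @return a `vol3d` on the same grid as `v`.
#' @export
resample <- function(v, t, interp = c("sinc", "linear", "nearest")) {
  interp <- match.arg(interp)
  M <- rigid_matrix(t, volume_centre(v))
  if (max(abs(M - diag(4))) < 1e-12 && interp != "nearest")
    return(v) # identity short-circuit (still exact for nearest below)
  Q <- index_map(v$affine, v$affine, M)
  pts <- grid_points(dim(v$data))
  s <- apply_index_map(Q, pts)
  pp <- pad_array(v$data, interp_pad(interp))
  out <- interp_points(pp, s$si, s$sj, s$sk, interp)
  vol3d(array(out, dim(v$data)), v$affine)
}

#' Apply simulated inter-scan motion to an echo series
#'
#' Every echo volume is resampled under the transform; the voxel-to-world
#' transform is left unchanged so the motion is baked into the intensities,
#' as with real inter-scan motion.
#'
#' @param series an `echo_series`.
#' @param t a [rigid_transform()].
#' @param interp interpolation kernel, see [resample()].
#' @return the moved `echo_series`.
#' @export
apply_motion <- function(series, t, interp = "sinc") {
  out <- series
  for (e in seq_len(n_echoes(series)))
    out$data[, , , e] <- resample(echo_volume(series, e), t, interp)$data
  out
}

#' Apply a registration transform to individual echoes
#'
#' Used to carry the final (step-4) PDw transform onto the individual PDw
#' echoes before R2* fitting, so that exactly one interpolation pass touches
#' any echo used for quantitative fitting.
#'
#' @param series an `echo_series`.
#' @param t the composed [rigid_transform()] from the registration pipeline.
#' @param interp interpolation kernel (default windowed sinc).
#' @return the resampled `echo_series` (acquisition metadata untouched).
#' @export
apply_to_echoes <- function(series, t, interp = "sinc") {
  apply_motion(series, t, interp)
}
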