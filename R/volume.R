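#' 3-D scalar volume bound to a voxel-to-world transform
#'
#' A `vol3d` is the package's basic spatial container: a 3-D numeric array
#' plus a 4x4 affine mapping *0-based* voxel indices (i, j, k) to world
#' coordinates in mm (right-anterior-superior axes).
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to identity spacing
#'   with the world origin at the volume centre.
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(data, affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("vol3d: 'data' must be a 3-D array")
  if (is.null(affine)) affine <- centred_affine(dim(data), c(1, 1, 1))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("vol3d: 'affine' must be a 4x4 matrix")
  structure(list(data = data, affine = affine), class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  vd <- voxel_size(x$affine)
  cat(sprintf("vol3d: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], vd[1], vd[2], vd[3]))
  invisible(x)
}

#' Voxel-to-world affine with the world origin at the grid centre
#'
#' @param dim integer length-3 grid shape.
#' @param voxel numeric length-3 voxel size in mm.
#' @return 4x4 affine matrix (0-based voxel indices to mm).
#' @export
centred_affine <- function(dim, voxel) {
  A <- diag(4)
  A[1:3, 1:3] <- diag(voxel, 3)
  A[1:3, 4] <- -voxel * (dim - 1) / 2
  A
}

voxel_size <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' World coordinates of the volume centre
#' @param v a `vol3d` or `echo_series`.
#' @return length-3 numeric, mm.
#' @export
volume_centre <- function(v) {
  d <- if (inherits(v, "echo_series")) dim(v$data)[1:3] else dim(v$data)
  as.numeric(v$affine %*% c((d - 1) / 2, 1))[1:3]
}

#' Acquisition parameters of one FLASH contrast
#'
#' @param contrast one of "PDw", "T1w", "MTw", "AFI".
#' @param TR repetition time, ms.
#' @param alpha nominal excitation flip angle, degrees.
#' @param echo_times echo times, ms, strictly increasing.
#' @param mt_pulse optional list describing the off-resonance MT pulse
#'   (metadata only; e.g. `list(duration_ms = 4, angle_deg = 220,
#'   offset_khz = 2)`).
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(contrast, TR, alpha, echo_times, mt_pulse = NULL) {
  stopifnot(TR > 0, alpha > 0, alpha < 90)
  if (length(echo_times) < 1 || any(diff(echo_times) <= 0))
    stop("acq_params: echo_times must be strictly increasing")
  structure(list(contrast = contrast, TR = TR, alpha = alpha,
                 echo_times = as.numeric(echo_times), mt_pulse = mt_pulse),
            class = "acq_params")
}

#' Multi-echo signal series for one contrast
#'
#' @param data 4-D array (x, y, z, echo).
#' @param acq the matching [acq_params()].
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(data, acq, affine = NULL) {
  if (length(dim(data)) != 4L)
    stop("echo_series: 'data' must be a 4-D array (x, y, z, echo)")
  if (dim(data)[4] != length(acq$echo_times))
    stop("echo_series: 4th dimension must match the number of echo times")
  if (is.null(affine)) affine <- centred_affine(dim(data)[1:3], c(1, 1, 1))
  structure(list(data = data, acq = acq, affine = as.matrix(affine)),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("echo_series [%s]: %d x %d x %d voxels, %d echoes (TE %.2f-%.2f ms), TR %.2f ms, alpha %.1f deg\n",
              x$acq$contrast, d[1], d[2], d[3], d[4],
              min(x$acq$echo_times), max(x$acq$echo_times),
              x$acq$TR, x$acq$alpha))
  invisible(x)
}

n_echoes <- function(series) dim(series$data)[4]

echo_volume <- function(series, e) {
  vol3d(series$data[, , , e, drop = TRUE], series$affine)
}

same_grid <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "echo_series")) dim(a$data)[1:3] else dim(a$data)
  db <- if (inherits(b, "echo_series")) dim(b$data)[1:3] else dim(b$data)
  identical(da, db) && max(abs(a$affine - b$affine)) < tol
}

stop_if_grid_mismatch <- function(a, b, what) {
  if (!same_grid(a, b)) stop(sprintf("%s: volumes are not on the same grid", what))
}

# ---- NIfTI + sidecar IO -----------------------------------------------------

#' Write a volume or echo series as NIfTI-1
#'
#' Volumes are written with the affine stored in the sform (code 2).
#' For an `echo_series`, a JSON sidecar with the acquisition parameters is
#' written next to the image when `sidecar = TRUE`.
#'
#' @param v a `vol3d` or `echo_series`.
#' @param path output path (`.nii` or `.nii.gz`; plain `.nii` recommended for
#'   text-only pipelines).
#' @param sidecar write the JSON sidecar for an `echo_series`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, sidecar = TRUE) {
  img <- RNifti::asNifti(v$data)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path)
  if (inherits(v, "echo_series") && sidecar)
    write_sidecar(v$acq, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a 3-D NIfTI volume
#' @param path NIfTI file path.
#' @return a `vol3d`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- strip_attrs(as.array(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1, drop = TRUE]
  vol3d(arr, unclass(RNifti::xform(img))[1:4, 1:4])
}

strip_attrs <- function(arr) {
  array(as.vector(arr), dim(arr))
}

#' Read a 4-D multi-echo NIfTI volume and its JSON sidecar
#' @param path NIfTI file path; the sidecar is `path` with extension `.json`.
#' @return an `echo_series`.
#' @export
read_echo_series <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- strip_attrs(as.array(img))
  if (length(dim(arr)) == 3L) arr <- array(arr, c(dim(arr), 1L))
  acq <- read_sidecar(sidecar_path(path))
  echo_series(arr, acq, unclass(RNifti::xform(img))[1:4, 1:4])
}

#' Write acquisition parameters as a JSON sidecar
#' @param acq an [acq_params()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(acq, path) {
  obj <- list(Contrast = acq$contrast,
              RepetitionTime_ms = acq$TR,
              FlipAngle_deg = acq$alpha,
              EchoTimes_ms = acq$echo_times,
              MTState = !is.null(acq$mt_pulse))
  if (!is.null(acq$mt_pulse)) obj$MTPulse <- acq$mt_pulse
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and validate a JSON sidecar
#'
#' @param path JSON sidecar path.
#' @return an [acq_params()].
#' @export
read_sidecar <- function(path) {
  if (!file.exists(path)) stop(sprintf("sidecar not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("RepetitionTime_ms", "FlipAngle_deg", "EchoTimes_ms", "MTState"))
    if (is.null(obj[[key]]))
      stop(sprintf("sidecar %s: missing required key '%s'", path, key))
  acq_params(contrast = if (is.null(obj$Contrast)) "unknown" else obj$Contrast,
             TR = obj$RepetitionTime_ms, alpha = obj$FlipAngle_deg,
             echo_times = obj$EchoTimes_ms,
             mt_pulse = if (isTRUE(obj$MTState)) {
               if (is.null(obj$MTPulse)) list() else obj$MTPulse
             } else NULL)
}
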