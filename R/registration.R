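# Intra-subject rigid co-registration: 6 degrees of freedom, normalised
# mutual information cost, multi-resolution derivative-free search, final
# resampling with a Hann-windowed sinc kernel.

#' Average echoes of a multi-echo series
#'
#' @param series an `echo_series`.
#' @param subset `"all"`, `"first_k"`, `"odd"` or `"even"` (1-based echo
#'   positions; `"odd"` selects echoes 1, 3, 5, ...).
#' @param k number of echoes when `subset = "first_k"`.
#' @return a `vol3d`, the voxelwise arithmetic mean over the selected echoes.
#' @export
average_echoes <- function(series, subset = c("all", "first_k", "odd", "even"),
                           k = NULL) {
  subset <- match.arg(subset)
  idx <- echo_subset_indices(n_echoes(series), subset, k)
  if (length(idx) == 0) stop("average_echoes: empty echo subset")
  m <- series$data[, , , idx[1], drop = TRUE]
  if (length(idx) > 1)
    for (e in idx[-1]) m <- m + series$data[, , , e, drop = TRUE]
  vol3d(m / length(idx), series$affine)
}

echo_subset_indices <- function(n, subset, k = NULL) {
  switch(subset,
         all = seq_len(n),
         first_k = seq_len(min(if (is.null(k)) n else k, n)),
         odd = seq(1, n, by = 2),
         even = if (n >= 2) seq(2, n, by = 2) else integer(0),
         stop(sprintf("unknown echo subset '%s'", subset)))
}

#' Invert image contrast
#'
#' Robust maximum (99.9th percentile) minus intensity, clipped below at 0,
#' so that CSF becomes brighter than cord tissue in a T1-weighted image.
#'
#' @param v a `vol3d`.
#' @return the inverted `vol3d`.
#' @export
invert_contrast <- function(v) {
  p <- stats::quantile(v$data, 0.999, names = FALSE)
  if (max(v$data) - min(v$data) < .Machine$double.eps * max(abs(v$data), 1)) {
    warning("invert_contrast: constant image, returning zeros")
    return(vol3d(array(0, dim(v$data)), v$affine))
  }
  vol3d(pmax(p - v$data, 0), v$affine)
}

robust_range <- function(x, lo = 0.005, hi = 0.995) {
  q <- stats::quantile(x, c(lo, hi), names = FALSE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1
  q
}

bin_index <- function(x, rng, bins) {
  b <- floor((x - rng[1]) / (rng[2] - rng[1]) * bins)
  pmin(pmax(b, 0), bins - 1L)
}

nmi_from_counts <- function(joint) {
  pj <- joint / sum(joint)
  pa <- rowSums(pj); pb <- colSums(pj)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  Hab <- ent(pj)
  if (Hab <= 0) return(1)
  (ent(pa) + ent(pb)) / Hab
}

nmi_vec <- function(ia, ib, bins) {
  joint <- tabulate(ia * bins + ib + 1L, nbins = bins * bins)
  nmi_from_counts(matrix(joint, bins, bins, byrow = TRUE))
}

#' Normalised mutual information of two volumes
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` from a joint histogram with `bins`
#' equal-width bins over each image's robust (0.5-99.5 percentile) range.
#' Ranges between 1 (independence) and 2 (identical images).
#'
#' @param a,b `vol3d` volumes on the same grid.
#' @param bins number of histogram bins per image.
#' @return scalar NMI (>= 1).
#' @export
nmi <- function(a, b, bins = 64) {
  stop_if_grid_mismatch(a, b, "nmi")
  ra <- robust_range(a$data); rb <- robust_range(b$data)
  if (diff(range(a$data)) == 0 || diff(range(b$data)) == 0) {
    warning("nmi: constant image; NMI defined as 1")
    return(1)
  }
  nmi_vec(bin_index(as.vector(a$data), ra, bins),
          bin_index(as.vector(b$data), rb, bins), bins)
}

# sample-point selection: voxels inside a padded bounding box of the
# above-threshold region of the fixed image (the cord slab), optionally
# strided for the coarse pyramid level.
sample_points <- function(fixed, pad_mm = 12, stride = 1L) {
  d <- dim(fixed$data)
  th <- 0.1 * stats::quantile(fixed$data, 0.999, names = FALSE)
  idx <- which(fixed$data > th, arr.ind = TRUE)
  if (nrow(idx) == 0) idx <- which(fixed$data >= 0, arr.ind = TRUE)
  vd <- voxel_size(fixed$affine)
  pad <- ceiling(pad_mm / vd)
  lo <- pmax(apply(idx, 2, min) - 1 - pad, 0)
  hi <- pmin(apply(idx, 2, max) - 1 + pad, d - 1)
  i <- seq(lo[1], hi[1], by = stride)
  j <- seq(lo[2], hi[2], by = stride)
  k <- seq(lo[3], hi[3], by = max(1L, as.integer(stride / max(1, vd[3] / vd[1]))))
  pts <- as.matrix(expand.grid(i = i, j = j, k = k))
  storage.mode(pts) <- "double"
  pts
}

#' Rigid registration by normalised mutual information
#'
#' Finds the 6-parameter rigid transform `t` maximising the NMI between
#' `fixed` and `resample(moving, t)`. Derivative-free Nelder-Mead search
#' over (tx, ty, tz, rx, ry, rz) with a two-level multi-resolution scheme
#' (strided samples, then full resolution within a padded cord bounding
#' box); trilinear interpolation during the search. Search is intended for
#' misalignments within about +/-10 mm and +/-10 degrees.
#'
#' @param moving,fixed `vol3d` volumes with overlapping fields of view.
#' @param bins histogram bins for the NMI cost.
#' @param init optional initial [rigid_transform()].
#' @param maxit iteration budget per optimisation stage.
#' @return a [rigid_transform()]; attribute `nmi` holds the attained cost and
#'   `converged` the optimiser status.
#' @export
register_rigid <- function(moving, fixed, bins = 64, init = NULL,
                           maxit = 400) {
  centre <- volume_centre(fixed)
  rb <- robust_range(moving$data)
  Ainv_mov <- solve(moving$affine)

  # cost: negative NMI over the field-of-view overlap, plus a small penalty
  # on lost overlap. Restricting the histogram to the overlap prevents the
  # out-of-view zero cluster from spuriously sharpening the joint histogram;
  # the penalty breaks the resulting plateau for anatomy that is (nearly)
  # uniform along an axis, preferring the maximum-overlap alignment.
  dm <- dim(moving$data)
  overlap_weight <- 0.2
  make_cost <- function(pts, interp) {
    pp <- pad_array(moving$data, interp_pad(interp))
    fvals <- fixed$data[pts + 1]
    dim(fvals) <- NULL
    fb <- bin_index(fvals, robust_range(fvals), bins)
    function(par) {
      t <- rigid_transform(par[1], par[2], par[3], par[4], par[5], par[6])
      Q <- Ainv_mov %*% rigid_matrix(t, centre) %*% fixed$affine
      s <- apply_index_map(Q, pts)
      keep <- s$si > -0.5 & s$si < dm[1] - 0.5 &
              s$sj > -0.5 & s$sj < dm[2] - 0.5 &
              s$sk > -0.5 & s$sk < dm[3] - 0.5
      if (sum(keep) < 100) return(0) # essentially no overlap
      mv <- interp_points(pp, s$si[keep], s$sj[keep], s$sk[keep], interp)
      -nmi_vec(fb[keep], bin_index(mv, rb, bins), bins) +
        overlap_weight * (1 - mean(keep))
    }
  }

  cost_coarse <- make_cost(sample_points(fixed, stride = 2L), "linear")
  par1 <- if (is.null(init)) rep(0, 6) else unname(init$params)
  if (is.null(init)) {
    # exhaustive coarse sweep over translations: NMI has local maxima at
    # grid-aligned shifts, so a derivative-free descent from the identity
    # alone is not reliable (rotations are handled by the sweeps below)
    grid <- as.matrix(expand.grid(tx = seq(-9, 9, by = 3),
                                  ty = seq(-9, 9, by = 3),
                                  tz = seq(-9, 9, by = 3)))
    vals <- apply(grid, 1, function(g) cost_coarse(c(g, 0, 0, 0)))
    par1 <- c(grid[which.min(vals), ], 0, 0, 0)
  }
  o1 <- stats::optim(par1, cost_coarse, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-9,
                                    parscale = rep(2, 6)))
  # full-resolution refinement on the structured (above-threshold) voxels
  th <- 0.05 * stats::quantile(fixed$data, 0.999, names = FALSE)
  pts_struct <- which(fixed$data > th, arr.ind = TRUE) - 1
  storage.mode(pts_struct) <- "double"
  if (nrow(pts_struct) < 100) pts_struct <- sample_points(fixed, stride = 1L)
  o2 <- stats::optim(o1$par, make_cost(pts_struct, "linear"),
                     method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-10))
  # windowed-sinc-interpolated cost: trilinear blurring flattens the NMI
  # basin for rotations about the near-cylindrical cord axis, sinc restores it
  cost_sinc <- make_cost(pts_struct, "sinc")
  par <- o2$par; val <- cost_sinc(par)
  # 1-D sweeps over the whole +/-10 mm/degree search range for the weakly
  # constrained parameters (slice-axis translation and all rotations): the
  # linear stages do not pin these down reliably on near-cylindrical anatomy
  sweep1d <- function(par, val, ax, rng) {
    for (r in rng) {
      p <- par; p[ax] <- r
      v <- cost_sinc(p)
      if (v < val) { par <- p; val <- v }
    }
    list(par = par, val = val)
  }
  for (ax in 3:6) {
    s <- sweep1d(par, val, ax, seq(-10, 10, by = 0.75))
    par <- s$par; val <- s$val
  }
  for (ax in 3:6) { # refine around the captured basin
    s <- sweep1d(par, val, ax, seq(par[ax] - 1, par[ax] + 1, by = 0.2))
    par <- s$par; val <- s$val
  }
  o3 <- stats::optim(par, cost_sinc, method = "Nelder-Mead",
                     control = list(maxit = min(maxit, 250), reltol = 1e-10,
                                    parscale = rep(0.5, 6)))
  best <- if (o3$value < val) o3 else list(par = par, value = val,
                                           convergence = 0L)
  t <- rigid_transform(best$par[1], best$par[2], best$par[3],
                       best$par[4], best$par[5], best$par[6])
  attr(t, "nmi") <- -best$value
  attr(t, "converged") <- best$convergence == 0
  if (best$convergence != 0)
    message("register_rigid: iteration budget reached; returning best transform found")
  t
}

robust_box_mean <- function(v) {
  th <- 0.1 * stats::quantile(v$data, 0.999, names = FALSE)
  idx <- which(v$data > th, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("build_target: image has no above-threshold voxels")
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  m <- mean(v$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
  if (m <= 0) stop("build_target: non-positive robust mean")
  m
}

#' Build the mid-pipeline registration target
#'
#' Each input is divided by its robust mean (mean over the cord bounding
#' box), then the three are averaged voxelwise.
#'
#' @param reg_pd registered averaged PDw volume.
#' @param reg_t1_inv registered, contrast-inverted averaged T1w volume.
#' @param ave_mt averaged MTw volume.
#' @return the target `vol3d`.
#' @export
build_target <- function(reg_pd, reg_t1_inv, ave_mt) {
  stop_if_grid_mismatch(reg_pd, ave_mt, "build_target")
  stop_if_grid_mismatch(reg_t1_inv, ave_mt, "build_target")
  vol3d((reg_pd$data / robust_box_mean(reg_pd) +
         reg_t1_inv$data / robust_box_mean(reg_t1_inv) +
         ave_mt$data / robust_box_mean(ave_mt)) / 3, ave_mt$affine)
}

#' Four-step intra-subject registration pipeline
#'
#' Step 1: register the averaged PDw and T1w volumes to the averaged MTw
#' volume. Step 2: invert the contrast of the registered T1w. Step 3: build
#' a new registration target as the normalised average of registered PDw,
#' inverted registered T1w and averaged MTw. Step 4: register the three
#' *original* averaged volumes to that target. The step-4 transforms are the
#' pipeline output, so only one interpolation is ever applied to data used
#' quantitatively.
#'
#' @param pd,t1,mt `echo_series` of the three contrasts.
#' @param bins NMI histogram bins.
#' @param reregister_mtw also re-register the averaged MTw to the target in
#'   step 4 (default `TRUE`); when `FALSE` the MTw transform is the identity.
#' @param maxit optimiser budget per stage, see [register_rigid()].
#' @return list with `transforms` (per-contrast step-4 [rigid_transform()]s),
#'   `volumes` (registered averaged volumes, sinc-resampled) and `target`.
#' @export
run_registration_pipeline <- function(pd, t1, mt, bins = 64,
                                      reregister_mtw = TRUE, maxit = 400) {
  ave_pd <- average_echoes(pd, "all")
  ave_t1 <- average_echoes(t1, "all")
  ave_mt <- average_echoes(mt, "all")
  # step 1
  t_pd1 <- register_rigid(ave_pd, ave_mt, bins = bins, maxit = maxit)
  t_t11 <- register_rigid(ave_t1, ave_mt, bins = bins, maxit = maxit)
  reg_pd1 <- resample(ave_pd, t_pd1, "sinc")
  reg_t11 <- resample(ave_t1, t_t11, "sinc")
  # steps 2-3
  target <- build_target(reg_pd1, invert_contrast(reg_t11), ave_mt)
  # step 4: original averaged images to the target (warm-started from step 1)
  t_pd <- register_rigid(ave_pd, target, bins = bins, init = t_pd1,
                         maxit = maxit)
  t_t1 <- register_rigid(ave_t1, target, bins = bins, init = t_t11,
                         maxit = maxit)
  t_mt <- if (reregister_mtw)
    register_rigid(ave_mt, target, bins = bins, maxit = maxit)
  else rigid_transform()
  list(transforms = list(pd = t_pd, t1 = t_t1, mt = t_mt),
       volumes = list(pd = resample(ave_pd, t_pd, "sinc"),
                      t1 = resample(ave_t1, t_t1, "sinc"),
                      mt = resample(ave_mt, t_mt, "sinc")),
       target = target)
}
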