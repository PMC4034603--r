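# Voxelwise estimation of the quantitative maps: log-linear R2* fit,
# rational-approximation inversion for T1/APD, MT saturation from the
# MT-FLASH signal equation, and MTR.

#' Log-linear R2* fit across echoes
#'
#' Ordinary least squares of `log(S)` against TE per voxel; the negated
#' slope is R2* (reported in 1/s) and the intercept gives the extrapolated
#' TE = 0 intensity. Voxels with any non-positive signal among the used
#' echoes, or fewer than two usable echoes, are masked (`NA`), not errors.
#'
#' @param series an `echo_series` (the multi-echo PDw acquisition).
#' @param subset echo subset passed to [echo_subset_indices()]
#'   (`"all"`, `"odd"`, `"even"`).
#' @return list of two `vol3d` maps: `R2star` (1/s) and `S0` (a.u.).
#' @export
fit_r2star <- function(series, subset = "all") {
  idx <- echo_subset_indices(n_echoes(series), subset)
  if (length(idx) < 2) stop("fit_r2star: need at least two echoes")
  te <- series$acq$echo_times[idx]
  d <- dim(series$data)[1:3]
  nvox <- prod(d)
  S <- matrix(series$data[, , , idx], nvox, length(idx))
  ok <- rowSums(S <= 0) == 0
  slope <- intercept <- rep(NA_real_, nvox)
  if (any(ok)) {
    L <- log(S[ok, , drop = FALSE])
    tc <- te - mean(te)
    slope[ok] <- as.vector(L %*% tc) / sum(tc^2)
    intercept[ok] <- rowMeans(L) - slope[ok] * mean(te)
  }
  list(R2star = vol3d(array(-slope * 1000, d), series$affine), # 1/ms -> 1/s
       S0 = vol3d(array(exp(intercept), d), series$affine))
}

#' T1 and apparent proton density from the dual-angle FLASH pair
#'
#' Inverts the rational approximation of the spoiled FLASH signal for the
#' co-registered PDw/T1w averaged volumes:
#' \deqn{R_1 = \tfrac12\,\frac{S_{T1}\alpha_{T1}/TR_{T1} - S_{PD}\alpha_{PD}/TR_{PD}}
#'   {S_{PD}/\alpha_{PD} - S_{T1}/\alpha_{T1}}}
#' \deqn{A = S_{PD} S_{T1}\,\frac{TR_{PD}\alpha_{T1}/\alpha_{PD} - TR_{T1}\alpha_{PD}/\alpha_{T1}}
#'   {S_{T1} TR_{PD}\alpha_{T1} - S_{PD} TR_{T1}\alpha_{PD}}}
#' When a transmit-field map is supplied, per-voxel effective angles
#' `f_T * alpha_nominal` are used for both contrasts (B1 correction).
#' Non-physical voxels (non-positive signals, denominators or R1) are
#' masked. T1 is clipped to (0, 10000] ms.
#'
#' @param S_pd,S_t1 averaged PDw and T1w `vol3d` volumes (co-registered).
#' @param acq_pd,acq_t1 the matching [acq_params()].
#' @param b1 optional transmit-field `vol3d` in percent of nominal.
#' @return list of `vol3d` maps: `T1` (ms), `A` (a.u.), `R1` (1/s).
#' @export
estimate_t1_apd <- function(S_pd, S_t1, acq_pd, acq_t1, b1 = NULL) {
  stop_if_grid_mismatch(S_pd, S_t1, "estimate_t1_apd")
  f <- 1
  if (!is.null(b1)) {
    stop_if_grid_mismatch(S_pd, b1, "estimate_t1_apd")
    f <- b1$data / 100
  }
  ap <- f * acq_pd$alpha * pi / 180
  a1 <- f * acq_t1$alpha * pi / 180
  sp <- S_pd$data; s1 <- S_t1$data
  num_r1 <- s1 * a1 / acq_t1$TR - sp * ap / acq_pd$TR
  den_r1 <- sp / ap - s1 / a1
  R1 <- 0.5 * num_r1 / den_r1 # 1/ms
  A <- sp * s1 * (acq_pd$TR * a1 / ap - acq_t1$TR * ap / a1) /
       (s1 * acq_pd$TR * a1 - sp * acq_t1$TR * ap)
  bad <- !(sp > 0 & s1 > 0) | !(den_r1 > 0) | !(R1 > 0) | !is.finite(R1) |
         !is.finite(A)
  R1[bad] <- NA_real_; A[bad] <- NA_real_
  T1 <- 1 / R1
  T1[T1 > 10000] <- 10000
  list(T1 = vol3d(T1, S_pd$affine), A = vol3d(A, S_pd$affine),
       R1 = vol3d(R1 * 1000, S_pd$affine)) # 1/s
}

#' MT saturation from the MT-FLASH signal equation
#'
#' Inserts the estimated amplitude and R1 into the approximate MT-FLASH
#' signal equation and solves for the per-pulse saturation:
#' \deqn{\delta = (A\,\alpha_{MT}/S_{MT} - 1)\,TR_{MT} R_1 - \alpha_{MT}^2/2}
#' The *nominal* (uncorrected) excitation angle is used: transmit/receive
#' field inhomogeneities are intrinsically compensated in this parameter.
#'
#' @param S_mt averaged MTw `vol3d` (co-registered).
#' @param A amplitude map from [estimate_t1_apd()].
#' @param R1 R1 map (1/s) from [estimate_t1_apd()].
#' @param acq_mt the MTw [acq_params()].
#' @return `vol3d` MT saturation map in percent units (100 * delta).
#' @export
compute_mtsat <- function(S_mt, A, R1, acq_mt) {
  stop_if_grid_mismatch(S_mt, A, "compute_mtsat")
  stop_if_grid_mismatch(S_mt, R1, "compute_mtsat")
  am <- acq_mt$alpha * pi / 180
  r1_ms <- R1$data / 1000
  delta <- (A$data * am / S_mt$data - 1) * acq_mt$TR * r1_ms - am^2 / 2
  delta[!(S_mt$data > 0) | !(A$data > 0)] <- NA_real_
  vol3d(100 * delta, S_mt$affine)
}

#' Magnetisation transfer ratio
#'
#' `MTR = 100 (S_ref - S_MT) / S_ref` in percent units, where the reference
#' is the averaged PDw volume (no MT pulse) co-registered with the averaged
#' MTw volume.
#'
#' @param S_ref reference (PDw) `vol3d`.
#' @param S_mt MT-weighted `vol3d`.
#' @return `vol3d` MTR map (p.u.); non-positive reference voxels masked.
#' @export
compute_mtr <- function(S_ref, S_mt) {
  stop_if_grid_mismatch(S_ref, S_mt, "compute_mtr")
  mtr <- 100 * (S_ref$data - S_mt$data) / S_ref$data
  mtr[!(S_ref$data > 0)] <- NA_real_
  vol3d(mtr, S_ref$affine)
}

#' Estimate the full set of parameter maps
#'
#' Orchestrates the voxelwise estimation on a co-registered dataset:
#' R2* from the multi-echo PDw data, echo-matched averaging (the PDw/T1w/MTw
#' averages use the same echo positions, the first five by default, so their
#' effective TE matches), optional compensation of the averaged volumes to
#' TE = 0 using the fitted R2* map, then T1/APD, MT saturation and MTR.
#'
#' @param data list with registered `echo_series` `pd`, `t1`, `mt`.
#' @param b1 optional transmit-field `vol3d` (percent of nominal) for
#'   flip-angle correction of T1 and APD.
#' @param echo_subset `"all"`, `"odd"` or `"even"`; applied identically to
#'   every contrast (within the echo-matched set for the averages, and to
#'   the full PDw echo train for the R2* fit).
#' @param t2star_compensation divide each echo-matched average by its mean
#'   `exp(-R2* TE)` decay factor so amplitudes refer to TE = 0
#'   (default `TRUE`).
#' @param b1_correct_apd apply the B1 correction to APD as well as T1
#'   (default `TRUE`; correction happens jointly through the effective
#'   angles).
#' @return an object of class `parameter_maps`: list of `vol3d` maps
#'   `APD`, `T1`, `R1`, `MTsat`, `MTR`, `R2star` plus the `subset` tag.
#' @export
estimate_all <- function(data, b1 = NULL, echo_subset = c("all", "odd", "even"),
                         t2star_compensation = TRUE, b1_correct_apd = TRUE) {
  echo_subset <- match.arg(echo_subset)
  for (cn in c("pd", "t1", "mt"))
    if (is.null(data[[cn]])) stop(sprintf("estimate_all: missing contrast '%s'", cn))
  r2 <- fit_r2star(data$pd, subset = echo_subset)
  n_match <- min(vapply(data[c("pd", "t1", "mt")], n_echoes, integer(1)))
  idx <- echo_subset_indices(n_match, echo_subset)
  averaged <- list()
  for (cn in c("pd", "t1", "mt")) {
    s <- data[[cn]]
    m <- s$data[, , , idx[1], drop = TRUE]
    if (length(idx) > 1) for (e in idx[-1]) m <- m + s$data[, , , e, drop = TRUE]
    m <- m / length(idx)
    if (t2star_compensation) {
      te <- s$acq$echo_times[idx]
      r2_ms <- r2$R2star$data / 1000
      k <- array(0, dim(m))
      for (t in te) k <- k + exp(-r2_ms * t)
      m <- m / (k / length(te))
    }
    averaged[[cn]] <- vol3d(m, s$affine)
  }
  b1_t1 <- b1
  fit <- estimate_t1_apd(averaged$pd, averaged$t1,
                         data$pd$acq, data$t1$acq, b1 = b1_t1)
  if (!is.null(b1) && !b1_correct_apd) {
    # amplitude from nominal angles, T1/R1 from corrected angles
    fit_nom <- estimate_t1_apd(averaged$pd, averaged$t1,
                               data$pd$acq, data$t1$acq, b1 = NULL)
    fit$A <- fit_nom$A
  }
  mtsat <- compute_mtsat(averaged$mt, fit$A, fit$R1, data$mt$acq)
  mtr <- compute_mtr(averaged$pd, averaged$mt)
  structure(list(APD = fit$A, T1 = fit$T1, R1 = fit$R1, MTsat = mtsat,
                 MTR = mtr, R2star = r2$R2star, subset = echo_subset),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("parameter_maps (echo subset: %s)\n", x$subset))
  for (p in c("APD", "T1", "MTsat", "MTR", "R2star")) {
    v <- x[[p]]$data
    cat(sprintf("  %-7s median %.4g (%d valid voxels)\n", p,
                stats::median(v, na.rm = TRUE), sum(!is.na(v))))
  }
  invisible(x)
}
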