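# Digital cervical-cord phantom: concentric CSF annulus / white-matter disc
# split into dorsal and lateral columns / central grey-matter butterfly, with
# known ground-truth parameter maps, inter-scan motion, a smooth transmit
# field and Rician noise.

CORD_LABELS <- c(background = 0L, CSF = 1L, GM = 2L, dorsal_WM = 3L,
                 left_lateral_WM = 4L, right_lateral_WM = 5L)

#' Default tissue parameter table
#'
#' Amplitudes `A` (a.u.), `T1` (ms), MT saturation per pulse `delta`
#' (fractional, p.u./100) and `R2star` (1/s) for the six phantom labels.
#' White-matter column and grey-matter values follow published healthy
#' cervical-cord tissue means; CSF values are literature-plausible defaults.
#'
#' @return data.frame with one row per tissue label.
#' @export
default_tissues <- function() {
  data.frame(
    label  = c("background", "CSF", "GM", "dorsal_WM",
               "left_lateral_WM", "right_lateral_WM"),
    A      = c(0, 8000, 5160, 4668, 4408, 4792),
    T1     = c(0, 4300, 1815, 1735, 1593, 1707),
    delta  = c(0, 0.001, 0.0118, 0.0143, 0.0147, 0.0143),
    R2star = c(0, 2, 18.9, 22.3, 21.2, 20.5),
    stringsAsFactors = FALSE
  )
}

#' Default acquisition parameters of the three FLASH contrasts and AFI
#'
#' PDw: TR 24.05 ms, alpha 6 deg, six echoes equally spaced over TE
#' 3.0-18.55 ms. T1w: TR 22 ms, alpha 20 deg, five echoes. MTw: five echoes
#' with a 4-ms Gaussian MT pulse (nominal 220 deg, 2 kHz off-resonance);
#' its readout TR/alpha default to the PDw values. AFI: alpha 60 deg,
#' TR pair 50/150 ms.
#'
#' @return named list of [acq_params()] (`pd`, `t1`, `mt`) plus `afi` settings.
#' @export
default_acquisition <- function() {
  te6 <- seq(3.0, 18.55, length.out = 6)
  list(
    pd = acq_params("PDw", TR = 24.05, alpha = 6, echo_times = te6),
    t1 = acq_params("T1w", TR = 22, alpha = 20, echo_times = te6[1:5]),
    mt = acq_params("MTw", TR = 24.05, alpha = 6, echo_times = te6[1:5],
                    mt_pulse = list(duration_ms = 4, angle_deg = 220,
                                    offset_khz = 2)),
    afi = list(nominal_deg = 60, TR1_ms = 50, TR2_ms = 150, TE_ms = 3.05)
  )
}

#' Specification of a synthetic cervical-cord subject
#'
#' @param dim grid shape (voxels).
#' @param voxel voxel size, mm.
#' @param cord_radius left-right semi-axis of the cord cross-section, mm.
#'   Cervical cords are elliptical: wider left-right than
#'   anterior-posterior (`cord_aspect` is the AP/LR ratio).
#' @param csf_radius left-right semi-axis of the CSF (subarachnoid) outer
#'   boundary, mm; must exceed `cord_radius`.
#' @param cord_aspect,csf_aspect anterior-posterior to left-right aspect
#'   ratios of the two ellipses.
#' @param z_profile along-slab anatomy: `cord_bulge` is the fractional cord
#'   radius increase at the cervical enlargement (smooth, peaking
#'   mid-slab), `csf_scallop` the fractional modulation of the CSF-space
#'   outer boundary with period `scallop_period_mm` (the scalloping of the
#'   subarachnoid space at vertebral levels). Both give the slab the
#'   through-slice structure that real acquisitions have.
#' @param render acquisition rendering model: in-plane `supersample` factor
#'   and Gaussian point-spread-function FWHM (mm). Labels are rendered at
#'   the supersampled resolution, blurred with the PSF and box-downsampled,
#'   so simulated images are band-limited with partial-volume edges as in a
#'   k-space-truncated acquisition. `supersample = 1` with `psf_fwhm_mm = 0`
#'   gives hard-edged voxels.
#' @param gm geometry of the grey-matter butterfly: lobe centre offset from
#'   the midline (mm), lobe semi-axes (mm), posterior shift (mm) and the
#'   half-width/half-height of the central commissure bridge (mm).
#' @param dorsal_halfwidth_deg angular half-width of the dorsal column sector
#'   about the posterior axis, degrees; the remaining white matter is split
#'   into left and right lateral columns by the midline.
#' @param acquisition per-contrast [acq_params()] (see
#'   [default_acquisition()]).
#' @param tissues tissue table (see [default_tissues()]).
#' @param motion named list of per-contrast [rigid_transform()]s simulating
#'   inter-scan motion (`pd`, `t1`, `mt`, `afi`).
#' @param b1 transmit-field model: mean (percent of nominal), in-plane
#'   gradient (percent per mm along x) and bounds (percent).
#' @param noise noise model: `"none"`, `"gaussian"` or `"rician"`, and the
#'   SNR (mean white-matter first-echo signal divided by sigma).
#' @param cohort_cv per-parameter inter-subject coefficients of variation
#'   (fractional) used by [generate_cohort()].
#' @param signal_mode `"approx"` (rational approximation, the model the
#'   estimator inverts) or `"exact"` (full spoiled steady state).
#' @param seed random seed making the phantom reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64, 64, 30), voxel = c(1, 1, 3),
                         cord_radius = 6.5, csf_radius = 9.5,
                         cord_aspect = 0.8, csf_aspect = 0.82,
                         z_profile = list(cord_bulge = 0.06,
                                          csf_scallop = 0.08,
                                          scallop_period_mm = 18),
                         render = list(supersample = 4L, psf_fwhm_mm = 0.8),
                         gm = list(lobe_offset = 2.0, lobe_ax = 1.8,
                                   lobe_ay = 2.3, shift = 0,
                                   bridge_halfwidth = 1.0,
                                   bridge_halfheight = 1.5),
                         dorsal_halfwidth_deg = 60,
                         acquisition = default_acquisition(),
                         tissues = default_tissues(),
                         motion = list(),
                         b1 = list(mean = 100, gradient = 0,
                                   bounds = c(70, 130)),
                         noise = list(model = "none", snr = 50),
                         cohort_cv = c(A = 0.10, T1 = 0.07, delta = 0.08,
                                       R2star = 0.07),
                         signal_mode = "approx",
                         seed = 1L) {
  if (cord_radius <= 0 || csf_radius <= 0)
    stop("phantom_spec: radii must be positive (geometry error)")
  if (csf_radius <= cord_radius)
    stop("phantom_spec: csf_radius must exceed cord_radius (geometry error)")
  if (!is.null(noise$model) && noise$model != "none" &&
      (is.null(noise$snr) || noise$snr <= 0))
    stop("phantom_spec: SNR must be positive when noise is enabled")
  if (csf_radius * csf_aspect <= cord_radius * cord_aspect)
    stop("phantom_spec: CSF ellipse must contain the cord ellipse (geometry error)")
  structure(list(dim = as.integer(dim), voxel = voxel,
                 cord_radius = cord_radius, csf_radius = csf_radius,
                 cord_aspect = cord_aspect, csf_aspect = csf_aspect,
                 z_profile = z_profile, render = render,
                 gm = gm, dorsal_halfwidth_deg = dorsal_halfwidth_deg,
                 acquisition = acquisition, tissues = tissues,
                 motion = motion, b1 = b1, noise = noise,
                 cohort_cv = cohort_cv, signal_mode = signal_mode,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build the phantom label geometry
#'
#' Concentric cross-section replicated along the slice axis: background
#' outside the CSF annulus, a CSF ring, a white-matter disc split by angular
#' sectors into dorsal, left-lateral and right-lateral columns, and a central
#' grey-matter butterfly (two mirrored elliptical lobes joined by a bridge).
#'
#' @param spec a [phantom_spec()].
#' @return a `vol3d` of integer labels (see `cordmpm:::CORD_LABELS`) with a
#'   `label_names` attribute.
#' @export
make_geometry <- function(spec) {
  d <- spec$dim
  sc <- zprofile_scales(spec)
  lab <- array(CORD_LABELS[["background"]], d)
  for (k in seq_len(d[3]))
    lab[, , k] <- render_label_slice(spec, supersample = 1L,
                                     cord_scale = sc$cord[k],
                                     csf_scale = sc$csf[k])
  v <- vol3d(lab, centred_affine(d, spec$voxel))
  attr(v, "label_names") <- CORD_LABELS
  v
}

# per-slice radius scale factors from the along-slab anatomy model
zprofile_scales <- function(spec) {
  nz <- spec$dim[3]
  zp <- spec$z_profile
  if (is.null(zp)) return(list(cord = rep(1, nz), csf = rep(1, nz)))
  z01 <- if (nz > 1) (0:(nz - 1)) / (nz - 1) else 0.5
  z_mm <- (0:(nz - 1)) * spec$voxel[3]
  list(cord = 1 + (zp$cord_bulge %||% 0) * sin(pi * z01),
       csf = 1 + (zp$csf_scallop %||% 0) *
               sin(2 * pi * z_mm / (zp$scallop_period_mm %||% 18)))
}

# one cross-sectional label slice, optionally at supersampled resolution
render_label_slice <- function(spec, supersample = 1L,
                               cord_scale = 1, csf_scale = 1) {
  n1 <- spec$dim[1] * supersample
  n2 <- spec$dim[2] * supersample
  v1 <- spec$voxel[1] / supersample
  v2 <- spec$voxel[2] / supersample
  # supersampled grid shares the world extent of the acquisition grid
  x0 <- -spec$voxel[1] * (spec$dim[1] - 1) / 2 - spec$voxel[1] / 2 + v1 / 2
  y0 <- -spec$voxel[2] * (spec$dim[2] - 1) / 2 - spec$voxel[2] / 2 + v2 / 2
  X <- matrix(x0 + (0:(n1 - 1)) * v1, n1, n2)
  Y <- matrix(y0 + (0:(n2 - 1)) * v2, n1, n2, byrow = TRUE)
  cr <- spec$cord_radius * cord_scale
  sr <- spec$csf_radius * csf_scale
  in_csf <- (X / sr)^2 + (Y / (sr * spec$csf_aspect))^2 <= 1
  in_cord <- (X / cr)^2 + (Y / (cr * spec$cord_aspect))^2 <= 1
  slice <- matrix(CORD_LABELS[["background"]], n1, n2)
  slice[in_csf] <- CORD_LABELS[["CSF"]]
  # white-matter columns: dorsal sector about the posterior (-y) axis,
  # remainder split left/right by the midline
  ang <- abs(atan2(X, -Y)) * 180 / pi # angle from posterior axis
  slice[in_cord & ang <= spec$dorsal_halfwidth_deg] <- CORD_LABELS[["dorsal_WM"]]
  slice[in_cord & ang > spec$dorsal_halfwidth_deg & X < 0] <-
    CORD_LABELS[["left_lateral_WM"]]
  slice[in_cord & ang > spec$dorsal_halfwidth_deg & X >= 0] <-
    CORD_LABELS[["right_lateral_WM"]]
  g <- spec$gm # grey matter scales with the cord
  lobe <- ((abs(X) - g$lobe_offset * cord_scale) / (g$lobe_ax * cord_scale))^2 +
          ((Y - g$shift * cord_scale) / (g$lobe_ay * cord_scale))^2 <= 1
  bridge <- abs(X) <= g$bridge_halfwidth * cord_scale &
            abs(Y - g$shift * cord_scale) <= g$bridge_halfheight * cord_scale
  slice[in_cord & (lobe | bridge)] <- CORD_LABELS[["GM"]]
  slice
}

gauss_filter_1d <- function(m, sigma_px, along_rows = TRUE) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2)); k <- k / sum(k)
  if (!along_rows) m <- t(m)
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) {
    src <- pmin(pmax(seq_len(n) + (i - 1 - r), 1), n)
    out <- out + k[i] * m[src, , drop = FALSE]
  }
  if (!along_rows) out <- t(out)
  out
}

#' Partial-volume tissue fractions of the phantom cross-section
#'
#' Renders the label geometry at the configured in-plane supersampling,
#' applies the acquisition point-spread function (Gaussian) at that
#' resolution and box-downsamples, yielding per-tissue partial-volume
#' fraction maps at acquisition resolution (they sum to 1 per voxel). This
#' is the band-limited image formation that a k-space-truncated acquisition
#' produces; simulated signals are fraction-weighted mixtures of the pure
#' tissue signals.
#'
#' @param spec a [phantom_spec()].
#' @return named list of 3-D fraction arrays, one per tissue label.
#' @export
tissue_fractions <- function(spec) {
  ss <- max(1L, as.integer(spec$render$supersample %||% 1L))
  psf <- spec$render$psf_fwhm_mm %||% 0
  sigma_px <- psf / (2 * sqrt(2 * log(2))) / (spec$voxel[1] / ss)
  d <- spec$dim
  sc <- zprofile_scales(spec)
  frac_slice <- function(cord_scale, csf_scale) {
    hi <- render_label_slice(spec, supersample = ss,
                             cord_scale = cord_scale, csf_scale = csf_scale)
    out <- list()
    for (nm in names(CORD_LABELS)) {
      ind <- (hi == CORD_LABELS[[nm]]) * 1
      ind <- gauss_filter_1d(gauss_filter_1d(ind, sigma_px, TRUE),
                             sigma_px, FALSE)
      lo <- matrix(0, d[1], d[2])
      for (i in seq_len(ss)) for (j in seq_len(ss))
        lo <- lo + ind[seq(i, by = ss, length.out = d[1]),
                       seq(j, by = ss, length.out = d[2])]
      out[[nm]] <- lo / ss^2
    }
    out
  }
  out <- lapply(names(CORD_LABELS), function(nm) array(0, d))
  names(out) <- names(CORD_LABELS)
  uniform <- max(abs(sc$cord - 1), abs(sc$csf - 1)) < 1e-12
  cache <- NULL
  for (k in seq_len(d[3])) {
    if (!uniform || is.null(cache))
      cache <- frac_slice(sc$cord[k], sc$csf[k])
    for (nm in names(CORD_LABELS)) out[[nm]][, , k] <- cache[[nm]]
  }
  out
}

#' Paint ground-truth parameter maps from a label volume
#'
#' @param labels label volume from [make_geometry()].
#' @param tissues tissue table (see [default_tissues()]).
#' @return list of four `vol3d` maps: `A` (a.u.), `T1` (ms), `delta`
#'   (fractional) and `R2star` (1/s), constant within each tissue region.
#' @export
assign_ground_truth <- function(labels, tissues = default_tissues()) {
  lab <- labels$data
  present <- sort(unique(as.vector(lab)))
  known <- CORD_LABELS[tissues$label]
  missing <- setdiff(present, known)
  if (length(missing) > 0)
    stop(sprintf("assign_ground_truth: unknown label(s) in volume: %s",
                 paste(missing, collapse = ", ")))
  out <- list()
  for (p in c("A", "T1", "delta", "R2star")) {
    m <- array(0, dim(lab))
    for (i in seq_len(nrow(tissues)))
      m[lab == CORD_LABELS[[tissues$label[i]]]] <- tissues[[p]][i]
    out[[p]] <- vol3d(m, labels$affine)
  }
  out
}

#' Steady-state spoiled FLASH signal amplitude
#'
#' `mode = "approx"` uses the rational approximation of the spoiled FLASH
#' steady state, extended with the per-pulse MT saturation term `delta`:
#' \deqn{S = A\,\alpha\, \frac{TR \cdot R_1}{\alpha^2/2 + \delta + TR \cdot R_1}}
#' with \eqn{\alpha} in radians and \eqn{R_1 = 1/T_1}. `mode = "exact"`
#' evaluates the full steady state
#' \eqn{S = A \sin\alpha\,(1-\delta)(1-E_1)/(1-(1-\delta)E_1\cos\alpha)}
#' (Ernst equation when `delta = 0`), used as the independent oracle for the
#' approximation.
#'
#' @param A signal amplitude, arbitrary units.
#' @param T1 longitudinal relaxation time, ms (> 0).
#' @param delta MT saturation per pulse, fractional (0 for non-MT contrasts).
#' @param alpha_deg effective excitation flip angle, degrees.
#' @param TR repetition time, ms.
#' @param mode `"approx"` or `"exact"`.
#' @return signal amplitude(s), same units as `A`. Vectorised over inputs.
#' @export
flash_signal <- function(A, T1, delta = 0, alpha_deg, TR,
                         mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  if (any(T1 <= 0)) stop("flash_signal: T1 must be positive")
  a <- alpha_deg * pi / 180
  if (mode == "approx") {
    tr_r1 <- TR / T1
    A * a * tr_r1 / (a^2 / 2 + delta + tr_r1)
  } else {
    E1 <- exp(-TR / T1)
    A * sin(a) * (1 - delta) * (1 - E1) / (1 - (1 - delta) * E1 * cos(a))
  }
}

#' Smooth transmit-field map from the phantom B1 model
#'
#' Affine in-plane ramp `mean + gradient * x`, bounded to the configured
#' percent range.
#'
#' @param spec a [phantom_spec()].
#' @return a `vol3d` of f_T in percent of nominal.
#' @export
make_b1_field <- function(spec) {
  d <- spec$dim
  affine <- centred_affine(d, spec$voxel)
  x <- (0:(d[1] - 1)) * spec$voxel[1] + affine[1, 4]
  f <- spec$b1$mean + spec$b1$gradient * x
  f <- pmin(pmax(f, spec$b1$bounds[1]), spec$b1$bounds[2])
  vol3d(array(rep(f, d[2] * d[3]), d), affine)
}

#' Simulate a multi-echo FLASH acquisition from ground-truth maps
#'
#' The steady-state amplitude per voxel is [flash_signal()] at the effective
#' flip angle `f_T * alpha_nominal`, decayed across echoes by
#' `exp(-R2star * TE)`.
#'
#' @param truth list of truth maps from [assign_ground_truth()].
#' @param acq an [acq_params()]; `delta` is used only when the contrast has
#'   an MT pulse.
#' @param b1 transmit-field `vol3d` in percent of nominal, or `NULL` for a
#'   uniform 100% field.
#' @param mode signal model, see [flash_signal()].
#' @return an `echo_series`.
#' @export
simulate_echoes <- function(truth, acq, b1 = NULL, mode = "approx") {
  A <- truth$A$data; T1 <- truth$T1$data
  delta <- if (!is.null(acq$mt_pulse)) truth$delta$data else 0
  if (!is.null(b1)) {
    stop_if_grid_mismatch(truth$A, b1, "simulate_echoes")
    f <- b1$data / 100
  } else f <- 1
  d <- dim(A)
  nz <- T1 > 0
  S0 <- array(0, d)
  alpha_eff <- (f * acq$alpha)
  if (length(alpha_eff) == 1) alpha_eff <- array(alpha_eff, d)
  # the MT pulse's saturation scales with the square of the local transmit
  # field (off-resonance pulse power), the dominant B1 effect on delta
  f2 <- if (length(f) == 1) array(f^2, d) else f^2
  dl <- if (length(delta) == 1) array(delta, d) else delta
  S0[nz] <- flash_signal(A[nz], T1[nz], dl[nz] * f2[nz], alpha_eff[nz],
                         acq$TR, mode)
  te <- acq$echo_times
  out <- array(0, c(d, length(te)))
  r2_ms <- truth$R2star$data / 1000 # 1/s -> 1/ms
  for (e in seq_along(te)) out[, , , e] <- S0 * exp(-r2_ms * te[e])
  echo_series(out, acq, truth$A$affine)
}

#' Simulate the two-volume AFI acquisition
#'
#' Idealised actual flip-angle imaging ratio model (perfect spoiling, T1
#' dependence neglected): with actual angle `a = f_T * nominal` and
#' `n = TR2/TR1`, volume 1 is the amplitude and volume 2 is
#' `amplitude * (1 + n cos a) / (n + cos a)`.
#'
#' @param b1 transmit-field `vol3d`, percent of nominal.
#' @param amplitude `vol3d` (or scalar) signal amplitude of volume 1.
#' @param nominal_deg nominal AFI excitation angle, degrees.
#' @param TR1_ms,TR2_ms the alternating TR pair, ms (`TR2 > TR1`).
#' @return list of two `vol3d` volumes (`S1`, `S2`).
#' @export
simulate_afi <- function(b1, amplitude, nominal_deg = 60,
                         TR1_ms = 50, TR2_ms = 150) {
  if (TR2_ms <= TR1_ms) stop("simulate_afi: TR2 must exceed TR1")
  n <- TR2_ms / TR1_ms
  amp <- if (inherits(amplitude, "vol3d")) amplitude$data
         else array(amplitude, dim(b1$data))
  ca <- cos(b1$data / 100 * nominal_deg * pi / 180)
  list(S1 = vol3d(amp, b1$affine),
       S2 = vol3d(amp * (1 + n * ca) / (n + ca), b1$affine))
}

#' Add measurement noise to an echo series
#'
#' Sigma is defined as the mean noiseless white-matter signal of the first
#' echo divided by the SNR (computed from `labels` unless `sigma` is given).
#' Rician noise is the magnitude of the signal plus complex Gaussian noise.
#'
#' @param series an `echo_series`.
#' @param snr signal-to-noise ratio (> 0).
#' @param model `"rician"`, `"gaussian"` or `"none"`.
#' @param seed random seed (required for models other than `"none"`).
#' @param labels label volume used to locate white matter for the sigma
#'   reference.
#' @param sigma noise standard deviation; overrides `snr`/`labels`.
#' @return the noisy `echo_series`.
#' @export
add_noise <- function(series, snr, model = c("rician", "gaussian", "none"),
                      seed = NULL, labels = NULL, sigma = NULL) {
  model <- match.arg(model)
  if (model == "none") return(series)
  if (is.null(sigma)) {
    if (is.null(labels))
      stop("add_noise: need 'labels' (or an explicit 'sigma') to reference SNR to white matter")
    if (snr <= 0) stop("add_noise: snr must be positive")
    wm <- labels$data %in% CORD_LABELS[c("dorsal_WM", "left_lateral_WM",
                                         "right_lateral_WM")]
    sigma <- mean(series$data[, , , 1][wm]) / snr
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(series$data)
  out <- series
  if (model == "gaussian") {
    out$data <- series$data + array(stats::rnorm(n, 0, sigma), dim(series$data))
  } else {
    re <- series$data + array(stats::rnorm(n, 0, sigma), dim(series$data))
    im <- array(stats::rnorm(n, 0, sigma), dim(series$data))
    out$data <- sqrt(re^2 + im^2)
  }
  attr(out, "noise_sigma") <- sigma
  out
}

# fraction-weighted mixture of pure-tissue FLASH signals (partial volume)
mix_echo_series <- function(spec, tissues, fractions, acq, b1) {
  d <- spec$dim
  f3 <- b1$data / 100
  out <- array(0, c(d, length(acq$echo_times)))
  for (i in seq_len(nrow(tissues))) {
    nm <- tissues$label[i]
    if (tissues$T1[i] <= 0) next # background contributes no signal
    frac <- fractions[[nm]]
    if (max(frac) <= 0) next
    dl <- if (!is.null(acq$mt_pulse)) tissues$delta[i] else 0
    # delta scales as f_T^2 (MT pulse power follows the transmit field)
    S0 <- flash_signal(tissues$A[i], tissues$T1[i], dl * f3^2,
                       f3 * acq$alpha, acq$TR, spec$signal_mode)
    r2_ms <- tissues$R2star[i] / 1000
    for (e in seq_along(acq$echo_times))
      out[, , , e] <- out[, , , e] +
        frac * S0 * exp(-r2_ms * acq$echo_times[e])
  }
  echo_series(out, acq, centred_affine(d, spec$voxel))
}

mix_amplitude <- function(spec, tissues, fractions) {
  d <- spec$dim
  amp <- array(0, d)
  for (i in seq_len(nrow(tissues)))
    amp <- amp + fractions[[tissues$label[i]]] * tissues$A[i]
  vol3d(amp, centred_affine(d, spec$voxel))
}

#' Simulate one complete subject dataset
#'
#' Builds geometry and truth maps, simulates the three FLASH contrasts and
#' the AFI pair, applies the configured per-contrast motion and adds noise.
#'
#' @param spec a [phantom_spec()].
#' @param tissues optional tissue table overriding `spec$tissues` (used by
#'   [generate_cohort()] for per-subject truths).
#' @param seed seed for the noise draws (defaults to `spec$seed`).
#' @param fractions optional precomputed [tissue_fractions()] (geometry is
#'   subject-independent, so cohorts reuse one set).
#' @return list with the `echo_series` (`pd`, `t1`, `mt`), AFI volumes
#'   (`afi1`, `afi2`), `labels`, truth maps and the B1 field.
#' @export
simulate_subject <- function(spec, tissues = NULL, seed = NULL,
                             fractions = NULL) {
  if (is.null(tissues)) tissues <- spec$tissues
  if (is.null(seed)) seed <- spec$seed
  labels <- make_geometry(spec)
  truth <- assign_ground_truth(labels, tissues)
  b1 <- make_b1_field(spec)
  acq <- spec$acquisition
  ss <- spec$render$supersample %||% 1L
  psf <- spec$render$psf_fwhm_mm %||% 0
  if (ss > 1L || psf > 0) {
    fr <- if (is.null(fractions)) tissue_fractions(spec) else fractions
    series <- list(pd = mix_echo_series(spec, tissues, fr, acq$pd, b1),
                   t1 = mix_echo_series(spec, tissues, fr, acq$t1, b1),
                   mt = mix_echo_series(spec, tissues, fr, acq$mt, b1))
    amp <- mix_amplitude(spec, tissues, fr)
    afi <- simulate_afi(b1, amp, acq$afi$nominal_deg,
                        acq$afi$TR1_ms, acq$afi$TR2_ms)
  } else {
    series <- list(pd = simulate_echoes(truth, acq$pd, b1, spec$signal_mode),
                   t1 = simulate_echoes(truth, acq$t1, b1, spec$signal_mode),
                   mt = simulate_echoes(truth, acq$mt, b1, spec$signal_mode))
    afi <- simulate_afi(b1, truth$A, acq$afi$nominal_deg,
                        acq$afi$TR1_ms, acq$afi$TR2_ms)
  }
  for (cn in names(series)) {
    if (!is.null(spec$motion[[cn]]))
      series[[cn]] <- apply_motion(series[[cn]], spec$motion[[cn]])
  }
  if (!is.null(spec$motion$afi)) {
    afi$S1 <- resample(afi$S1, spec$motion$afi, "sinc")
    afi$S2 <- resample(afi$S2, spec$motion$afi, "sinc")
  }
  if (spec$noise$model != "none") {
    sigma <- mean(series$pd$data[, , , 1][labels$data %in%
               CORD_LABELS[c("dorsal_WM", "left_lateral_WM",
                             "right_lateral_WM")]]) / spec$noise$snr
    for (i in seq_along(series))
      series[[i]] <- add_noise(series[[i]], model = spec$noise$model,
                               seed = seed + i, sigma = sigma)
    afi_noise <- function(v, s) {
      vol3d(sqrt((v$data + array(stats::rnorm(length(v$data), 0, s), dim(v$data)))^2 +
                 array(stats::rnorm(length(v$data), 0, s), dim(v$data))^2),
            v$affine)
    }
    set.seed(seed + 10L)
    afi$S1 <- afi_noise(afi$S1, sigma)
    afi$S2 <- afi_noise(afi$S2, sigma)
  }
  list(pd = series$pd, t1 = series$t1, mt = series$mt,
       afi1 = afi$S1, afi2 = afi$S2,
       labels = labels, truth = truth, b1 = b1, tissues = tissues)
}

#' Generate a cohort of synthetic subjects with known truths
#'
#' Per subject, each of the four tissue parameters is scaled by a normal
#' multiplier with the configured inter-subject coefficient of variation
#' (shared across tissues, so tissue contrasts are preserved). Drawn T1
#' values below 100 ms are resampled (truncation) with a message. When `dir`
#' is given, NIfTI volumes, JSON sidecars and the truth manifest CSV are
#' written per subject.
#'
#' @param spec a [phantom_spec()]; `spec$cohort_cv` holds the per-parameter
#'   inter-subject CoVs (fractional).
#' @param n_subjects number of subjects (>= 1).
#' @param dir optional output directory; `NULL` keeps the cohort in memory.
#' @param seed cohort seed (defaults to `spec$seed`).
#' @return list with `subjects` (list of [simulate_subject()] outputs) and
#'   `manifest` (data.frame: subject, tissue, A, T1_ms, MTsat_pu,
#'   R2star_s.1), plus `paths` when written.
#' @export
generate_cohort <- function(spec, n_subjects, dir = NULL, seed = NULL) {
  if (n_subjects < 1) stop("generate_cohort: n_subjects must be >= 1")
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  cv <- spec$cohort_cv
  fr <- tissue_fractions(spec)
  subjects <- vector("list", n_subjects)
  manifest <- NULL
  for (s in seq_len(n_subjects)) {
    tis <- spec$tissues
    for (p in c("A", "T1", "delta", "R2star")) {
      cvp <- if (!is.na(cv[p])) cv[[p]] else 0
      if (cvp > 0) {
        repeat {
          m <- stats::rnorm(1, 1, cvp)
          drawn <- tis[[p]] * m
          bad <- p == "T1" & any(drawn > 0 & drawn < 100)
          if (!bad && m > 0) break
          message(sprintf("generate_cohort: subject %d: resampled truncated %s draw", s, p))
        }
        tis[[p]] <- drawn
      }
    }
    subjects[[s]] <- simulate_subject(spec, tissues = tis,
                                      seed = seed + 1000L * s, fractions = fr)
    manifest <- rbind(manifest, data.frame(
      subject = s, tissue = tis$label, A = tis$A, T1_ms = tis$T1,
      MTsat_pu = 100 * tis$delta, R2star_s.1 = tis$R2star,
      stringsAsFactors = FALSE))
  }
  out <- list(subjects = subjects, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (s in seq_len(n_subjects)) {
      sd <- file.path(dir, sprintf("sub-%02d", s))
      dir.create(sd, showWarnings = FALSE)
      sub <- subjects[[s]]
      p <- list(pd = file.path(sd, "pdw.nii"), t1 = file.path(sd, "t1w.nii"),
                mt = file.path(sd, "mtw.nii"),
                afi1 = file.path(sd, "afi1.nii"),
                afi2 = file.path(sd, "afi2.nii"),
                labels = file.path(sd, "labels.nii"))
      write_volume(sub$pd, p$pd); write_volume(sub$t1, p$t1)
      write_volume(sub$mt, p$mt)
      write_volume(sub$afi1, p$afi1, sidecar = FALSE)
      write_volume(sub$afi2, p$afi2, sidecar = FALSE)
      jsonlite::write_json(list(Nominal_B1_deg = spec$acquisition$afi$nominal_deg,
                                RepetitionTime1_ms = spec$acquisition$afi$TR1_ms,
                                RepetitionTime2_ms = spec$acquisition$afi$TR2_ms),
                           file.path(sd, "afi.json"), auto_unbox = TRUE,
                           digits = NA)
      write_volume(sub$labels, p$labels, sidecar = FALSE)
      paths[[s]] <- p
    }
    utils::write.csv(manifest, file.path(dir, "truth_manifest.csv"),
                     row.names = FALSE)
    out$paths <- paths
  }
  out
}
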