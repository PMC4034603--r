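# Subject- and cohort-level orchestration: registration -> B1 mapping ->
# parameter maps (all/odd/even echo subsets) -> ROI statistics, with
# reproducible configuration and provenance.

PKG_VERSION <- function() as.character(utils::packageVersion("cordmpm"))

# small polynomial content hash of the serialised configuration
# (provenance tag only, not cryptographic)
config_hash <- function(x) {
  s <- jsonlite::serializeJSON(x)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default run configuration
#'
#' All tunable options of a subject run, in one serialisable list.
#'
#' @param registration run the four-step co-registration (disable for data
#'   known to be motion-free, e.g. simulated cohorts).
#' @param reregister_mtw see [run_registration_pipeline()].
#' @param bins NMI histogram bins.
#' @param maxit optimiser budget per registration stage.
#' @param b1_correction apply AFI-derived flip-angle correction.
#' @param b1_smoothing_fwhm_mm B1 map smoothing kernel, mm.
#' @param echo_subsets echo subsets to estimate maps for.
#' @param t2star_compensation see [estimate_all()].
#' @param b1_correct_apd see [estimate_all()].
#' @param seed seed recorded with the run.
#' @return named list of options.
#' @export
default_config <- function(registration = TRUE, reregister_mtw = TRUE,
                           bins = 64, maxit = 400, b1_correction = TRUE,
                           b1_smoothing_fwhm_mm = 8,
                           echo_subsets = c("all", "odd", "even"),
                           t2star_compensation = TRUE, b1_correct_apd = TRUE,
                           seed = 1L) {
  list(registration = registration, reregister_mtw = reregister_mtw,
       bins = bins, maxit = maxit, b1_correction = b1_correction,
       b1_smoothing_fwhm_mm = b1_smoothing_fwhm_mm,
       echo_subsets = echo_subsets,
       t2star_compensation = t2star_compensation,
       b1_correct_apd = b1_correct_apd, seed = seed)
}

validate_dataset <- function(dataset) {
  for (cn in c("pd", "t1", "mt")) {
    s <- dataset[[cn]]
    if (is.null(s)) stop(sprintf("run_subject: missing contrast '%s'", cn))
    if (!inherits(s, "echo_series"))
      stop(sprintf("run_subject: '%s' is not an echo_series", cn))
  }
  if (is.null(dataset$mt$acq$mt_pulse))
    stop("run_subject: MTw sidecar does not declare an MT pulse (MTState)")
  if (!is.null(dataset$pd$acq$mt_pulse))
    stop("run_subject: PDw sidecar declares an MT pulse (MTState)")
  invisible(TRUE)
}

#' Run the full pipeline for one subject
#'
#' Stages: four-step rigid co-registration of the three contrasts; AFI B1
#' mapping co-registered to the registered T1w; parameter-map estimation for
#' each configured echo subset (registration transforms are reused across
#' subsets); ROI statistics and odd/even robustness.
#'
#' @param dataset subject data: `echo_series` `pd`, `t1`, `mt`; optional
#'   `vol3d` `afi1`, `afi2` and `labels`. Either an in-memory list (e.g.
#'   from [simulate_subject()]) or a list of file paths (see
#'   [read_subject_files()]).
#' @param config options from [default_config()].
#' @param rois optional [roi_set()]; built from `dataset$labels` when absent.
#' @param out_dir optional directory: maps are written as NIfTI, statistics
#'   as CSV, and a provenance JSON (config, hash, version) alongside.
#' @return list with `maps` (per echo subset), `transforms`, `b1`, `stats`
#'   (ROI summary of the all-echo maps), `robustness` (per region x
#'   parameter) and `provenance`.
#' @export
run_subject <- function(dataset, config = default_config(), rois = NULL,
                        out_dir = NULL) {
  if (is.character(dataset$pd)) dataset <- read_subject_files(dataset)
  validate_dataset(dataset)
  transforms <- NULL
  reg <- dataset
  if (isTRUE(config$registration)) {
    pipe <- run_registration_pipeline(dataset$pd, dataset$t1, dataset$mt,
                                      bins = config$bins,
                                      reregister_mtw = config$reregister_mtw,
                                      maxit = config$maxit)
    transforms <- pipe$transforms
    reg <- dataset
    for (cn in c("pd", "t1", "mt"))
      reg[[cn]] <- apply_to_echoes(dataset[[cn]], transforms[[cn]])
  }
  b1 <- NULL
  if (isTRUE(config$b1_correction) && !is.null(dataset$afi1)) {
    raw_b1 <- compute_b1_map(dataset$afi1, dataset$afi2,
                             nominal_deg = dataset$afi_nominal %||% 60,
                             TR1_ms = dataset$afi_tr1 %||% 50,
                             TR2_ms = dataset$afi_tr2 %||% 150)
    t_b1 <- rigid_transform()
    if (isTRUE(config$registration)) {
      reg_t1w <- average_echoes(reg$t1, "all")
      t_b1 <- register_rigid(dataset$afi1, reg_t1w, bins = config$bins,
                             maxit = config$maxit)
      t_b1 <- rigid_invert(t_b1, volume_centre(reg_t1w))
    }
    b1 <- prepare_b1_for_correction(raw_b1, average_echoes(reg$t1, "all"),
                                    t = t_b1,
                                    smoothing_fwhm_mm = config$b1_smoothing_fwhm_mm)
  }
  maps <- list()
  for (ss in config$echo_subsets)
    maps[[ss]] <- estimate_all(reg, b1 = b1, echo_subset = ss,
                               t2star_compensation = config$t2star_compensation,
                               b1_correct_apd = config$b1_correct_apd)
  if (is.null(rois) && !is.null(dataset$labels)) rois <- roi_set(dataset$labels)
  stats_tab <- robust_tab <- NULL
  if (!is.null(rois)) {
    stats_tab <- roi_summary(maps[["all"]] %||% maps[[1]], rois)
    if (!is.null(maps$odd) && !is.null(maps$even)) {
      so <- roi_summary(maps$odd, rois); se <- roi_summary(maps$even, rois)
      robust_tab <- data.frame(region = so$region, parameter = so$parameter,
                               odd_value = so$mean, even_value = se$mean,
                               robustness_percent =
                                 robustness_percent(so$mean, se$mean),
                               stringsAsFactors = FALSE)
    }
  }
  prov <- list(package = "cordmpm", version = PKG_VERSION(),
               config = config, config_hash = config_hash(config),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  out <- list(maps = maps, transforms = transforms, b1 = b1,
              stats = stats_tab, robustness = robust_tab, provenance = prov)
  if (!is.null(out_dir)) write_subject_outputs(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read one subject's input files
#'
#' @param paths list with NIfTI paths `pd`, `t1`, `mt` (sidecar JSONs are
#'   expected alongside), optional `afi1`, `afi2`, `afi_json` and `labels`.
#' @return in-memory dataset for [run_subject()].
#' @export
read_subject_files <- function(paths) {
  out <- list(pd = read_echo_series(paths$pd),
              t1 = read_echo_series(paths$t1),
              mt = read_echo_series(paths$mt))
  if (!is.null(paths$afi1)) {
    out$afi1 <- read_volume(paths$afi1)
    out$afi2 <- read_volume(paths$afi2)
    aj <- paths$afi_json %||% file.path(dirname(paths$afi1), "afi.json")
    if (file.exists(aj)) {
      meta <- jsonlite::read_json(aj, simplifyVector = TRUE)
      out$afi_nominal <- meta$Nominal_B1_deg
      out$afi_tr1 <- meta$RepetitionTime1_ms
      out$afi_tr2 <- meta$RepetitionTime2_ms
    }
  }
  if (!is.null(paths$labels)) out$labels <- read_volume(paths$labels)
  out
}

write_subject_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  units <- c(APD = "a.u.", T1 = "ms", R1 = "1/s", MTsat = "p.u.",
             MTR = "p.u.", R2star = "1/s")
  for (ss in names(res$maps)) {
    for (p in names(units)) {
      v <- res$maps[[ss]][[p]]
      out <- v; out$data[is.na(out$data)] <- 0
      write_volume(out, file.path(out_dir, sprintf("%s_%s.nii", p, ss)),
                   sidecar = FALSE)
    }
  }
  if (!is.null(res$stats))
    utils::write.csv(res$stats, file.path(out_dir, "roi_stats.csv"),
                     row.names = FALSE)
  if (!is.null(res$robustness))
    utils::write.csv(res$robustness, file.path(out_dir, "robustness.csv"),
                     row.names = FALSE)
  if (!is.null(res$transforms))
    for (cn in names(res$transforms))
      write_rigid(res$transforms[[cn]],
                  file.path(out_dir, sprintf("transform_%s.json", cn)))
  jsonlite::write_json(res$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Aggregate a cohort of subject runs
#'
#' Emits the cohort table (per region x parameter: cohort mean of the
#' per-subject spatial means, cohort SD and inter-subject CoV), paired
#' GM-vs-WM t-tests per parameter, and odd/even robustness summaries
#' (median and range across subjects, plus the intra-class correlation of
#' the odd/even pair).
#'
#' @param results list of [run_subject()] outputs (>= 2 subjects). A failed
#'   subject may be `NULL`; it is logged and skipped.
#' @param wm_region,gm_region region names used for the paired tests.
#' @return list with `cohort` (data.frame), `paired_tests`, `robustness`
#'   and `icc` data.frames.
#' @export
run_cohort <- function(results, wm_region = "dorsal_WM", gm_region = "GM") {
  ok <- !vapply(results, is.null, logical(1))
  if (sum(!ok) > 0)
    message(sprintf("run_cohort: skipping %d failed subject(s)", sum(!ok)))
  results <- results[ok]
  n <- length(results)
  if (n < 2) stop("run_cohort: need at least two subjects")
  stats_all <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(subject = i, results[[i]]$stats)))
  cohort <- do.call(rbind, lapply(
    split(stats_all, list(stats_all$region, stats_all$parameter)),
    function(g) data.frame(region = g$region[1], parameter = g$parameter[1],
                           cohort_mean = mean(g$mean),
                           cohort_sd = stats::sd(g$mean),
                           CoV_percent = cov_percent(g$mean),
                           stringsAsFactors = FALSE)))
  rownames(cohort) <- NULL
  get_vals <- function(region, param) {
    v <- stats_all[stats_all$region == region & stats_all$parameter == param, ]
    v$mean[order(v$subject)]
  }
  params <- unique(stats_all$parameter)
  paired <- NULL
  if (n >= 3) {
    paired <- do.call(rbind, lapply(params, function(p) {
      tt <- tryCatch(paired_ttest(get_vals(gm_region, p),
                                  get_vals(wm_region, p)),
                     error = function(e) {
                       message("run_cohort: paired test for ", p,
                               " undefined: ", conditionMessage(e))
                       list(t = NA_real_, df = NA_real_, p = NA_real_)
                     })
      data.frame(parameter = p, comparison = sprintf("%s vs %s",
                 gm_region, wm_region), t = tt$t, df = tt$df, p = tt$p,
                 stringsAsFactors = FALSE)
    }))
  } else {
    message("run_cohort: fewer than 3 subjects, paired t-test rows skipped (df too small)")
  }
  robust <- icc_tab <- NULL
  if (!is.null(results[[1]]$robustness)) {
    rob_all <- do.call(rbind, lapply(seq_len(n), function(i)
      cbind(subject = i, results[[i]]$robustness)))
    whole <- rob_all # per-region rows; summarise per parameter across regions/subjects
    robust <- do.call(rbind, lapply(split(whole, whole$parameter), function(g)
      data.frame(parameter = g$parameter[1],
                 median_robustness = stats::median(g$robustness_percent),
                 min_robustness = min(g$robustness_percent),
                 max_robustness = max(g$robustness_percent),
                 stringsAsFactors = FALSE)))
    rownames(robust) <- NULL
    if (n >= 3) {
      icc_tab <- do.call(rbind, lapply(params, function(p) {
        g <- rob_all[rob_all$parameter == p & rob_all$region == wm_region, ]
        r <- icc(cbind(g$odd_value, g$even_value))
        data.frame(parameter = p, icc = r$icc, model = r$model,
                   stringsAsFactors = FALSE)
      }))
    }
  }
  list(cohort = cohort, paired_tests = paired, robustness = robust,
       icc = icc_tab, n_subjects = n)
}
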