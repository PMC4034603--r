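#!/usr/bin/env Rscript
# Command-line front end for the cordmpm pipeline.
#
#   Rscript scripts/mpm.R <subcommand> [options]
#
# Subcommands: simulate | register | b1map | fitmaps | roistats | run | cohort

suppressPackageStartupMessages({
  library(cordmpm)
  library(optparse)
})

usage <- function() {
  cat("usage: mpm.R <simulate|register|b1map|fitmaps|roistats|run|cohort> [options]\n",
      "run 'mpm.R <subcommand> --help' for subcommand options\n")
  quit(status = 2)
}

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) usage()
cmd <- args[1]
rest <- args[-1]

parse <- function(opts) {
  parse_args(OptionParser(option_list = opts), args = rest)
}

paths_opts <- list(
  make_option("--pd", type = "character", help = "PDw multi-echo NIfTI"),
  make_option("--t1", type = "character", help = "T1w multi-echo NIfTI"),
  make_option("--mt", type = "character", help = "MTw multi-echo NIfTI"),
  make_option("--afi1", type = "character", default = NULL),
  make_option("--afi2", type = "character", default = NULL),
  make_option("--labels", type = "character", default = NULL),
  make_option("--out", type = "character", default = "mpm_out"))

status <- tryCatch({
  switch(cmd,
    simulate = {
      o <- parse(list(
        make_option("--subjects", type = "integer", default = 1),
        make_option("--snr", type = "double", default = 0,
                    help = "Rician SNR; 0 disables noise"),
        make_option("--seed", type = "integer", default = 1),
        make_option("--out", type = "character", default = "phantom")))
      spec <- phantom_spec(noise = if (o$snr > 0)
                             list(model = "rician", snr = o$snr)
                           else list(model = "none"),
                           seed = o$seed)
      generate_cohort(spec, o$subjects, dir = o$out)
      message("wrote ", o$subjects, " subject(s) to ", o$out)
      0L
    },
    register = {
      o <- parse(c(paths_opts, list(
        make_option("--dof", type = "integer", default = 6),
        make_option("--cost", type = "character", default = "nmi"),
        make_option("--interp", type = "character", default = "sinc"),
        make_option("--bins", type = "integer", default = 64))))
      if (o$dof != 6 || o$cost != "nmi")
        stop("only --dof 6 --cost nmi is implemented")
      ds <- read_subject_files(o[c("pd", "t1", "mt")])
      pipe <- run_registration_pipeline(ds$pd, ds$t1, ds$mt, bins = o$bins)
      dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
      for (cn in names(pipe$transforms))
        write_rigid(pipe$transforms[[cn]],
                    file.path(o$out, sprintf("transform_%s.json", cn)))
      for (cn in names(pipe$volumes))
        write_volume(pipe$volumes[[cn]],
                     file.path(o$out, sprintf("reg_%s.nii", cn)))
      0L
    },
    b1map = {
      o <- parse(c(paths_opts, list(
        make_option("--nominal", type = "double", default = 60),
        make_option("--tr1", type = "double", default = 50),
        make_option("--tr2", type = "double", default = 150),
        make_option("--fwhm", type = "double", default = 8))))
      b1 <- compute_b1_map(read_volume(o$afi1), read_volume(o$afi2),
                           o$nominal, o$tr1, o$tr2)
      b1 <- smooth_gaussian(b1, o$fwhm)
      dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
      write_volume(b1, file.path(o$out, "b1_percent.nii"))
      0L
    },
    fitmaps = {
      o <- parse(c(paths_opts, list(
        make_option("--b1", type = "character", default = NULL),
        make_option("--echo-subset", type = "character", default = "all",
                    dest = "echo_subset"))))
      ds <- read_subject_files(o[c("pd", "t1", "mt")])
      b1 <- if (!is.null(o$b1)) read_volume(o$b1) else NULL
      maps <- estimate_all(ds, b1 = b1, echo_subset = o$echo_subset)
      dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
      for (p in c("APD", "T1", "R1", "MTsat", "MTR", "R2star")) {
        v <- maps[[p]]; v$data[is.na(v$data)] <- 0
        write_volume(v, file.path(o$out, sprintf("%s_%s.nii", p,
                                                 o$echo_subset)))
      }
      0L
    },
    roistats = {
      o <- parse(c(paths_opts, list(
        make_option("--maps", type = "character",
                    help = "directory holding <param>_all.nii maps"),
        make_option("--erode", type = "integer", default = 1))))
      maps <- list()
      for (p in c("APD", "T1", "MTsat", "MTR", "R2star")) {
        v <- read_volume(file.path(o$maps, sprintf("%s_all.nii", p)))
        v$data[v$data == 0] <- NA
        maps[[p]] <- v
      }
      rois <- roi_set(read_volume(o$labels), erode = o$erode)
      tab <- roi_summary(maps, rois)
      dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(tab, file.path(o$out, "roi_stats.csv"),
                       row.names = FALSE)
      0L
    },
    run = {
      o <- parse(c(paths_opts, list(
        make_option("--no-register", action = "store_true", default = FALSE,
                    dest = "no_register"))))
      ds <- read_subject_files(o)
      cfg <- default_config(registration = !o$no_register)
      run_subject(ds, cfg, out_dir = o$out)
      0L
    },
    cohort = {
      o <- parse(list(
        make_option("--dir", type = "character",
                    help = "directory of sub-XX folders from 'simulate'"),
        make_option("--no-register", action = "store_true", default = FALSE,
                    dest = "no_register"),
        make_option("--out", type = "character", default = "cohort_out")))
      subs <- list.dirs(o$dir, recursive = FALSE)
      subs <- subs[grepl("sub-", basename(subs))]
      cfg <- default_config(registration = !o$no_register)
      results <- lapply(subs, function(sd) {
        tryCatch({
          p <- list(pd = file.path(sd, "pdw.nii"), t1 = file.path(sd, "t1w.nii"),
                    mt = file.path(sd, "mtw.nii"),
                    afi1 = file.path(sd, "afi1.nii"),
                    afi2 = file.path(sd, "afi2.nii"),
                    labels = file.path(sd, "labels.nii"))
          ds <- read_subject_files(p)
          run_subject(ds, cfg, rois = roi_set(ds$labels, erode = 1))
        }, error = function(e) { message(sd, " failed: ", conditionMessage(e)); NULL })
      })
      agg <- run_cohort(results)
      dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(agg$cohort, file.path(o$out, "cohort_stats.csv"),
                       row.names = FALSE)
      if (!is.null(agg$paired_tests))
        utils::write.csv(agg$paired_tests,
                         file.path(o$out, "paired_tests.csv"),
                         row.names = FALSE)
      if (!is.null(agg$robustness))
        utils::write.csv(agg$robustness, file.path(o$out, "robustness.csv"),
                         row.names = FALSE)
      0L
    },
    usage())
}, error = function(e) {
  message("error: ", conditionMessage(e))
  if (grepl("sidecar|missing|not found", conditionMessage(e))) 1L else 2L
})
quit(status = if (is.numeric(status)) status else 0L)
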