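# ROI summaries and reproducibility statistics: spatial means, inter-subject
# coefficient of variation, odd/even-echo robustness, paired t-tests and
# intra-class correlation.

#' Named regions of interest from a label volume
#'
#' @param labels label `vol3d` (integer codes).
#' @param names named integer vector mapping region names to label codes;
#'   defaults to the phantom cord labels (background excluded).
#' @param erode in-plane erosion depth in voxels applied per region
#'   (8-neighbourhood, slice-wise). Interior ROIs avoid partial-volume
#'   contamination at tissue boundaries, mirroring manual ROI placement
#'   away from edges.
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(labels, names = NULL, erode = 0L) {
  if (is.null(names)) {
    names <- CORD_LABELS[setdiff(base::names(CORD_LABELS), "background")]
  }
  if (erode > 0) {
    lab <- labels$data
    for (code in names) {
      m <- lab == code
      d <- dim(m)
      for (it in seq_len(erode)) {
        keep <- m
        for (dx in -1:1) for (dy in -1:1) {
          if (dx == 0 && dy == 0) next
          src_i <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
          src_j <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
          keep <- keep & m[src_i, src_j, , drop = FALSE]
        }
        m <- keep
      }
      lab[labels$data == code & !m] <- -1L # boundary voxels excluded
    }
    labels <- vol3d(lab, labels$affine)
  }
  structure(list(labels = labels, names = names), class = "roi_set")
}

#' Region-wise summary of parameter maps
#'
#' Per region and parameter: spatial mean, sample SD and the count of valid
#' (unmasked) voxels.
#'
#' @param maps a `parameter_maps` object (or plain list of `vol3d` maps).
#' @param rois an [roi_set()] aligned with the maps.
#' @param parameters which maps to summarise.
#' @return data.frame with columns region, parameter, mean, sd, n_voxels.
#' @export
roi_summary <- function(maps, rois,
                        parameters = c("APD", "T1", "MTsat", "MTR", "R2star")) {
  lab <- rois$labels$data
  rows <- list()
  for (rn in names(rois$names)) {
    sel <- lab == rois$names[[rn]]
    for (p in parameters) {
      v <- maps[[p]]$data[sel]
      v <- v[!is.na(v)]
      if (length(v) == 0)
        stop(sprintf("roi_summary: region '%s' empty after validity masking", rn))
      rows[[length(rows) + 1]] <- data.frame(
        region = rn, parameter = p, mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else 0,
        n_voxels = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Inter-subject coefficient of variation
#'
#' `CoV = 100 * SD / mean` (sample SD, n - 1 denominator) across per-subject
#' mean values.
#'
#' @param values per-subject means (length >= 2).
#' @return CoV in percent.
#' @export
cov_percent <- function(values) {
  if (length(values) < 2) stop("cov_percent: need at least two values")
  m <- mean(values)
  if (m <= 0) stop("cov_percent: mean must be positive")
  100 * stats::sd(values) / m
}

#' Intra-subject odd/even robustness
#'
#' CoV of the two measurements obtained from odd and even echo subsets:
#' `100 * SD(pair) / mean(pair)` with the sample SD of two values,
#' `|a - b| / sqrt(2)`.
#'
#' @param value_odd,value_even the paired measurements.
#' @return robustness in percent.
#' @export
robustness_percent <- function(value_odd, value_even) {
  m <- (value_odd + value_even) / 2
  if (any(m <= 0)) stop("robustness_percent: mean of the pair must be positive")
  100 * (abs(value_odd - value_even) / sqrt(2)) / m
}

#' Paired t-test on per-subject values
#'
#' Classical paired t statistic on the differences, two-sided p-value from
#' the t distribution with n - 1 degrees of freedom.
#'
#' @param a,b paired per-subject values of equal length (>= 2).
#' @return list with `t`, `df`, `p`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("paired_ttest: need paired vectors of equal length >= 2")
  d <- a - b
  if (stats::sd(d) == 0)
    stop("paired_ttest: zero-variance differences, t undefined")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Intra-class correlation coefficient for two measurements per subject
#'
#' `model = "one_way"` gives ICC(1,1) from one-way random-effects mean
#' squares, `(MSB - MSW) / (MSB + MSW)` for k = 2 (the default: odd/even
#' halves are not distinguishable raters). `model = "two_way"` gives the
#' absolute-agreement single-measure ICC(A,1).
#'
#' @param pairs n x 2 matrix (or data.frame) of the two measurements per
#'   subject (n >= 3).
#' @param model `"one_way"` or `"two_way"`.
#' @return list with `icc` and `model`; `icc` is `NA` (with a warning) for
#'   degenerate variance.
#' @export
icc <- function(pairs, model = c("one_way", "two_way")) {
  model <- match.arg(model)
  pairs <- as.matrix(pairs)
  n <- nrow(pairs); k <- ncol(pairs)
  if (n < 3 || k != 2) stop("icc: need an n x 2 matrix with n >= 3")
  grand <- mean(pairs)
  row_m <- rowMeans(pairs); col_m <- colMeans(pairs)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((pairs - grand)^2)
  msb <- ss_rows / (n - 1)
  msw <- (ss_tot - ss_rows) / (n * (k - 1))
  if (msb + msw <= 0) {
    warning("icc: degenerate variance, coefficient undefined")
    return(list(icc = NA_real_, model = model))
  }
  val <- if (model == "one_way") {
    (msb - msw) / (msb + msw)
  } else {
    mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
    msc <- ss_cols / (k - 1)
    (msb - mse) / (msb + (k - 1) * mse + k / n * (msc - mse))
  }
  list(icc = val, model = model)
}
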