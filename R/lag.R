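#' Detect the first significant rise of a time-course profile
#'
#' The onset rule: the rise time is the earliest timepoint `t > 0` whose
#' mean exceeds the baseline mean at `t = 0` by more than
#' `max(floor, z * sqrt(se(0)^2 + se(t)^2))`. The z-criterion guards
#' against replicate noise; the absolute floor (in units of the profile
#' scale, by default the 0-100 min-max scale) guards against calling
#' trivially small but precise changes. Raising either parameter can only
#' delay or suppress the call, never advance it.
#'
#' @param prof Profile data frame for one series with columns `timepoint`,
#'   `mean`, `se`, including a `t = 0` baseline.
#' @param z Pooled-SE multiplier. Default 2.
#' @param floor Absolute minimum change on the profile scale. Default 5
#'   (i.e. five percent of the 0-100 axis).
#' @return The rise timepoint in minutes, or `NA` if the profile never
#'   rises under the rule.
#' @export
detect_rise <- function(prof, z = 2, floor = 5) {
  prof <- .one_series(prof)
  base <- prof[prof$timepoint == 0, , drop = FALSE]
  if (nrow(base) != 1) stop("profile needs exactly one t = 0 baseline")
  later <- prof[prof$timepoint > 0, , drop = FALSE]
  thresh <- pmax(floor, z * sqrt(base$se^2 + later$se^2))
  hit <- later$timepoint[later$mean > base$mean + thresh]
  if (length(hit)) min(hit) else NA_real_
}

#' Detect a transient dip in a time-course profile
#'
#' The dip time is the earliest `t > 0` whose mean falls below the
#' baseline by more than `max(floor, z * pooled SE)`, *provided* the
#' profile later recovers to at least `baseline - floor` (otherwise the
#' decrease is monotone, not transient, and no dip is called).
#'
#' @inheritParams detect_rise
#' @return The dip timepoint in minutes, or `NA`.
#' @export
detect_dip <- function(prof, z = 2, floor = 5) {
  prof <- .one_series(prof)
  base <- prof[prof$timepoint == 0, , drop = FALSE]
  if (nrow(base) != 1) stop("profile needs exactly one t = 0 baseline")
  later <- prof[prof$timepoint > 0, , drop = FALSE]
  thresh <- pmax(floor, z * sqrt(base$se^2 + later$se^2))
  below <- later$mean < base$mean - thresh
  for (i in which(below)) {
    recov <- later$timepoint > later$timepoint[i] &
      later$mean >= base$mean - floor
    if (any(recov)) return(later$timepoint[i])
  }
  NA_real_
}

.one_series <- function(prof) {
  stopifnot(all(c("timepoint", "mean", "se") %in% names(prof)))
  if ("series_id" %in% names(prof) && length(unique(prof$series_id)) > 1)
    stop("profile contains multiple series; subset to one")
  rm <- attr(prof, "rep_means")
  prof <- prof[order(prof$timepoint), , drop = FALSE]
  if (anyDuplicated(prof$timepoint)) stop("duplicated timepoints")
  attr(prof, "rep_means") <- rm
  prof
}

#' RNA-to-mark lag between two profiles
#'
#' The lag is `rise(mark) - rise(rna)` in minutes on the sampled grid
#' (never interpolated): positive means the chromatin mark trails the
#' transcript. If either rise is undetected the lag is undefined (`NA`),
#' never coerced to zero. An optional bootstrap resamples biological
#' replicates (via the `rep_means` attribute that [class_average()]
#' attaches), rescales each resampled profile over its own series, and
#' reports a percentile confidence interval over the defined resampled
#' lags.
#'
#' @param rna,mark Profile data frames sharing one timepoint grid, each
#'   with a `t = 0` baseline (typically min-max scaled class averages).
#' @param z,floor Onset-rule parameters, see [detect_rise()].
#' @param B Bootstrap replicates; 0 (default) disables the bootstrap.
#' @param conf Confidence level for the percentile interval.
#' @return A list: `rna_rise`, `mark_rise`, `mark_dip`, `lag`, and (when
#'   bootstrapped) `ci` (two minutes values) plus `boot_defined`, the
#'   fraction of resamples with a defined lag.
#' @export
compute_lag <- function(rna, mark, z = 2, floor = 5, B = 0, conf = 0.95) {
  rna <- .one_series(rna); mark <- .one_series(mark)
  if (!identical(sort(rna$timepoint), sort(mark$timepoint)))
    stop("profiles are on different timepoint grids")
  r_rise <- detect_rise(rna, z, floor)
  m_rise <- detect_rise(mark, z, floor)
  out <- list(rna_rise = r_rise, mark_rise = m_rise,
              mark_dip = detect_dip(mark, z, floor),
              lag = if (is.na(r_rise) || is.na(m_rise)) NA_real_
                    else m_rise - r_rise)
  if (B > 0) {
    lags <- vapply(seq_len(B), function(b) {
      rb <- .boot_profile(rna)
      mb <- .boot_profile(mark)
      rr <- detect_rise(rb, z, floor)
      mm <- detect_rise(mb, z, floor)
      if (is.na(rr) || is.na(mm)) NA_real_ else mm - rr
    }, numeric(1))
    def <- lags[!is.na(lags)]
    out$boot_defined <- length(def) / B
    out$ci <- if (length(def))
      unname(stats::quantile(def, c((1 - conf) / 2, (1 + conf) / 2)))
    else c(NA_real_, NA_real_)
  }
  out
}

# Resample biological replicates of one profile and rescale to 0-100 over
# the resampled series. Falls back to the observed profile when no
# replicate-level data are attached.
.boot_profile <- function(prof) {
  rm <- attr(prof, "rep_means")
  if (is.null(rm)) return(prof)
  reps <- unique(rm$replicate)
  take <- sample(reps, length(reps), replace = TRUE)
  vals <- vapply(sort(unique(rm$timepoint)), function(tp) {
    v <- vapply(take, function(r)
      rm$value[rm$timepoint == tp & rm$replicate == r][1], numeric(1))
    c(mean(v), stats::sd(v) / sqrt(length(v)))
  }, numeric(2))
  bp <- data.frame(timepoint = sort(unique(rm$timepoint)),
                   mean = vals[1, ], se = vals[2, ])
  minmax_scale(bp)
}
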