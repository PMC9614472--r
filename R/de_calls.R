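#' Significance call tokens
#'
#' Ordered set of per-contrast call tokens used throughout the package.
#' `UP_SSTF`/`DOWN_SSTF` mark a statistically significant two-fold (SSTF)
#' change, the strict criterion; `UP_RELAXED`/`DOWN_RELAXED` mark a
#' significant 1.5-fold change at the relaxed criterion, used only for
#' reclassification; `NONE` marks no call.
#'
#' @export
CALL_LEVELS <- c("UP_SSTF", "DOWN_SSTF", "UP_RELAXED", "DOWN_RELAXED", "NONE")

#' Significance thresholds for differential-expression calls
#'
#' The strict criterion is a statistically significant two-fold change
#' (|log2FC| strictly greater than `strict_lfc`, p below `strict_p`); the
#' relaxed criterion is a 1.5-fold change (|log2FC| at or above
#' `relaxed_lfc = log2(1.5)`) with p below `relaxed_p`. The strict bound is
#' a strict inequality, the relaxed bound is inclusive, because the relaxed
#' rule is phrased as "1.5-fold change" rather than "more than 1.5-fold".
#'
#' @param strict_lfc Strict |log2 fold change| bound (exclusive). Default 1.
#' @param strict_p Strict p-value bound (exclusive). Default 0.05.
#' @param relaxed_lfc Relaxed |log2 fold change| bound (inclusive).
#'   Default `log2(1.5)`.
#' @param relaxed_p Relaxed p-value bound (exclusive). Default 0.1.
#' @return A list of class `de_thresholds`.
#' @examples
#' th <- de_thresholds()
#' sstf_call(-4.26, 0.001, th)
#' @export
de_thresholds <- function(strict_lfc = 1, strict_p = 0.05,
                          relaxed_lfc = log2(1.5), relaxed_p = 0.1) {
  stopifnot(strict_lfc > 0, relaxed_lfc > 0, relaxed_lfc <= strict_lfc,
            strict_p > 0, strict_p <= 1, relaxed_p > 0, relaxed_p <= 1)
  structure(list(strict_lfc = strict_lfc, strict_p = strict_p,
                 relaxed_lfc = relaxed_lfc, relaxed_p = relaxed_p),
            class = "de_thresholds")
}

#' Strict/relaxed significance call for one or more DE results
#'
#' Maps (log2 fold change, p-value) pairs to a call token. The strict (SSTF)
#' criterion takes precedence over the relaxed one; a result meeting the
#' strict criterion always meets the relaxed one. Missing p-values yield
#' `NONE` with a warning; non-finite log2 fold changes are an error.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param p Numeric vector of p-values in `[0, 1]` (recycled to length of
#'   `log2fc`); may contain `NA`.
#' @param thresholds A [de_thresholds()] object.
#' @return Character vector of tokens from [CALL_LEVELS].
#' @examples
#' sstf_call(c(-4.26, 1.0, -0.70), c(0.001, 0.001, 0.02))
#' @export
sstf_call <- function(log2fc, p, thresholds = de_thresholds()) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  if (any(!is.finite(log2fc)))
    stop("non-finite log2fc at position(s): ",
         paste(which(!is.finite(log2fc)), collapse = ", "))
  n <- length(log2fc)
  p <- rep_len(p, n)
  if (any(bad <- !is.na(p) & (p < 0 | p > 1)))
    stop("p-values outside [0, 1] at position(s): ",
         paste(which(bad), collapse = ", "))
  out <- rep("NONE", n)
  miss <- is.na(p)
  if (any(miss))
    warning(sum(miss), " record(s) with missing p-value set to NONE")
  ok <- !miss
  strict <- ok & abs(log2fc) > thresholds$strict_lfc & p < thresholds$strict_p
  relax <- ok & !strict &
    abs(log2fc) >= thresholds$relaxed_lfc & p < thresholds$relaxed_p
  out[strict & log2fc > 0] <- "UP_SSTF"
  out[strict & log2fc < 0] <- "DOWN_SSTF"
  out[relax & log2fc > 0] <- "UP_RELAXED"
  out[relax & log2fc < 0] <- "DOWN_RELAXED"
  out
}

#' Convert a log2 fold change to a fold change
#'
#' @param log2fc Finite numeric vector.
#' @return `2 ^ log2fc`.
#' @examples
#' fold_change(4.72101552) # 26.4-fold when rounded for display
#' @export
fold_change <- function(log2fc) {
  if (any(!is.finite(log2fc))) stop("non-finite log2fc")
  2^log2fc
}

#' Display helper: fold change rounded to 3 significant figures
#'
#' @inheritParams fold_change
#' @export
fold_change_display <- function(log2fc) signif(fold_change(log2fc), 3)
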