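#' Construct a differential-expression table
#'
#' A DE table holds at most one record per (gene, contrast) pair with its
#' log2 fold change, raw and adjusted p-values, and the significance call
#' recomputed under the supplied thresholds.
#'
#' @param records Data frame with columns `gene_id`, `contrast`, `log2fc`,
#'   `pvalue`, `padj` (`pvalue`/`padj` may be `NA`).
#' @param thresholds A [de_thresholds()] object used to (re)compute calls.
#' @param p_use Which p-value feeds the call: the raw one (`"pvalue"`, the
#'   default, reading the published "P < 0.05" criterion literally) or the
#'   BH-adjusted one (`"padj"`; falls back to the raw value where no
#'   adjusted one is present). With per-gene tests on three replicates the
#'   adjusted-p route is far more conservative; see the methods vignette.
#' @param contrasts Character vector of admissible contrast tokens.
#' @return The records with a recomputed `call` column, class `de_table`.
#' @export
de_table <- function(records, thresholds = de_thresholds(),
                     p_use = c("pvalue", "padj"),
                     contrasts = .study_contrast_names()) {
  p_use <- match.arg(p_use)
  need <- c("gene_id", "contrast", "log2fc", "pvalue", "padj")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  records <- as.data.frame(records)[,
    c(need, setdiff(names(records), need)), drop = FALSE]
  unknown <- setdiff(unique(records$contrast), contrasts)
  if (length(unknown))
    stop("unknown contrast token(s): ", paste(unknown, collapse = ", "))
  key <- paste(records$gene_id, records$contrast)
  if (anyDuplicated(key))
    stop("duplicate (gene_id, contrast) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  p <- if (p_use == "padj") ifelse(is.na(records$padj), records$pvalue,
                                   records$padj) else records$pvalue
  records$call <- if (nrow(records))
    suppressWarnings(sstf_call(records$log2fc, p, thresholds))
  else character(0)
  records$call[nrow(records) > 0 & is.na(p)] <- "NONE"
  structure(records, class = c("de_table", "data.frame"),
            thresholds = thresholds, p_use = p_use)
}

#' Read a differential-expression table from TSV
#'
#' Expects a UTF-8 tab-separated file with header
#' `gene_id contrast log2fc pvalue padj` and `NA` for missing values.
#' Calls are recomputed on load; they are not stored in the file.
#'
#' @param path File path.
#' @inheritParams de_table
#' @return A [de_table()].
#' @export
read_de_table <- function(path, thresholds = de_thresholds(),
                          p_use = c("pvalue", "padj"),
                          contrasts = .study_contrast_names()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character",
                                         contrast = "character"))
  de_table(df, thresholds = thresholds, p_use = p_use, contrasts = contrasts)
}

#' Write a differential-expression table to TSV
#'
#' Only the five storage columns are written (calls are derived state and
#' recomputed on read), so write followed by read is the identity on
#' records.
#'
#' @param x A [de_table()] or compatible data frame.
#' @param path File path.
#' @export
write_de_table <- function(x, path) {
  cols <- c("gene_id", "contrast", "log2fc", "pvalue", "padj")
  utils::write.table(as.data.frame(x)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Differential expression between two sample groups of a count matrix
#'
#' A deliberately simple, documented test for synthetic counts (it does not
#' attempt to reproduce a negative binomial GLM with shrinkage): counts are
#' normalized by median-of-ratios size factors, the log2 fold change is
#' `log2((meanA + c) / (meanB + c))` of normalized group means with
#' pseudocount `c`, the p-value comes from a two-sample t-test on
#' `log2(normalized + c)` (pooled variance by default: with equal,
#' replicate-level groups of three the Welch degrees-of-freedom estimate is
#' noisy and markedly conservative, while the pooled test is calibrated and
#' more powerful; set `var_equal = FALSE` for Welch), and adjusted p-values
#' are Benjamini-Hochberg within the contrast.
#'
#' Genes with zero counts in every sample of both groups get `log2fc = 0`,
#' missing p-values and call `NONE`.
#'
#' @param counts Non-negative integer matrix, genes x samples, with row and
#'   column names.
#' @param samples_a,samples_b Disjoint character vectors of column names
#'   (numerator group A, denominator group B), each of length >= 2.
#' @param contrast Contrast token stored on the records.
#' @param thresholds A [de_thresholds()] object.
#' @param pseudocount Pseudocount `c` added to normalized counts. Default 1.
#' @param p_use Passed to [de_table()].
#' @param sf Optional named size factors covering both groups. Supplying
#'   factors estimated once on the full experiment (the usual practice) is
#'   preferable to the default, which estimates them from the two groups
#'   alone and is biased when a large fraction of genes changes in one
#'   direction.
#' @param sf_method Passed to [size_factors()] when `sf` is `NULL`.
#' @param var_equal Pool the group variances (default `TRUE`); `FALSE`
#'   gives Welch's test.
#' @return A [de_table()] with one record per gene.
#' @export
run_de <- function(counts, samples_a, samples_b, contrast = "R60",
                   thresholds = de_thresholds(), pseudocount = 1,
                   p_use = c("pvalue", "padj"), sf = NULL,
                   sf_method = c("median_ratio", "pseudo"),
                   var_equal = TRUE) {
  p_use <- match.arg(p_use)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row (gene) and column (sample) names")
  if (length(bad <- intersect(samples_a, samples_b)))
    stop("groups overlap: ", paste(bad, collapse = ", "))
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stop("each group needs at least 2 samples")
  if (length(miss <- setdiff(c(samples_a, samples_b), colnames(counts))))
    stop("sample(s) not in counts: ", paste(miss, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")

  sub <- counts[, c(samples_a, samples_b), drop = FALSE]
  if (is.null(sf)) {
    sf <- size_factors(sub, method = sf_method)
  } else {
    if (length(miss <- setdiff(colnames(sub), names(sf))))
      stop("size factors missing for sample(s): ",
           paste(miss, collapse = ", "))
    sf <- sf[colnames(sub)]
    stopifnot(all(sf > 0))
  }
  norm <- sweep(sub, 2, sf, "/")
  a <- norm[, samples_a, drop = FALSE]
  b <- norm[, samples_b, drop = FALSE]
  log2fc <- log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))

  la <- log2(a + pseudocount)
  lb <- log2(b + pseudocount)
  p <- .ttest_p(la, lb, var_equal = var_equal)
  allzero <- rowSums(sub) == 0
  p[allzero] <- NA_real_
  padj <- stats::p.adjust(p, method = "BH")
  rec <- data.frame(gene_id = rownames(counts), contrast = contrast,
                    log2fc = log2fc, pvalue = p, padj = padj,
                    row.names = NULL, stringsAsFactors = FALSE)
  de_table(rec, thresholds = thresholds, p_use = p_use,
           contrasts = unique(c(contrast, .study_contrast_names())))
}

# Row-wise two-sample t-test p-values, equivalent to apply()ing
# stats::t.test but vectorized across genes. Degenerate rows (zero pooled
# variance) give p = 1 when the means agree and p = 0 otherwise.
.ttest_p <- function(a, b, var_equal = TRUE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  if (var_equal) {
    vp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    sesq <- vp * (1 / na + 1 / nb)
    df <- na + nb - 2
  } else {
    sesq <- va / na + vb / nb
    df <- sesq^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tt <- (ma - mb) / sqrt(sesq)
  p <- 2 * stats::pt(-abs(tt), df)
  deg <- sesq == 0
  p[deg] <- ifelse(ma[deg] == mb[deg], 1, 0)
  unname(p)
}
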