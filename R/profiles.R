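#' Median-of-ratios size factors
#'
#' The standard sequencing-depth estimator: for each sample, the median
#' over reference genes of the ratio of its count to the gene's geometric
#' mean across samples. Only genes with strictly positive counts in every
#' sample serve as references; when none exist the `"pseudo"` method adds
#' 0.5 to all counts before computing the reference, which is the advice
#' given by the error in the default mode.
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @param method `"median_ratio"` (default; errors without an all-positive
#'   gene) or `"pseudo"`.
#' @return Positive numeric vector, one factor per sample, named by the
#'   column names.
#' @export
size_factors <- function(counts, method = c("median_ratio", "pseudo")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (method == "pseudo") counts <- counts + 0.5
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has positive counts in every sample; ",
         "use method = \"pseudo\"")
  logref <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2,
              function(cnt) exp(stats::median(log(cnt) - logref)))
  stopifnot(all(sf > 0))
  sf
}

#' Variance-stabilizing log transform of normalized counts
#'
#' A simple stabilizer for cross-scale comparison of count profiles:
#' `log2(count / size_factor + 1)`. It is strictly increasing in the
#' count, finite at zero, and flattens the strong mean-variance dependence
#' of raw counts; it is not a fitted-dispersion transformation.
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @param sf Size factors from [size_factors()] (default: computed here).
#' @return Numeric matrix of the same shape.
#' @export
vst_counts <- function(counts, sf = size_factors(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(sf) == ncol(counts), all(sf > 0))
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Validate sample metadata
#'
#' @param meta Data frame with columns `sample_id`, `genotype` (`WT` or
#'   `PIF_NULL`), `condition` (`D`, `R`, `WL`, `FR`), `timepoint` (minutes)
#'   and `replicate`.
#' @return The validated data frame, class `sample_meta`.
#' @export
sample_meta <- function(meta) {
  need <- c("sample_id", "genotype", "condition", "timepoint", "replicate")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  meta <- as.data.frame(meta)
  stopifnot(!anyDuplicated(meta$sample_id),
            all(meta$genotype %in% c("WT", "PIF_NULL")),
            all(meta$condition %in% c("D", "R", "WL", "FR")),
            is.numeric(meta$timepoint))
  structure(meta, class = c("sample_meta", "data.frame"))
}

#' Class-average time-course profiles
#'
#' For a set of genes, computes one profile per (genotype, condition)
#' series: at each timepoint the class mean is first taken over genes
#' within each biological replicate, then the reported mean and standard
#' error are taken over replicates (so the SE reflects biological
#' replication, not gene-to-gene spread).
#'
#' @param genes Character vector of gene ids, all present in `mat`.
#' @param mat Numeric matrix (typically [vst_counts()] output),
#'   genes x samples.
#' @param meta A [sample_meta()] data frame covering the columns of `mat`.
#' @param conditions Conditions to profile (default `WL` and `FR`).
#' @return A tidy data frame (`series_id`, `genotype`, `condition`,
#'   `timepoint`, `mean`, `se`, `scale = "VST"`) with the replicate-level
#'   class means attached as attribute `rep_means` (`series_id`,
#'   `timepoint`, `replicate`, `value`) for bootstrap use.
#' @export
class_average <- function(genes, mat, meta, conditions = c("WL", "FR")) {
  meta <- sample_meta(meta)
  if (length(miss <- setdiff(genes, rownames(mat))))
    stop("gene(s) missing from matrix: ", paste(miss, collapse = ", "))
  meta <- meta[meta$condition %in% conditions &
                 meta$sample_id %in% colnames(mat), , drop = FALSE]
  sub <- mat[genes, meta$sample_id, drop = FALSE]
  repval <- data.frame(
    series_id = paste(meta$genotype, meta$condition, sep = "."),
    genotype = meta$genotype, condition = meta$condition,
    timepoint = meta$timepoint, replicate = meta$replicate,
    value = colMeans(sub), row.names = NULL, stringsAsFactors = FALSE)
  agg <- function(f) stats::aggregate(
    value ~ series_id + genotype + condition + timepoint, repval, f)
  m <- agg(mean)
  s <- agg(function(v) stats::sd(v) / sqrt(length(v)))
  prof <- m[order(m$series_id, m$timepoint), , drop = FALSE]
  prof$se <- s$value[match(paste(prof$series_id, prof$timepoint),
                           paste(s$series_id, s$timepoint))]
  names(prof)[names(prof) == "value"] <- "mean"
  prof$scale <- "VST"
  rownames(prof) <- NULL
  attr(prof, "rep_means") <-
    repval[, c("series_id", "timepoint", "replicate", "value")]
  prof
}

#' Min-max scale profiles to a common 0-100 axis
#'
#' Rescales profile means so that, within each normalization domain, 100 is
#' the maximum mean and 0 the minimum, with the extremes taken jointly over
#' *all* series sharing the domain (so e.g. the wild-type and mutant FR and
#' WL series of one class and assay stay comparable on one axis). Standard
#' errors are scaled by the same factor `100 / (max - min)`. A degenerate
#' domain (all means equal) yields zeros with zero SE and a `degenerate`
#' flag.
#'
#' @param prof A profile data frame as from [class_average()].
#' @param by Optional column name defining normalization domains; by
#'   default the whole input is one domain.
#' @return The profile with scaled `mean`/`se`, `scale = "MINMAX_0_100"`,
#'   and a logical `degenerate` column.
#' @export
minmax_scale <- function(prof, by = NULL) {
  stopifnot(all(c("mean", "se") %in% names(prof)))
  dom <- if (is.null(by)) rep(1L, nrow(prof)) else prof[[by]]
  prof$degenerate <- FALSE
  for (d in unique(dom)) {
    i <- dom == d
    rng <- range(prof$mean[i])
    if (diff(rng) == 0) {
      prof$mean[i] <- 0
      prof$se[i] <- 0
      prof$degenerate[i] <- TRUE
    } else {
      k <- 100 / diff(rng)
      prof$mean[i] <- (prof$mean[i] - rng[1]) * k
      prof$se[i] <- prof$se[i] * k
    }
  }
  prof$scale <- "MINMAX_0_100"
  prof
}

#' Extract one series from a multi-series profile
#'
#' Subsets a profile data frame to a single `series_id`, carrying along the
#' matching slice of the `rep_means` attribute (plain `[` subsetting would
#' drop it), so the result can feed [compute_lag()]'s bootstrap.
#'
#' @param prof Profile data frame with a `series_id` column.
#' @param series One series id.
#' @return The single-series profile with its `rep_means` attribute.
#' @export
series_profile <- function(prof, series) {
  if (!series %in% prof$series_id)
    stop("series not found: ", series)
  out <- prof[prof$series_id == series, , drop = FALSE]
  rm <- attr(prof, "rep_means")
  if (!is.null(rm))
    attr(out, "rep_means") <- rm[rm$series_id == series, , drop = FALSE]
  out
}

#' Write tidy profiles as TSV
#' @param prof Profile data frame.
#' @param path Output file.
#' @export
write_profiles <- function(prof, path) {
  utils::write.table(as.data.frame(prof), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
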