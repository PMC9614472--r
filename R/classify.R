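#' Select candidate direct target genes
#'
#' A gene is a candidate when it is (1) light-responsive: SSTF repressed by
#' red light (`R60` down) or SSTF induced by shade at any FR timepoint;
#' (2) PIF-dependent: SSTF down in the dark-grown PIF quartet mutant or in
#' the shade-treated PIF-null sextuple mutant; and (3) bound by at least
#' one PIF. Counts surviving each successive filter are reported as
#' messages.
#'
#' @param ev A [gene_evidence()] data frame.
#' @return Character vector of candidate gene ids.
#' @export
select_candidates <- function(ev) {
  stopifnot(inherits(ev, "gene_evidence"))
  fr_up <- .any_call(ev, .fr_contrasts(), "UP_SSTF")
  light <- ev$R60 == "DOWN_SSTF" | fr_up
  dep <- ev$PIFQ_D == "DOWN_SSTF" | ev$PIFS_FR180 == "DOWN_SSTF"
  bound <- nzchar(ev$bound_by)
  message("candidate selection: ", nrow(ev), " genes in; ",
          sum(light), " light-responsive; ",
          sum(light & dep), " also PIF-dependent; ",
          sum(light & dep & bound), " also PIF-bound")
  ev$gene_id[light & dep & bound]
}

.any_call <- function(ev, contrasts, tokens) {
  Reduce(`|`, lapply(contrasts, function(cc) ev[[cc]] %in% tokens))
}

#' Assign Group 1/2/3 membership from per-contrast calls
#'
#' Group 1: SSTF downregulated by red light and in the dark-grown PIF
#' quartet mutant. Group 2: SSTF upregulated by FR at 30, 60, 120 and/or
#' 180 min and SSTF downregulated in the shade-treated PIF-null mutant.
#' Group 3: SSTF upregulated by FR at 30, 60 and/or 120 min, assigned only
#' when Group 2 fails (the two definitions otherwise overlap and the
#' published table never co-assigns them); 180-min induction alone never
#' triggers Group 3. All groups additionally require PIF binding, which is
#' a precondition here.
#'
#' @param ev A [gene_evidence()] data frame (PIF-bound genes).
#' @return A list (one element per gene) of sorted integer vectors, subsets
#'   of `{1, 2, 3}`; an empty vector means no group is supported.
#' @export
assign_groups <- function(ev) {
  stopifnot(inherits(ev, "gene_evidence"))
  g1 <- ev$R60 == "DOWN_SSTF" & ev$PIFQ_D == "DOWN_SSTF"
  fr_any <- .any_call(ev, .fr_contrasts(), "UP_SSTF")
  fr_early <- .any_call(ev, c("FR30", "FR60", "FR120"), "UP_SSTF")
  g2 <- fr_any & ev$PIFS_FR180 == "DOWN_SSTF"
  g3 <- fr_early & !g2
  lapply(seq_len(nrow(ev)), function(i)
    which(c(g1[i], g2[i], g3[i])))
}

#' Map group membership to the original response class
#'
#' Group 1 alone is class E (etiolation-responsive only); Group 1 together
#' with Group 2 or 3 is class ES; Group 2 or 3 without Group 1 is class S;
#' no group at all is `UNCLASSIFIED`.
#'
#' @param groups Integer vector (one gene) or list of integer vectors.
#' @return Character class token(s).
#' @export
original_class <- function(groups) {
  one <- function(g) {
    if (length(g) == 0) return("UNCLASSIFIED")
    if (1 %in% g) {
      if (any(c(2, 3) %in% g)) "ES" else "E"
    } else "S"
  }
  if (is.list(groups)) vapply(groups, one, character(1)) else one(groups)
}

#' Resort one original class under anomaly exclusion and relaxed cutoffs
#'
#' Anomalous genes are excluded first (final class `ANOM`). Among the
#' rest, an S-class gene showing a red-light reduction at the strict or
#' relaxed criterion moves to ES, and an E-class gene showing an FR
#' induction at either criterion moves to ES; all other classes pass
#' through unchanged. An `UNCLASSIFIED` original passes through with a
#' warning.
#'
#' @param original Character vector of original class tokens.
#' @param ev A [gene_evidence()] data frame aligned with `original`.
#' @return Data frame with columns `final_class` and `resort_reason`
#'   (`S_TO_ES_R_REDUCTION`, `E_TO_ES_FR_INDUCTION` or `NONE`).
#' @export
resort_class <- function(original, ev) {
  stopifnot(inherits(ev, "gene_evidence"), length(original) == nrow(ev))
  if (any(un <- original == "UNCLASSIFIED"))
    warning(sum(un), " UNCLASSIFIED gene(s) pass through resorting")
  final <- original
  reason <- rep("NONE", length(original))
  anom <- !is.na(ev$anomaly)
  r_down <- ev$R60 %in% c("DOWN_SSTF", "DOWN_RELAXED")
  fr_up <- .any_call(ev, .fr_contrasts(), c("UP_SSTF", "UP_RELAXED"))
  s2es <- !anom & original == "S" & r_down
  e2es <- !anom & original == "E" & fr_up
  final[s2es] <- "ES"; reason[s2es] <- "S_TO_ES_R_REDUCTION"
  final[e2es] <- "ES"; reason[e2es] <- "E_TO_ES_FR_INDUCTION"
  final[anom] <- "ANOM"; reason[anom] <- "NONE"
  data.frame(final_class = final, resort_reason = reason,
             stringsAsFactors = FALSE)
}

#' Full classification pipeline over an evidence table
#'
#' Runs group assignment, original-class mapping, anomaly exclusion and
#' relaxed-cutoff resorting for every gene, and tallies the bookkeeping.
#' Rows whose calls support no group can fall back to an externally
#' supplied group membership (used for the printed table, whose cells only
#' show SSTF values that matter); such rows are reported in the summary,
#' never silently reclassified.
#'
#' @param ev A [gene_evidence()] data frame.
#' @param fallback_groups Optional list of integer vectors, aligned with
#'   `ev`, consulted only where the derived groups are empty (e.g. the
#'   printed group column of the published table).
#' @return A list with `assignments` (data frame: `gene_id`, `groups`
#'   string, `group_support` flag, `original_class`, `final_class`,
#'   `resort_reason`) and `summary` (candidate count, per-class original
#'   and final counts, anomaly breakdown, resort tallies, unsupported
#'   rows).
#' @export
classify_all <- function(ev, fallback_groups = NULL) {
  stopifnot(inherits(ev, "gene_evidence"))
  groups <- assign_groups(ev)
  support <- lengths(groups) > 0
  if (!is.null(fallback_groups)) {
    stopifnot(length(fallback_groups) == nrow(ev))
    groups[!support] <- fallback_groups[!support]
  }
  orig <- original_class(groups)
  rs <- suppressWarnings(resort_class(orig, ev))
  assignments <- data.frame(
    gene_id = ev$gene_id,
    groups = vapply(groups, paste, character(1), collapse = ","),
    group_support = support,
    original_class = orig,
    final_class = rs$final_class,
    resort_reason = rs$resort_reason,
    stringsAsFactors = FALSE)
  cls <- function(x, lv) c(table(factor(x, levels = lv)))
  summary <- list(
    n_genes = nrow(ev),
    original_counts = cls(orig, c("E", "ES", "S", "ANOM", "UNCLASSIFIED")),
    final_counts = cls(rs$final_class,
                       c("E", "ES", "S", "ANOM", "UNCLASSIFIED")),
    n_anomalous = sum(!is.na(ev$anomaly)),
    anomaly_breakdown = cls(ev$anomaly[!is.na(ev$anomaly)],
                            .anomaly_tokens),
    n_resorted_pool = sum(is.na(ev$anomaly)),
    resort_tally = cls(rs$resort_reason[rs$resort_reason != "NONE"],
                       c("S_TO_ES_R_REDUCTION", "E_TO_ES_FR_INDUCTION")),
    unsupported = ev$gene_id[!support])
  list(assignments = assignments, summary = summary)
}

#' Classify the packaged printed table and audit it against print
#'
#' Convenience wrapper: builds evidence from the printed cells, classifies
#' with the printed group column as fallback for unsupported rows, and
#' reports where the recomputation disagrees with the printed labels.
#' A printed group is called *underivable* when it names Group 2 but the
#' pS cell is a dash (the printed cells cannot evidence that group); such
#' rows, like rows with no supporting cells at all, are reported rather
#' than treated as recomputation failures.
#'
#' @param t1 A [read_table1()] data frame (default: the packaged table).
#' @return A [classify_all()] result with an extra `audit` element:
#'   `unsupported` (gene ids with no cell-supported group), `group_mismatch`
#'   (derived vs printed groups differ), `underivable_group` (subset of the
#'   mismatches explained by a dash in a required cell), `class_mismatch`
#'   (recomputed original class differs from print).
#' @export
classify_table1 <- function(t1 = read_table1()) {
  ev <- table1_evidence(t1)
  res <- classify_all(ev, fallback_groups = ev$printed_groups)
  derived <- assign_groups(ev)
  support <- lengths(derived) > 0
  printed <- ev$printed_groups
  mism <- support & !mapply(identical, derived, printed)
  underivable <- mism & vapply(seq_along(printed), function(i)
    2 %in% printed[[i]] && ev$PIFS_FR180[i] == "NONE", logical(1))
  res$audit <- list(
    unsupported = ev$gene_id[!support],
    group_mismatch = ev$gene_id[mism],
    underivable_group = ev$gene_id[underivable],
    class_mismatch = ev$gene_id[res$assignments$original_class !=
                                  ev$printed_original])
  res
}

#' Advisory anomaly screen
#'
#' Suggests anomaly annotations for review; never applied automatically,
#' because the published exclusions were manual and no thresholds are
#' stated. A gene is flagged `R_INDUCED` when its red-light contrast shows
#' a significant *induction* (the opposite of the PIF-activated pattern),
#' and `HIGH_IN_WL` when its mean white-light baseline expression lies
#' above `wl_quantile` of the panel (requires `counts` and `meta`).
#'
#' @param ev A [gene_evidence()] data frame.
#' @param counts Optional count matrix for the white-light screen.
#' @param meta Optional [sample_meta()] for `counts`.
#' @param wl_quantile Panel quantile above which white-light baseline
#'   expression is considered suspiciously high. Default 0.9.
#' @return Data frame `gene_id`, `suggested_anomaly` for flagged genes.
#' @export
flag_anomalies <- function(ev, counts = NULL, meta = NULL,
                           wl_quantile = 0.9) {
  stopifnot(inherits(ev, "gene_evidence"))
  out <- data.frame(gene_id = character(0),
                    suggested_anomaly = character(0))
  r_ind <- ev$R60 %in% c("UP_SSTF", "UP_RELAXED")
  if (any(r_ind))
    out <- rbind(out, data.frame(gene_id = ev$gene_id[r_ind],
                                 suggested_anomaly = "R_INDUCED"))
  if (!is.null(counts)) {
    meta <- sample_meta(meta)
    wl <- meta$sample_id[meta$condition == "WL" & meta$timepoint == 0]
    if (length(wl) == 0) stop("no white-light baseline samples in meta")
    v <- vst_counts(counts)
    expr <- rowMeans(v[, wl, drop = FALSE])
    hi <- names(expr)[expr > stats::quantile(expr, wl_quantile)]
    hi <- intersect(hi, ev$gene_id)
    if (length(hi))
      out <- rbind(out, data.frame(gene_id = hi,
                                   suggested_anomaly = "HIGH_IN_WL"))
  }
  rownames(out) <- NULL
  out
}

#' Write classification assignments as TSV
#' @param result A [classify_all()] result.
#' @param path Output file.
#' @export
write_assignments <- function(result, path) {
  utils::write.table(result$assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
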