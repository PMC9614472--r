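#' Per-gene evidence bundle for the classifier
#'
#' One row per gene: a call token for each of the seven study contrasts, a
#' PIF-binding code, and an optional anomaly annotation. Binding codes are
#' digit strings over 1/3/4/5/7 for PIF1/3/4/5/7 (no genome-wide binding
#' data exist for PIF6, so 6 is rejected); an empty string means not bound.
#'
#' @param calls Data frame with columns `gene_id` and the seven contrast
#'   names (`R60`, `PIFQ_D`, `FR30`, `FR60`, `FR120`, `FR180`,
#'   `PIFS_FR180`), each a token from [CALL_LEVELS].
#' @param bound_by Character vector of binding codes ("" for unbound).
#' @param anomaly Optional character vector of anomaly tokens
#'   (`HIGH_IN_WL`, `R_INDUCED`, `LOW`, `ARTIFACTUAL`) or `NA`.
#' @return A data frame of class `gene_evidence`.
#' @export
gene_evidence <- function(calls, bound_by, anomaly = NA_character_) {
  need <- c("gene_id", .study_contrast_names())
  if (length(miss <- setdiff(need, names(calls))))
    stop("missing contrast column(s): ", paste(miss, collapse = ", "))
  calls <- as.data.frame(calls)[, need, drop = FALSE]
  for (cc in .study_contrast_names()) {
    if (any(bad <- !calls[[cc]] %in% CALL_LEVELS))
      stop("invalid call token(s) in ", cc, ": ",
           paste(unique(calls[[cc]][bad]), collapse = ", "))
  }
  bound_by <- rep_len(as.character(bound_by), nrow(calls))
  if (any(grepl("6", bound_by)))
    stop("binding code contains PIF6, for which no binding data exist")
  if (any(bad <- !grepl("^[13457]*$", bound_by)))
    stop("invalid binding code(s): ", paste(unique(bound_by[bad]),
                                            collapse = ", "))
  anomaly <- rep_len(anomaly, nrow(calls))
  if (any(bad <- !is.na(anomaly) & !anomaly %in% .anomaly_tokens))
    stop("invalid anomaly token(s): ", paste(unique(anomaly[bad]),
                                             collapse = ", "))
  calls$bound_by <- bound_by
  calls$anomaly <- anomaly
  structure(calls, class = c("gene_evidence", "data.frame"))
}

#' Build classifier evidence from a DE table, binding and anomaly lists
#'
#' Pivots a seven-contrast [de_table()] into one row of call tokens per
#' gene and attaches PIF-binding codes and anomaly annotations. Genes of
#' the DE table missing a record for some contrast get `NONE` there; a
#' contrast absent from the table altogether is an error.
#'
#' @param de A [de_table()] covering the seven study contrasts.
#' @param binding Data frame with columns `gene_id`, `bound_by` (binding
#'   code; genes absent from it count as unbound).
#' @param anomalies Optional data frame with columns `gene_id`, `anomaly`.
#' @return A [gene_evidence()] data frame.
#' @export
evidence_from_de <- function(de, binding, anomalies = NULL) {
  cn <- .study_contrast_names()
  if (length(miss <- setdiff(cn, unique(de$contrast))))
    stop("DE table lacks contrast(s): ", paste(miss, collapse = ", "))
  genes <- unique(de$gene_id)
  calls <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cc in cn) {
    sub <- de[de$contrast == cc, c("gene_id", "call")]
    calls[[cc]] <- sub$call[match(genes, sub$gene_id)]
    calls[[cc]][is.na(calls[[cc]])] <- "NONE"
  }
  bound <- binding$bound_by[match(genes, binding$gene_id)]
  bound[is.na(bound)] <- ""
  anom <- rep(NA_character_, length(genes))
  if (!is.null(anomalies))
    anom <- anomalies$anomaly[match(genes, anomalies$gene_id)]
  gene_evidence(calls, bound_by = bound, anomaly = anom)
}
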