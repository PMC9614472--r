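#' Path to the packaged candidate PIF direct-target-gene table
#' @return File path of the packaged TSV transcription.
#' @export
table1_path <- function() {
  system.file("extdata", "table1_pif_dtg.tsv", package = "shadeclass",
              mustWork = TRUE)
}

.table1_cell_cols <- c("r60", "pifq", "fr30", "fr60", "fr120", "fr180", "ps")

#' Read the packaged transcription of the candidate DTG table
#'
#' The table lists the 169 candidate PIF direct target genes with their
#' per-contrast log2 fold-change cells. A cell holds either a printed
#' number (a statistically significant two-fold change), the token `DASH`
#' (no SSTF change) or the token `STARS` (significant 1.5-fold change at
#' the relaxed criterion, printed only where it matters for
#' recategorization). Remaining columns carry the PIF-binding code (digit
#' string over 1/3/4/5/7), the printed original and new class, the printed
#' group membership, and the anomaly rationale (`NA` when not anomalous).
#'
#' @param path TSV path; defaults to the packaged table.
#' @return A validated data frame of class `table1`.
#' @export
read_table1 <- function(path = table1_path()) {
  t1 <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("locus", "name", .table1_cell_cols, "bound", "orig_class",
            "new_class", "group", "anom_reason")
  if (!all(need %in% names(t1)))
    stop("fixture must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(t1$locus))
    stop("duplicated locus: ", t1$locus[duplicated(t1$locus)])
  for (cc in .table1_cell_cols) {
    v <- t1[[cc]]
    num <- suppressWarnings(as.numeric(v))
    if (any(bad <- is.na(num) & !v %in% c("DASH", "STARS")))
      stop("bad cell(s) in column ", cc, ": ", paste(v[bad], collapse = ", "))
  }
  stopifnot(all(t1$orig_class %in% c("E", "ES", "S")),
            all(t1$new_class %in% c("E", "ES", "S", "ANOM")),
            all(grepl("^[13457]+$", t1$bound)),
            all(is.na(t1$anom_reason) |
                  t1$anom_reason %in% .anomaly_tokens))
  structure(t1, class = c("table1", "data.frame"))
}

.anomaly_tokens <- c("HIGH_IN_WL", "R_INDUCED", "LOW", "ARTIFACTUAL")

# Map one fixture column of printed cells to call tokens. Printed numeric
# cells are SSTF by construction (the table prints only SSTF values), so
# the sign alone sets the direction; STARS is a relaxed call whose sign is
# taken from the resorting context of its column: an R60 star means a
# relaxed reduction, a star in an FR column a relaxed induction. STARS
# never appears in the pifq or pS columns, which play no role in
# resorting.
.cell_calls <- function(cells, column) {
  star_call <- switch(column,
    r60 = "DOWN_RELAXED",
    fr30 = , fr60 = , fr120 = , fr180 = "UP_RELAXED",
    pifq = , ps = NA_character_)
  num <- suppressWarnings(as.numeric(cells))
  out <- ifelse(cells == "DASH", "NONE",
         ifelse(cells == "STARS", star_call,
         ifelse(num > 0, "UP_SSTF", "DOWN_SSTF")))
  if (any(is.na(out)))
    stop("STARS cell in column '", column, "' has no defined direction")
  out
}

#' Convert the printed table into per-gene classifier evidence
#'
#' @param t1 A [read_table1()] data frame.
#' @return A [gene_evidence()] data frame with the printed group column
#'   attached as `printed_groups` (used as fallback for rows whose printed
#'   cells support no group) and printed classes as `printed_original` /
#'   `printed_new`.
#' @export
table1_evidence <- function(t1) {
  stopifnot(inherits(t1, "table1"))
  calls <- data.frame(
    gene_id = t1$locus,
    R60 = .cell_calls(t1$r60, "r60"),
    PIFQ_D = .cell_calls(t1$pifq, "pifq"),
    FR30 = .cell_calls(t1$fr30, "fr30"),
    FR60 = .cell_calls(t1$fr60, "fr60"),
    FR120 = .cell_calls(t1$fr120, "fr120"),
    FR180 = .cell_calls(t1$fr180, "fr180"),
    PIFS_FR180 = .cell_calls(t1$ps, "ps"),
    stringsAsFactors = FALSE)
  ev <- gene_evidence(calls, bound_by = t1$bound, anomaly = t1$anom_reason)
  ev$printed_groups <- .parse_group(t1$group)
  ev$printed_original <- t1$orig_class
  ev$printed_new <- t1$new_class
  ev$name <- t1$name
  ev
}

# "1 & 2" / "1&3" / "2" -> integer vectors
.parse_group <- function(x) {
  lapply(strsplit(gsub("[^123]", " ", x), " +"),
         function(g) sort(unique(as.integer(g[nzchar(g)]))))
}
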