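#' Genomic intervals as plain data frames
#'
#' Internal coordinate convention: 0-based half-open `[start, end)`, i.e.
#' BED-native. GFF3 input (1-based closed) is converted at the boundary by
#' [read_annotation()].
#'
#' @param chrom,start,end,strand Interval fields; strand in `+`, `-`, `.`.
#' @param gene_id Optional identifiers.
#' @return Data frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              gene_id = NULL) {
  n <- length(start)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(strand, n)
  stopifnot(length(end) == n, all(strand %in% c("+", "-", ".")))
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("empty or inverted interval(s)")
  out <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                    end = as.integer(end), strand = strand,
                    stringsAsFactors = FALSE)
  if (!is.null(gene_id)) out <- cbind(gene_id = as.character(gene_id), out,
                                      stringsAsFactors = FALSE)
  structure(out, class = c("genomic_intervals", "data.frame"))
}

#' Transcription start site of stranded gene intervals
#'
#' Convention: the TSS of a `+`-strand gene is its start; of a `-`-strand
#' gene the last covered base, `end - 1` (0-based). Unstranded genes are
#' an error because the TSS is undefined without orientation.
#'
#' @param genes A [genomic_intervals()] data frame with strands.
#' @return Integer vector of 0-based TSS positions.
#' @export
tss_of <- function(genes) {
  if (any(genes$strand == "."))
    stop("unstranded gene(s): TSS undefined; provide +/- strands")
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Fixed-width windows centered on transcription start sites
#'
#' Builds one `width`-bp window per gene, centered on the TSS:
#' `[tss - width/2, tss + width/2)`. The width must be even, otherwise the
#' centering is ambiguous. Windows running off the chromosome start are
#' clipped at 0 with a warning.
#'
#' @param genes A [genomic_intervals()] data frame with `gene_id`.
#' @param width Even positive window width in bp; default 300.
#' @return A [genomic_intervals()] data frame with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand` and `tss`.
#' @export
tss_windows <- function(genes, width = 300) {
  if (width <= 0 || width %% 2 != 0)
    stop("width must be a positive even integer (got ", width,
         "); choose an even value so the window centers on the TSS")
  tss <- tss_of(genes)
  start <- tss - width %/% 2
  if (any(clip <- start < 0)) {
    warning(sum(clip), " window(s) clipped at position 0")
    start[clip] <- 0L
  }
  out <- genomic_intervals(genes$chrom, start, tss + width %/% 2,
                           genes$strand, gene_id = genes$gene_id)
  out$tss <- as.integer(tss)
  out
}

#' Read gene annotation from GFF3 or BED
#'
#' Uses `rtracklayer` for parsing; GFF3 keeps only `gene`-type features
#' (falling back to all features if none) and takes `ID`/`gene_id`/`Name`
#' as identifier; BED uses the name column. Coordinates are returned in the
#' package's 0-based half-open convention.
#'
#' @param path Annotation file.
#' @param format `"auto"` (from extension), `"gff3"` or `"bed"`.
#' @return A [genomic_intervals()] data frame with `gene_id`.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else "gff3"
  gr <- if (format == "bed") rtracklayer::import(path, format = "BED")
        else rtracklayer::import(path, format = "GFF3")
  if (format == "gff3") {
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md) && any(md$type == "gene"))
      gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
    id <- if ("ID" %in% names(md)) md$ID
          else if ("gene_id" %in% names(md)) md$gene_id
          else md$Name
  } else {
    id <- S4Vectors::mcols(gr)$name
  }
  if (is.null(id) || any(is.na(id)))
    stop("annotation features lack identifiers")
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                    st, gene_id = as.character(id))
}

#' Read read intervals from BED
#' @param path BED file of read (or fragment) intervals.
#' @return A [genomic_intervals()] data frame.
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L,
                    GenomicRanges::end(gr), st)
}

#' Count reads in TSS windows
#'
#' A read is counted in a window iff its midpoint, `floor((start+end)/2)`,
#' lies inside the window (half-open, so a midpoint exactly at the window
#' end is outside). Where windows overlap, each read is assigned to at
#' most one: the window whose center is nearest its midpoint, ties going
#' to the lexicographically smaller `gene_id`. Reads on chromosomes with
#' no windows are ignored and tallied in a message. With
#' `mode = "overlap"` a read is instead counted in every window it
#' overlaps by at least one base (no unique assignment).
#'
#' @param reads A [genomic_intervals()] data frame of reads.
#' @param windows Output of [tss_windows()].
#' @param mode `"midpoint"` (default) or `"overlap"`.
#' @return Named integer vector of counts, one per window, in window
#'   order.
#' @export
count_in_windows <- function(reads, windows, mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  counts <- stats::setNames(integer(nrow(windows)), windows$gene_id)
  orphan <- !reads$chrom %in% unique(windows$chrom)
  if (any(orphan))
    message(sum(orphan), " read(s) on chromosome(s) without windows ignored")
  reads <- reads[!orphan, , drop = FALSE]
  if (nrow(reads) == 0 || nrow(windows) == 0) return(counts)

  wr <- GenomicRanges::GRanges(windows$chrom,
          IRanges::IRanges(windows$start + 1L, windows$end))
  if (mode == "overlap") {
    rr <- GenomicRanges::GRanges(reads$chrom,
            IRanges::IRanges(reads$start + 1L, reads$end))
    ov <- GenomicRanges::findOverlaps(rr, wr)
    hits <- table(factor(S4Vectors::subjectHits(ov),
                         levels = seq_len(nrow(windows))))
    counts[] <- as.integer(hits)
    return(counts)
  }

  mid <- (reads$start + reads$end) %/% 2L
  mr <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(mid + 1L,
                                                             width = 1L))
  ov <- GenomicRanges::findOverlaps(mr, wr)
  if (length(ov) == 0) return(counts)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  center <- (windows$start + windows$end) / 2
  dist <- abs(mid[qh] - center[sh])
  # per read: nearest window center, ties to smaller gene_id
  ord <- order(qh, dist, windows$gene_id[sh])
  keep <- ord[!duplicated(qh[ord])]
  hits <- table(factor(sh[keep], levels = seq_len(nrow(windows))))
  counts[] <- as.integer(hits)
  counts
}

#' Aggregate bedGraph coverage over TSS windows
#'
#' For each window, sums coverage value times overlap width over all
#' bedGraph intervals intersecting it, rounded to the nearest integer
#' (an approximation of a read count from a coverage track).
#'
#' @param path bedGraph file.
#' @param windows Output of [tss_windows()].
#' @return Named integer vector of per-window totals.
#' @export
quantify_bedgraph <- function(path, windows) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  wr <- GenomicRanges::GRanges(windows$chrom,
          IRanges::IRanges(windows$start + 1L, windows$end))
  ov <- GenomicRanges::findOverlaps(gr, wr)
  out <- stats::setNames(numeric(nrow(windows)), windows$gene_id)
  if (length(ov)) {
    pw <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr)[S4Vectors::queryHits(ov)],
      IRanges::ranges(wr)[S4Vectors::subjectHits(ov)]))
    val <- S4Vectors::mcols(gr)$score[S4Vectors::queryHits(ov)] * pw
    agg <- tapply(val, factor(S4Vectors::subjectHits(ov),
                              levels = seq_len(nrow(windows))), sum)
    out[] <- ifelse(is.na(agg), 0, agg)
  }
  stats::setNames(as.integer(round(out)), windows$gene_id)
}

#' Export windows as BED
#'
#' @param windows Output of [tss_windows()].
#' @param path Output BED file.
#' @export
windows_to_bed <- function(windows, path) {
  bed <- data.frame(windows$chrom, windows$start, windows$end,
                    windows$gene_id, 0L, windows$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
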