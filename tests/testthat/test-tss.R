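test_that("TSS extraction follows the strand convention", {
  g <- genomic_intervals("Chr1", c(1000, 1000), c(2000, 2000),
                         c("+", "-"), gene_id = c("a", "b"))
  expect_equal(tss_of(g), c(1000L, 1999L))
  gu <- genomic_intervals("Chr1", 10, 20, ".")
  expect_error(tss_of(gu), "unstranded")
})

test_that("TSS windows are centered, clipped, and even-width only", {
  g <- genomic_intervals("Chr1", 1000, 2000, "+", gene_id = "a")
  w <- tss_windows(g, 300)
  expect_equal(c(w$start, w$end), c(850L, 1150L))
  expect_equal(w$end - w$start, 300L)
  near <- genomic_intervals("Chr1", 100, 900, "+", gene_id = "b")
  expect_warning(wc <- tss_windows(near, 300), "clipped")
  expect_equal(c(wc$start, wc$end), c(0L, 250L))
  expect_error(tss_windows(g, 301), "even")
})

test_that("midpoint counting respects half-open window bounds", {
  w <- tss_windows(genomic_intervals("Chr1", 1000, 2000, "+",
                                     gene_id = "a"), 300)
  # window [850, 1150): midpoints 850 (at start: in), 1149 (in),
  # 1150 (at end: out)
  reads <- genomic_intervals("Chr1", c(840, 1139, 1140), c(860, 1159, 1160))
  expect_equal(unname(count_in_windows(reads, w)), 2L)
  # ten reads strictly inside, none outside
  set.seed(5)
  mids <- sample(850:1149, 10)
  r10 <- genomic_intervals("Chr1", mids - 10, mids + 10)
  expect_equal(unname(count_in_windows(r10, w)), 10L)
  expect_equal(unname(count_in_windows(r10[0, ], w)), 0L)
})

test_that("overlapping windows assign each read once, by nearest center", {
  g <- genomic_intervals("Chr1", c(1000, 1200), c(2000, 2200), "+",
                         gene_id = c("zzz", "aaa"))
  w <- tss_windows(g, 300)  # centers 1000 and 1200, windows overlap
  # midpoint 1050: nearer to center 1000 (zzz); 1100: equidistant, tie
  # goes to the lexicographically smaller id (aaa)
  reads <- genomic_intervals("Chr1", c(1040, 1090), c(1060, 1110))
  cnt <- count_in_windows(reads, w)
  expect_equal(cnt[["zzz"]], 1L)
  expect_equal(cnt[["aaa"]], 1L)
  expect_equal(sum(cnt), nrow(reads))
})

test_that("window counting matches a brute-force oracle", {
  set.seed(17)
  for (i in 1:30) {
    n_w <- sample(2:8, 1)
    tsspos <- sample(500:5000, n_w)
    genes <- genomic_intervals(rep("Chr1", n_w), tsspos, tsspos + 1000,
                               "+", gene_id = sprintf("g%02d", 1:n_w))
    w <- suppressWarnings(tss_windows(genes, 300))
    n_r <- sample(10:200, 1)
    st <- sample(0:6000, n_r, replace = TRUE)
    reads <- genomic_intervals(rep("Chr1", n_r), st, st + 50)
    got <- count_in_windows(reads, w)
    # oracle: per-read scan over all windows
    want <- stats::setNames(integer(n_w), w$gene_id)
    for (r in seq_len(n_r)) {
      mid <- (reads$start[r] + reads$end[r]) %/% 2
      inw <- which(w$start <= mid & mid < w$end)
      if (length(inw)) {
        d <- abs(mid - (w$start[inw] + w$end[inw]) / 2)
        best <- inw[order(d, w$gene_id[inw])][1]
        want[best] <- want[best] + 1L
      }
    }
    expect_equal(got, want)
    expect_lte(sum(got), n_r)
    # translation invariance
    sh <- 917L
    got2 <- count_in_windows(
      genomic_intervals(reads$chrom, reads$start + sh, reads$end + sh),
      within(w, { start <- start + sh; end <- end + sh; tss <- tss + sh }))
    expect_equal(unname(got2), unname(got))
  }
})

test_that("reads on window-less chromosomes are ignored with a note", {
  w <- tss_windows(genomic_intervals("Chr1", 1000, 2000, "+",
                                     gene_id = "a"), 300)
  reads <- genomic_intervals(c("Chr1", "Chr9"), c(990, 990), c(1010, 1010))
  expect_message(cnt <- count_in_windows(reads, w), "without windows")
  expect_equal(unname(cnt), 1L)
})

test_that("overlap mode counts a read in every window it touches", {
  g <- genomic_intervals("Chr1", c(1000, 1100), c(2000, 2100), "+",
                         gene_id = c("a", "b"))
  w <- tss_windows(g, 300)  # [850,1150) and [950,1250)
  reads <- genomic_intervals("Chr1", 1000, 1040)
  expect_equal(sum(count_in_windows(reads, w, mode = "overlap")), 2L)
})

test_that("annotation and read files round-trip through rtracklayer", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "Chr1\ttest\tgene\t1001\t2000\t.\t+\t.\tID=AT1G01010",
    "Chr1\ttest\tgene\t3001\t4000\t.\t-\t.\tID=AT1G01020"), gff)
  ann <- read_annotation(gff)
  # 1-based closed GFF3 becomes 0-based half-open
  expect_equal(ann$start, c(1000L, 3000L))
  expect_equal(ann$end, c(2000L, 4000L))
  expect_equal(tss_of(ann), c(1000L, 3999L))
  w <- tss_windows(ann, 300)
  bed <- withr::local_tempfile(fileext = ".bed")
  windows_to_bed(w, bed)
  back <- read_annotation(bed, format = "bed")
  expect_equal(back$start, w$start)
  expect_equal(back$end, w$end)
  expect_equal(back$gene_id, w$gene_id)
})

test_that("bedGraph aggregation sums value times overlap width", {
  w <- tss_windows(genomic_intervals("Chr1", 1000, 2000, "+",
                                     gene_id = "a"), 300)  # [850, 1150)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("Chr1\t800\t900\t2", # 50 bp inside * 2 = 100
               "Chr1\t900\t1100\t1", # 200 inside
               "Chr1\t1140\t1200\t3"), bg) # 10 inside * 3 = 30
  expect_equal(quantify_bedgraph(bg, w), c(a = 330L))
})
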