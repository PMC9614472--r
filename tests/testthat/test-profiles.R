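test_that("median-of-ratios size factors match hand-computed cases", {
  m <- matrix(c(10, 20, 40, 10, 20, 40), 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(a = c(10, 20, 40), b = c(20, 40, 80))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # genes with any zero never contribute to the median
  m3 <- rbind(m2, g4 = c(0, 1e6))
  expect_equal(size_factors(m3), size_factors(m2))
  # no all-positive gene: default errors, pseudo mode recovers
  m4 <- cbind(a = c(0, 5), b = c(5, 0))
  expect_error(size_factors(m4), "pseudo")
  expect_length(size_factors(m4, method = "pseudo"), 2)
})

test_that("size factors agree with the reference implementation", {
  set.seed(13)
  cnt <- make_counts(exp(runif(200, log(50), log(5000))), 5)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  expect_equal(unname(size_factors(cnt)), unname(ref), tolerance = 1e-8)
})

test_that("per-sample rescaling propagates into size factors", {
  set.seed(19)
  cnt <- make_counts(exp(runif(100, log(100), log(1000))), 4)
  k <- c(0.5, 1, 2, 4)
  sf1 <- size_factors(cnt)
  sf2 <- size_factors(sweep(cnt, 2, k, "*"))
  expect_equal(unname(sf2), unname(sf1 * k / exp(mean(log(k)))),
               tolerance = 1e-8)
})

test_that("the variance-stabilizing transform behaves as documented", {
  expect_equal(vst_counts(matrix(0), sf = 1)[1], 0)
  expect_equal(vst_counts(matrix(7), sf = 1)[1], 3)
  set.seed(23)
  cnt <- make_counts(exp(runif(50, log(10), log(1000))), 4)
  v <- vst_counts(cnt)
  for (j in 1:4) expect_false(is.unsorted(v[order(cnt[, j]), j]))
})

test_that("the transform flattens the count mean-variance relation", {
  set.seed(29)
  mu <- exp(seq(log(10), log(10000), length.out = 200))
  cnt <- make_counts(mu, 6, dispersion = 0.05)
  mm <- rowMeans(cnt)  # variance regressed on the count mean throughout
  slope <- function(m) {
    vv <- apply(m, 1, var)
    keep <- vv > 0
    unname(coef(stats::lm(log(vv[keep]) ~ log(mm[keep])))[2])
  }
  expect_gt(slope(cnt), 1.5)                    # raw counts: ~ quadratic
  expect_lt(abs(slope(vst_counts(cnt, sf = rep(1, 6)))), 0.3)
})

test_that("min-max scaling hits 0 and 100 jointly across a domain", {
  p1 <- make_profile(c(1, 2, 3), se = 0.5, timepoints = c(0, 30, 60))
  s1 <- minmax_scale(p1)
  expect_equal(s1$mean, c(0, 50, 100))
  expect_equal(s1$se, rep(0.5 * 100 / 2, 3))
  two <- rbind(cbind(series_id = "x",
                     make_profile(c(0, 10), se = 1, c(0, 30))),
               cbind(series_id = "y",
                     make_profile(c(5, 20), se = 1, c(0, 30))))
  s2 <- minmax_scale(two)
  expect_equal(s2$mean, c(0, 50, 25, 100))
  const <- make_profile(c(4, 4, 4), timepoints = c(0, 30, 60))
  s3 <- minmax_scale(const)
  expect_true(all(s3$degenerate))
  expect_equal(s3$mean, c(0, 0, 0))
  expect_equal(s3$se, c(0, 0, 0))
})

test_that("min-max scaling is invariant to affine input transforms", {
  set.seed(37)
  for (i in 1:20) {
    p <- make_profile(rnorm(5, 10, 4), se = runif(5))
    a <- runif(1, 0.1, 5); b <- rnorm(1, 0, 20)
    pa <- p; pa$mean <- a * p$mean + b; pa$se <- a * p$se
    expect_equal(minmax_scale(pa)$mean, minmax_scale(p)$mean,
                 tolerance = 1e-10)
    expect_equal(minmax_scale(pa)$se, minmax_scale(p)$se,
                 tolerance = 1e-10)
  }
})

test_that("class averages are gene-first with replicate-level SE", {
  meta <- sample_meta(data.frame(
    sample_id = paste0("s", 1:6),
    genotype = "WT", condition = "FR",
    timepoint = rep(c(0, 30), each = 3), replicate = rep(1:3, 2)))
  # one gene, identical replicates: zero SE
  m <- matrix(c(4, 4, 4, 8, 8, 8), 1, dimnames = list("g1", meta$sample_id))
  p <- class_average("g1", m, meta)
  expect_equal(p$mean, c(4, 8))
  expect_equal(p$se, c(0, 0))
  # one gene, replicates 3/4/5: textbook SE
  m2 <- matrix(c(3, 4, 5, 3, 4, 5), 1, dimnames = list("g1", meta$sample_id))
  p2 <- class_average("g1", m2, meta)
  expect_equal(p2$mean, c(4, 4))
  expect_equal(p2$se, rep(1 / sqrt(3), 2), tolerance = 1e-12)
  # two genes averaging to the same replicate means: identical profile
  m3 <- rbind(g1 = c(2, 3, 4, 2, 3, 4), g2 = c(4, 5, 6, 4, 5, 6))
  colnames(m3) <- meta$sample_id
  p3 <- class_average(c("g1", "g2"), m3, meta)
  expect_equal(p3$mean, c(4, 4))  # replicate-level class means are 3/4/5
  expect_equal(p3$se, p2$se, tolerance = 1e-12)
  expect_error(class_average("gX", m3, meta), "gX")
  # single-gene class average equals the gene's own profile
  rm <- attr(p, "rep_means")
  expect_equal(rm$value, unname(m[1, ]))
})

test_that("series extraction keeps the replicate-level attribute", {
  meta <- sample_meta(data.frame(
    sample_id = paste0("s", 1:12),
    genotype = "WT", condition = rep(c("FR", "WL"), each = 6),
    timepoint = rep(rep(c(0, 30), each = 3), 2),
    replicate = rep(1:3, 4)))
  set.seed(43)
  m <- matrix(rnorm(12, 5), 1, dimnames = list("g1", meta$sample_id))
  p <- class_average("g1", m, meta)
  one <- series_profile(p, "WT.FR")
  expect_equal(unique(one$series_id), "WT.FR")
  expect_equal(unique(attr(one, "rep_means")$series_id), "WT.FR")
  expect_error(series_profile(p, "nope"), "not found")
})
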