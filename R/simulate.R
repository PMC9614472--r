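#' Parameters for the synthetic RNA-seq / H3K4me3 time-course generator
#'
#' The generator emulates the study design: 3 biological replicates of
#' wild-type and PIF-null seedlings sampled in darkness (with a 60-min red
#' light treatment for the wild type) and along a 0/30/60/120/180-min
#' white-light vs simulated-shade (FR) time course, with per-class
#' response templates:
#' * **E** -- high in darkness, repressed `dark_fold`-fold by red light,
#'   flat in shade;
#' * **ES** -- dark-high and red-repressed *and* shade-induced from 30 min;
#' * **S** -- shade-induced only;
#' * **NULL_BG** -- unresponsive background.
#'
#' Dark induction of E/ES genes is absent in the PIF-null genotype, and the
#' shade induction of ES/S genes is attenuated there by `attenuation`
#' (multiplier on the induced excess). The H3K4me3 window-count template
#' reuses the transcript shade template delayed by `mark_delay` grid steps,
#' compressed toward 1 by `mark_effect`, with an optional transient dip at
#' 30 min of depth `dip_depth`.
#'
#' Counts are negative binomial with variance `mu + dispersion * mu^2`
#' (Poisson when `dispersion = 0`).
#'
#' @param n_genes Named counts of genes per class
#'   (`E`, `ES`, `S`, `NULL_BG`).
#' @param baseline_range Range of per-gene baseline mean counts, drawn
#'   log-uniformly. Default 200-2000.
#' @param dispersion NB dispersion. Default 0.05.
#' @param effect_fold Peak fold change of the class templates. Default 4.
#' @param fr_onset Timepoint (min) at which shade induction starts.
#'   Default 30.
#' @param dark_fold Dark/red fold for E and ES genes (defaults to
#'   `effect_fold`).
#' @param attenuation Residual fraction of the shade-induced excess in the
#'   PIF-null genotype. Default 0.1 (the sextuple mutant retains only a
#'   marginal shade response).
#' @param mark_delay RNA-to-mark onset delay in grid steps. Default 2
#'   (RNA onset 30 min, mark onset 120 min).
#' @param dip_depth Fractional depth of the transient 30-min mark dip.
#'   Default 0.2 (0 disables it).
#' @param mark_effect Compression of the mark template toward 1 (the mark
#'   moves less than the transcript). Default 0.5.
#' @param mark_baseline_range Baseline range for mark window counts.
#' @param replicates Biological replicates per design cell. Default 3.
#' @param timepoints Sampling grid in minutes.
#' @param libsize_range Per-sample library-size multipliers are drawn
#'   uniformly from this range. Default 0.8-1.2.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = c(E = 30, ES = 30, S = 30, NULL_BG = 200),
                       baseline_range = c(200, 2000),
                       dispersion = 0.05,
                       effect_fold = 4,
                       fr_onset = 30,
                       dark_fold = effect_fold,
                       attenuation = 0.1,
                       mark_delay = 2,
                       dip_depth = 0.2,
                       mark_effect = 0.5,
                       mark_baseline_range = c(500, 2000),
                       replicates = 3,
                       timepoints = c(0, 30, 60, 120, 180),
                       libsize_range = c(0.8, 1.2)) {
  p <- list(n_genes = n_genes, baseline_range = baseline_range,
            dispersion = dispersion, effect_fold = effect_fold,
            fr_onset = fr_onset, dark_fold = dark_fold,
            attenuation = attenuation, mark_delay = mark_delay,
            dip_depth = dip_depth, mark_effect = mark_effect,
            mark_baseline_range = mark_baseline_range,
            replicates = replicates, timepoints = sort(timepoints),
            libsize_range = libsize_range)
  stopifnot(all(c("E", "ES", "S", "NULL_BG") %in% names(n_genes)),
            all(n_genes >= 0), dispersion >= 0, effect_fold > 1,
            dark_fold > 1, attenuation >= 0, attenuation <= 1,
            mark_delay >= 0, mark_delay == round(mark_delay),
            dip_depth >= 0, dip_depth < 1,
            mark_effect > 0, mark_effect <= 1,
            replicates >= 2, 0 %in% timepoints,
            fr_onset %in% timepoints, fr_onset > 0,
            all(baseline_range > 0), diff(baseline_range) >= 0,
            all(libsize_range > 0))
  structure(p, class = "sim_params")
}

# Shade-induction template over the timepoint grid: 1 before onset, then a
# linear ramp in fold space reaching effect_fold two grid steps after
# onset.
.fr_template <- function(tp, onset, fold) {
  i0 <- match(onset, tp)
  mult <- rep(1, length(tp))
  steps <- seq_along(tp) - i0
  ramp <- pmin(1, (steps + 1) / 3)
  on <- steps >= 0
  mult[on] <- 1 + (fold - 1) * ramp[on]
  mult
}

# Generating mean multiplier for one (class, genotype, condition,
# timepoint); the design cells are D (t 0), R (t 60, WT only), WL and FR
# series.
.template_mult <- function(class, genotype, condition, timepoint, p) {
  fr <- .fr_template(p$timepoints, p$fr_onset, p$effect_fold)
  dark <- class %in% c("E", "ES")
  induced <- class %in% c("ES", "S")
  if (condition == "D")
    return(if (dark && genotype == "WT") p$dark_fold else 1)
  if (condition == "R")
    return(1)  # red light restores E/ES genes to baseline
  if (condition == "WL")
    return(1)
  # FR
  if (!induced) return(1)
  m <- fr[match(timepoint, p$timepoints)]
  if (genotype == "PIF_NULL") m <- 1 + (m - 1) * p$attenuation
  m
}

# Mark multiplier: transcript FR template delayed by mark_delay grid
# steps, compressed by mark_effect, optional transient dip at 30 min.
.mark_mult <- function(class, genotype, condition, timepoint, p) {
  if (condition %in% c("D", "R")) {
    base <- .template_mult(class, genotype, condition, timepoint, p)
    return(1 + (base - 1) * p$mark_effect)
  }
  induced <- class %in% c("ES", "S")
  if (condition == "WL" || !induced) return(1)
  i <- match(timepoint, p$timepoints)
  lagged <- max(1, i - p$mark_delay)
  fr <- .fr_template(p$timepoints, p$fr_onset, p$effect_fold)
  m <- 1 + (fr[lagged] - 1) * p$mark_effect
  if (genotype == "PIF_NULL") m <- 1 + (m - 1) * p$attenuation
  if (p$dip_depth > 0 && timepoint == 30) m <- m * (1 - p$dip_depth)
  m
}

#' Simulate an RNA-seq and H3K4me3 window-count time course
#'
#' Draws seeded negative binomial counts for every design cell of the
#' study (dark, red-treated dark, and the white-light vs simulated-shade
#' series for both genotypes) with planted E/ES/S/background class
#' structure, PIF-dependent attenuation, and an H3K4me3 signal that trails
#' the transcript signal. The seed fixes the full output; per-gene
#' substreams are derived from it so that enlarging the gene set does not
#' perturb the counts of existing genes.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed for the root generator.
#' @return A list with `rna` and `mark` count matrices (genes x samples),
#'   `meta` (a [sample_meta()] frame), and `truth` (per gene: `class`,
#'   `bound_by`, planted `rna_onset` / `mark_onset` minutes).
#' @export
simulate_experiment <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  classes <- rep(names(p$n_genes), p$n_genes)
  ng <- length(classes)
  genes <- sprintf("G%04d_%s", seq_len(ng), classes)

  cells <- rbind(
    data.frame(genotype = "WT", condition = "D", timepoint = 0),
    data.frame(genotype = "WT", condition = "R", timepoint = 60),
    data.frame(genotype = "PIF_NULL", condition = "D", timepoint = 0),
    expand.grid(genotype = c("WT", "PIF_NULL"), condition = c("WL", "FR"),
                timepoint = p$timepoints, stringsAsFactors = FALSE))
  meta <- do.call(rbind, lapply(seq_len(p$replicates), function(r)
    cbind(cells, replicate = r)))
  meta$sample_id <- sprintf("%s_%s_t%03d_r%d", meta$genotype,
                            meta$condition, meta$timepoint, meta$replicate)
  meta <- sample_meta(meta[, c("sample_id", "genotype", "condition",
                               "timepoint", "replicate")])

  set.seed(seed)
  lib <- stats::runif(nrow(meta), p$libsize_range[1], p$libsize_range[2])
  gene_seeds <- seed + 1000003L * seq_len(ng)  # per-gene substreams
  base_rna <- base_mark <- numeric(ng)
  rna <- mark <- matrix(0L, ng, nrow(meta),
                        dimnames = list(genes, meta$sample_id))
  lu <- function(rng) exp(stats::runif(1, log(rng[1]), log(rng[2])))
  draw <- function(mu) {
    if (p$dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / p$dispersion)
  }
  for (i in seq_len(ng)) {
    set.seed(gene_seeds[i] %% .Machine$integer.max)
    base_rna[i] <- lu(p$baseline_range)
    base_mark[i] <- lu(p$mark_baseline_range)
    mult_r <- mapply(.template_mult, meta$genotype, meta$condition,
                     meta$timepoint,
                     MoreArgs = list(class = classes[i], p = p))
    mult_m <- mapply(.mark_mult, meta$genotype, meta$condition,
                     meta$timepoint,
                     MoreArgs = list(class = classes[i], p = p))
    rna[i, ] <- draw(base_rna[i] * mult_r * lib)
    mark[i, ] <- draw(base_mark[i] * mult_m * lib)
  }

  bound <- ifelse(classes == "NULL_BG",
                  rep(c("45", ""), length.out = ng), "1345")
  onset_idx <- match(p$fr_onset, p$timepoints)
  mark_onset_idx <- min(onset_idx + p$mark_delay, length(p$timepoints))
  truth <- data.frame(
    gene_id = genes, class = classes, bound_by = bound,
    rna_onset = ifelse(classes %in% c("ES", "S"), p$fr_onset, NA),
    mark_onset = ifelse(classes %in% c("ES", "S"),
                        p$timepoints[mark_onset_idx], NA),
    stringsAsFactors = FALSE)
  list(rna = rna, mark = mark, meta = meta, truth = truth,
       params = p, seed = seed)
}

#' Derive the seven study-contrast DE calls from a simulation
#'
#' Runs [run_de()] for each study contrast on the simulated RNA counts,
#' using the design cells defined by [study_contrasts()]. Size factors are
#' estimated once across the full simulated experiment and shared by every
#' contrast (as a single normalization of one sequencing experiment would
#' be).
#'
#' @param sim Output of [simulate_experiment()].
#' @param thresholds A [de_thresholds()] object.
#' @param p_use Passed to [run_de()].
#' @return A seven-contrast [de_table()].
#' @export
emit_de_inputs <- function(sim, thresholds = de_thresholds(),
                           p_use = c("pvalue", "padj")) {
  p_use <- match.arg(p_use)
  sf <- size_factors(sim$rna)
  ctr <- study_contrasts()
  meta <- sim$meta
  cell <- function(g, cond, tp) {
    ids <- meta$sample_id[meta$genotype == g & meta$condition == cond &
                            meta$timepoint == tp]
    if (length(ids) == 0)
      stop("design cell missing from simulation: (", g, ", ", cond,
           ", ", tp, ")")
    ids
  }
  tabs <- lapply(seq_len(nrow(ctr)), function(i) {
    run_de(sim$rna,
           cell(ctr$num_genotype[i], ctr$num_condition[i],
                ctr$num_timepoint[i]),
           cell(ctr$den_genotype[i], ctr$den_condition[i],
                ctr$den_timepoint[i]),
           contrast = ctr$name[i], thresholds = thresholds, p_use = p_use,
           sf = sf)
  })
  de_table(do.call(rbind, lapply(tabs, as.data.frame)),
           thresholds = thresholds, p_use = p_use)
}

#' Write simulation outputs as plain TSV files
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f, rn = FALSE)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE,
                       fileEncoding = "UTF-8")
  wt(data.frame(gene_id = rownames(sim$rna), sim$rna,
                check.names = FALSE), "rna_counts.tsv")
  wt(data.frame(gene_id = rownames(sim$mark), sim$mark,
                check.names = FALSE), "mark_counts.tsv")
  wt(as.data.frame(sim$meta), "sample_meta.tsv")
  wt(sim$truth, "ground_truth.tsv")
  invisible(dir)
}
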