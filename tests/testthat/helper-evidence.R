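# Shared test helpers: small evidence/count constructors built in code.

# Evidence row builder: unspecified contrasts default to NONE.
make_evidence <- function(genes, ..., bound_by = "1345",
                          anomaly = NA_character_) {
  calls <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cc in study_contrasts()$name)
    calls[[cc]] <- rep("NONE", length(genes))
  over <- list(...)
  for (cc in names(over)) calls[[cc]] <- over[[cc]]
  gene_evidence(calls, bound_by = bound_by, anomaly = anomaly)
}

# NB count matrix with per-gene means mu (recycled across samples).
make_counts <- function(mu, n_samples = 6, dispersion = 0.05,
                        genes = sprintf("g%03d", seq_along(mu)),
                        samples = sprintf("s%d", seq_len(n_samples))) {
  m <- matrix(stats::rnbinom(length(mu) * n_samples,
                             mu = rep(mu, n_samples),
                             size = 1 / dispersion),
              nrow = length(mu), ncol = n_samples,
              dimnames = list(genes, samples))
  m
}

# Single-series profile frame for the onset detector.
make_profile <- function(means, se = 1,
                         timepoints = c(0, 30, 60, 120, 180)) {
  data.frame(timepoint = timepoints[seq_along(means)], mean = means,
             se = rep_len(se, length(means)))
}

# Fixture evidence for one locus by name.
fixture_evidence <- function() {
  ev <- table1_evidence(read_table1())
  ev
}

evidence_row <- function(ev, name) ev[ev$name == name, , drop = FALSE]
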