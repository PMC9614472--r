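test_that("candidate selection applies all three filters", {
  ev <- make_evidence(
    paste0("g", 1:6),
    R60 = c("DOWN_SSTF", "DOWN_SSTF", "NONE", "NONE", "DOWN_SSTF",
            "NONE"),
    PIFQ_D = c("DOWN_SSTF", "NONE", "NONE", "NONE", "NONE", "DOWN_SSTF"),
    FR60 = c("NONE", "NONE", "UP_SSTF", "UP_SSTF", "NONE", "NONE"),
    PIFS_FR180 = c("NONE", "NONE", "DOWN_SSTF", "DOWN_SSTF", "NONE",
                   "NONE"),
    bound_by = c("1345", "1345", "1345", "", "1345", "1345"))
  # independent oracle: check each gene against the three predicates
  expected <- character(0)
  for (i in 1:6) {
    light <- ev$R60[i] == "DOWN_SSTF" ||
      any(unlist(ev[i, c("FR30", "FR60", "FR120", "FR180")]) == "UP_SSTF")
    dep <- ev$PIFQ_D[i] == "DOWN_SSTF" || ev$PIFS_FR180[i] == "DOWN_SSTF"
    if (light && dep && nzchar(ev$bound_by[i]))
      expected <- c(expected, ev$gene_id[i])
  }
  expect_equal(expected, c("g1", "g3"))
  expect_equal(suppressMessages(select_candidates(ev)), expected)
  # g4: responsive and dependent but unbound; g5: no PIF dependence
  expect_false("g4" %in% expected)
  expect_false("g5" %in% expected)
})

test_that("group assignment reproduces the printed spot-check rows", {
  ev <- fixture_evidence()
  grp <- function(nm) assign_groups(evidence_row(ev, nm))[[1]]
  expect_equal(grp("PIL1"), c(1L, 2L))
  expect_equal(grp("IBH1"), c(1L, 3L))
  expect_equal(grp("YUC8"), 2L)
  expect_equal(grp("ATHB52"), 1L)
  # FR180-only induction never triggers Group 3
  expect_equal(grp("SAUR36"), 1L)
})

test_that("group membership maps to original classes", {
  expect_equal(original_class(1L), "E")          # e.g. ATHB52
  expect_equal(original_class(c(1L, 2L)), "ES")  # e.g. PIL1
  expect_equal(original_class(c(1L, 3L)), "ES")  # e.g. IBH1
  expect_equal(original_class(2L), "S")          # e.g. YUC8
  expect_equal(original_class(3L), "S")
  expect_equal(original_class(integer(0)), "UNCLASSIFIED")
  expect_equal(original_class(list(1L, c(2L), integer(0))),
               c("E", "S", "UNCLASSIFIED"))
})

test_that("resorting follows anomaly exclusion and relaxed cutoffs", {
  ev <- fixture_evidence()
  one <- function(nm, orig) {
    r <- resort_class(orig, evidence_row(ev, nm))
    c(r$final_class, r$resort_reason)
  }
  expect_equal(one("PAR1", "S"), c("ES", "S_TO_ES_R_REDUCTION"))
  expect_equal(one("CYP78A7", "S"), c("ES", "S_TO_ES_R_REDUCTION"))
  expect_equal(one("SAUR36", "E"), c("ES", "E_TO_ES_FR_INDUCTION"))
  expect_equal(one("HFR1", "S"), c("ANOM", "NONE"))
  expect_equal(one("YUC8", "S"), c("S", "NONE"))
  expect_equal(one("ATHB52", "E"), c("E", "NONE"))
  expect_warning(resort_class("UNCLASSIFIED", evidence_row(ev, "YUC8")),
                 "UNCLASSIFIED")
})

test_that("resorting is idempotent and never crosses E and S", {
  ev <- fixture_evidence()
  res <- classify_all(ev, fallback_groups = ev$printed_groups)
  non_anom <- is.na(ev$anomaly)
  again <- resort_class(res$assignments$final_class[non_anom],
                        ev[non_anom, , drop = FALSE])
  expect_equal(again$final_class,
               res$assignments$final_class[non_anom])
  expect_true(all(again$resort_reason == "NONE"))
  # E and S only ever move to ES or ANOM
  moved <- res$assignments$original_class != res$assignments$final_class
  expect_true(all(res$assignments$final_class[moved] %in% c("ES", "ANOM")))
})

test_that("class counts are conserved and empty input is handled", {
  ev <- fixture_evidence()
  res <- classify_all(ev, fallback_groups = ev$printed_groups)
  expect_equal(sum(res$summary$final_counts), nrow(ev))
  empty <- make_evidence(character(0))
  res0 <- classify_all(empty)
  expect_equal(nrow(res0$assignments), 0L)
  expect_true(all(res0$summary$final_counts == 0))
})

test_that("rows without cell support are reported, not guessed", {
  res <- classify_table1()
  # AIF4 prints dashes everywhere; BZIP3 prints an R60 increase
  expect_setequal(res$audit$unsupported, c("AT1G09250", "AT5G15830"))
  expect_equal(res$audit$class_mismatch, character(0))
})

test_that("the advisory anomaly screen flags but never applies", {
  ev <- fixture_evidence()
  sug <- flag_anomalies(ev)
  # BZIP3 prints an R-light induction and is picked up by the screen
  expect_true("AT5G15830" %in% sug$gene_id)
  expect_true(all(sug$suggested_anomaly == "R_INDUCED"))
  # the screen's output has no effect on classification
  res <- classify_all(ev, fallback_groups = ev$printed_groups)
  expect_equal(sum(res$summary$final_counts), 169L)
  sim <- simulate_experiment(
    sim_params(n_genes = c(E = 3, ES = 3, S = 3, NULL_BG = 6)), seed = 29)
  de <- emit_de_inputs(sim)
  ev2 <- evidence_from_de(de, sim$truth[, c("gene_id", "bound_by")])
  sug2 <- flag_anomalies(ev2, counts = sim$rna, meta = sim$meta)
  expect_true(all(c("gene_id", "suggested_anomaly") %in% names(sug2)))
})
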