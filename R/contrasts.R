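#' The seven study contrasts
#'
#' Each contrast names a (numerator, denominator) pair of design cells, a
#' design cell being a (genotype, condition, timepoint) triple. `R60`
#' compares dark-grown seedlings after 60 min of red light to darkness;
#' `PIFQ_D` compares the dark-grown PIF-null mutant to dark-grown wild type;
#' `FR30`..`FR180` compare white-light-grown wild type after 30-180 min of
#' far-red-supplemented light (simulated shade) to the white-light control
#' at the same timepoint; `PIFS_FR180` compares the PIF-null mutant to wild
#' type, both after 180 min of simulated shade.
#'
#' Timepoints are minutes; `D` cells carry timepoint 0.
#'
#' @return A data frame with columns `name`, `num_genotype`,
#'   `num_condition`, `num_timepoint`, `den_genotype`, `den_condition`,
#'   `den_timepoint`, `description`.
#' @export
study_contrasts <- function() {
  fr <- c(30, 60, 120, 180)
  data.frame(
    name = c("R60", "PIFQ_D", paste0("FR", fr), "PIFS_FR180"),
    num_genotype = c("WT", "PIF_NULL", rep("WT", 4), "PIF_NULL"),
    num_condition = c("R", "D", rep("FR", 4), "FR"),
    num_timepoint = c(60, 0, fr, 180),
    den_genotype = c("WT", "WT", rep("WT", 4), "WT"),
    den_condition = c("D", "D", rep("WL", 4), "FR"),
    den_timepoint = c(0, 0, fr, 180),
    description = c(
      "60 min red light vs darkness, dark-grown WT",
      "dark-grown PIF-null mutant vs dark-grown WT",
      sprintf("%d min simulated shade vs WL control, WT", fr),
      "PIF-null mutant vs WT after 180 min simulated shade"),
    stringsAsFactors = FALSE)
}

#' Contrast name vectors used by the classifier
#' @keywords internal
.fr_contrasts <- function() c("FR30", "FR60", "FR120", "FR180")

#' @keywords internal
.study_contrast_names <- function() study_contrasts()$name
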