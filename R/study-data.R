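# Published summary tables of the dwarf-mutant study, bundled as plain-text
# inputs: per-population segregation counts and line-level height summaries.

#' Segregation counts of the dwarf-mutant cross populations
#'
#' Tall / semi-dwarf / dwarf plant counts for the parents, F1, F2 and both
#' backcrosses, with each population's total size and the expected
#' single-locus ratio. Height classes use the 110/170 cm thresholds of
#' [height_class_rule()]. `n_total` can exceed the classified total (the F2
#' had 576 plants of which 566 were classified); pass it as `total` to
#' [chi_square_gof()].
#'
#' @return data.frame: population, n_total, tall, semi_dwarf, dwarf,
#'   expected_ratio.
#' @export
study_segregation_counts <- function() {
  utils::read.table(system.file("extdata", "segregation_counts.tsv",
                                package = "dwarfmapr"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Line-level height summaries (mean and SD, cm)
#'
#' Average mature plant heights of the dwarf mutants, the wild-type parent
#' line and the F1 hybrid.
#'
#' @return data.frame: line, height_mean_cm, height_sd_cm.
#' @export
study_phenotype_summary <- function() {
  utils::read.table(system.file("extdata", "phenotype_summary.tsv",
                                package = "dwarfmapr"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}
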