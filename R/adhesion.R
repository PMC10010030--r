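## Adhesion-assay classification: forestomach-epithelium colonization of a
## strain relative to the rodent-adapted reference strain. The printed
## thresholds are self-consistent: 10% of the reference corresponds to
## 6.6 log10 CFU/g and 20% to 6.9 log10, both implying a reference density
## of 7.6 log10 CFU/g.

#' Relative adherence (percent of the reference strain)
#'
#' percent = 100 * 10^(strain - reference), both on the log10 CFU/g scale.
#'
#' @param strain_log10,reference_log10 adherent cell densities, log10 CFU/g.
#' @return percent relative adherence.
#' @export
relative_adherence <- function(strain_log10, reference_log10) {
  if (!all(is.finite(c(strain_log10, reference_log10))))
    stop_input("non-finite adhesion values")
  100 * 10^(strain_log10 - reference_log10)
}

#' Classify epithelial adhesion
#'
#' Effective iff log10 CFU/g >= `effective_log10` (6.9, equivalently >= 20%
#' of the reference), ineffective iff <= `ineffective_log10` (6.6, <= 10%),
#' intermediate in the unassigned gap between the two published thresholds.
#' Boundary equality goes to the adjacent definitive class.
#'
#' @param log10_cfu_g adherent cell density (vectorized).
#' @param effective_log10,ineffective_log10 class thresholds.
#' @return character vector in \{"effective", "intermediate", "ineffective"\}.
#' @export
classify_adhesion <- function(log10_cfu_g, effective_log10 = 6.9,
                              ineffective_log10 = 6.6) {
  ifelse(log10_cfu_g >= effective_log10, "effective",
         ifelse(log10_cfu_g <= ineffective_log10, "ineffective",
                "intermediate"))
}

#' Classify an adhesion assay table
#'
#' Adds relative percent, class, and a bubble-size column (area proportional
#' to the log-transformed relative count, for plotting) to an assay table.
#'
#' @param assay data.frame with columns `strain` and `log10_cfu_g`.
#' @param reference_log10 reference-strain density (default 7.6).
#' @return the table with `relative_percent`, `class` and `bubble_area`
#'   columns.
#' @export
classify_adhesion_table <- function(assay, reference_log10 = 7.6) {
  assay$relative_percent <- relative_adherence(assay$log10_cfu_g,
                                               reference_log10)
  assay$class <- classify_adhesion(assay$log10_cfu_g)
  assay$bubble_area <- pmax(log10(assay$relative_percent), 0)
  assay
}
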