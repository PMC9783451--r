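#' Field survey tallies
#'
#' The published count data from the wing surveys: the rattling fraction
#' among field-sampled and lab-born males (file-gap scoring), and scraper
#' prevalence in the Wailua population in 2015 vs 2019.
#'
#' @return A tibble: `survey`, `trait`, `positive`, `total`.
#' @export
survey_counts <- function() {
  tibble(
    survey = c("field_2020", "lab_born", "wailua_2015", "wailua_2019"),
    trait = c("file_gaps", "file_gaps", "scraper", "scraper"),
    positive = c(8L, 13L, 0L, 16L),
    total = c(31L, 48L, 27L, 27L)
  )
}

#' Percentages from survey counts
#'
#' @param counts A count tibble as from [survey_counts()].
#' @return The input with a `percent` column (`100 * positive / total`).
#' @export
count_percentages <- function(counts = survey_counts()) {
  dplyr::mutate(as_tibble(counts),
                percent = 100 * .data$positive / .data$total)
}
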