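#' Assemble the individuals x traits matrix
#'
#' Joins calling-song, courtship-song and wing feature tables on
#' `individual_id` into the scaled trait matrix used for morph discovery.
#' With the default feature set this yields 33 traits per complete-case
#' individual: 9 calling-song + 9 courtship-song characteristics and 15
#' continuous wing variables (harp width, mirror size and 13 shape PC
#' scores). The categorical structure scores (scraper/mirror/file gaps)
#' are kept for classification and the scraper analyses rather than
#' entering the default clustering set; pass an explicit `traits` vector
#' to include them (they are encoded 0/1 before scaling).
#'
#' A missing mirror is a real phenotype, not missing data: `mirror_size`
#' is recorded as 0 for mirror-absent wings so those individuals are not
#' lost to complete-case filtering.
#'
#' @param song_features Tibble from [extract_song_features()] rows, with
#'   `individual_id`, `song_type` and the nine feature columns; both song
#'   types are expected per individual.
#' @param wing_features Tibble from [extract_wing_features()].
#' @param require_complete Drop individuals with any missing trait
#'   (default). Dropped IDs are reported via a message and stored in the
#'   `"dropped_ids"` attribute.
#' @param traits Optional explicit character vector of trait columns to
#'   keep (post-join names), for configurations other than the default.
#' @return A tibble: `individual_id` plus z-scored numeric trait columns
#'   (each mean 0, SD 1). Attributes: `"scaling"` (per-trait mean/sd
#'   tibble), `"dropped_ids"`.
#' @export
assemble_trait_matrix <- function(song_features, wing_features,
                                  require_complete = TRUE, traits = NULL) {
  song_features <- as_tibble(song_features)
  wing_features <- as_tibble(wing_features)
  feats <- intersect(song_feature_names(), names(song_features))
  wide <- tidyr::pivot_wider(
    dplyr::select(song_features, dplyr::all_of(c("individual_id", "song_type",
                                                 feats))),
    names_from = "song_type", values_from = dplyr::all_of(feats),
    names_glue = "{song_type}_{.value}")
  wing <- dplyr::mutate(
    wing_features,
    mirror_size = dplyr::if_else(!.data$mirror_present &
                                   is.na(.data$mirror_size),
                                 0, .data$mirror_size),
    dplyr::across(dplyr::any_of(c("scraper_present", "mirror_present",
                                  "file_gaps_present")), as.numeric))
  joined <- dplyr::inner_join(wide, wing, by = "individual_id")
  if (nrow(joined) == 0L) {
    abort("no individuals shared between song and wing feature tables")
  }
  trait_cols <- traits %||%
    setdiff(names(joined),
            c("individual_id", "scraper_present", "mirror_present",
              "file_gaps_present"))
  missing_cols <- setdiff(trait_cols, names(joined))
  if (length(missing_cols) > 0) {
    abort(paste0("requested traits not present: ",
                 paste(missing_cols, collapse = ", ")))
  }
  joined <- dplyr::select(joined, dplyr::all_of(c("individual_id", trait_cols)))
  dropped <- character(0)
  if (require_complete) {
    ok <- complete.cases(joined[trait_cols])
    dropped <- joined$individual_id[!ok]
    if (length(dropped) > 0) {
      inform(paste0("dropped ", length(dropped),
                    " incomplete individual(s): ",
                    paste(dropped, collapse = ", ")))
    }
    joined <- joined[ok, ]
  }
  if (nrow(joined) < 2L) abort("fewer than 2 complete-case individuals")
  mu <- vapply(joined[trait_cols], mean, numeric(1))
  sig <- vapply(joined[trait_cols], sd, numeric(1))
  flat <- trait_cols[sig <= 0 | !is.finite(sig)]
  if (length(flat) > 0) {
    abort(paste0("zero-variance trait(s) cannot be scaled: ",
                 paste(flat, collapse = ", ")))
  }
  for (tc in trait_cols) joined[[tc]] <- (joined[[tc]] - mu[tc]) / sig[tc]
  attr(joined, "scaling") <- tibble(trait = trait_cols, mean = unname(mu),
                                    sd = unname(sig))
  attr(joined, "dropped_ids") <- dropped
  joined
}

.trait_values <- function(trait_matrix) {
  m <- as.matrix(trait_matrix[setdiff(names(trait_matrix), "individual_id")])
  rownames(m) <- trait_matrix$individual_id
  m
}
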