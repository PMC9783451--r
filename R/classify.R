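#' Default diagnostic traits for morph classification
#'
#' The phenotypic characteristics that separate morphs in the cluster
#' analysis and are available even when only one song type was recorded.
#' @return Character vector of trait names.
#' @export
diagnostic_traits <- function() {
  c("mirror_present", "harp_width", "amplitude_db", "frequency_evenness",
    "dominant_frequency", "file_gaps_present")
}

#' Name clusters as morphs
#'
#' Maps integer cluster labels to morph names using the phenotypes that
#' define each morph: the cluster in which file gaps predominate is
#' `rattling`; of the rest, the quietest (lowest mean calling-song
#' amplitude) is `purring` and the loudest is `ancestral`; any further
#' clusters are labelled `other`.
#'
#' @param labels Integer cluster labels named by individual id.
#' @param features A data frame keyed by `individual_id` with at least
#'   `file_gaps_present` and a calling-song amplitude column
#'   (`calling_amplitude_db` or `amplitude_db`).
#' @return Named character vector of morph labels, same order as `labels`.
#' @export
name_morph_clusters <- function(labels, features) {
  features <- as_tibble(features)
  amp_col <- intersect(c("calling_amplitude_db", "amplitude_db"),
                       names(features))[1]
  if (is.na(amp_col)) abort("features must contain a calling-song amplitude column")
  df <- tibble(individual_id = names(labels), cluster = as.integer(labels))
  df <- dplyr::left_join(df, features, by = "individual_id")
  per <- dplyr::summarise(
    dplyr::group_by(df, .data$cluster),
    gap_frac = mean(as.numeric(.data$file_gaps_present)),
    amp = mean(.data[[amp_col]]), .groups = "drop")
  morph <- rep("other", nrow(per))
  rattling <- which(per$gap_frac >= 0.5)
  if (length(rattling) > 0) {
    morph[rattling[which.max(per$gap_frac[rattling])]] <- "rattling"
  }
  rest <- which(morph == "other")
  if (length(rest) > 0) morph[rest[which.min(per$amp[rest])]] <- "purring"
  rest <- which(morph == "other")
  if (length(rest) > 0) morph[rest[which.max(per$amp[rest])]] <- "ancestral"
  setNames(morph[match(df$cluster, per$cluster)], df$individual_id)
}

#' Morph assignment from a clustering
#'
#' @param gap A [gap_statistic()] result (labels at `best_k`) or a named
#'   integer label vector.
#' @param features Feature table used to name clusters (see
#'   [name_morph_clusters()]).
#' @return A `morph_assignment` tibble: `individual_id`, `morph`, `method`
#'   (`"clustered"`), `cluster`.
#' @export
assign_morphs <- function(gap, features) {
  labels <- if (inherits(gap, "gap_result")) gap$labels else gap
  morphs <- name_morph_clusters(labels, features)
  out <- tibble(individual_id = names(labels),
                morph = unname(morphs),
                method = "clustered",
                cluster = as.integer(unname(labels)))
  class(out) <- c("morph_assignment", class(out))
  out
}

#' Nearest-centroid morph classification
#'
#' Operationalises the manual classification of individuals that lack the
#' complete data required for clustering: morph centroids are computed on
#' z-scored diagnostic traits of the training (clustered) individuals, and
#' each candidate is assigned the morph of its nearest centroid (Euclidean
#' distance; binary flags encoded 0/1). Works when only one song type is
#' available, as long as the diagnostic traits are present. Ties go to the
#' lowest-index morph (training factor order) with a warning.
#'
#' @param features Candidate feature table keyed by `individual_id`,
#'   containing the diagnostic trait columns.
#' @param training_features Feature table for the clustered individuals.
#' @param training_assignment A `morph_assignment` (or data frame with
#'   `individual_id`, `morph`) for the training individuals.
#' @param traits Diagnostic trait columns; default [diagnostic_traits()].
#' @return A `morph_assignment` tibble with `method = "rule_classified"`
#'   and one `dist_<morph>` diagnostic column per training morph.
#' @export
classify_nearest_centroid <- function(features, training_features,
                                      training_assignment,
                                      traits = diagnostic_traits()) {
  features <- as_tibble(features)
  training_features <- as_tibble(training_features)
  traits <- intersect(traits, names(training_features))
  traits <- intersect(traits, names(features))
  if (length(traits) == 0L) {
    abort("no diagnostic traits shared between candidates and training data")
  }
  train <- dplyr::inner_join(
    dplyr::select(as_tibble(training_assignment), "individual_id", "morph"),
    training_features, by = "individual_id")
  num <- function(df) {
    m <- vapply(traits, function(tc) as.numeric(df[[tc]]),
                numeric(nrow(df)))
    matrix(m, nrow = nrow(df), dimnames = list(NULL, traits))
  }
  xt <- num(train)
  mu <- colMeans(xt)
  sig <- apply(xt, 2, sd)
  sig[sig <= 0 | !is.finite(sig)] <- 1      # flat trait: leave unscaled
  scale_mat <- function(m) sweep(sweep(m, 2, mu), 2, sig, "/")
  xt <- scale_mat(xt)
  morph_levels <- unique(train$morph)
  centroids <- t(vapply(morph_levels, function(m) {
    colMeans(xt[train$morph == m, , drop = FALSE])
  }, numeric(length(traits))))
  xc <- scale_mat(num(features))
  if (any(!is.finite(xc))) {
    abort("candidates have missing values in the diagnostic traits")
  }
  d <- vapply(seq_len(nrow(centroids)), function(i) {
    sqrt(rowSums(sweep(xc, 2, centroids[i, ])^2))
  }, numeric(nrow(xc)))
  d <- matrix(d, nrow = nrow(xc))
  pick <- apply(d, 1, function(row) {
    hits <- which(row == min(row))
    if (length(hits) > 1) {
      warn("candidate equidistant from multiple morph centroids; using the first")
    }
    hits[1]
  })
  out <- tibble(individual_id = features$individual_id,
                morph = morph_levels[pick],
                method = "rule_classified")
  for (i in seq_along(morph_levels)) {
    out[[paste0("dist_", morph_levels[i])]] <- d[, i]
  }
  class(out) <- c("morph_assignment", class(out))
  out
}
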