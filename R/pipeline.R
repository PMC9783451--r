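#' Extract song and wing features from a synthetic cohort
#'
#' Runs [extract_song_features()] over every recording and
#' [extract_wing_features()] over the wings (with a shared Procrustes
#' alignment).
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param bands Band table for the song features.
#' @param window_size,overlap Spectral settings.
#' @param n_shape_axes Shape PC scores to keep.
#' @return List with `song_features` and `wing_features` tibbles.
#' @export
extract_cohort_features <- function(cohort, bands = default_bands(),
                                    window_size = 256, overlap = 0.5,
                                    n_shape_axes = 13) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  song_features <- purrr::map_dfr(
    cohort$songs, extract_song_features, bands = bands,
    window_size = window_size, overlap = overlap)
  wing_features <- extract_wing_features(cohort$wings, cohort$flags,
                                         n_shape_axes = n_shape_axes)
  list(song_features = song_features, wing_features = wing_features)
}

#' Combine wing features with calling-song features
#'
#' The unscaled per-individual table used for cluster naming, nearest-
#' centroid classification and the form-function correlation grid.
#'
#' @param song_features Long song feature table (both song types).
#' @param wing_features Wing feature table.
#' @return A tibble keyed by `individual_id` with the wing columns and the
#'   nine calling-song feature columns (unprefixed).
#' @export
combine_features <- function(song_features, wing_features) {
  calling <- dplyr::filter(as_tibble(song_features),
                           .data$song_type == "calling")
  calling <- dplyr::select(calling, "individual_id",
                           dplyr::all_of(intersect(song_feature_names(),
                                                   names(calling))))
  dplyr::inner_join(as_tibble(wing_features), calling, by = "individual_id")
}

#' Pipeline configuration
#'
#' @param n_individuals,morph_proportions,archetypes,seed,sample_rate,duration_s
#'   Cohort settings (see [cohort_spec()]).
#' @param bands Band table for song features.
#' @param window_size,overlap Spectral settings.
#' @param k_max,B,rule Gap-statistic settings.
#' @param n_shape_axes Shape PC scores kept as wing traits.
#' @param threshold_curve Optional [threshold_curve()] (or node data frame
#'   / CSV path) enabling the detectability stage.
#' @param phonotaxis Logical: simulate phonotaxis trials and fit the
#'   stimulus model.
#' @param response_probs,n_females Phonotaxis simulation settings.
#' @param out_dir Optional directory for the report files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_individuals = 59,
                            morph_proportions = c(ancestral = 0.40,
                                                  purring = 0.33,
                                                  rattling = 0.27),
                            archetypes = default_archetypes(),
                            seed = 1, sample_rate = 44100, duration_s = 0.5,
                            bands = default_bands(),
                            window_size = 256, overlap = 0.5,
                            k_max = 10, B = 50, rule = "firstSEmax",
                            n_shape_axes = 13,
                            threshold_curve = NULL, phonotaxis = FALSE,
                            response_probs = c(ancestral = 0.9,
                                               rattling = 0.6,
                                               purring = 0.3,
                                               white_noise = 0.02),
                            n_females = 30,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar settings are read from the YAML mapping; unspecified settings
#' keep the [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$morph_proportions)) {
    raw$morph_proportions <- unlist(raw$morph_proportions)
  }
  if (!is.null(raw$response_probs)) {
    raw$response_probs <- unlist(raw$response_probs)
  }
  if (!is.null(raw$bands)) raw$bands <- as_tibble(raw$bands)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' simulate -> extract -> cluster -> classify -> form-function ->
#' receiver. Every stage is driven by the single seed in the config; the
#' returned report (and any files written to `out_dir`) are deterministic
#' given the config.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list: `morph_counts`, `gap`,
#'   `assignment`, `agreement` (cluster vs generator labels),
#'   `formfunction`, `manovas`, `detectability` (when a threshold curve is
#'   configured), `phonotaxis` (when enabled), `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  cohort <- stage("simulate", generate_cohort(cohort_spec(
    n_individuals = config$n_individuals,
    morph_proportions = config$morph_proportions,
    archetypes = config$archetypes, seed = config$seed,
    sample_rate = config$sample_rate, duration_s = config$duration_s)))
  feats <- stage("extract", extract_cohort_features(
    cohort, bands = config$bands, window_size = config$window_size,
    overlap = config$overlap, n_shape_axes = config$n_shape_axes))
  tm <- stage("assemble", assemble_trait_matrix(feats$song_features,
                                                feats$wing_features))
  gap <- stage("cluster", gap_statistic(tm, k_max = config$k_max,
                                        B = config$B, seed = config$seed,
                                        rule = config$rule))
  combined <- combine_features(feats$song_features, feats$wing_features)
  assignment <- stage("classify", assign_morphs(gap, combined))
  agreement <- dplyr::inner_join(assignment, cohort$metadata,
                                 by = "individual_id",
                                 suffix = c("_assigned", "_true"))
  agreement_rate <- mean(agreement$morph_assigned == agreement$morph_true)
  ff <- stage("formfunction", formfunction_report(combined, assignment))
  manovas <- stage("manova", .pipeline_manovas(feats, assignment))
  report <- list(
    morph_counts = dplyr::count(assignment, .data$morph, name = "n"),
    gap = gap, assignment = assignment,
    agreement = agreement_rate,
    formfunction = ff, manovas = manovas,
    log = list(seed = config$seed, n_individuals = config$n_individuals,
               morph_proportions = as.list(config$morph_proportions),
               window_size = config$window_size, overlap = config$overlap,
               k_max = config$k_max, B = config$B, rule = config$rule,
               sample_rate = config$sample_rate,
               duration_s = config$duration_s,
               bands = as.list(config$bands))
  )
  if (!is.null(config$threshold_curve)) {
    curve <- if (inherits(config$threshold_curve, "threshold_curve")) {
      config$threshold_curve
    } else threshold_curve(config$threshold_curve)
    report$detectability <- stage("detectability", {
      dplyr::summarise(
        dplyr::group_by(
          dplyr::inner_join(combined,
                            dplyr::select(assignment, "individual_id",
                                          "morph"),
                            by = "individual_id"),
          .data$morph),
        median_dominant_hz = median(.data$dominant_frequency),
        required_db = required_amplitude(.data$median_dominant_hz, curve),
        .groups = "drop")
    })
  }
  if (isTRUE(config$phonotaxis)) {
    report$phonotaxis <- stage("phonotaxis", {
      trials <- generate_phonotaxis_trials(
        response_probs = config$response_probs,
        n_females = config$n_females, seed = config$seed)
      fit <- fit_phonotaxis(trials)
      list(trials = trials, fit = fit,
           contrasts = pairwise_contrasts(fit))
    })
  }
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_pipeline_report(report, config$out_dir)
  report
}

.pipeline_manovas <- function(feats, assignment) {
  morph_of <- setNames(assignment$morph, assignment$individual_id)
  song_manova <- function(type) {
    sub <- dplyr::filter(feats$song_features, .data$song_type == type)
    sub <- sub[sub$individual_id %in% names(morph_of), ]
    m <- as.matrix(sub[intersect(song_feature_names(), names(sub))])
    pcs <- prcomp(m, center = TRUE, scale. = TRUE)$x[, 1:2]
    manova_pillai(pcs, morph_of[sub$individual_id])
  }
  wing_manova <- function() {
    cols <- grep("^shape_pc", names(feats$wing_features), value = TRUE)[1:2]
    sub <- feats$wing_features[feats$wing_features$individual_id %in%
                                 names(morph_of), ]
    manova_pillai(as.matrix(sub[cols]), morph_of[sub$individual_id])
  }
  dplyr::bind_rows(
    dplyr::mutate(song_manova("calling"), analysis = "calling_song"),
    dplyr::mutate(song_manova("courtship"), analysis = "courtship_song"),
    dplyr::mutate(wing_manova(), analysis = "wing_shape")
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  best k: %d; cluster-truth agreement: %.1f%%\n",
              x$gap$best_k, 100 * x$agreement))
  cat("  morph counts: ",
      paste(x$morph_counts$morph, x$morph_counts$n, sep = "=",
            collapse = ", "), "\n")
  cat(sprintf("  decoupling flags: %d of %d trait pairs\n",
              x$formfunction$n_flagged, nrow(x$formfunction$decoupling)))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits plain-text, deterministic outputs: feature-level CSVs, the gap
#' curve, morph assignments, the correlation grid, the decoupling summary
#' (JSON), the dendrogram (Newick) and the run log (JSON; parameters and
#' seeds only, no timestamps).
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_csv(report$morph_counts, p("morph_counts.csv"))
  readr::write_csv(report$gap$table, p("gap_curve.csv"))
  readr::write_csv(as_tibble(report$assignment), p("morphs.csv"))
  readr::write_csv(report$formfunction$grid, p("correlations.csv"))
  readr::write_csv(report$manovas, p("manovas.csv"))
  jsonlite::write_json(
    list(best_k = report$gap$best_k, agreement = report$agreement,
         n_flagged = report$formfunction$n_flagged,
         decoupled_pairs = dplyr::filter(report$formfunction$decoupling,
                                         .data$decoupled)[
                                           c("trait_x", "trait_y")]),
    p("decoupling.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$log, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA)
  if (requireNamespace("ape", quietly = TRUE)) {
    write_dendrogram_newick(report$gap$clustering, p("dendrogram.nwk"))
  }
  if (!is.null(report$detectability)) {
    readr::write_csv(report$detectability, p("detectability.csv"))
  }
  if (!is.null(report$phonotaxis)) {
    readr::write_csv(report$phonotaxis$trials, p("phonotaxis_trials.csv"))
    readr::write_csv(report$phonotaxis$contrasts, p("contrasts.csv"))
  }
  invisible(out_dir)
}
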