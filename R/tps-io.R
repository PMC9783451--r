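#' Read a TPS landmark file
#'
#' Parses the tpsDIG2 dialect of the TPS format: `LM=` records followed by
#' one `x y` pair per line, with optional `IMAGE=`, `ID=` and `SCALE=`
#' records. Coordinates are multiplied by `SCALE` when present. The
#' coordinate convention is tpsDIG's: origin bottom-left, y increasing
#' upward; set `flip_y = TRUE` for digitizers that use image (top-left)
#' coordinates.
#'
#' @param path Path to a `.tps` file.
#' @param n_landmarks Required landmark count per specimen (default 14, the
#'   wing landmark scheme).
#' @param flip_y Negate y coordinates on read.
#' @return A list of [landmark_configuration()] objects, in file order.
#' @export
read_tps <- function(path, n_landmarks = 14, flip_y = FALSE) {
  if (!file.exists(path)) abort(paste0("TPS file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  configs <- list()
  i <- 1L
  spec_no <- 0L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", line, ignore.case = TRUE)) {
      abort(paste0("malformed TPS record at line ", i,
                   ": expected 'LM=' but found '", line, "'"))
    }
    spec_no <- spec_no + 1L
    lm <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", line,
                                          ignore.case = TRUE)))
    if (is.na(lm)) abort(paste0("unparseable LM= count at line ", i))
    coords <- matrix(NA_real_, nrow = lm, ncol = 2)
    for (j in seq_len(lm)) {
      i <- i + 1L
      if (i > length(lines)) {
        abort(paste0("specimen ", spec_no, ": file ends before all ",
                     lm, " landmarks were read"))
      }
      xy <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                 "\\s+")[[1]]))
      if (length(xy) != 2L || any(is.na(xy))) {
        abort(paste0("malformed coordinate line ", i,
                     " (specimen ", spec_no, "): '", lines[i], "'"))
      }
      coords[j, ] <- xy
    }
    id <- NULL
    scale <- 1
    i <- i + 1L
    while (i <= length(lines) &&
           grepl("^(IMAGE|ID|SCALE)\\s*=", trimws(lines[i]),
                 ignore.case = TRUE)) {
      kv <- trimws(lines[i])
      if (grepl("^ID\\s*=", kv, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", kv, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", kv, ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", kv, ignore.case = TRUE))
        if (is.na(scale)) abort(paste0("unparseable SCALE= at line ", i))
      } else if (is.null(id)) {
        id <- sub("^IMAGE\\s*=\\s*", "", kv, ignore.case = TRUE)
      }
      i <- i + 1L
    }
    if (lm != n_landmarks) {
      abort(paste0("specimen ", id %||% spec_no, " has LM=", lm,
                   " landmarks; expected ", n_landmarks))
    }
    if (flip_y) coords[, 2] <- -coords[, 2]
    configs[[spec_no]] <- landmark_configuration(
      coords * scale,
      individual_id = id %||% paste0("specimen_", spec_no),
      scale_mm_per_unit = scale
    )
  }
  configs
}

#' Write landmark configurations as TPS
#'
#' @param configs A list of [landmark_configuration()] objects or a single
#'   configuration.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (inherits(configs, "landmark_configuration")) configs <- list(configs)
  out <- unlist(lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    c(paste0("LM=", nrow(cfg$points)),
      sprintf("%.8g %.8g", cfg$points[, 1], cfg$points[, 2]),
      paste0("ID=", cfg$individual_id))
  }))
  writeLines(out, path)
  invisible(path)
}
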