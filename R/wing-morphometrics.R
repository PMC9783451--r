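#' Construct a landmark configuration
#'
#' Fourteen ordered (x, y) landmarks digitised on a right wing, in
#' calibrated image coordinates (bottom-left origin, y upward). Landmark
#' indices are 1-based throughout: landmarks 5 and 14 bound the harp along
#' the x-axis, landmarks 6-11 mark the mirror perimeter.
#'
#' @param points A 14 x 2 numeric matrix (or anything coercible).
#' @param individual_id Identifier string.
#' @param scale_mm_per_unit Optional calibration (mm per coordinate unit)
#'   already applied to `points`; recorded as metadata.
#' @param n_landmarks Expected landmark count.
#' @return An object of class `landmark_configuration`.
#' @export
landmark_configuration <- function(points, individual_id = "unknown",
                                   scale_mm_per_unit = NA_real_,
                                   n_landmarks = 14) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) abort("points must have two columns (x, y)")
  if (nrow(points) != n_landmarks) {
    abort(paste0("expected ", n_landmarks, " landmarks, got ", nrow(points)))
  }
  if (any(!is.finite(points))) abort("landmark coordinates must be finite")
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  if (any(d < 1e-12)) {
    warn(paste0("configuration ", individual_id,
                " contains coincident landmarks"))
  }
  structure(
    list(points = unname(points), individual_id = as.character(individual_id),
         scale_mm_per_unit = scale_mm_per_unit),
    class = "landmark_configuration"
  )
}

#' @export
print.landmark_configuration <- function(x, ...) {
  cat(sprintf("<landmark_configuration> %s: %d landmarks\n",
              x$individual_id, nrow(x$points)))
  invisible(x)
}

#' Centroid size of a landmark set
#'
#' Square root of the summed squared distances of the points to their
#' centroid; the standard geometric-morphometrics size measure. Invariant
#' to rotation and translation; scales linearly under isotropic scaling.
#'
#' @param points An n x 2 coordinate matrix (n >= 2) or a
#'   `landmark_configuration`.
#' @return Centroid size in the units of the coordinates.
#' @export
centroid_size <- function(points) {
  if (inherits(points, "landmark_configuration")) points <- points$points
  points <- as.matrix(points)
  if (nrow(points) < 2L) abort("centroid size needs at least 2 points")
  centred <- sweep(points, 2, colMeans(points))
  cs <- sqrt(sum(centred^2))
  if (cs < 1e-12) abort("degenerate configuration: all points identical")
  cs
}

#' Harp width
#'
#' Linear distance along the x-axis between landmarks 5 and 14, on
#' calibrated raw coordinates (pre-Procrustes, since alignment would
#' destroy size).
#'
#' @param config A [landmark_configuration()].
#' @return Harp width in calibrated units.
#' @export
harp_width <- function(config) {
  stopifnot(inherits(config, "landmark_configuration"))
  w <- abs(config$points[5, 1] - config$points[14, 1])
  if (w < 1e-12) {
    warn(paste0("degenerate harp width for ", config$individual_id,
                ": landmarks 5 and 14 share an x coordinate"))
  }
  w
}

#' Mirror size
#'
#' Centroid size of the mirror-perimeter landmarks (6-11), on calibrated
#' raw coordinates. Returns `NA` when the mirror is absent.
#'
#' @param config A [landmark_configuration()].
#' @param mirror_present Logical flag for this specimen.
#' @return Centroid size, or `NA_real_` when `mirror_present` is `FALSE`.
#' @export
mirror_size <- function(config, mirror_present = TRUE) {
  stopifnot(inherits(config, "landmark_configuration"))
  if (!isTRUE(mirror_present)) return(NA_real_)
  centroid_size(config$points[6:11, , drop = FALSE])
}

#' Generalized Procrustes alignment
#'
#' Iterative superimposition of landmark configurations: each configuration
#' is centred, scaled to unit centroid size, and rotated (ordinary
#' least-squares, proper rotations) to the current mean shape; the mean is
#' re-estimated until its change falls below `tol`.
#'
#' @param configs List of [landmark_configuration()] objects (>= 2, equal
#'   landmark counts).
#' @param tol Convergence tolerance on the root-mean-square change of the
#'   mean shape.
#' @param max_iter Iteration cap; hitting it is reported, not an error.
#' @return A `procrustes_result`: `aligned` (list of k x 2 matrices),
#'   `mean_shape`, `centroid_sizes` (pre-scaling sizes), `ids`,
#'   `iterations`, `final_change`, `converged`.
#' @export
generalized_procrustes <- function(configs, tol = 1e-10, max_iter = 100) {
  if (length(configs) < 2L) abort("need at least 2 configurations")
  mats <- lapply(configs, function(cfg) {
    stopifnot(inherits(cfg, "landmark_configuration"))
    cfg$points
  })
  k <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 1L) != k)) {
    abort("all configurations must have the same landmark count")
  }
  ids <- vapply(configs, function(cfg) cfg$individual_id, character(1))
  sizes <- numeric(length(mats))
  for (i in seq_along(mats)) {
    ctr <- sweep(mats[[i]], 2, colMeans(mats[[i]]))
    cs <- sqrt(sum(ctr^2))
    if (cs < 1e-12) abort(paste0("degenerate configuration: ", ids[i]))
    sizes[i] <- cs
    mats[[i]] <- ctr / cs
  }
  rotate_to <- function(x, target) {
    m <- crossprod(x, target)
    sv <- svd(m)
    r <- sv$v %*% t(sv$u)
    if (det(r) < 0) {            # force a proper rotation
      sv$v[, 2] <- -sv$v[, 2]
      r <- sv$v %*% t(sv$u)
    }
    x %*% t(r)
  }
  mean_shape <- mats[[1]]
  iterations <- 0L
  change <- Inf
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    mats <- lapply(mats, rotate_to, target = mean_shape)
    new_mean <- Reduce(`+`, mats) / length(mats)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    change <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (change < tol) break
  }
  # final pass so every configuration is aligned to the converged mean
  mats <- lapply(mats, rotate_to, target = mean_shape)
  structure(
    list(aligned = mats,
         mean_shape = Reduce(`+`, mats) / length(mats),
         centroid_sizes = sizes, ids = ids,
         iterations = iterations, final_change = change,
         converged = change < tol),
    class = "procrustes_result"
  )
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf(
    "<procrustes_result> %d specimens, %d landmarks; %d iterations (change %.2e)\n",
    length(x$aligned), nrow(x$mean_shape), x$iterations, x$final_change))
  invisible(x)
}

#' Shape PCA on Procrustes-aligned coordinates
#'
#' Covariance-based PCA of the flattened aligned coordinates. Axis signs
#' follow the convention that the largest-magnitude loading on each
#' component is positive, so scores are invariant to specimen order.
#'
#' @param gpa A `procrustes_result`.
#' @param n_axes Number of leading components to return.
#' @return A tibble with `individual_id` and `shape_pc1` .. columns;
#'   the `prcomp` fit is attached as attribute `"pca"`.
#' @export
shape_pca <- function(gpa, n_axes = 10) {
  stopifnot(inherits(gpa, "procrustes_result"))
  flat <- t(vapply(gpa$aligned, function(m) as.numeric(m),
                   numeric(length(gpa$aligned[[1]]))))
  fit <- prcomp(flat, center = TRUE, scale. = FALSE)
  n_axes <- min(n_axes, ncol(fit$x))
  for (j in seq_len(n_axes)) {
    top <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[top, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  out <- as_tibble(fit$x[, seq_len(n_axes), drop = FALSE],
                   .name_repair = ~ paste0("shape_pc", seq_len(n_axes)))
  out <- dplyr::bind_cols(tibble(individual_id = gpa$ids), out)
  attr(out, "pca") <- fit
  out
}

#' Extract wing features for a set of specimens
#'
#' Combines the physical structure measures (harp width and mirror size on
#' calibrated raw coordinates), the categorical structure flags, and shape
#' PC scores from a generalized Procrustes alignment.
#'
#' @param configs List of [landmark_configuration()] objects.
#' @param flags A data frame with columns `individual_id`, `scraper_present`,
#'   `mirror_present`, `file_gaps_present` (logical or 0/1).
#' @param gpa_context Optional precomputed `procrustes_result`; computed
#'   from `configs` when `NULL` and `n_shape_axes > 0`.
#' @param n_shape_axes Number of shape PC score columns (0 to skip).
#' @return A tibble, one row per specimen: `individual_id`, `harp_width`,
#'   `mirror_size` (`NA` when the mirror is absent), the three flags, and
#'   `shape_pc*` columns.
#' @export
extract_wing_features <- function(configs, flags, gpa_context = NULL,
                                  n_shape_axes = 13) {
  flags <- as_tibble(flags)
  need <- c("individual_id", "scraper_present", "mirror_present",
            "file_gaps_present")
  if (!all(need %in% names(flags))) {
    abort(paste0("flags must have columns: ", paste(need, collapse = ", ")))
  }
  flags <- dplyr::mutate(flags, dplyr::across(
    dplyr::all_of(need[-1]), ~ as.logical(as.numeric(.x))))
  ids <- vapply(configs, function(cfg) cfg$individual_id, character(1))
  missing_flags <- setdiff(ids, flags$individual_id)
  if (length(missing_flags) > 0) {
    abort(paste0("no structure flags for: ",
                 paste(missing_flags, collapse = ", ")))
  }
  flags <- flags[match(ids, flags$individual_id), ]
  out <- tibble(
    individual_id = ids,
    harp_width = vapply(configs, harp_width, numeric(1)),
    mirror_size = vapply(seq_along(configs), function(i) {
      mirror_size(configs[[i]], flags$mirror_present[i])
    }, numeric(1)),
    scraper_present = flags$scraper_present,
    mirror_present = flags$mirror_present,
    file_gaps_present = flags$file_gaps_present
  )
  if (n_shape_axes > 0 && length(configs) >= 3) {
    gpa <- gpa_context %||% generalized_procrustes(configs)
    out <- dplyr::left_join(out, shape_pca(gpa, n_shape_axes),
                            by = "individual_id")
  }
  out
}
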