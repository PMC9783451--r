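#' Gap statistic for choosing the number of morphs
#'
#' For each candidate k the within-cluster dispersion `W_k` (half the mean
#' within-cluster pairwise distance sum, raised to `d_power`) is computed
#' from cuts of a Ward.D2 hierarchy, and compared with the expected
#' dispersion under `B` uniform reference datasets:
#' `gap(k) = mean(log W*_k) - log W_k`. The standard error `s_k` is the SD
#' of `log W*_k` inflated by `sqrt(1 + 1/B)`. The default reference space
#' (`"scaledPCA"`) draws uniformly over the ranges of the principal axes of
#' the centred data and rotates back, so the null box follows the data's
#' orientation; `"original"` draws over each observed trait range.
#'
#' @param x A trait matrix tibble (see [assemble_trait_matrix()]) or a
#'   numeric matrix of scaled traits.
#' @param k_max Largest candidate k (must be below the row count).
#' @param B Number of reference datasets (>= 10).
#' @param seed Integer seed for the reference draws; the caller's RNG state
#'   is left untouched.
#' @param rule Model-selection rule applied to the gap curve:
#'   `"firstSEmax"` (default), `"globalmax"`, or `"Tibshirani"` (the
#'   original 1-SE rule).
#' @param se_factor Multiplier on `s_k` in the SE-based rules.
#' @param reference `"scaledPCA"` (default) or `"original"` null reference.
#' @param d_power Power applied to pairwise distances in `W_k` (1 default;
#'   2 gives the sum-of-squares-to-centroid dispersion).
#' @return A `gap_result`: tibble-backed `table` (k, log_w, log_w_ref, gap,
#'   se), `best_k`, `labels` (cluster labels at `best_k`), `B`, `seed`,
#'   `rule`, and the `ward_clustering` of the observed data.
#' @export
gap_statistic <- function(x, k_max = 10, B = 100, seed = 1,
                          rule = c("firstSEmax", "globalmax", "Tibshirani"),
                          se_factor = 1,
                          reference = c("scaledPCA", "original"),
                          d_power = 1) {
  rule <- match.arg(rule)
  reference <- match.arg(reference)
  if (is.data.frame(x)) x <- .trait_values(x)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k_max < 1) abort("k_max must be >= 1")
  if (k_max >= n) abort("k_max must be smaller than the number of rows")
  if (B < 10) abort("B must be >= 10 reference datasets")
  ks <- seq_len(k_max)
  cl <- ward_cluster(x)
  log_w <- log(vapply(ks, function(k) {
    .within_dispersion(x, cut_clusters(cl, k), d_power)
  }, numeric(1)))
  if (reference == "scaledPCA") {
    ctr <- sweep(x, 2, colMeans(x))
    rot <- svd(ctr, nu = 0)$v
    box <- ctr %*% rot
  } else {
    rot <- NULL
    box <- x
  }
  lo <- apply(box, 2, min)
  hi <- apply(box, 2, max)
  m <- ncol(box)   # can be < ncol(x) when n - 1 < ncol(x)
  log_w_ref <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ref <- matrix(runif(n * m, rep(lo, each = n), rep(hi, each = n)),
                    nrow = n)
      if (!is.null(rot)) ref <- ref %*% t(rot)
      hc <- as.hclust(ward_cluster(ref))
      vapply(ks, function(k) {
        log(.within_dispersion(ref, cutree(hc, k), d_power))
      }, numeric(1))
    }, numeric(k_max))
  })
  log_w_ref <- matrix(log_w_ref, nrow = k_max)
  gap <- rowMeans(log_w_ref) - log_w
  se <- apply(log_w_ref, 1, sd) * sqrt(1 + 1 / B)
  best_k <- select_k(gap, se, rule = rule, se_factor = se_factor)
  structure(
    list(table = tibble(k = ks, log_w = log_w,
                        log_w_ref = rowMeans(log_w_ref), gap = gap, se = se),
         best_k = best_k, labels = cut_clusters(cl, best_k),
         B = B, seed = seed, rule = rule, reference = reference,
         d_power = d_power, clustering = cl),
    class = "gap_result"
  )
}

.within_dispersion <- function(x, labels, d_power = 1) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(stats::dist(xs)^d_power) / nrow(xs)
  }, numeric(1)))
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Select k from a gap curve
#'
#' `"firstSEmax"`: locate the first local maximum of the gap curve, then
#' take the smallest k whose gap is within `se_factor * s` of it.
#' `"globalmax"`: argmax of the gap. `"Tibshirani"`: the smallest k with
#' `gap(k) >= gap(k+1) - se_factor * s(k+1)`.
#'
#' @param gap,se Numeric vectors over k = 1..k_max.
#' @param rule,se_factor See [gap_statistic()].
#' @return The selected k.
#' @export
select_k <- function(gap, se, rule = c("firstSEmax", "globalmax", "Tibshirani"),
                     se_factor = 1) {
  rule <- match.arg(rule)
  k_max <- length(gap)
  stopifnot(length(se) == k_max, k_max >= 1)
  if (rule == "globalmax") return(which.max(gap))
  if (rule == "Tibshirani") {
    if (k_max == 1L) return(1L)
    ok <- gap[-k_max] >= gap[-1] - se_factor * se[-1]
    return(if (any(ok)) which.max(ok) else k_max)
  }
  decr <- diff(gap) <= 0
  first_max <- if (any(decr)) which.max(decr) else k_max
  earlier <- gap[seq_len(first_max - 1L)] >= gap[first_max] -
    se_factor * se[first_max]
  if (any(earlier)) which(earlier)[1L] else first_max
}

#' @export
print.gap_result <- function(x, ...) {
  cat(sprintf("<gap_result> best k = %d (%s rule, B = %d, seed = %d)\n",
              x$best_k, x$rule, x$B, x$seed))
  print(x$table)
  invisible(x)
}

#' @export
tidy.gap_result <- function(x, ...) x$table

#' @export
glance.gap_result <- function(x, ...) {
  tibble(best_k = x$best_k, k_max = nrow(x$table), B = x$B,
         seed = x$seed, rule = x$rule)
}

#' @export
autoplot.gap_result <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$k, .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$se,
                                          ymax = .data$gap + .data$se)) +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$table$k) +
    ggplot2::labs(x = "Number of clusters k", y = "Gap statistic",
                  title = sprintf("Gap curve (best k = %d, %s)",
                                  object$best_k, object$rule)) +
    ggplot2::theme_minimal()
}
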