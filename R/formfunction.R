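#' Pearson correlation with asymptotic t p-value
#'
#' Product-moment correlation with the asymptotic t approximation:
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-sided. Pairs with missing values are dropped (pairwise-complete).
#' With fewer than `min_n` complete pairs, or zero variance in either
#' vector, the entry is returned as NA with a reason rather than an error
#' — insufficient within-group variation is an expected outcome of the
#' within-morph analysis, not a failure.
#'
#' @param x,y Numeric vectors of equal length.
#' @param trait_x,trait_y Names recorded in the output.
#' @param min_n Minimum complete pairs to report a p-value (default 4).
#' @return A one-row tibble: `trait_x`, `trait_y`, `r`, `n`, `t_stat`,
#'   `df`, `p`, `flagged_small_n`, `na_reason`.
#' @export
pearson_with_p <- function(x, y, trait_x = "x", trait_y = "y", min_n = 4) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  na_row <- function(reason) {
    tibble(trait_x = trait_x, trait_y = trait_y, r = NA_real_, n = n,
           t_stat = NA_real_, df = NA_real_, p = NA_real_,
           flagged_small_n = n < min_n, na_reason = reason)
  }
  if (n < 3) return(na_row("fewer than 3 complete pairs"))
  if (sd(x) <= 0 || sd(y) <= 0) return(na_row("insufficient variation"))
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(min(r, 1), -1)
  if (n < min_n) return(na_row("fewer complete pairs than min_n"))
  df <- n - 2
  if (abs(r) >= 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df)
  }
  tibble(trait_x = trait_x, trait_y = trait_y, r = r, n = n,
         t_stat = t_stat, df = df, p = p, flagged_small_n = FALSE,
         na_reason = NA_character_)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite (fractional)
#' degrees of freedom and a two-sided p-value.
#'
#' @param x,y Numeric vectors (each n >= 2 with nonzero variance).
#' @return A one-row tibble: `test_name`, `statistic`, `df`, `p`, `n_x`,
#'   `n_y`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) abort("each group needs n >= 2")
  vx <- var(x); vy <- var(y)
  if (vx <= 0 && vy <= 0) abort("both groups are degenerate (zero variance)")
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  tibble(test_name = "welch_t", statistic = t_stat, df = df,
         p = 2 * pt(-abs(t_stat), df),
         n_x = nx, n_y = ny, mean_x = mean(x), mean_y = mean(y))
}

#' Levene / Brown-Forsythe test for homogeneity of variance
#'
#' One-way ANOVA F on absolute deviations from the group center (median by
#' default, the Brown-Forsythe variant; mean gives the classical Levene
#' statistic).
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2), or a
#'   numeric vector with `g` a grouping factor.
#' @param g Optional grouping factor when `groups` is a vector.
#' @param center `"median"` (default) or `"mean"`.
#' @return A one-row tibble: `test_name`, `statistic` (F), `df1`, `df2`,
#'   `p`, `group_ns`.
#' @export
levene_test <- function(groups, g = NULL, center = c("median", "mean")) {
  center <- match.arg(center)
  if (!is.list(groups)) {
    if (is.null(g)) abort("supply groups as a list, or a vector with g")
    groups <- split(as.numeric(groups), g)
  }
  groups <- lapply(groups, function(v) v[is.finite(v)])
  if (length(groups) < 2) abort("need at least 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2)) abort("every group needs n >= 2")
  cfun <- if (center == "median") median else mean
  z <- lapply(groups, function(v) abs(v - cfun(v)))
  k <- length(z)
  n <- sum(ns)
  zbar <- mean(unlist(z))
  zbar_i <- vapply(z, mean, numeric(1))
  ss_between <- sum(ns * (zbar_i - zbar)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) {
    sum((z[[i]] - zbar_i[i])^2)
  }, numeric(1)))
  df1 <- k - 1
  df2 <- n - k
  f_stat <- (ss_between / df1) / (ss_within / df2)
  tibble(test_name = paste0("levene_", center), statistic = f_stat,
         df1 = df1, df2 = df2, p = pf(f_stat, df1, df2, lower.tail = FALSE),
         group_ns = list(unname(ns)))
}

#' MANOVA with Pillai's trace
#'
#' Multivariate one-way comparison of a response matrix (typically PC1-2
#' of a song or wing PCA) across groups. Between- and within-group SSCP
#' matrices give Pillai's trace and its standard approximate F. Wilks'
#' lambda (Rao's F approximation) is available via `statistic`.
#'
#' @param Y Numeric response matrix (rows = individuals).
#' @param groups Grouping factor.
#' @param statistic `"Pillai"` (default) or `"Wilks"`.
#' @return A one-row tibble: `statistic_name`, `statistic_value`,
#'   `approx_f`, `df1`, `df2`, `p`.
#' @export
manova_pillai <- function(Y, groups, statistic = c("Pillai", "Wilks")) {
  statistic <- match.arg(statistic)
  Y <- as.matrix(Y)
  groups <- factor(groups)
  n <- nrow(Y)
  g <- nlevels(groups)
  p <- ncol(Y)
  if (g < 2) abort("need at least 2 groups")
  if (any(table(groups) < 2)) abort("every group needs n >= 2")
  if (n < g + p) abort("too few rows for the response dimension; reduce responses")
  grand <- colMeans(Y)
  H <- matrix(0, p, p)
  E <- matrix(0, p, p)
  for (lev in levels(groups)) {
    yi <- Y[groups == lev, , drop = FALSE]
    mi <- colMeans(yi)
    H <- H + nrow(yi) * tcrossprod(mi - grand)
    E <- E + crossprod(sweep(yi, 2, mi))
  }
  if (abs(det(E)) < 1e-300) {
    abort("singular within-group SSCP; reduce the number of responses")
  }
  q <- g - 1
  s <- min(p, q)
  if (statistic == "Pillai") {
    V <- sum(diag(H %*% solve(H + E)))
    m <- (abs(p - q) - 1) / 2
    nn <- (n - g - p - 1) / 2
    df1 <- s * (2 * m + s + 1)
    df2 <- s * (2 * nn + s + 1)
    f_stat <- ((2 * nn + s + 1) / (2 * m + s + 1)) * V / (s - V)
    out_val <- V
  } else {
    lambda <- det(E) / det(H + E)
    r <- n - g - (p - q + 1) / 2
    u <- (p * q - 2) / 4
    t_par <- if (p^2 + q^2 - 5 > 0) {
      sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5))
    } else 1
    df1 <- p * q
    df2 <- r * t_par - 2 * u
    lam_t <- lambda^(1 / t_par)
    f_stat <- ((1 - lam_t) / lam_t) * df2 / df1
    out_val <- lambda
  }
  tibble(statistic_name = statistic, statistic_value = out_val,
         approx_f = f_stat, df1 = df1, df2 = df2,
         p = pf(f_stat, df1, df2, lower.tail = FALSE))
}

#' Default form-function trait pairs
#'
#' Wing-structure x calling-song pairs examined in the within-morph
#' correlation grid.
#' @return A tibble with columns `trait_x` (form), `trait_y` (function).
#' @export
default_trait_pairs <- function() {
  tidyr::expand_grid(
    trait_x = c("mirror_size", "harp_width", "scraper_present"),
    trait_y = c("dominant_frequency", "amplitude_db", "frequency_evenness"))
}

#' Within-morph form-function correlation report
#'
#' Computes the per-morph grid of Pearson correlations between wing
#' structures and song characteristics, and summarises the decoupling
#' signature: trait pairs whose set of significantly correlated morphs
#' differs in identity or sign across morphs. Under form-function
#' continuity every morph shows the same significant relationships with
#' the same signs; decoupling is flagged when morphs differ.
#'
#' @param features Feature table keyed by `individual_id` containing the
#'   traits in `trait_pairs` (binary flags may be logical; they are encoded
#'   0/1).
#' @param assignment A `morph_assignment` (or data frame with
#'   `individual_id`, `morph`).
#' @param trait_pairs Tibble of `trait_x`, `trait_y` pairs; default
#'   [default_trait_pairs()].
#' @param alpha Significance level for the decoupling summary.
#' @param p_adjust `"none"` (default; raw p-values, matching the grid the
#'   analysis reports) or `"holm"`.
#' @return A `formfunction_report`: `grid` (per morph x pair correlation
#'   entries), `decoupling` (per pair: significant morphs, signs, flag),
#'   `n_flagged`.
#' @export
formfunction_report <- function(features, assignment,
                                trait_pairs = default_trait_pairs(),
                                alpha = 0.05,
                                p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  df <- dplyr::inner_join(
    dplyr::select(as_tibble(assignment), "individual_id", "morph"),
    as_tibble(features), by = "individual_id")
  if (nrow(df) == 0L) abort("no individuals shared between features and assignment")
  morphs <- unique(df$morph)
  grid <- purrr::map_dfr(morphs, function(m) {
    sub <- df[df$morph == m, ]
    if (nrow(sub) < 4) {
      warn(paste0("morph ", m, " has n = ", nrow(sub),
                  " < 4; correlations reported as NA"))
    }
    purrr::pmap_dfr(trait_pairs, function(trait_x, trait_y) {
      entry <- pearson_with_p(as.numeric(sub[[trait_x]]),
                              as.numeric(sub[[trait_y]]),
                              trait_x, trait_y)
      dplyr::bind_cols(tibble(morph = m), entry)
    })
  })
  if (p_adjust == "holm") grid$p <- p.adjust(grid$p, method = "holm")
  decoupling <- grid |>
    dplyr::mutate(sig = !is.na(.data$p) & .data$p < alpha,
                  sign = dplyr::if_else(.data$sig, sign(.data$r), 0)) |>
    dplyr::group_by(.data$trait_x, .data$trait_y) |>
    dplyr::summarise(
      sig_morphs = list(.data$morph[.data$sig]),
      sig_signs = list(.data$sign[.data$sig]),
      n_sig = sum(.data$sig),
      decoupled = .data$n_sig > 0 && .data$n_sig < dplyr::n(),
      .groups = "drop")
  # a pair is also decoupled when all morphs are significant with mixed signs
  mixed <- vapply(decoupling$sig_signs, function(s) {
    length(unique(s)) > 1
  }, logical(1))
  decoupling$decoupled <- decoupling$decoupled | mixed
  structure(
    list(grid = grid, decoupling = decoupling,
         n_flagged = sum(decoupling$decoupled), alpha = alpha),
    class = "formfunction_report"
  )
}

#' @export
print.formfunction_report <- function(x, ...) {
  cat(sprintf("<formfunction_report> %d trait pairs, %d flagged as decoupled (alpha = %g)\n",
              nrow(x$decoupling), x$n_flagged, x$alpha))
  print(x$decoupling)
  invisible(x)
}

#' @export
tidy.formfunction_report <- function(x, ...) x$grid

#' @export
glance.formfunction_report <- function(x, ...) {
  tibble(n_pairs = nrow(x$decoupling), n_flagged = x$n_flagged,
         alpha = x$alpha)
}

#' Plot a within-morph correlation grid
#'
#' Heatmap of the per-morph form-function correlations; cells with an
#' asterisk are significant at the report's alpha, grey cells are NA
#' (insufficient within-morph variation).
#'
#' @param report A `formfunction_report`.
#' @return A ggplot object.
#' @export
plot_correlation_grid <- function(report) {
  stopifnot(inherits(report, "formfunction_report"))
  g <- dplyr::mutate(report$grid,
                     pair = paste(.data$trait_x, "~", .data$trait_y),
                     label = dplyr::if_else(
                       is.na(.data$r), "NA",
                       paste0(sprintf("%.2f", .data$r),
                              dplyr::if_else(!is.na(.data$p) &
                                               .data$p < report$alpha,
                                             "*", ""))))
  ggplot2::ggplot(g, ggplot2::aes(.data$morph, .data$pair, fill = .data$r)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::labs(x = "Morph", y = "Form ~ Function pair", fill = "r",
                  title = "Within-morph form-function correlations") +
    ggplot2::theme_minimal()
}
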