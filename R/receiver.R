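#' Construct a detectability threshold curve
#'
#' An audiogram-style mapping from frequency to the amplitude required to
#' elicit a receiver (female) response, supplied as nodes and interpolated
#' linearly in log-frequency between them. Queries outside the node range
#' are errors, not extrapolations: the curve is only known where it was
#' measured.
#'
#' @param nodes A data frame with columns `hz` (strictly increasing) and
#'   `db_spl`, or a path to a two-column CSV with those names.
#' @return A `threshold_curve` object.
#' @export
threshold_curve <- function(nodes) {
  if (is.character(nodes)) {
    nodes <- readr::read_csv(nodes, show_col_types = FALSE)
  }
  nodes <- as_tibble(nodes)
  if (!all(c("hz", "db_spl") %in% names(nodes))) {
    abort("threshold curve needs columns hz and db_spl")
  }
  if (nrow(nodes) < 2) abort("threshold curve needs at least 2 nodes")
  if (any(diff(nodes$hz) <= 0)) abort("node frequencies must be strictly increasing")
  if (any(nodes$hz <= 0)) abort("node frequencies must be positive")
  structure(list(nodes = nodes, interpolation = "linear_logf"),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("<threshold_curve> %d nodes, %g-%g Hz (linear in log f)\n",
              nrow(x$nodes), min(x$nodes$hz), max(x$nodes$hz)))
  invisible(x)
}

#' Required amplitude at a frequency
#'
#' @param frequency Frequency in Hz (vectorised), within the curve's node
#'   range.
#' @param curve A [threshold_curve()].
#' @return Required amplitude(s) in dB SPL.
#' @export
required_amplitude <- function(frequency, curve) {
  stopifnot(inherits(curve, "threshold_curve"))
  rng <- range(curve$nodes$hz)
  if (any(frequency < rng[1] | frequency > rng[2])) {
    abort(sprintf(
      "frequency outside the threshold curve's domain [%g, %g] Hz",
      rng[1], rng[2]))
  }
  approx(log(curve$nodes$hz), curve$nodes$db_spl, xout = log(frequency))$y
}

#' Detectability margin of a song
#'
#' `margin = song_spl_db - required_amplitude(dominant_frequency)`: a
#' positive margin predicts the song is detectable by the receiver.
#'
#' @param features A one-row song feature tibble (from
#'   [extract_song_features()]) or a numeric dominant frequency in Hz.
#' @param song_spl_db Song amplitude on the curve's dB SPL scale.
#' @param curve A [threshold_curve()].
#' @return A one-row tibble: `dominant_frequency`, `song_spl_db`,
#'   `required_db`, `margin_db`, `detectable`.
#' @export
detectability_margin <- function(features, song_spl_db, curve) {
  f <- if (is.numeric(features)) features else features$dominant_frequency
  req <- required_amplitude(f, curve)
  tibble(dominant_frequency = f, song_spl_db = song_spl_db,
         required_db = req, margin_db = song_spl_db - req,
         detectable = song_spl_db - req >= 0)
}

#' Threshold difference between two dominant frequencies
#'
#' How much louder a song at `f2` must be than one at `f1` to be equally
#' detectable: `required_amplitude(f2) - required_amplitude(f1)`.
#'
#' @param f1,f2 Frequencies in Hz.
#' @param curve A [threshold_curve()].
#' @return Difference in dB (positive when `f2` needs to be louder).
#' @export
threshold_difference <- function(f1, f2, curve) {
  required_amplitude(f2, curve) - required_amplitude(f1, curve)
}

#' @export
autoplot.threshold_curve <- function(object, ...) {
  fq <- exp(seq(log(min(object$nodes$hz)), log(max(object$nodes$hz)),
                length.out = 200))
  df <- tibble(hz = fq, db_spl = required_amplitude(fq, object))
  ggplot2::ggplot(df, ggplot2::aes(.data$hz / 1000, .data$db_spl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::mutate(object$nodes,
                                             hz = .data$hz / 1000),
                        ggplot2::aes(.data$hz, .data$db_spl)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (kHz)", y = "Required amplitude (dB SPL)",
                  title = "Receiver response threshold") +
    ggplot2::theme_minimal()
}

#' Firth penalized logistic regression
#'
#' Maximizes the Jeffreys-prior-penalized log-likelihood
#' `l(beta) + 0.5 * log det I(beta)` by Newton iteration on the
#' hat-value-adjusted score `U*(beta) = X' (y - p + h (0.5 - p))`, with
#' step-halving on penalized-likelihood decreases. The penalty guarantees
#' finite estimates even under complete separation.
#'
#' @param x Design matrix (full column rank), or a data frame of
#'   predictors; an intercept column is added unless one is present.
#' @param y Binary outcome vector (0/1 or logical).
#' @param max_iter Newton iteration cap.
#' @param tol Convergence tolerance on the modified-score norm.
#' @return A `firth_fit`: `coefficients`, `se`, `vcov`,
#'   `penalized_loglik`, `iterations`, `converged`, plus the data.
#' @export
firth_logistic <- function(x, y, max_iter = 100, tol = 1e-6) {
  if (is.data.frame(x)) x <- as.matrix(x)
  x <- as.matrix(x)
  if (!any(apply(x, 2, function(col) all(col == 1)))) {
    x <- cbind(`(Intercept)` = 1, x)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("y must be binary (0/1)")
  if (nrow(x) != length(y)) abort("nrow(x) must equal length(y)")
  if (qr(x)$rank < ncol(x)) abort("design matrix is rank-deficient")
  k <- ncol(x)
  beta <- rep(0, k)
  pen_ll <- function(beta) {
    eta <- drop(x %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(x * w, x)
    log_denom <- ifelse(eta > 30, eta, log1p(exp(eta)))
    as.numeric(sum(y * eta - log_denom) + 0.5 * determinant(info)$modulus)
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  iterations <- 0L
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    eta <- drop(x %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(x * w, x)
    info_inv <- solve(info)
    # hat values of the weighted design
    h <- rowSums((x %*% info_inv) * x) * w
    u_star <- drop(crossprod(x, y - p + h * (0.5 - p)))
    if (sqrt(sum(u_star^2)) < tol) { converged <- TRUE; break }
    step <- drop(info_inv %*% u_star)
    lambda <- 1
    repeat {
      ll_new <- pen_ll(beta + lambda * step)
      if (ll_new >= ll_old - 1e-10 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step
    ll_old <- pen_ll(beta)
  }
  if (!converged) {
    warn(paste0("Firth fit did not reach score tolerance ", tol, " in ",
                max_iter, " iterations"))
  }
  eta <- drop(x %*% beta)
  w <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-12)
  vcov <- solve(crossprod(x * w, x))
  dimnames(vcov) <- list(colnames(x), colnames(x))
  structure(
    list(coefficients = setNames(beta, colnames(x)),
         se = sqrt(diag(vcov)), vcov = vcov,
         penalized_loglik = as.numeric(pen_ll(beta)),
         iterations = iterations, converged = converged,
         x = x, y = y),
    class = "firth_fit"
  )
}

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf("<firth_fit> %d coefficients, penalized logLik %.3f (%s in %d iterations)\n",
              length(x$coefficients), x$penalized_loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.firth_fit <- function(x, ...) {
  z <- x$coefficients / x$se
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = unname(x$se), statistic = unname(z),
         p.value = unname(2 * pnorm(-abs(z))))
}

#' @export
glance.firth_fit <- function(x, ...) {
  tibble(penalized_loglik = x$penalized_loglik, n = length(x$y),
         iterations = x$iterations, converged = x$converged)
}

#' Fit phonotaxis responses with Firth logistic regression
#'
#' Convenience wrapper: builds a treatment-coded design from the stimulus
#' factor of a trial table and fits [firth_logistic()].
#'
#' @param trials A data frame with columns `stimulus` and a logical/0-1
#'   `response` column.
#' @param response Name of the outcome column (default `"responded"`).
#' @param reference Reference stimulus level (default first alphabetically).
#' @return A `firth_fit` with the stimulus levels attached.
#' @export
fit_phonotaxis <- function(trials, response = "responded", reference = NULL) {
  trials <- as_tibble(trials)
  if (!all(c("stimulus", response) %in% names(trials))) {
    abort(paste0("trials must contain columns stimulus and ", response))
  }
  stim <- factor(trials$stimulus)
  if (!is.null(reference)) stim <- stats::relevel(stim, ref = reference)
  mm <- stats::model.matrix(~ stim)
  colnames(mm) <- sub("^stim", "", colnames(mm))
  fit <- firth_logistic(mm, as.numeric(trials[[response]]))
  fit$stimulus_levels <- levels(stim)
  fit
}

#' Pairwise stimulus contrasts from a Firth fit
#'
#' Wald contrasts of the linear predictor between every pair of stimulus
#' levels (log-odds differences on the penalized fit), with optional Holm
#' adjustment.
#'
#' @param fit A `firth_fit` from [fit_phonotaxis()].
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return A tibble: `level_1`, `level_2`, `estimate` (log-odds of level_1
#'   minus level_2), `std.error`, `statistic`, `p.value`.
#' @export
pairwise_contrasts <- function(fit, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(fit, "firth_fit"))
  levels <- fit$stimulus_levels
  if (is.null(levels)) abort("fit has no stimulus factor; use fit_phonotaxis()")
  k <- length(fit$coefficients)
  # linear-predictor row for each level under treatment coding
  lp <- function(lev) {
    v <- numeric(k)
    v[1] <- 1
    idx <- match(lev, names(fit$coefficients))
    if (!is.na(idx)) v[idx] <- 1
    v
  }
  pairs <- utils::combn(levels, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    l1 <- pairs[1, i]; l2 <- pairs[2, i]
    cvec <- lp(l1) - lp(l2)
    est <- sum(cvec * fit$coefficients)
    se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    z <- est / se
    tibble(level_1 = l1, level_2 = l2, estimate = est, std.error = se,
           statistic = z, p.value = 2 * pnorm(-abs(z)))
  })
  if (p_adjust == "holm") out$p.value <- p.adjust(out$p.value, "holm")
  out
}
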