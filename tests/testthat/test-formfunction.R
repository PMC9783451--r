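test_that("pearson_with_p reproduces hand-computed and reference values", {
  x <- 1:10
  perf <- pearson_with_p(x, 2 * x + 1)
  expect_equal(perf$r, 1)
  expect_equal(perf$p, 0)
  expect_equal(pearson_with_p(c(1, 2, 3), c(1, 3, 2), min_n = 3)$r, 0.5)
  set.seed(31)
  a <- rnorm(15); b <- 0.4 * a + rnorm(15)
  mine <- pearson_with_p(a, b)
  ref <- cor.test(a, b)
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-8)
  expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
})

test_that("pearson_with_p reports NA with a reason instead of failing", {
  res <- pearson_with_p(1:5, rep(2, 5))
  expect_true(is.na(res$r))
  expect_match(res$na_reason, "insufficient variation")
  small <- pearson_with_p(1:3, c(2, 1, 3))
  expect_true(is.na(small$p))
  expect_true(small$flagged_small_n)
})

test_that("pearson_with_p is symmetric and invariant to positive affine maps", {
  set.seed(32)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(pearson_with_p(a, b)$r, pearson_with_p(b, a)$r)
  expect_equal(pearson_with_p(3 * a + 7, b)$r, pearson_with_p(a, b)$r,
               tolerance = 1e-12)
})

test_that("Welch t-test matches the direct formula and the reference", {
  wt <- welch_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(wt$statistic, -1.549193, tolerance = 1e-6)
  expect_equal(wt$df, 2.941176, tolerance = 1e-6)
  same <- welch_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  set.seed(33)
  a <- rnorm(20); b <- rnorm(25, 0.5, 2)
  ref <- t.test(a, b)
  mine <- welch_t_test(a, b)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-8)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
})

test_that("scraper and scraperless purring songs separate by Welch test across seeds", {
  arch <- default_archetypes()$purring
  arch$carrier_hz_sd <- 300   # tight jitter around the two class medians
  sig <- vapply(1:20, function(s) {
    with_scraper <- vapply(1:8, function(i) {
      song <- synthesize_song(arch, seed = s * 1000 + i,
                              scraper_present = TRUE)
      dominant_frequency(power_spectrum(song$recording, 1024))
    }, numeric(1))
    without <- vapply(1:8, function(i) {
      song <- synthesize_song(arch, seed = s * 1000 + 500 + i,
                              scraper_present = FALSE)
      dominant_frequency(power_spectrum(song$recording, 1024))
    }, numeric(1))
    res <- welch_t_test(with_scraper, without)
    res$p < 0.01 && res$statistic < 0
  }, logical(1))
  expect_true(all(sig))
})

test_that("Levene/Brown-Forsythe matches car::leveneTest and detects unequal spread", {
  # mirror-image groups have equal spread
  g1 <- c(-2, -1, 0, 1, 2)
  eq <- levene_test(list(g1, -g1))
  expect_lt(eq$statistic, 1e-20)
  set.seed(34)
  v <- rnorm(36) * rep(c(1, 2, 3), each = 12)
  g <- factor(rep(1:3, each = 12))
  mine <- levene_test(v, g = g)
  ref <- car::leveneTest(v, g)
  expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-8)
  expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-8)
  expect_equal(c(mine$df1, mine$df2), ref$Df, tolerance = 1e-12)
  # mean-centred variant against the reference too
  mine_mean <- levene_test(v, g = g, center = "mean")
  ref_mean <- car::leveneTest(v, g, center = mean)
  expect_equal(mine_mean$statistic, ref_mean$`F value`[1], tolerance = 1e-8)
})

test_that("Levene detects a 1:4 variance ratio in nearly all seeded replicates", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    levene_test(list(rnorm(50, sd = 1), rnorm(50, sd = 2)))$p < 0.01
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("MANOVA Pillai and Wilks match the reference implementation to 1e-8", {
  set.seed(35)
  Y <- matrix(rnorm(60), 30, 2)
  grp <- factor(rep(letters[1:3], each = 10))
  mine <- manova_pillai(Y, grp)
  ref <- summary(manova(Y ~ grp), test = "Pillai")$stats
  expect_equal(mine$statistic_value, ref[1, "Pillai"], tolerance = 1e-8)
  expect_equal(mine$approx_f, ref[1, "approx F"], tolerance = 1e-8)
  expect_equal(mine$df1, ref[1, "num Df"])
  expect_equal(mine$df2, ref[1, "den Df"])
  expect_equal(mine$p, ref[1, "Pr(>F)"], tolerance = 1e-8)
  wilks <- manova_pillai(Y, grp, statistic = "Wilks")
  refw <- summary(manova(Y ~ grp), test = "Wilks")$stats
  expect_equal(wilks$statistic_value, refw[1, "Wilks"], tolerance = 1e-8)
  expect_equal(wilks$approx_f, refw[1, "approx F"], tolerance = 1e-8)
})

test_that("MANOVA with one response equals the one-way ANOVA F", {
  set.seed(36)
  y <- rnorm(24, rep(c(0, 1, 3), each = 8))
  grp <- factor(rep(1:3, each = 8))
  mine <- manova_pillai(matrix(y, ncol = 1), grp)
  ref <- anova(lm(y ~ grp))
  expect_equal(mine$approx_f, ref$`F value`[1], tolerance = 1e-8)
  expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("MANOVA separates grossly shifted groups and stays calibrated under the null", {
  set.seed(37)
  Y <- rbind(matrix(rnorm(30), 15, 2),
             sweep(matrix(rnorm(30), 15, 2), 2, c(10, 0), `+`))
  grp <- factor(rep(1:2, each = 15))
  expect_lt(manova_pillai(Y, grp)$p, 1e-6)
  null_ps <- vapply(1:20, function(s) {
    set.seed(s + 100)
    manova_pillai(matrix(rnorm(60), 30, 2), factor(rep(1:3, each = 10)))$p
  }, numeric(1))
  expect_gte(sum(null_ps > 0.05), 17)
})

test_that("the decoupling summary flags morph-specific couplings and not shared ones", {
  set.seed(39)
  n <- 30
  mk <- function(morph, couple) {
    ms <- runif(n, 1, 2)
    tibble::tibble(
      individual_id = paste0(morph, 1:n),
      mirror_size = ms,
      harp_width = runif(n, 2, 3),
      scraper_present = 1,
      dominant_frequency = if (couple) 3000 * ms + rnorm(n, 0, 100) else
        runif(n, 4000, 6000),
      amplitude_db = rnorm(n, -20),
      frequency_evenness = -runif(n, 0, 0.4))
  }
  features <- dplyr::bind_rows(mk("rattling", TRUE), mk("ancestral", FALSE),
                               mk("purring", FALSE))
  assignment <- tibble::tibble(
    individual_id = features$individual_id,
    morph = rep(c("rattling", "ancestral", "purring"), each = n))
  rep1 <- formfunction_report(features, assignment)
  cell <- dplyr::filter(rep1$grid, .data$trait_x == "mirror_size",
                        .data$trait_y == "dominant_frequency")
  expect_true(cell$p[cell$morph == "rattling"] < 0.05)
  expect_true(all(is.na(cell$p[cell$morph != "rattling"]) |
                    cell$p[cell$morph != "rattling"] >= 0.05))
  flagged <- dplyr::filter(rep1$decoupling, .data$decoupled)
  expect_true(any(flagged$trait_x == "mirror_size" &
                    flagged$trait_y == "dominant_frequency"))
  # scraper_present has no variation anywhere: NA cells, never flagged
  expect_true(all(is.na(dplyr::filter(rep1$grid,
                                      .data$trait_x == "scraper_present")$r)))

  # identical coupling in every morph is continuity, not decoupling
  features2 <- dplyr::bind_rows(mk("rattling", TRUE), mk("ancestral", TRUE),
                                mk("purring", TRUE))
  rep2 <- formfunction_report(features2, assignment)
  pair2 <- dplyr::filter(rep2$decoupling, .data$trait_x == "mirror_size",
                         .data$trait_y == "dominant_frequency")
  expect_false(pair2$decoupled)
})

test_that("single-morph input yields a grid without cross-morph flags", {
  set.seed(40)
  features <- tibble::tibble(
    individual_id = paste0("i", 1:10),
    mirror_size = runif(10), harp_width = runif(10), scraper_present = 1,
    dominant_frequency = runif(10, 4000, 5000),
    amplitude_db = rnorm(10), frequency_evenness = -runif(10, 0, 0.3))
  assignment <- tibble::tibble(individual_id = features$individual_id,
                               morph = "ancestral")
  rep1 <- formfunction_report(features, assignment)
  expect_equal(unique(rep1$grid$morph), "ancestral")
  expect_equal(rep1$n_flagged, 0)
})
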