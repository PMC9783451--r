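test_that("a pure-tone archetype song has near one-hot frequency evenness", {
  arch <- morph_archetype(
    name = "tonal", carrier_hz_mean = 4800, carrier_hz_sd = 0,
    noise_mix_mean = 0, noise_mix_sd = 0,
    amplitude_db_mean = -12, amplitude_db_sd = 0,
    mirror_present_prob = 1, scraper_present_prob = 1,
    file_gaps_present = FALSE,
    harp_width_mean = 2.4, harp_width_sd = 0,
    mirror_csize_mean = 1.8, mirror_csize_sd = 0)
  song <- synthesize_song(arch, seed = 1, ambient_noise_db = -Inf)
  f <- extract_song_features(song$recording)
  expect_lt(abs(f$frequency_evenness - (-sqrt(1 / 6))), 0.02)
  expect_equal(f$amplitude_db, -12, tolerance = 0.5)
})

test_that("purring songs are quieter and more even than ancestral songs", {
  arcs <- default_archetypes()
  anc <- synthesize_song(arcs$ancestral, seed = 10)
  pur <- synthesize_song(arcs$purring, seed = 10)
  fa <- extract_song_features(anc$recording)
  fp <- extract_song_features(pur$recording)
  expect_lt(fp$amplitude_db, fa$amplitude_db)
  expect_gt(fp$frequency_evenness, fa$frequency_evenness)
})

test_that("the extractor recovers the drawn carrier within one spectral bin", {
  arch <- default_archetypes()$purring
  arch$carrier_hz_sd <- 300
  song <- synthesize_song(arch, seed = 3, scraper_present = TRUE)
  dom <- dominant_frequency(power_spectrum(song$recording, 4096))
  expect_lt(abs(dom - song$truth$carrier_hz), 44100 / 4096 + 1e-9)
  # amplitude recovered within 0.5 dB when no ambient floor is added
  song2 <- synthesize_song(arch, seed = 4, scraper_present = TRUE,
                           ambient_noise_db = -Inf)
  f2 <- extract_song_features(song2$recording)
  expect_lt(abs(f2$amplitude_db - song2$truth$amplitude_db), 0.5)
})

test_that("frequency evenness increases with the noise mixing fraction", {
  mixes <- seq(0.05, 0.9, length.out = 10)
  ev <- vapply(seq_along(mixes), function(i) {
    arch <- morph_archetype(
      name = "sweep", carrier_hz_mean = 4800, carrier_hz_sd = 0,
      noise_mix_mean = mixes[i], noise_mix_sd = 0,
      amplitude_db_mean = -15, amplitude_db_sd = 0,
      mirror_present_prob = 1, scraper_present_prob = 1,
      file_gaps_present = FALSE,
      harp_width_mean = 2.4, harp_width_sd = 0,
      mirror_csize_mean = 1.8, mirror_csize_sd = 0)
    song <- synthesize_song(arch, seed = 100 + i, ambient_noise_db = -Inf)
    extract_song_features(song$recording)$frequency_evenness
  }, numeric(1))
  expect_gte(cor(mixes, ev, method = "spearman"), 0.95)
})

test_that("carriers at or above Nyquist are rejected", {
  arch <- default_archetypes()$ancestral
  arch$carrier_hz_mean <- 30000
  expect_error(synthesize_song(arch, seed = 1, sample_rate = 44100),
               "Nyquist")
})

test_that("noise-free wings hit the drawn harp width exactly; absent mirrors collapse", {
  arch <- default_archetypes()$purring
  arch$landmark_noise_sd <- 0
  w <- synthesize_wing(arch, seed = 5)
  expect_equal(harp_width(w$config), w$truth$harp_width_target,
               tolerance = 1e-12)
  expect_false(w$flags$mirror_present)
  expect_true(is.na(w$truth$mirror_csize_target))
  # the collapsed mirror is far smaller than any real mirror
  expect_lt(centroid_size(w$config$points[6:11, ]), 0.2)
  # purring never has a mirror under the default archetype
  flags <- vapply(1:50, function(s) {
    synthesize_wing(default_archetypes()$purring, seed = s)$flags$mirror_present
  }, logical(1))
  expect_false(any(flags))
})

test_that("mean harp width over 200 draws recovers the archetype mean within 2 SE", {
  arch <- default_archetypes()$ancestral
  widths <- vapply(1:200, function(s) {
    harp_width(synthesize_wing(arch, seed = s)$config)
  }, numeric(1))
  se <- sd(widths) / sqrt(200)
  expect_lt(abs(mean(widths) - arch$harp_width_mean), 2 * se + 1e-12)
})

test_that("cohorts are reproducible, respect proportions, and carry ground truth", {
  spec <- cohort_spec(n_individuals = 59, seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$songs[[17]]$samples, c2$songs[[17]]$samples)
  expect_identical(c1$wings[[30]]$points, c2$wings[[30]]$points)
  # rattling fraction within binomial 95% bounds of 0.27
  n_rat <- sum(c1$metadata$morph == "rattling")
  bounds <- qbinom(c(0.025, 0.975), 59, 0.27)
  expect_gte(n_rat, bounds[1])
  expect_lte(n_rat, bounds[2])
  # degenerate proportions produce a single morph
  c3 <- generate_cohort(cohort_spec(n_individuals = 10,
                                    morph_proportions = c(ancestral = 1,
                                                          purring = 0,
                                                          rattling = 0),
                                    seed = 1))
  expect_true(all(c3$metadata$morph == "ancestral"))
})

test_that("ancestral wings have every structure but file gaps; rattling have gaps", {
  co <- generate_cohort(cohort_spec(n_individuals = 30, seed = 9))
  flags <- dplyr::inner_join(co$flags, co$metadata, by = "individual_id")
  anc <- dplyr::filter(flags, morph == "ancestral")
  expect_true(all(anc$scraper_present & anc$mirror_present))
  expect_false(any(anc$file_gaps_present))
  rat <- dplyr::filter(flags, morph == "rattling")
  expect_true(all(rat$file_gaps_present))
})

test_that("phonotaxis trials obey the contact-implies-response invariant", {
  t0 <- generate_phonotaxis_trials(c(a = 0, b = 0), n_females = 10, seed = 2)
  expect_false(any(t0$responded))
  t1 <- generate_phonotaxis_trials(c(a = 0.7, b = 0.5), n_females = 50,
                                   contact_prob_given_response = 0,
                                   seed = 3)
  expect_false(any(t1$contacted_speaker))
  expect_true(any(t1$responded))
  t2 <- generate_phonotaxis_trials(n_females = 30, seed = 7)
  expect_true(all(t2$responded[t2$contacted_speaker]))
  expect_equal(nrow(t2), 30 * 4)
  expect_identical(t2, generate_phonotaxis_trials(n_females = 30, seed = 7))
})
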