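# Synthetic cohort generator: determinism, planted spectral structure,
# artifact injection with ground truth, cohort structure, round-trip I/O.

test_that("identical seeds reproduce recordings and cohorts bit-for-bit", {
  spec <- cohort_spec(n_hc = 2, n_ad = 1, duration_s = 5, fs = 250, seed = 4)
  r1 <- generate_subject_eeg(profile_hc(), spec, 123)
  r2 <- generate_subject_eeg(profile_hc(), spec, 123)
  expect_identical(r1$data, r2$data)
  r3 <- generate_subject_eeg(profile_hc(), spec, 124)
  expect_false(identical(r1$data, r3$data))

  c1 <- generate_cohort(spec = spec, artifacts = artifact_spec())
  c2 <- generate_cohort(spec = spec, artifacts = artifact_spec())
  expect_identical(
    lapply(c1$recordings, `[[`, "data"),
    lapply(c2$recordings, `[[`, "data"))
  expect_identical(c1$masks[[1]]$epochs, c2$masks[[1]]$epochs)
})

test_that("background-only profile gives a flat normalized spectrum", {
  p <- group_profile("flat",
                     band_weights = c(delta = 0, theta = 0, alpha = 0,
                                      beta = 0),
                     pink_exponent = 0, channel_gain_sd = 0, subject_sd = 0)
  spec <- cohort_spec(n_hc = 1, n_ad = 0, duration_s = 120, fs = 250,
                      channels = "Cz", seed = 9)
  rec <- generate_subject_eeg(p, spec, 42)
  psd <- normalize_psd(average_psd(epoch(rec)))
  bins <- psd$norm_psd[psd$freq >= 3 & psd$freq <= 30]
  # each of the 28 bins should be ~1/28; periodogram ordinates averaged
  # over 120 epochs have relative SE 1/sqrt(120) ~ 0.09
  expect_equal(sum(bins), 1, tolerance = 1e-12)
  expect_true(all(abs(bins * 28 - 1) < 6 / sqrt(120)))
})

test_that("band weights drive relative band power monotonically", {
  p_alpha <- group_profile("alpha",
                           band_weights = c(delta = 0.1, theta = 0.1,
                                            alpha = 3, beta = 0.1))
  spec <- cohort_spec(n_hc = 1, n_ad = 0, duration_s = 30, fs = 250, seed = 2)
  rec <- generate_subject_eeg(p_alpha, spec, 7)
  bp <- band_power(normalize_psd(average_psd(epoch(rec))))
  bp_mean <- tapply(bp$power, bp$band, mean)
  expect_true(all(bp_mean["alpha"] > bp_mean[c("delta", "theta", "beta")]))
})

test_that("cohort has the specified size, labels, and channel records", {
  spec <- cohort_spec(n_hc = 23, n_ad = 18, duration_s = 2, fs = 250,
                      seed = 11)
  coh <- generate_cohort(spec = spec)
  s <- summary(coh)
  expect_equal(nrow(s), 41)
  expect_equal(sum(s$group == "HC"), 23)
  expect_equal(sum(s$group == "AD"), 18)
  expect_equal(sum(s$n_channels), 574)

  one <- generate_cohort(spec = cohort_spec(n_hc = 1, n_ad = 0,
                                            duration_s = 2, seed = 1))
  expect_equal(summary(one)$group, "HC")
})

test_that("zero artifact rate leaves the recording untouched", {
  spec <- cohort_spec(n_hc = 1, n_ad = 0, duration_s = 10, fs = 250, seed = 3)
  rec <- generate_subject_eeg(profile_hc(), spec, 5)
  inj <- inject_artifacts(rec, artifact_spec(rate_per_min = 0), seed = 1)
  expect_identical(inj$recording$data, rec$data)
  expect_false(any(inj$mask$epochs$is_artifact))
})

test_that("ground-truth mask marks exactly the epochs overlapping events", {
  spec <- cohort_spec(n_hc = 1, n_ad = 0, duration_s = 60, fs = 250,
                      channels = c("Fp1", "O2"), seed = 8)
  rec <- generate_subject_eeg(profile_hc(), spec, 21)
  inj <- inject_artifacts(rec, artifact_spec(rate_per_min = 4), seed = 13)
  expect_gt(nrow(inj$events), 0)
  # recompute expected marked epochs from the event log (sample-based,
  # matching the injection arithmetic)
  for (ch in unique(inj$mask$epochs$channel)) {
    ev <- inj$events[inj$events$channel == ch, ]
    expected <- rep(FALSE, 60)
    for (i in seq_len(nrow(ev))) {
      idx0 <- floor(ev$start_s[i] * 250) + 1
      idx1 <- min(idx0 + round(ev$duration_s[i] * 250) - 1, 60 * 250)
      expected[((idx0 - 1) %/% 250 + 1):((idx1 - 1) %/% 250 + 1)] <- TRUE
    }
    got <- inj$mask$epochs$is_artifact[inj$mask$epochs$channel == ch]
    expect_identical(got, expected)
  }
  # samples in unmarked epochs are untouched
  marked <- inj$mask$epochs$is_artifact[inj$mask$epochs$channel == "Fp1"]
  ci <- match("Fp1", rec$channels)
  for (e in which(!marked)) {
    idx <- ((e - 1) * 250 + 1):(e * 250)
    expect_identical(inj$recording$data[ci, idx], rec$data[ci, idx])
  }
})

test_that("event counts follow the specified Poisson rate", {
  spec <- cohort_spec(n_hc = 1, n_ad = 0, duration_s = 300, fs = 250,
                      seed = 17)
  rec <- generate_subject_eeg(profile_hc(), spec, 31)
  inj <- inject_artifacts(rec, artifact_spec(rate_per_min = 2), seed = 19)
  # 2/min x 5 min x 14 channels = 140 expected events
  bounds <- qpois(c(0.005, 0.995), 140)
  expect_gte(nrow(inj$events), bounds[1])
  expect_lte(nrow(inj$events), bounds[2])
})

test_that("rates leaving under 90 s clean in expectation warn", {
  spec <- cohort_spec(n_hc = 1, n_ad = 0, duration_s = 120, fs = 250,
                      channels = "Cz", seed = 2)
  rec <- generate_subject_eeg(profile_hc(), spec, 3)
  expect_warning(inject_artifacts(rec, artifact_spec(rate_per_min = 30),
                                  seed = 1),
                 "clean")
  expect_no_warning(inject_artifacts(rec, artifact_spec(rate_per_min = 1),
                                     seed = 1))
})

test_that("invalid specs fail naming the offending field", {
  expect_error(cohort_spec(n_hc = -1), "n_hc")
  expect_error(cohort_spec(fs = 60), "fs")
  expect_error(cohort_spec(channels = c("Cz", "Cz")), "channels")
  expect_error(group_profile("x", band_weights = c(delta = -1, theta = 1,
                                                   alpha = 1, beta = 1)),
               "band_weights")
  expect_error(artifact_spec(amplitude_factor = 0.5), "amplitude_factor")
})

test_that("cohorts round-trip through plain-text files", {
  spec <- cohort_spec(n_hc = 2, n_ad = 1, duration_s = 3, fs = 250,
                      channels = c("Fp1", "Cz"), seed = 6)
  coh <- generate_cohort(spec = spec, artifacts = artifact_spec())
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_setequal(names(back$recordings), names(coh$recordings))
  r0 <- coh$recordings[["AD01"]]
  r1 <- back$recordings[["AD01"]]
  expect_equal(r1$data, r0$data, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(r1$group, "AD")
  expect_equal(r1$fs, 250)
  expect_equal(back$masks[["AD01"]]$epochs$is_artifact,
               coh$masks[["AD01"]]$epochs$is_artifact)
})
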