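# Periodogram, masked averaging, normalization, band power, montage
# averaging, feature table.

test_that("periodogram matches its analytic values", {
  const <- periodogram_psd(rep(3, 250), 250)
  expect_equal(const$power[const$freq == 0], 9, tolerance = 1e-12)
  expect_lt(max(const$power[const$freq != 0]), 1e-20)

  t <- 0:249
  s10 <- sin(2 * pi * 10 * t / 250)
  pg <- periodogram_psd(s10, 250)
  expect_equal(pg$power[pg$freq == 10], 0.25, tolerance = 1e-12)
  others <- pg$power[pg$freq != 10 & pg$freq != 240]  # 240 = alias of 10
  expect_lt(max(others), 1e-20)

  expect_error(periodogram_psd(numeric(0), 250), "samples")
})

test_that("periodogram agrees with the brute-force DFT oracle", {
  withr::with_seed(3, {
    for (L in c(16, 250)) {
      x <- rnorm(L)
      fast <- periodogram_psd(x, fs = L)
      slow <- oracle_periodogram(x, fs = L)
      expect_equal(fast$freq, slow$freq)
      nz <- slow$power > 1e-12
      expect_lt(max(abs(fast$power[nz] - slow$power[nz]) / slow$power[nz]),
                1e-10)
    }
  })
})

test_that("Parseval's identity holds for the two-sided periodogram", {
  withr::with_seed(4, {
    for (i in 1:5) {
      x <- rnorm(250, sd = runif(1, 0.5, 20))
      pg <- periodogram_psd(x, 250)
      expect_equal(sum(pg$power) * 250 / 250, mean(x^2), tolerance = 1e-9)
    }
  })
})

test_that("masked averaging uses exactly the clean epochs", {
  one <- sin(2 * pi * 7 * (0:249) / 250)
  rec <- eeg_recording(matrix(rep(one, 10), 1), fs = 250, channels = "Cz")
  ep <- epoch(rec)
  avg <- average_psd(ep)
  single <- periodogram_psd(one, 250)
  expect_equal(avg$psd, single$power[single$freq <= 125],
               tolerance = 1e-12)
  expect_equal(unique(avg$n_epochs_used), 10)

  # half the epochs carry a different signal and are flagged
  other <- sin(2 * pi * 20 * (0:249) / 250)
  mixed <- eeg_recording(matrix(c(rep(one, 5), rep(other, 5)), 1),
                         fs = 250, channels = "Cz")
  mask <- eegpsd:::new_artifact_mask(
    tibble::tibble(channel = "Cz", epoch = 1:10,
                   is_artifact = rep(c(FALSE, TRUE), each = 5)), 1)
  avg2 <- average_psd(epoch(mixed), mask)
  expect_equal(unique(avg2$n_epochs_used), 5)
  expect_equal(avg2$psd, single$power[single$freq <= 125],
               tolerance = 1e-12)
})

test_that("averaged white-noise periodograms are flat within sampling error", {
  withr::with_seed(9, {
    rec <- eeg_recording(matrix(rnorm(200 * 250), 1), fs = 250,
                         channels = "Cz")
  })
  avg <- average_psd(epoch(rec))
  bins <- avg$psd[avg$freq > 0 & avg$freq < 125]
  s <- mean(bins)
  # periodogram ordinates are ~ s * chi2_2 / 2: SE of the 200-epoch mean
  # is s / sqrt(200); at 3 SE a few of 124 bins may exceed by chance
  z <- abs(bins - s) / (s / sqrt(200))
  expect_gt(mean(z < 3), 0.95)
  expect_true(all(z < 5))
})

test_that("normalization yields unit 3-30 Hz mass and scale invariance", {
  spec <- cohort_spec(n_hc = 1, n_ad = 0, duration_s = 10, fs = 250,
                      channels = c("Fp1", "Cz"), seed = 12)
  rec <- generate_subject_eeg(profile_hc(), spec, 77)
  psd <- average_psd(epoch(rec))
  norm <- normalize_psd(psd)
  sums <- tapply(norm$norm_psd[norm$freq >= 3 & norm$freq <= 30],
                 norm$channel[norm$freq >= 3 & norm$freq <= 30], sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  scaled <- rec
  scaled$data <- scaled$data * 1000
  norm2 <- normalize_psd(average_psd(epoch(scaled)))
  expect_equal(norm2$norm_psd, norm$norm_psd, tolerance = 1e-12)

  flat <- psd
  flat$psd <- rep(1, nrow(flat))
  nf <- normalize_psd(flat)
  expect_equal(unique(nf$norm_psd[nf$freq >= 3 & nf$freq <= 30]), 1 / 28,
               tolerance = 1e-12)

  zero <- psd
  zero$psd <- rep(0, nrow(zero))
  expect_error(normalize_psd(zero), "zero total power")
})

test_that("band powers are means over the observable integer bins", {
  spec <- cohort_spec(n_hc = 1, n_ad = 0, duration_s = 10, fs = 250,
                      channels = "Cz", seed = 13)
  psd <- average_psd(epoch(generate_subject_eeg(profile_hc(), spec, 5)))
  flat <- psd
  flat$psd <- rep(1, nrow(flat))
  bp <- band_power(normalize_psd(flat))
  expect_equal(bp$power[bp$band == "theta"], 1 / 28, tolerance = 1e-12)
  # delta is restricted to 3-4 Hz and flagged partial
  expect_true(bp$partial[bp$band == "delta"])
  expect_equal(bp$power[bp$band == "delta"], 1 / 28, tolerance = 1e-12)
  # beta extends to 32 Hz: bins 31-32 are outside the normalization sum
  expect_false(bp$partial[bp$band == "beta"])

  conc <- psd
  conc$psd <- ifelse(conc$freq == 7, 1, 1e-6)
  bpc <- band_power(normalize_psd(conc))
  pw <- setNames(bpc$power, as.character(bpc$band))
  expect_true(pw["theta"] > 10 * max(pw[c("delta", "alpha", "beta")]))
})

test_that("planted AD profiles raise theta for the same subject seed", {
  spec <- cohort_spec(n_hc = 1, n_ad = 0, duration_s = 30, fs = 250,
                      channels = "Cz", seed = 14)
  bp_of <- function(profile) {
    rec <- generate_subject_eeg(profile, spec, 999)
    band_power(normalize_psd(average_psd(epoch(rec))))
  }
  hc <- bp_of(profile_hc())
  ad <- bp_of(profile_ad())
  expect_gt(ad$power[ad$band == "theta"], hc$power[hc$band == "theta"])
  expect_lt(ad$power[ad$band == "alpha"], hc$power[hc$band == "alpha"])
})

test_that("montage averaging pools valid channels and keeps unit mass", {
  spec <- cohort_spec(n_hc = 1, n_ad = 0, duration_s = 10, fs = 250,
                      seed = 15)
  rec <- generate_subject_eeg(profile_hc(), spec, 44)
  norm <- normalize_psd(average_psd(epoch(rec)))
  m <- montage_average(norm)
  expect_equal(unique(m$n_channels), 14)
  expect_equal(sum(m$norm_psd[m$freq >= 3 & m$freq <= 30]), 1,
               tolerance = 1e-9)

  # identical channels: montage mean equals any channel
  rec2 <- eeg_recording(matrix(rep(rec$data[1, ], 3), 3, byrow = TRUE),
                        fs = 250, channels = c("Fp1", "Cz", "O2"))
  n2 <- normalize_psd(average_psd(epoch(rec2)))
  m2 <- montage_average(n2)
  expect_equal(m2$norm_psd, n2$norm_psd[n2$channel == "Cz"],
               tolerance = 1e-12)

  # excluding one channel averages the remaining 13
  norm13 <- norm[norm$channel != "O1", ]
  m13 <- montage_average(norm13)
  expect_equal(unique(m13$n_channels), 13)
  by_hand <- tapply(norm13$norm_psd, norm13$freq, mean)
  expect_equal(as.numeric(by_hand[as.character(m13$freq)]), m13$norm_psd,
               tolerance = 1e-12)
})

test_that("the feature table has montage-by-bin structure", {
  spec <- cohort_spec(n_hc = 2, n_ad = 2, duration_s = 5, fs = 250,
                      seed = 16)
  coh <- generate_cohort(spec = spec)
  psd <- cohort_norm_psd(coh)
  tab <- build_feature_table(psd)
  expect_equal(dim(tab), c(4, 2 + 98))
  expect_equal(feature_columns(tab)[1:8],
               c("Fp1_5Hz", "Fp1_6Hz", "Fp1_7Hz", "Fp1_8Hz", "Fp1_9Hz",
                 "Fp1_10Hz", "Fp1_11Hz", "Fp2_5Hz"))

  tab1 <- build_feature_table(psd, montage = "P8")
  expect_equal(length(feature_columns(tab1)), 7)

  # a subject missing O1 gets 7 NA cells, imputed from column means
  psd_m <- psd[!(psd$subject_id == "HC01" & psd$channel == "O1"), ]
  tab_m <- build_feature_table(psd_m)
  o1 <- grep("^O1_", names(tab_m), value = TRUE)
  expect_equal(sum(is.na(tab_m[tab_m$subject_id == "HC01", o1])), 7)
  imp <- impute_missing(tab_m)
  expect_false(anyNA(imp[, feature_columns(imp)]))
  expect_equal(attr(imp, "n_imputed"), 7)
  expect_equal(imp[["O1_5Hz"]][imp$subject_id == "HC01"],
               mean(tab_m[["O1_5Hz"]], na.rm = TRUE))
})

test_that("the whole feature table is invariant to global rescaling", {
  spec <- cohort_spec(n_hc = 2, n_ad = 2, duration_s = 5, fs = 250,
                      seed = 18)
  coh <- generate_cohort(spec = spec)
  tab <- quick_feature_table(coh)
  coh2 <- coh
  for (id in names(coh2$recordings))
    coh2$recordings[[id]]$data <- coh2$recordings[[id]]$data * 37.5
  tab2 <- quick_feature_table(coh2)
  expect_equal(tab2, tab, tolerance = 1e-12)
})
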