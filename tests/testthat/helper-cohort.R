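# Shared fixtures: small synthetic cohorts and fast feature pipelines.
# Recordings are generated at 250 Hz so no resampling is involved unless a
# test asks for it.

# A null profile pair: identical spectra in both groups; subject_sd = 0
# isolates periodogram sampling noise so binomial references apply.
null_profiles <- function(subject_sd = 0) {
  hc <- group_profile("HC", subject_sd = subject_sd)
  ad <- hc
  ad$name <- "AD"
  list(hc = hc, ad = ad)
}

# Normalized per-channel PSDs for every recording of a cohort, skipping
# preprocessing (synthetic data are already at the target rate and
# artifact-free unless masks are supplied).
cohort_norm_psd <- function(cohort, masks = NULL) {
  dplyr::bind_rows(lapply(names(cohort$recordings), function(id) {
    ep <- epoch(cohort$recordings[[id]])
    normalize_psd(average_psd(ep, mask = masks[[id]]))
  }))
}

# Feature table for an artifact-free cohort with no preprocessing.
quick_feature_table <- function(cohort) {
  build_feature_table(cohort_norm_psd(cohort))
}

# Artifact-free cohort with a planted AD effect (0 = null) and its table.
planted_table <- function(seed, effect = 1, n_hc = 10, n_ad = 10,
                          duration_s = 30, subject_sd = 0.15) {
  hc <- profile_hc()
  hc$subject_sd <- subject_sd
  ad <- profile_ad(effect)
  ad$subject_sd <- subject_sd
  spec <- cohort_spec(n_hc = n_hc, n_ad = n_ad, duration_s = duration_s,
                      fs = 250, seed = seed)
  quick_feature_table(generate_cohort(hc, ad, spec))
}

# A deterministic sinusoid recording for filter/epoch tests.
sine_recording <- function(freqs, amps = rep(1, length(freqs)),
                           duration_s = 20, fs = 250,
                           channels = "Cz", dc = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  x <- rep(dc, length(t))
  for (i in seq_along(freqs)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t)
  data <- matrix(rep(x, length(channels)), nrow = length(channels),
                 byrow = TRUE)
  eeg_recording(data, fs = fs, channels = channels, subject_id = "sine")
}

# Brute-force DFT periodogram oracle (direct O(L^2) sum, no FFT).
oracle_periodogram <- function(x, fs) {
  L <- length(x)
  n <- 0:(L - 1)
  p <- vapply(0:(L - 1), function(k) {
    s <- sum(x * exp(-2i * pi * k * n / L))
    Mod(s)^2 / (L * fs)
  }, numeric(1))
  tibble::tibble(freq = (0:(L - 1)) * fs / L, power = p)
}

# Two-sided permutation p-value for a difference in means oracle.
permutation_p <- function(hc, ad, n_perm = 10000, seed = 1) {
  obs <- abs(mean(hc) - mean(ad))
  pooled <- c(hc, ad)
  n1 <- length(hc)
  stats <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n1)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    }, numeric(1))
  })
  (1 + sum(stats >= obs - 1e-12)) / (n_perm + 1)
}
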