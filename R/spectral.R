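# Periodogram PSD, artifact-masked epoch averaging, 3-30 Hz relative-power
# normalization, band powers, montage averaging, and the channel-by-bin
# feature table.
#
# With 1-s epochs at 250 Hz (L = Fs = 250) the DFT bins fall exactly on
# integer Hz, so "the bin at f Hz" is unambiguous throughout.

#' Periodogram estimate of the PSD
#'
#' Two-sided, unsmoothed periodogram of a finite signal:
#' \deqn{P(f) = \frac{1}{L F_s}\left|\sum_{n=0}^{L-1} x(n)
#'   e^{-j 2\pi f n / F_s}\right|^2}
#' evaluated at the DFT frequencies \eqn{f_k = k F_s / L}. All \eqn{L} bins
#' are returned (no one-sided doubling); downstream analysis reads the
#' positive-frequency bins, and the 3-30 Hz normalization cancels any
#' constant convention factor.
#'
#' @param x Numeric vector (one epoch of one channel, uV).
#' @param fs Sampling rate in Hz.
#' @return A tibble with columns `freq` (Hz) and `power` (uV^2/Hz); note
#'   `sum(power) * fs / L` equals `mean(x^2)` (Parseval).
#' @export
periodogram_psd <- function(x, fs) {
  L <- length(x)
  if (L < 2) abort("periodogram needs at least 2 samples")
  p <- Mod(fft(x))^2 / (L * fs)
  tibble(freq = (0:(L - 1)) * fs / L, power = p)
}

# Per-epoch periodograms for a whole epoch_array; returns list(freq, power)
# with power an array (bin, channel, epoch) over bins 0..floor(spe/2).
epoch_periodograms <- function(epochs) {
  arr <- epochs$epochs
  nch <- dim(arr)[1]; nep <- dim(arr)[2]; spe <- dim(arr)[3]
  m <- matrix(aperm(arr, c(3, 1, 2)), nrow = spe)
  pw <- Mod(stats::mvfft(m))^2 / (spe * epochs$fs)
  keep <- seq_len(spe %/% 2 + 1)
  freq <- (keep - 1) * epochs$fs / spe
  power <- array(pw[keep, , drop = FALSE], dim = c(length(keep), nch, nep))
  list(freq = freq, power = power)
}

#' Average per-epoch periodograms over clean epochs
#'
#' Computes the periodogram of every 1-s epoch and averages, per channel,
#' over the epochs not flagged by `mask`. Channels failing the
#' clean-duration gate (when `mask` has been gated) are dropped. With no
#' mask, all epochs of all channels are used.
#'
#' @param epochs An `epoch_array` from [epoch()].
#' @param mask Optional `artifact_mask` aligned with `epochs`.
#' @return A tibble (one row per channel and positive-frequency bin):
#'   `subject_id`, `group`, `channel`, `freq`, `psd`, `n_epochs_used`.
#' @export
average_psd <- function(epochs, mask = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  pg <- epoch_periodograms(epochs)
  nch <- length(epochs$channels)
  keep_channels <- epochs$channels
  clean <- matrix(TRUE, nrow = nch, ncol = epochs$n_epochs,
                  dimnames = list(epochs$channels, NULL))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "artifact_mask"))
    ri <- match(mask$epochs$channel, rownames(clean))
    ok <- !is.na(ri) & mask$epochs$epoch <= ncol(clean)
    clean[cbind(ri[ok], mask$epochs$epoch[ok])] <- !mask$epochs$is_artifact[ok]
    if (!is.null(mask$channels))
      keep_channels <- intersect(epochs$channels,
                                 mask$channels$channel[mask$channels$is_valid])
  }
  ci <- match(keep_channels, epochs$channels)
  nf <- length(pg$freq)
  avg <- matrix(0, nrow = nf, ncol = length(ci))
  n_used <- integer(length(ci))
  for (j in seq_along(ci)) {
    use <- clean[ci[j], ]
    if (!any(use))
      abort(sprintf("channel %s has zero clean epochs", keep_channels[j]))
    avg[, j] <- rowMeans(pg$power[, ci[j], use, drop = FALSE])
    n_used[j] <- sum(use)
  }
  tibble(
    subject_id = epochs$subject_id, group = epochs$group,
    channel = rep(keep_channels, each = nf),
    freq = rep(pg$freq, times = length(ci)),
    psd = as.vector(avg),
    n_epochs_used = rep(n_used, each = nf)
  )
}

#' Normalize a PSD to relative power over 3-30 Hz
#'
#' Divides each frequency bin by the sum of the integer-Hz bins from 3 to
#' 30 inclusive (28 bins), per channel, making the spectrum scale-invariant.
#' The normalized bins over 3-30 Hz therefore sum to exactly 1.
#'
#' @param psd_tbl Tibble from [average_psd()] (or [montage_average()]).
#' @param norm_range Length-2 numeric, inclusive normalization range in Hz.
#' @return The input tibble with a `norm_psd` column added.
#' @export
normalize_psd <- function(psd_tbl, norm_range = c(3, 30)) {
  stopifnot(all(c("channel", "freq", "psd") %in% names(psd_tbl)))
  in_range <- is_integer_bin(psd_tbl$freq) &
    psd_tbl$freq >= norm_range[1] - 1e-9 &
    psd_tbl$freq <= norm_range[2] + 1e-9
  psd_tbl$..in_range <- in_range
  out <- psd_tbl %>%
    group_by_present(c("subject_id", "channel")) %>%
    mutate(norm_psd = {
      denom <- sum(.data$psd[.data$..in_range])
      if (denom <= 0)
        abort(sprintf("zero total power in %g-%g Hz for channel %s",
                      norm_range[1], norm_range[2], .data$channel[1]))
      .data$psd / denom
    }) %>%
    ungroup()
  out$..in_range <- NULL
  out
}

is_integer_bin <- function(freq) abs(freq - round(freq)) < 1e-9

group_by_present <- function(df, cols) {
  dplyr::group_by(df, !!!rlang::syms(intersect(cols, names(df))))
}

#' Band-wise mean relative power
#'
#' For each channel and band, the arithmetic mean of the normalized PSD
#' over the band's integer bins intersected with the observable range
#' (default 3-35 Hz after the band-pass filter): delta is computed from the
#' surviving 3-4 Hz bins and flagged `partial`; beta uses 14-32 Hz as
#' defined.
#'
#' @param psd_tbl Normalized PSD tibble from [normalize_psd()].
#' @param bands Band definition tibble, see [eeg_bands()].
#' @param available Length-2 numeric, observable frequency range in Hz.
#' @return A tibble: `subject_id`, `group`, `channel`, `band`, `power`,
#'   `partial`.
#' @export
band_power <- function(psd_tbl, bands = eeg_bands(), available = c(3, 35)) {
  stopifnot("norm_psd" %in% names(psd_tbl))
  purrr::pmap_dfr(bands, function(band, lo, hi) {
    lo_eff <- max(lo, available[1])
    hi_eff <- min(hi, available[2])
    if (lo_eff > hi_eff)
      abort(sprintf("band %s has no observable bins in %g-%g Hz",
                    band, available[1], available[2]))
    psd_tbl %>%
      filter(is_integer_bin(.data$freq),
             .data$freq >= lo_eff - 1e-9, .data$freq <= hi_eff + 1e-9) %>%
      group_by_present(c("subject_id", "group", "channel")) %>%
      summarise(power = mean(.data$norm_psd), .groups = "drop") %>%
      mutate(band = band, partial = (lo_eff > lo) || (hi_eff < hi))
  }) %>%
    mutate(band = factor(.data$band, levels = bands$band)) %>%
    arrange(dplyr::across(dplyr::any_of(c("subject_id", "channel", "band"))))
}

#' Average PSDs over all valid channels of a subject
#'
#' Unweighted mean of the per-channel spectra (raw and, when present,
#' normalized). Because normalization is linear over channels, the
#' montage-mean normalized spectrum still sums to 1 over 3-30 Hz.
#'
#' @param psd_tbl PSD tibble from [average_psd()] or [normalize_psd()],
#'   possibly spanning several subjects.
#' @return A tibble like the input with `channel = "montage"` and one row
#'   per subject and frequency; `n_channels` records how many channels
#'   entered the mean.
#' @export
montage_average <- function(psd_tbl) {
  stopifnot(all(c("channel", "freq", "psd") %in% names(psd_tbl)))
  psd_tbl %>%
    group_by_present(c("subject_id", "group", "freq")) %>%
    summarise(
      n_channels = dplyr::n(),
      dplyr::across(dplyr::any_of(c("psd", "norm_psd")), mean),
      .groups = "drop") %>%
    mutate(channel = "montage", .after = dplyr::any_of("group"))
}

feature_name <- function(channel, bin) sprintf("%s_%dHz", channel, bin)

#' Build the subjects-by-(channel, bin) feature table
#'
#' One row per subject; one column per (montage channel, integer Hz bin)
#' pair over the candidate bins (default 5-11 Hz inclusive, so 7 bins x 14
#' channels = 98 columns for the full montage). Column order is montage
#' order with ascending bins within channel. Channels excluded for a
#' subject yield `NA` cells (impute with [impute_missing()] before
#' modelling).
#'
#' @param norm_psd_tbl Stacked normalized PSD tibble over a cohort
#'   (columns `subject_id`, `group`, `channel`, `freq`, `norm_psd`).
#' @param montage Channel order defining the columns.
#' @param bins Integer candidate bins in Hz.
#' @return A tibble: `subject_id`, `group`, then the feature columns named
#'   `<channel>_<bin>Hz`.
#' @export
build_feature_table <- function(norm_psd_tbl, montage = montage_1020_14(),
                                bins = 5:11) {
  stopifnot(all(c("subject_id", "group", "channel", "freq", "norm_psd") %in%
                  names(norm_psd_tbl)))
  long <- norm_psd_tbl %>%
    filter(.data$channel %in% montage,
           is_integer_bin(.data$freq),
           round(.data$freq) %in% bins) %>%
    mutate(feature = feature_name(.data$channel, round(.data$freq)))
  wide <- long %>%
    select("subject_id", "group", "feature", "norm_psd") %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "norm_psd")
  cols <- as.vector(t(outer(montage, bins, feature_name)))
  for (cl in setdiff(cols, names(wide)))
    wide[[cl]] <- NA_real_
  out <- wide[, c("subject_id", "group", cols)]
  if (nrow(out) < 2 || length(unique(out$group)) < 2)
    abort("feature table needs at least 2 subjects covering both groups")
  out
}

#' Feature columns of a feature table
#' @param table A feature table from [build_feature_table()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "group"))
}

#' Impute missing feature cells with column means
#'
#' Column means are computed over all subjects without reference to group
#' labels, so imputation cannot leak the outcome.
#'
#' @param table A feature table from [build_feature_table()].
#' @return The table with `NA` cells replaced; the number of imputed cells
#'   is recorded in the `"n_imputed"` attribute.
#' @export
impute_missing <- function(table) {
  cols <- feature_columns(table)
  n_imp <- 0L
  for (cl in cols) {
    miss <- is.na(table[[cl]])
    if (any(miss)) {
      table[[cl]][miss] <- mean(table[[cl]], na.rm = TRUE)
      n_imp <- n_imp + sum(miss)
    }
  }
  attr(table, "n_imputed") <- n_imp
  table
}
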