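# Synthetic resting-state EEG cohorts.
#
# Signal model per subject-channel: a stationary Gaussian process whose
# one-sided power spectral density is
#   S(f) = 1 / max(f, 0.5)^pink_exponent  +  sum_b (w_b * j_b)^2 * bump_b(f)
# where w_b are the profile's band weights, j_b log-normal per-subject
# jitters, and bump_b a raised-cosine bump over band b normalized to unit
# mean over the band's integer bins. Realizations are synthesized by
# frequency-domain shaping of white Gaussian noise (one FFT per channel),
# then scaled so the expected channel RMS is 10 uV times a log-normal
# per-channel gain. Absolute scale only matters for artifact amplitudes and
# bad-channel screening; relative band structure is what the downstream
# normalized features see.

BACKGROUND_RMS_UV <- 10

#' Define a group's spectral profile
#'
#' @param name Group label, e.g. `"HC"` or `"AD"`.
#' @param band_weights Named numeric vector with entries `delta`, `theta`,
#'   `alpha`, `beta`: relative oscillatory amplitude per band (>= 0).
#' @param pink_exponent Spectral slope of the 1/f background (>= 0).
#' @param channel_gain_sd SD (log scale) of the per-channel multiplicative
#'   gain.
#' @param subject_sd SD (log scale) of the per-subject multiplicative jitter
#'   applied to each band weight.
#' @return A `group_profile` object.
#' @export
group_profile <- function(name,
                          band_weights = c(delta = 0.6, theta = 0.9,
                                           alpha = 1.9, beta = 0.45),
                          pink_exponent = 1,
                          channel_gain_sd = 0.1,
                          subject_sd = 0.15) {
  need <- c("delta", "theta", "alpha", "beta")
  if (!all(need %in% names(band_weights)))
    stop_config("band_weights", "must name delta, theta, alpha and beta")
  band_weights <- band_weights[need]
  if (any(band_weights < 0))
    stop_config("band_weights", "must be >= 0")
  if (pink_exponent < 0)
    stop_config("pink_exponent", "must be >= 0")
  if (channel_gain_sd < 0 || subject_sd < 0)
    stop_config("channel_gain_sd/subject_sd", "must be >= 0")
  structure(
    list(name = name, band_weights = band_weights,
         pink_exponent = pink_exponent,
         channel_gain_sd = channel_gain_sd, subject_sd = subject_sd),
    class = "group_profile"
  )
}

#' Default healthy-control profile
#'
#' Alpha-dominant resting spectrum over a 1/f background, typical of
#' eyes-closed healthy adults.
#'
#' @return A `group_profile`.
#' @export
profile_hc <- function() group_profile("HC")

#' Default Alzheimer's-disease profile
#'
#' Spectral slowing relative to [profile_hc()]: elevated theta weight,
#' reduced alpha and beta weights. `effect` scales the planted group
#' difference geometrically: 0 gives the HC profile (a null cohort), 1 the
#' full default contrast, values above 1 exaggerate it.
#'
#' @param effect Effect-size multiplier on the log weight ratios.
#' @return A `group_profile`.
#' @export
profile_ad <- function(effect = 1) {
  hc <- profile_hc()
  full <- c(delta = 0.6, theta = 1.35, alpha = 1.25, beta = 0.30)
  ratio <- full / hc$band_weights
  w <- hc$band_weights * ratio^effect
  group_profile("AD", band_weights = w,
                pink_exponent = hc$pink_exponent,
                channel_gain_sd = hc$channel_gain_sd,
                subject_sd = hc$subject_sd)
}

#' Define an artifact injection specification
#'
#' @param rate_per_min Expected events per minute per channel (>= 0).
#' @param kinds Subset of `"ocular"` (low-frequency high-amplitude
#'   transient) and `"muscle"` (broadband > 20 Hz burst).
#' @param amplitude_factor Event peak amplitude relative to the channel's
#'   background RMS (> 1). The default 20 puts events around 200 uV over a
#'   10 uV background, typical of ocular and movement artifacts.
#' @param duration_s Event duration in seconds.
#' @return An `artifact_spec` object.
#' @export
artifact_spec <- function(rate_per_min = 2,
                          kinds = c("ocular", "muscle"),
                          amplitude_factor = 20,
                          duration_s = 0.5) {
  kinds <- match.arg(kinds, c("ocular", "muscle"), several.ok = TRUE)
  if (rate_per_min < 0) stop_config("rate_per_min", "must be >= 0")
  if (amplitude_factor <= 1) stop_config("amplitude_factor", "must be > 1")
  if (duration_s <= 0) stop_config("duration_s", "must be > 0")
  structure(
    list(rate_per_min = rate_per_min, kinds = kinds,
         amplitude_factor = amplitude_factor, duration_s = duration_s),
    class = "artifact_spec"
  )
}

#' Define a synthetic cohort
#'
#' Defaults reproduce the study design the pipeline targets: 23 HC and
#' 18 AD subjects, 5-minute recordings at 250 Hz on the 14-channel 10-20
#' montage.
#'
#' @param n_hc,n_ad Subject counts per group.
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz (> 70 so the 35 Hz analysis ceiling is
#'   below Nyquist).
#' @param channels Ordered channel labels.
#' @param seed Integer RNG seed for the whole cohort.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_hc = 23, n_ad = 18, duration_s = 300, fs = 250,
                        channels = montage_1020_14(), seed = 1) {
  if (n_hc < 0) stop_config("n_hc", "must be >= 0")
  if (n_ad < 0) stop_config("n_ad", "must be >= 0")
  if (n_hc + n_ad < 1) stop_config("n_hc + n_ad", "must be >= 1")
  if (duration_s <= 0) stop_config("duration_s", "must be > 0")
  if (fs <= 70) stop_config("fs", "must exceed 70 Hz (twice the 35 Hz ceiling)")
  if (anyDuplicated(channels)) stop_config("channels", "must be unique")
  structure(
    list(n_hc = n_hc, n_ad = n_ad, duration_s = duration_s, fs = fs,
         channels = as.character(channels), seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Raised-cosine bump over [lo - 0.5, hi + 0.5], normalized to unit mean over
# the band's integer bins.
band_bump <- function(f, lo, hi) {
  a <- lo - 0.5
  b <- hi + 0.5
  centre <- (a + b) / 2
  half <- (b - a) / 2
  rc <- function(x) {
    v <- numeric(length(x))
    inside <- x > a & x < b
    v[inside] <- 0.5 * (1 + cos(pi * (x[inside] - centre) / half))
    v
  }
  bins <- seq(lo, hi)
  rc(f) / mean(rc(bins))
}

# One-sided target PSD shape at frequencies f (>= 0) for a profile with
# jittered weights.
profile_psd_shape <- function(f, profile, jitter = NULL) {
  w <- profile$band_weights
  if (!is.null(jitter)) w <- w * jitter
  s <- 1 / pmax(f, 0.5)^profile$pink_exponent
  bands <- eeg_bands()
  for (i in seq_len(nrow(bands))) {
    wb <- w[[bands$band[i]]]
    if (wb > 0) s <- s + wb^2 * band_bump(f, bands$lo[i], bands$hi[i])
  }
  s
}

#' Generate one subject's synthetic EEG recording
#'
#' Draws per-subject band-weight jitters and per-channel gains, then
#' synthesizes each channel by frequency-domain shaping of white Gaussian
#' noise to the profile's target spectrum. Identical `(profile, spec,
#' subject_seed)` give bit-identical recordings.
#'
#' @param profile A [group_profile()].
#' @param spec A [cohort_spec()] (supplies duration, sampling rate,
#'   channels).
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier stored in the recording.
#' @return An [eeg_recording()] with `group` set to the profile name.
#' @export
generate_subject_eeg <- function(profile, spec, subject_seed,
                                 subject_id = "subject") {
  stopifnot(inherits(profile, "group_profile"), inherits(spec, "cohort_spec"))
  n <- as.integer(round(spec$duration_s * spec$fs))
  nch <- length(spec$channels)
  with_local_seed(subject_seed, {
    jitter <- stats::rlnorm(4, 0, profile$subject_sd)
    names(jitter) <- c("delta", "theta", "alpha", "beta")
    gains <- stats::rlnorm(nch, 0, profile$channel_gain_sd)
    z <- matrix(rnorm(n * nch), nrow = n, ncol = nch)

    k <- 0:(n - 1)
    fgrid <- pmin(k, n - k) * spec$fs / n   # |f| on the two-sided DFT grid
    h <- sqrt(profile_psd_shape(fgrid, profile, jitter))
    h[1] <- 0                               # no DC
    x <- Re(stats::mvfft(stats::mvfft(z) * h, inverse = TRUE)) / n
    scale <- BACKGROUND_RMS_UV / sqrt(mean(h^2))
    x <- sweep(x, 2, gains * scale, `*`)
    eeg_recording(t(x), fs = spec$fs, channels = spec$channels,
                  subject_id = subject_id, group = profile$name)
  })
}

# Unit-peak event waveform of L samples, enveloped by a short-taper Tukey
# window so the event carries near-full amplitude over its whole duration.
# Ocular events are trains of sharp biphasic deflections (derivative-of-
# Gaussian, ~50 ms lobes, random polarity) like blink flutter; muscle
# events are 20-45 Hz noise bursts.
artifact_waveform <- function(kind, L, fs) {
  i <- seq_len(L) - 1
  taper <- max(2, round(0.1 * L))
  win <- rep(1, L)
  ramp <- 0.5 - 0.5 * cos(pi * (0:(taper - 1)) / taper)
  win[1:taper] <- ramp
  win[L:(L - taper + 1)] <- ramp
  if (kind == "ocular") {
    n_pulse <- max(2, round(L / fs / 0.35))
    centres <- seq(0.06 * fs, L - 0.06 * fs, length.out = n_pulse)
    if (L < 0.15 * fs) centres <- L / 2
    w <- numeric(L)
    for (ctr in centres) {
      s <- (i - ctr) / (0.05 * fs)
      w <- w + sample(c(-1, 1), 1) * (-s * exp(-s^2 / 2))
    }
    w <- win * w
  } else {
    z <- rnorm(L)
    zf <- fft(z)
    f <- pmin(i, L - i) * fs / L
    zf[f < 20 | f > 45] <- 0
    w <- win * Re(fft(zf, inverse = TRUE)) / L
  }
  w / max(abs(w))
}

#' Inject transient artifacts into a recording
#'
#' Adds Poisson-distributed ocular and/or muscle events per channel and
#' returns the contaminated copy together with a ground-truth mask marking
#' every 1-s epoch that overlaps an injected event. Samples outside marked
#' epochs are untouched.
#'
#' @param rec An [eeg_recording()].
#' @param spec An [artifact_spec()].
#' @param seed Integer seed.
#' @param epoch_length_s Epoch grid used for the ground-truth mask.
#' @return A list with elements `recording` (modified copy), `mask`
#'   (an `artifact_mask` with the ground truth), and `events` (tibble of
#'   injected events: `channel`, `kind`, `start_s`, `duration_s`).
#' @export
inject_artifacts <- function(rec, spec, seed, epoch_length_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "artifact_spec"))
  n <- ncol(rec$data)
  if (n == 0) abort("recording is empty")
  dur <- n / rec$fs
  n_ep <- floor(dur / epoch_length_s)
  spe <- as.integer(round(rec$fs * epoch_length_s))
  L <- max(2L, as.integer(round(spec$duration_s * rec$fs)))

  expected_marked_s <- spec$rate_per_min * (dur / 60) *
    (spec$duration_s + epoch_length_s)
  if (dur >= 90 && dur - expected_marked_s < 90)
    warn(sprintf(
      "artifact rate leaves ~%.0f s clean in expectation (< 90 s)",
      max(0, dur - expected_marked_s)))

  data <- rec$data
  mask_mat <- matrix(FALSE, nrow = nrow(data), ncol = n_ep)
  events <- list()
  with_local_seed(seed, {
    for (ch in seq_len(nrow(data))) {
      n_ev <- rpois(1, spec$rate_per_min * dur / 60)
      if (n_ev == 0) next
      rms_ch <- sqrt(mean(data[ch, ]^2))
      starts <- runif(n_ev, 0, max(0, dur - spec$duration_s))
      kinds <- sample(spec$kinds, n_ev, replace = TRUE)
      for (ev in seq_len(n_ev)) {
        idx0 <- floor(starts[ev] * rec$fs) + 1
        idx <- idx0:min(idx0 + L - 1, n)
        w <- artifact_waveform(kinds[ev], L, rec$fs)[seq_along(idx)]
        data[ch, idx] <- data[ch, idx] + spec$amplitude_factor * rms_ch * w
        ep_a <- (idx[1] - 1) %/% spe + 1
        ep_b <- (idx[length(idx)] - 1) %/% spe + 1
        eps <- ep_a:min(ep_b, n_ep)
        mask_mat[ch, eps[eps >= 1]] <- TRUE
      }
      events[[length(events) + 1]] <- tibble(
        channel = rec$channels[ch], kind = kinds, start_s = starts,
        duration_s = spec$duration_s)
    }
  })
  out <- rec
  out$data <- data
  epochs <- tibble(
    channel = rep(rec$channels, each = n_ep),
    epoch = rep(seq_len(n_ep), times = nrow(data)),
    is_artifact = as.vector(t(mask_mat))
  )
  list(recording = out,
       mask = new_artifact_mask(epochs, epoch_length_s),
       events = if (length(events)) bind_rows(events) else
         tibble(channel = character(), kind = character(),
                start_s = numeric(), duration_s = numeric()))
}

#' Generate a labelled synthetic cohort
#'
#' Produces `n_hc + n_ad` recordings (HC first, then AD) with per-subject
#' seeds derived deterministically from the cohort seed, optionally
#' contaminated with artifacts carrying ground-truth masks.
#'
#' @param hc_profile,ad_profile [group_profile()]s for the two groups.
#' @param spec A [cohort_spec()].
#' @param artifacts Optional [artifact_spec()]; `NULL` for artifact-free
#'   cohorts.
#' @return An `eeg_cohort`: list with `recordings` (named list of
#'   [eeg_recording()]s), `masks` (named list of ground-truth
#'   `artifact_mask`s or `NULL`), and the generating specs.
#' @export
generate_cohort <- function(hc_profile = profile_hc(),
                            ad_profile = profile_ad(),
                            spec = cohort_spec(),
                            artifacts = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- c(sprintf("HC%02d", seq_len(spec$n_hc)),
           sprintf("AD%02d", seq_len(spec$n_ad)))
  profiles <- c(rep(list(hc_profile), spec$n_hc),
                rep(list(ad_profile), spec$n_ad))
  recordings <- vector("list", length(ids))
  masks <- if (is.null(artifacts)) NULL else vector("list", length(ids))
  for (i in seq_along(ids)) {
    rec <- generate_subject_eeg(profiles[[i]], spec,
                                subject_seed(spec$seed, i),
                                subject_id = ids[i])
    if (!is.null(artifacts)) {
      inj <- inject_artifacts(rec, artifacts,
                              seed = subject_seed(spec$seed + 500009L, i))
      rec <- inj$recording
      masks[[i]] <- inj$mask
    }
    recordings[[i]] <- rec
  }
  names(recordings) <- ids
  if (!is.null(masks)) names(masks) <- ids
  structure(
    list(recordings = recordings, masks = masks, spec = spec,
         hc_profile = hc_profile, ad_profile = ad_profile,
         artifact_spec = artifacts),
    class = "eeg_cohort"
  )
}

#' @export
print.eeg_cohort <- function(x, ...) {
  groups <- vapply(x$recordings, function(r) r$group, character(1))
  cat(sprintf(
    "<eeg_cohort> %d subjects (%d HC, %d AD), %d channels, %.0f s at %g Hz\n",
    length(x$recordings), sum(groups == "HC"), sum(groups == "AD"),
    length(x$spec$channels), x$spec$duration_s, x$spec$fs))
  if (!is.null(x$masks)) cat("  ground-truth artifact masks present\n")
  invisible(x)
}

#' Summarise a cohort as a tibble
#'
#' @param object An `eeg_cohort`.
#' @param ... Unused.
#' @return One row per subject: `subject_id`, `group`, `n_channels`,
#'   `duration_s`, `fs`.
#' @export
summary.eeg_cohort <- function(object, ...) {
  purrr::map_dfr(object$recordings, function(r) {
    tibble(subject_id = r$subject_id, group = r$group,
           n_channels = length(r$channels),
           duration_s = duration_s(r), fs = r$fs)
  })
}

#' Write a cohort to disk as plain-text files
#'
#' One `<id>_data.csv` (samples x channels) plus `<id>.json` sidecar
#' (subject id, group, sampling rate, channel order) per subject, a
#' `labels.csv`, and — when ground-truth masks exist — a `masks.csv` with
#' columns subject, channel, epoch_index, is_artifact.
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    utils::write.csv(t(rec$data),
                     file.path(dir, paste0(rec$subject_id, "_data.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(subject_id = rec$subject_id, group = rec$group, fs = rec$fs,
           channels = rec$channels),
      file.path(dir, paste0(rec$subject_id, ".json")),
      auto_unbox = TRUE)
  }
  utils::write.csv(summary(cohort)[, c("subject_id", "group")],
                   file.path(dir, "labels.csv"), row.names = FALSE)
  if (!is.null(cohort$masks)) {
    masks <- purrr::imap_dfr(cohort$masks, function(m, id)
      dplyr::mutate(m$epochs, subject = id, .before = 1))
    names(masks)[names(masks) == "epoch"] <- "epoch_index"
    utils::write.csv(masks, file.path(dir, "masks.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `*_data.csv` + `*.json` pairs.
#' @return An `eeg_cohort` (without generating specs; masks restored when
#'   `masks.csv` is present).
#' @export
read_cohort <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(sidecars) == 0) abort(sprintf("no subject sidecars in %s", dir))
  recordings <- lapply(sidecars, function(sc) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    dat <- utils::read.csv(
      file.path(dir, paste0(meta$subject_id, "_data.csv")))
    eeg_recording(t(as.matrix(dat)), fs = meta$fs, channels = meta$channels,
                  subject_id = meta$subject_id, group = meta$group)
  })
  names(recordings) <- vapply(recordings, function(r) r$subject_id,
                              character(1))
  masks <- NULL
  mf <- file.path(dir, "masks.csv")
  if (file.exists(mf)) {
    mtbl <- as_tibble(utils::read.csv(mf))
    masks <- lapply(split(mtbl, mtbl$subject), function(d) {
      new_artifact_mask(
        tibble(channel = d$channel, epoch = d$epoch_index,
               is_artifact = as.logical(d$is_artifact)),
        epoch_length_s = 1)
    })
    masks <- masks[names(recordings)]
  }
  structure(
    list(recordings = recordings, masks = masks, spec = NULL,
         hc_profile = NULL, ad_profile = NULL, artifact_spec = NULL),
    class = "eeg_cohort"
  )
}
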