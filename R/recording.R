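#' Construct an EEG recording
#'
#' Light S3 container for one subject's multi-channel resting-state EEG:
#' a channels-by-samples voltage matrix (microvolts) plus sampling rate,
#' ordered channel labels, and an optional group label.
#'
#' @param data Numeric matrix, channels in rows, samples in columns (uV).
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels, one per row of `data`.
#' @param subject_id Subject identifier.
#' @param group Group label, `"HC"`, `"AD"` or `NA`.
#' @param excluded_channels Tibble with columns `channel`, `reason` recording
#'   channels dropped along the way (starts empty).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels, subject_id = "subject",
                          group = NA_character_,
                          excluded_channels = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != length(channels))
    abort("`data` must have one row per channel label")
  if (anyDuplicated(channels))
    abort("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop_config("fs", "must be a single positive number")
  if (is.null(excluded_channels))
    excluded_channels <- tibble(channel = character(), reason = character())
  rownames(data) <- channels
  structure(
    list(
      subject_id = subject_id,
      group = group,
      fs = fs,
      channels = as.character(channels),
      data = data,
      excluded_channels = excluded_channels
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$fs
  cat(sprintf(
    "<eeg_recording> %s  group: %s\n  %d channels x %d samples (%.1f s at %g Hz)\n",
    x$subject_id, ifelse(is.na(x$group), "?", x$group),
    nrow(x$data), ncol(x$data), dur, x$fs
  ))
  if (nrow(x$excluded_channels) > 0)
    cat(sprintf("  excluded: %s\n",
                paste(x$excluded_channels$channel, collapse = ", ")))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Segment a recording into fixed-length epochs
#'
#' Cuts each channel into consecutive non-overlapping windows of
#' `epoch_length_s` seconds; a trailing partial window is discarded.
#' Concatenating the epochs reproduces the input truncated at the last full
#' window.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_length_s Epoch length in seconds (default 1).
#' @return An `epoch_array`: list with `epochs` (array channel x epoch x
#'   sample), `fs`, `epoch_length_s`, `n_epochs`, `channels`, `subject_id`,
#'   `group`.
#' @export
epoch <- function(rec, epoch_length_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- rec$fs * epoch_length_s
  if (abs(spe - round(spe)) > 1e-9)
    stop_config("epoch_length_s", "must give a whole number of samples per epoch")
  spe <- as.integer(round(spe))
  n <- ncol(rec$data)
  n_epochs <- n %/% spe
  if (n_epochs < 1)
    abort("recording shorter than one epoch")
  nch <- nrow(rec$data)
  used <- rec$data[, seq_len(n_epochs * spe), drop = FALSE]
  # (channel, sample-within-epoch, epoch) -> (channel, epoch, sample)
  arr <- array(used, dim = c(nch, spe, n_epochs))
  arr <- aperm(arr, c(1, 3, 2))
  dimnames(arr) <- list(rec$channels, NULL, NULL)
  structure(
    list(
      subject_id = rec$subject_id,
      group = rec$group,
      fs = rec$fs,
      epoch_length_s = epoch_length_s,
      n_epochs = n_epochs,
      channels = rec$channels,
      epochs = arr
    ),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf(
    "<epoch_array> %s: %d channels x %d epochs of %g s at %g Hz\n",
    x$subject_id, length(x$channels), x$n_epochs, x$epoch_length_s, x$fs
  ))
  invisible(x)
}

#' Reassemble an epoch array into a continuous matrix
#'
#' Inverse of [epoch()] up to the discarded trailing partial window.
#'
#' @param ep An `epoch_array`.
#' @return A channels-by-samples matrix.
#' @export
unepoch <- function(ep) {
  arr <- aperm(ep$epochs, c(1, 3, 2))  # channel, sample, epoch
  dim(arr) <- c(dim(arr)[1], dim(arr)[2] * dim(arr)[3])
  rownames(arr) <- ep$channels
  arr
}
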