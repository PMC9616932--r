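# Per-epoch artifact screening: five summary features per (channel, epoch),
# a margin classifier (SVM) or a deterministic amplitude-threshold rule, and
# the minimum clean-duration gate.

new_artifact_mask <- function(epochs, epoch_length_s, channels = NULL,
                              min_clean_s = NA_real_) {
  structure(
    list(epochs = epochs, channels = channels,
         epoch_length_s = epoch_length_s, min_clean_s = min_clean_s),
    class = "artifact_mask"
  )
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d channels x %d epochs, %d flagged (%.1f%%)\n",
              length(unique(x$epochs$channel)),
              max(x$epochs$epoch),
              sum(x$epochs$is_artifact),
              100 * mean(x$epochs$is_artifact)))
  if (!is.null(x$channels))
    cat(sprintf("  clean-duration gate at %g s: %d/%d channels valid\n",
                x$min_clean_s, sum(x$channels$is_valid), nrow(x$channels)))
  invisible(x)
}

#' Per-epoch screening features
#'
#' For every (channel, epoch): maximum absolute amplitude (uV), variance
#' (uV^2), line length (mean absolute first difference, uV), excess
#' kurtosis (0 by convention for constant epochs), and the fraction of
#' periodogram power above 20 Hz.
#'
#' @param epochs An `epoch_array` from [epoch()].
#' @return A tibble with columns `channel`, `epoch` and the five features.
#' @export
extract_epoch_features <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_array"))
  arr <- epochs$epochs
  nch <- dim(arr)[1]; nep <- dim(arr)[2]; spe <- dim(arr)[3]
  if (nep < 1) abort("no epochs to featurize")
  # columns = one epoch of one channel; column order: channel fastest
  m <- matrix(aperm(arr, c(3, 1, 2)), nrow = spe)
  mu <- colMeans(m)
  cm <- sweep(m, 2, mu)
  v <- colSums(cm^2) / (spe - 1)
  m2 <- colSums(cm^2) / spe
  m4 <- colSums(cm^4) / spe
  kurt <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)
  max_abs <- apply(abs(m), 2, max)
  ll <- colMeans(abs(diff(m)))
  pw <- Mod(stats::mvfft(m))^2
  f <- (seq_len(spe) - 1) * epochs$fs / spe
  pos <- f > 0 & f <= epochs$fs / 2
  tot <- colSums(pw[pos, , drop = FALSE])
  hi <- colSums(pw[pos & f > 20, , drop = FALSE])
  hfr <- ifelse(tot > 0, hi / tot, 0)
  tibble(
    channel = rep(epochs$channels, times = nep),
    epoch = rep(seq_len(nep), each = nch),
    max_abs_amplitude = max_abs,
    variance = v,
    line_length = ll,
    kurtosis = kurt,
    high_freq_ratio = hfr
  ) %>% arrange(.data$channel, .data$epoch)
}

artifact_feature_names <- function() {
  c("max_abs_amplitude", "variance", "line_length", "kurtosis",
    "high_freq_ratio")
}

#' Train the epoch-level artifact classifier
#'
#' Fits a margin classifier (support vector machine on the five
#' standardized screening features; radial or linear kernel) to labelled
#' epochs, e.g. labels taken from a synthetic cohort's ground-truth masks.
#'
#' @param features Tibble from [extract_epoch_features()].
#' @param labels Logical vector (`TRUE` = artifact), aligned with the rows
#'   of `features`.
#' @param seed Integer seed (the fit itself is deterministic; the seed is
#'   fixed for reproducibility of any internal sampling).
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost SVM cost parameter.
#' @return An `artifact_model`.
#' @export
train_artifact_classifier <- function(features, labels, seed = 0,
                                      kernel = c("radial", "linear"),
                                      cost = 1) {
  kernel <- match.arg(kernel)
  y <- as.logical(labels)
  if (length(unique(y)) < 2)
    abort("both artifact and clean epochs are required for training")
  x <- as.matrix(features[, artifact_feature_names()])
  fit <- with_local_seed(seed, {
    e1071::svm(x, factor(y, levels = c(FALSE, TRUE)), kernel = kernel,
               cost = cost, scale = TRUE)
  })
  structure(
    list(svm = fit, kernel = kernel, cost = cost,
         features = artifact_feature_names()),
    class = "artifact_model"
  )
}

#' @export
print.artifact_model <- function(x, ...) {
  cat(sprintf("<artifact_model> SVM (%s kernel, cost %g) on %d features\n",
              x$kernel, x$cost, length(x$features)))
  invisible(x)
}

#' Classify epochs as artifact or clean
#'
#' Applies either a trained [train_artifact_classifier()] model or, when
#' `model` is `NULL`, the deterministic fallback rule: an epoch is an
#' artifact when its maximum absolute amplitude exceeds `threshold_uv`.
#'
#' @param features Tibble from [extract_epoch_features()].
#' @param model An `artifact_model`, or `NULL` for the threshold rule.
#' @param threshold_uv Amplitude threshold in uV for the fallback rule
#'   (default 100).
#' @param epoch_length_s Epoch length in seconds.
#' @return An `artifact_mask` (ungated; see [apply_clean_duration_gate()]).
#' @export
classify_epochs <- function(features, model = NULL, threshold_uv = 100,
                            epoch_length_s = 1) {
  need <- c("channel", "epoch", artifact_feature_names())
  if (!all(need %in% names(features)))
    abort("`features` must come from extract_epoch_features()")
  if (is.null(model)) {
    flag <- features$max_abs_amplitude > threshold_uv
  } else {
    stopifnot(inherits(model, "artifact_model"))
    x <- as.matrix(features[, model$features])
    flag <- stats::predict(model$svm, x) == "TRUE"
  }
  new_artifact_mask(
    tibble(channel = features$channel, epoch = features$epoch,
           is_artifact = flag),
    epoch_length_s = epoch_length_s
  )
}

#' Apply the minimum clean-duration gate
#'
#' Computes each channel's artifact-free duration and marks it valid when
#' that duration is at least `min_clean_s` (inclusive; default 90 s, i.e.
#' 1.5 min). Channels failing the gate are excluded from all downstream
#' averaging; a subject with no valid channel is flagged for exclusion via
#' the `subject_valid` attribute.
#'
#' @param mask An `artifact_mask`.
#' @param min_clean_s Minimum artifact-free duration in seconds.
#' @return The gated `artifact_mask`, with a per-channel tibble in
#'   `$channels` (`channel`, `clean_duration_s`, `is_valid`).
#' @export
apply_clean_duration_gate <- function(mask, min_clean_s = 90) {
  stopifnot(inherits(mask, "artifact_mask"))
  ch <- mask$epochs %>%
    group_by(.data$channel) %>%
    summarise(
      clean_duration_s = sum(!.data$is_artifact) * mask$epoch_length_s,
      .groups = "drop") %>%
    mutate(is_valid = .data$clean_duration_s >= min_clean_s)
  out <- mask
  out$channels <- ch
  out$min_clean_s <- min_clean_s
  attr(out, "subject_valid") <- any(ch$is_valid)
  out
}

#' Confusion summary of a predicted mask against ground truth
#'
#' @param predicted,truth `artifact_mask`s over the same (channel, epoch)
#'   grid.
#' @return One-row tibble with `sensitivity`, `specificity`, `n_artifact`,
#'   `n_clean`.
#' @export
mask_confusion <- function(predicted, truth) {
  j <- dplyr::inner_join(predicted$epochs, truth$epochs,
                         by = c("channel", "epoch"),
                         suffix = c("_pred", "_true"))
  if (nrow(j) != nrow(truth$epochs))
    abort("masks are not on the same (channel, epoch) grid")
  tibble(
    sensitivity = mean(j$is_artifact_pred[j$is_artifact_true]),
    specificity = mean(!j$is_artifact_pred[!j$is_artifact_true]),
    n_artifact = sum(j$is_artifact_true),
    n_clean = sum(!j$is_artifact_true)
  )
}
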