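# ggplot2 views of the main result types: group-mean spectra, band powers,
# the t-statistic heat map, and the pooled out-of-fold ROC curve.

#' Group-mean normalized PSD with SEM ribbons
#'
#' @param psd_tbl Normalized PSD tibble (typically [montage_average()]
#'   output over a cohort) with `group`, `freq`, `norm_psd`.
#' @param range Frequency range to display (Hz).
#' @return A ggplot object.
#' @export
plot_psd <- function(psd_tbl, range = c(3, 35)) {
  stopifnot(all(c("group", "freq", "norm_psd") %in% names(psd_tbl)))
  d <- psd_tbl %>%
    filter(.data$freq >= range[1], .data$freq <= range[2]) %>%
    group_by(.data$group, .data$freq) %>%
    summarise(mean = mean(.data$norm_psd),
              sem = sd(.data$norm_psd) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$freq, .data$mean,
                                  colour = .data$group,
                                  fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Relative power",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Band-power group comparison bar plot
#'
#' @param band_stats Tibble from [band_comparison()].
#' @return A ggplot object (group means with SEM error bars per band).
#' @export
plot_band_power <- function(band_stats) {
  d <- band_stats %>%
    tidyr::pivot_longer(c("mean_hc", "mean_ad"), names_to = "group",
                        values_to = "mean") %>%
    mutate(sem = ifelse(.data$group == "mean_hc", .data$sem_hc,
                        .data$sem_ad),
           group = ifelse(.data$group == "mean_hc", "HC", "AD"))
  ggplot2::ggplot(d, ggplot2::aes(.data$band, .data$mean,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "Mean relative band power", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Heat map of per-feature t statistics
#'
#' Channels on the y axis (montage order), candidate bins on the x axis;
#' cells with p < 0.05 are outlined.
#'
#' @param feature_stats Tibble from [groupwise_ttest()].
#' @param montage Channel order for the y axis.
#' @return A ggplot object.
#' @export
plot_t_heatmap <- function(feature_stats, montage = montage_1020_14()) {
  d <- feature_stats %>%
    mutate(channel = factor(.data$channel, levels = rev(montage)),
           significant = !is.na(.data$p) & .data$p < 0.05)
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$bin), .data$channel,
                                  fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = d[d$significant, ], fill = NA,
                       colour = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy") +
    ggplot2::labs(x = "Frequency bin (Hz)", y = NULL,
                  fill = "t (HC - AD)") +
    ggplot2::theme_minimal()
}

#' ROC curve of pooled out-of-fold predictions
#'
#' @param object An `eeg_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eeg_cv
#' @export
autoplot.eeg_cv <- function(object, ...) {
  p <- object$predictions
  truth <- p$group == object$positive
  ord <- order(-p$prob_positive)
  tpr <- c(0, cumsum(truth[ord]) / sum(truth))
  fpr <- c(0, cumsum(!truth[ord]) / sum(!truth))
  d <- tibble(fpr = fpr, tpr = tpr)
  ggplot2::ggplot(d, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Pooled out-of-fold ROC (AUC %.1f%%)",
                      object$metrics$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
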