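# Group-comparison statistics and statistics-guided feature selection.
#
# Group convention everywhere: t statistics are HC minus AD, two-tailed.
# The default is Welch's unequal-variance t; `var_equal = TRUE` gives the
# pooled-variance Student test. No multiple-testing correction enters the
# selection (features are ranked by raw p); a Benjamini-Hochberg adjusted
# column is reported alongside for transparency.

two_group_t <- function(hc, ad, var_equal = FALSE) {
  hc <- hc[!is.na(hc)]
  ad <- ad[!is.na(ad)]
  if (length(hc) < 2 || length(ad) < 2)
    abort("each group needs at least 2 observations")
  res <- tryCatch(
    t.test(hc, ad, var.equal = var_equal),
    error = function(e) NULL)   # constant data
  if (is.null(res)) {
    t_val <- if (mean(hc) == mean(ad)) 0 else NA_real_
    p_val <- if (mean(hc) == mean(ad)) 1 else NA_real_
    degenerate <- TRUE
  } else {
    t_val <- unname(res$statistic)
    p_val <- res$p.value
    degenerate <- FALSE
  }
  tibble(
    t = t_val, p = p_val,
    mean_hc = mean(hc), mean_ad = mean(ad),
    sd_hc = sd(hc), sd_ad = sd(ad),
    sem_hc = sd(hc) / sqrt(length(hc)), sem_ad = sd(ad) / sqrt(length(ad)),
    n_hc = length(hc), n_ad = length(ad),
    degenerate = degenerate
  )
}

#' Per-feature two-sample t-tests between groups
#'
#' Compares every feature column of a feature table between the HC and AD
#' groups with a two-tailed, unpaired two-sample t-test (Welch by default).
#' The sign convention is HC minus AD: a negative t means the feature is
#' larger in AD. Missing cells are dropped pairwise; a Benjamini-Hochberg
#' adjusted p (`p_bh`) is reported but never used for selection.
#'
#' @param table Feature table from [build_feature_table()].
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @param groups Length-2 character, the (reference, comparison) labels.
#' @return A tibble, one row per feature: `feature`, `channel`, `bin`, `t`,
#'   `p`, `p_bh`, group means/SDs/SEMs/sizes, `degenerate`.
#' @export
groupwise_ttest <- function(table, var_equal = FALSE,
                            groups = c("HC", "AD")) {
  cols <- feature_columns(table)
  g <- table$group
  if (sum(g == groups[1]) < 2 || sum(g == groups[2]) < 2)
    abort("each group needs at least 2 subjects")
  x1 <- as.matrix(table[g == groups[1], cols, drop = FALSE])
  x2 <- as.matrix(table[g == groups[2], cols, drop = FALSE])
  col_stats <- function(x) {
    n <- colSums(!is.na(x))
    m <- colMeans(x, na.rm = TRUE)
    v <- (colSums(x^2, na.rm = TRUE) - n * m^2) / (n - 1)
    v <- pmax(v, 0)
    list(n = n, m = m, v = v)
  }
  s1 <- col_stats(x1); s2 <- col_stats(x2)
  if (any(s1$n < 2) || any(s2$n < 2))
    abort("each group needs at least 2 non-missing values per feature")
  if (var_equal) {
    sp2 <- ((s1$n - 1) * s1$v + (s2$n - 1) * s2$v) / (s1$n + s2$n - 2)
    se2 <- sp2 * (1 / s1$n + 1 / s2$n)
    df <- s1$n + s2$n - 2
  } else {
    a <- s1$v / s1$n; b <- s2$v / s2$n
    se2 <- a + b
    df <- se2^2 / (a^2 / (s1$n - 1) + b^2 / (s2$n - 1))
  }
  degenerate <- se2 <= 0 | !is.finite(df)
  t_val <- ifelse(degenerate,
                  ifelse(s1$m == s2$m, 0, NA_real_),
                  (s1$m - s2$m) / sqrt(se2))
  p_val <- ifelse(degenerate,
                  ifelse(s1$m == s2$m, 1, NA_real_),
                  2 * stats::pt(-abs(t_val), df))
  out <- tibble(
    feature = cols, t = unname(t_val), p = unname(p_val),
    mean_hc = unname(s1$m), mean_ad = unname(s2$m),
    sd_hc = unname(sqrt(s1$v)), sd_ad = unname(sqrt(s2$v)),
    sem_hc = unname(sqrt(s1$v / s1$n)), sem_ad = unname(sqrt(s2$v / s2$n)),
    n_hc = unname(s1$n), n_ad = unname(s2$n),
    degenerate = unname(degenerate)
  )
  parts <- strsplit(out$feature, "_(?=[0-9]+Hz$)", perl = TRUE)
  out$channel <- vapply(parts, `[`, character(1), 1)
  out$bin <- suppressWarnings(
    as.integer(sub("Hz$", "", vapply(parts, `[`, character(1), 2))))
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out %>% select("feature", "channel", "bin", "t", "p", "p_bh",
                 dplyr::everything())
}

#' Band-level group comparison on montage-mean band powers
#'
#' One two-tailed, unpaired t-test per frequency band comparing the
#' montage-averaged relative band power between groups, with group means
#' and SEMs for plotting.
#'
#' @param band_tbl Tibble from [band_power()] on montage-averaged spectra:
#'   columns `subject_id`, `group`, `band`, `power`.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @param groups Length-2 character, the (reference, comparison) labels.
#' @return A tibble with one row per band.
#' @export
band_comparison <- function(band_tbl, var_equal = FALSE,
                            groups = c("HC", "AD")) {
  stopifnot(all(c("group", "band", "power") %in% names(band_tbl)))
  band_tbl %>%
    group_by(.data$band) %>%
    dplyr::group_modify(function(d, key) {
      two_group_t(d$power[d$group == groups[1]],
                  d$power[d$group == groups[2]],
                  var_equal = var_equal)
    }) %>%
    ungroup()
}

#' Select the k features with the lowest p-values
#'
#' Ranks candidate features by ascending p; ties are broken
#' deterministically by larger |t|, then montage order, then ascending bin.
#' Features with undefined p (degenerate columns) are never selected.
#'
#' @param stats Tibble from [groupwise_ttest()].
#' @param k Number of features to select (default 4).
#' @param montage Channel order used for tie-breaking.
#' @return The top-`k` rows of `stats`, ascending in p, with a `rank`
#'   column.
#' @export
select_top_features <- function(stats, k = 4, montage = montage_1020_14()) {
  cand <- stats %>% filter(!is.na(.data$p))
  if (nrow(cand) < k)
    abort(sprintf("only %d candidate features with defined p (need %d)",
                  nrow(cand), k))
  cand %>%
    arrange(.data$p, desc(abs(.data$t)),
            match(.data$channel, montage), .data$bin) %>%
    head(k) %>%
    mutate(rank = row_number(), .before = 1)
}
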