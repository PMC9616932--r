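# Stratified k-fold cross-validated, L2-regularized logistic regression and
# the pooled out-of-fold metrics.
#
# The regularized fit minimizes
#   -loglik(beta) + ||w||^2 / (2C)
# with the intercept unpenalized, so the inverse-regularization C has its
# conventional meaning (C = 1 default) and larger C means less shrinkage.

#' Partition subjects into stratified folds
#'
#' Shuffles each class with the given seed and deals it into `k` folds so
#' per-fold class counts differ from exact proportionality by at most one
#' subject. Deterministic given the seed.
#'
#' @param labels Character or factor vector of class labels.
#' @param k Number of folds (default 5).
#' @param seed Integer shuffle seed (default 0).
#' @return Integer vector of fold assignments (1..k) aligned with `labels`.
#' @export
stratified_folds <- function(labels, k = 5, seed = 0) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k))
    abort(sprintf("every class needs at least k = %d members", k))
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cls in names(counts)) {
      idx <- sample(which(labels == cls))
      n <- length(idx)
      sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
      fold[idx] <- rep(seq_len(k), times = sizes)
    }
  })
  fold
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit an L2-regularized logistic regression
#'
#' Penalized iteratively-reweighted least squares (Newton) fit of a binary
#' logistic model with ridge penalty `1/(2C)` on the slopes and an
#' unpenalized intercept. Handles single-feature designs and separable
#' data (the penalty keeps the optimum finite).
#'
#' @param x Numeric matrix of predictors (rows = subjects). Standardize
#'   with training-fold statistics before fitting; [cross_validate()] does
#'   this for you.
#' @param y Logical or 0/1 vector, `TRUE`/1 for the positive class.
#' @param C Inverse regularization strength (default 1).
#' @param max_iter Newton iteration cap (default 400).
#' @param tol Convergence tolerance on the coefficient step.
#' @param intercept Fit an intercept (default `TRUE`).
#' @return A `logit_model`: list with `intercept`, `coef`, `C`,
#'   `converged`, `n_iter`.
#' @export
fit_logistic <- function(x, y, C = 1, max_iter = 400, tol = 1e-10,
                         intercept = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) abort("both classes must be present")
  if (C <= 0) stop_config("C", "must be > 0")
  n <- nrow(x); p <- ncol(x)
  X <- if (intercept) cbind(1, x) else x
  pen <- c(if (intercept) 0 else NULL, rep(1 / C, p))
  beta <- numeric(ncol(X))
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- sigmoid(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X * w, X) + diag(pen, ncol(X))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warn(sprintf("logistic fit did not converge in %d iterations", max_iter))
  structure(
    list(
      intercept = if (intercept) unname(beta[1]) else 0,
      coef = stats::setNames(beta[(if (intercept) 2 else 1):length(beta)],
                             colnames(x)),
      C = C, converged = converged, n_iter = iter
    ),
    class = "logit_model"
  )
}

#' @export
print.logit_model <- function(x, ...) {
  cat(sprintf("<logit_model> C = %g, %d features, %s in %d iterations\n",
              x$C, length(x$coef),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Predict from a fitted logistic model
#'
#' @param object A `logit_model`.
#' @param newx Numeric matrix on the same scale as the training matrix.
#' @param type `"response"` for probabilities, `"class"` for 0/1 at 0.5.
#' @param ... Unused.
#' @return Numeric vector of probabilities or 0/1 labels.
#' @export
predict.logit_model <- function(object, newx,
                                type = c("response", "class"), ...) {
  type <- match.arg(type)
  pr <- sigmoid(drop(as.matrix(newx) %*% object$coef + object$intercept))
  if (type == "class") as.numeric(pr >= 0.5) else pr
}

# Rank (Mann-Whitney) AUC of scores for a logical/0-1 truth vector;
# ties get the midrank convention.
rank_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  s <- apply(train, 2, sd)
  s[s == 0 | is.na(s)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, s, `/`),
       test = sweep(sweep(test, 2, mu), 2, s, `/`))
}

#' Default hyperparameter grid
#'
#' Inverse regularization strengths spanning four orders of magnitude
#' around the conventional default C = 1, L2 penalty, intercept on.
#'
#' @return A tibble with a `C` column.
#' @export
default_grid <- function() tibble(C = c(0.01, 0.1, 1, 10, 100))

#' Grid-search hyperparameters by cross-validated accuracy
#'
#' Evaluates every grid row by stratified k-fold pooled accuracy and
#' returns the best; ties go to stronger regularization (smaller C), then
#' grid order.
#'
#' @param x Feature matrix (rows = subjects).
#' @param y Logical vector, `TRUE` for the positive class.
#' @param grid Tibble with a `C` column (see [default_grid()]).
#' @param k Folds (default 5).
#' @param seed Fold shuffle seed.
#' @return A list: `best` (one-row tibble), `results` (grid with an
#'   `accuracy` column, proportion in 0-1).
#' @export
grid_search <- function(x, y, grid = default_grid(), k = 5, seed = 0) {
  if (is.null(grid) || nrow(grid) == 0) abort("hyperparameter grid is empty")
  x <- as.matrix(x)
  fold <- stratified_folds(ifelse(y, "pos", "neg"), k = k, seed = seed)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0
    for (f in seq_len(k)) {
      st <- standardize_train_test(x[fold != f, , drop = FALSE],
                                   x[fold == f, , drop = FALSE])
      m <- fit_logistic(st$train, y[fold != f], C = grid$C[i])
      pred <- predict(m, st$test, type = "class")
      correct <- correct + sum(pred == as.numeric(y[fold == f]))
    }
    correct / length(y)
  }, numeric(1))
  results <- grid %>% mutate(accuracy = acc)
  best_i <- order(-acc, grid$C, seq_len(nrow(grid)))[1]
  list(best = results[best_i, ], results = results)
}

#' Cross-validated classification of a feature table
#'
#' Stratified k-fold cross-validation of L2-regularized logistic regression
#' on a subjects-by-features table, reporting the pooled out-of-fold
#' metrics: accuracy (correct out-of-fold predictions over all subjects),
#' rank AUC over pooled out-of-fold probabilities, and precision/recall
#' with AD as the positive class — all as percentages.
#'
#' Feature handling follows `selection_mode`:
#' * `"full-cohort"` — use `features` selected on the whole cohort (the
#'   replicated study procedure; optimistically biased under the null).
#' * `"nested"` — re-run t-test ranking and top-`k_features` selection
#'   inside each training fold (leakage-free variant).
#'
#' Features are standardized with training-fold statistics only.
#'
#' @param table Feature table from [build_feature_table()] (impute missing
#'   cells first). Needs `subject_id` and `group` columns.
#' @param features Character vector of feature columns to use
#'   (`full-cohort` mode). `NULL` in `nested` mode.
#' @param selection_mode `"full-cohort"` or `"nested"`.
#' @param k_features Features selected per training fold in nested mode.
#' @param k Folds (default 5).
#' @param seed Fold shuffle seed (default 0).
#' @param C Inverse regularization strength; ignored when `grid` is given.
#' @param grid Optional hyperparameter grid searched with [grid_search()]
#'   on the same folds before the final fits.
#' @param positive Positive class label (default `"AD"`).
#' @param var_equal Passed to nested-mode t-tests.
#' @param montage Tie-break channel order for nested selection.
#' @return An `eeg_cv` object; see [tidy.eeg_cv()] and [glance.eeg_cv()].
#' @export
cross_validate <- function(table, features = NULL,
                           selection_mode = c("full-cohort", "nested"),
                           k_features = 4, k = 5, seed = 0, C = 1,
                           grid = NULL, positive = "AD",
                           var_equal = FALSE,
                           montage = montage_1020_14()) {
  selection_mode <- match.arg(selection_mode)
  y <- table$group == positive
  if (selection_mode == "full-cohort") {
    if (is.null(features)) {
      st <- groupwise_ttest(table, var_equal = var_equal)
      features <- select_top_features(st, k = k_features,
                                      montage = montage)$feature
    }
    xall <- as.matrix(table[, features, drop = FALSE])
    if (anyNA(xall)) abort("impute missing cells before cross-validation")
  } else {
    if (anyNA(as.matrix(table[, feature_columns(table)])))
      abort("impute missing cells before cross-validation")
  }
  fold <- stratified_folds(table$group, k = k, seed = seed)

  hyper <- list(C = C)
  if (!is.null(grid)) {
    gx <- if (selection_mode == "full-cohort") xall else
      as.matrix(table[, feature_columns(table), drop = FALSE])
    # the grid is selected on its own fold split (seed + 1), not the split
    # it is finally scored on, so the chosen C is not the max over the
    # scoring partition
    gs <- grid_search(gx, y, grid = grid, k = k, seed = seed + 1)
    hyper <- list(C = gs$best$C, grid_results = gs$results)
  }

  preds <- vector("list", k)
  fold_features <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (selection_mode == "nested") {
      st <- groupwise_ttest(table[tr, ], var_equal = var_equal)
      feats <- select_top_features(st, k = k_features,
                                   montage = montage)$feature
    } else {
      feats <- features
    }
    fold_features[[f]] <- feats
    xm <- as.matrix(table[, feats, drop = FALSE])
    sts <- standardize_train_test(xm[tr, , drop = FALSE],
                                  xm[te, , drop = FALSE])
    m <- fit_logistic(sts$train, y[tr], C = hyper$C)
    pr <- predict(m, sts$test, type = "response")
    preds[[f]] <- tibble(
      subject_id = table$subject_id[te],
      group = table$group[te],
      fold = f,
      prob_positive = pr,
      predicted = ifelse(pr >= 0.5, positive,
                         setdiff(unique(table$group), positive)[1])
    )
  }
  predictions <- bind_rows(preds)
  correct <- predictions$predicted == predictions$group
  folds <- predictions %>%
    group_by(.data$fold) %>%
    summarise(n_test = dplyr::n(),
              n_correct = sum(.data$predicted == .data$group),
              accuracy = 100 * .data$n_correct / .data$n_test,
              .groups = "drop")
  truth <- predictions$group == positive
  metrics <- list(
    accuracy = 100 * sum(correct) / nrow(predictions),
    auc = 100 * rank_auc(predictions$prob_positive, truth),
    precision = 100 * {
      pp <- predictions$predicted == positive
      if (any(pp)) mean(truth[pp]) else NA_real_
    },
    recall = 100 * mean(predictions$predicted[truth] == positive)
  )
  structure(
    list(folds = folds, predictions = predictions, metrics = metrics,
         hyperparameters = hyper,
         features = if (selection_mode == "full-cohort") features else
           fold_features,
         selection_mode = selection_mode, k = k, seed = seed,
         positive = positive),
    class = "eeg_cv"
  )
}

#' @export
print.eeg_cv <- function(x, ...) {
  cat(sprintf(
    "<eeg_cv> %d-fold stratified CV (%s selection)\n  pooled accuracy %.2f%%  AUC %.2f%%  precision %.2f%%  recall %.2f%%\n",
    x$k, x$selection_mode, x$metrics$accuracy, x$metrics$auc,
    x$metrics$precision, x$metrics$recall))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-fold results of a cross-validation
#'
#' @param x An `eeg_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A tibble with one row per fold: `fold`, `n_test`, `n_correct`,
#'   `accuracy` (percent).
#' @method tidy eeg_cv
#' @export
tidy.eeg_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validation
#'
#' @param x An `eeg_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A one-row tibble: pooled `accuracy`, `auc`, `precision`,
#'   `recall` (percent), `C`, `k`, `selection_mode`.
#' @method glance eeg_cv
#' @export
glance.eeg_cv <- function(x, ...) {
  tibble(accuracy = x$metrics$accuracy, auc = x$metrics$auc,
         precision = x$metrics$precision, recall = x$metrics$recall,
         C = x$hyperparameters$C, k = x$k,
         selection_mode = x$selection_mode)
}
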