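# Linear max-margin classification panels via recursive feature
# elimination with cross-validation. The linear SVM itself comes from
# e1071; feature ranking, fold handling, the elimination loop and the
# AUC machinery live here.

stratified_folds <- function(y, k) {
  y <- as.factor(y)
  folds <- integer(length(y))
  for (lev in levels(y)) {
    ix <- which(y == lev)
    folds[ix] <- sample(rep(seq_len(k), length.out = length(ix)))
  }
  folds
}

fit_linear_svm <- function(X, y, C) {
  e1071::svm(x = X, y = as.factor(y), kernel = "linear", cost = C,
             scale = FALSE)
}

svm_weights <- function(model) {
  as.numeric(crossprod(model$coefs, model$SV))
}

# standardize (and median-impute missing cells) using training-fold
# statistics only, so nothing leaks from the held-out fold
standardize_train_test <- function(train, test) {
  if (anyNA(train) || anyNA(test)) {
    med <- apply(train, 2, median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    for (j in seq_len(ncol(train))) {
      train[is.na(train[, j]), j] <- med[j]
      test[is.na(test[, j]), j] <- med[j]
    }
  }
  mu <- colMeans(train)
  sdev <- apply(train, 2, sd)
  sdev[sdev == 0] <- 1
  list(
    train = sweep(sweep(train, 2, mu, "-"), 2, sdev, "/"),
    test = sweep(sweep(test, 2, mu, "-"), 2, sdev, "/")
  )
}

impute_median <- function(X) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) {
      m <- median(X[, j], na.rm = TRUE)
      X[nas, j] <- if (is.finite(m)) m else 0
    }
  }
  X
}

#' Tune the SVM regularization strength by stratified cross-validation
#'
#' Grid search over `c_grid` scored by mean stratified k-fold accuracy;
#' features are standardized inside each training fold only, ties go to
#' the smallest C.
#'
#' @param X Numeric samples x features matrix.
#' @param y Binary class labels (two levels).
#' @param c_grid Candidate C values (default `10^(-3:3)`).
#' @param k Folds (default 5; reduced with a warning if a class is
#'   smaller than k).
#' @param seed Integer seed controlling fold assignment.
#' @return List with `best_c`, `accuracy` (tibble: c, accuracy), `k`.
#' @export
tune_c <- function(X, y, c_grid = 10^(-3:3), k = 5, seed = 1L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) abort("y must have exactly two classes")
  min_class <- min(table(y))
  if (min_class < k) {
    warn(sprintf("smallest class has %d members; reducing k to %d",
                 min_class, min_class))
    k <- min_class
  }
  if (k < 2) abort("need at least 2 samples per class")
  set.seed(as.integer(seed))
  folds <- stratified_folds(y, k)
  acc <- vapply(c_grid, function(C) {
    mean(vapply(seq_len(k), function(f) {
      s <- standardize_train_test(X[folds != f, , drop = FALSE],
                                  X[folds == f, , drop = FALSE])
      model <- fit_linear_svm(s$train, y[folds != f], C)
      mean(predict(model, s$test) == y[folds == f])
    }, numeric(1)))
  }, numeric(1))
  best <- min(c_grid[acc == max(acc)])
  list(best_c = best, accuracy = tibble(c = c_grid, accuracy = acc), k = k)
}

# One RFE path: returns feature sets visited (largest to smallest) and,
# if test data is given, accuracy at each size.
rfe_path <- function(Xtr, ytr, C, Xte = NULL, yte = NULL, step = 1L) {
  active <- colnames(Xtr)
  sizes <- integer(0); accs <- numeric(0)
  order_removed <- character(0)
  while (length(active) >= 1) {
    model <- fit_linear_svm(Xtr[, active, drop = FALSE], ytr, C)
    if (!is.null(Xte)) {
      sizes <- c(sizes, length(active))
      accs <- c(accs, mean(predict(model, Xte[, active, drop = FALSE]) == yte))
    } else {
      sizes <- c(sizes, length(active))
    }
    if (length(active) == 1) break
    w <- abs(svm_weights(model))
    drop_n <- min(step, length(active) - 1L)
    drop_ix <- order(w)[seq_len(drop_n)]
    order_removed <- c(order_removed, active[drop_ix])
    active <- active[-drop_ix]
  }
  # removal order is worst-first, so the best-ranked features sit at the
  # end: the survivor preceded by the last features removed
  list(sizes = sizes, accuracy = accs,
       ranking = c(order_removed, active))
}

#' Recursive feature elimination with cross-validation
#'
#' With the regularization strength fixed (tuned beforehand via
#' [tune_c()] unless supplied), features are iteratively eliminated by
#' smallest absolute linear-SVM weight. The elimination path is computed
#' independently inside each training fold (standardization on the
#' training part only) and scored on the held-out fold at every panel
#' size from the full feature set down to one; the optimal size
#' maximizes mean cross-validated accuracy with ties resolved toward the
#' smaller panel. The final panel is the top of an elimination path on
#' the full data at that size, and the model restricted to the panel is
#' re-validated by a fresh stratified k-fold to give the reported
#' accuracy and pooled out-of-fold AUC.
#'
#' @param X Numeric samples x features matrix (candidate features, e.g.
#'   differentially abundant proteins for the contrast).
#' @param y Binary class labels.
#' @param C Regularization strength; `NULL` tunes it first.
#' @param k Folds (default 5).
#' @param step Features removed per iteration (default 1).
#' @param seed Integer seed.
#' @return A `plasma_panel` object: `selected`, `cv_accuracy`,
#'   `panel_auc`, `auc_ci`, `tuned_c`, `cv_curve` (tibble size x mean
#'   accuracy), `per_feature_auc` (tibble with bootstrap CIs),
#'   `fold_assignments`, `seed`.
#' @export
rfecv_select <- function(X, y, C = NULL, k = 5, step = 1L, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) abort("y must have exactly two classes")
  const <- apply(X, 2, function(v) sd(v, na.rm = TRUE) == 0 ||
                   !is.finite(sd(v, na.rm = TRUE)))
  if (any(const)) {
    warn(sprintf("dropping %d constant feature(s) before elimination", sum(const)))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0) abort("no non-constant features")

  if (is.null(C)) C <- tune_c(X, y, k = k, seed = stage_seed(seed, "panel"))$best_c
  min_class <- min(table(y))
  if (min_class < k) {
    warn(sprintf("smallest class has %d members; reducing k to %d", min_class, min_class))
    k <- min_class
  }
  set.seed(as.integer(seed))
  folds <- stratified_folds(y, k)

  p <- ncol(X)
  acc_by_size <- matrix(NA_real_, k, p)
  for (f in seq_len(k)) {
    s <- standardize_train_test(X[folds != f, , drop = FALSE],
                                X[folds == f, , drop = FALSE])
    path <- rfe_path(s$train, y[folds != f], C, s$test, y[folds == f], step)
    acc_by_size[f, path$sizes] <- path$accuracy
  }
  mean_acc <- colMeans(acc_by_size, na.rm = TRUE)
  tested_sizes <- which(!is.nan(mean_acc))
  best_size <- min(tested_sizes[mean_acc[tested_sizes] ==
                                  max(mean_acc[tested_sizes])])

  full_std <- scale(impute_median(X))
  full_path <- rfe_path(full_std, y, C, step = step)
  selected <- tail(full_path$ranking, best_size)

  # re-validate on the selected panel with a fresh fold split
  refolds <- stratified_folds(y, k)
  dec <- numeric(length(y))
  correct <- logical(length(y))
  for (f in seq_len(k)) {
    s <- standardize_train_test(X[refolds != f, selected, drop = FALSE],
                                X[refolds == f, selected, drop = FALSE])
    model <- fit_linear_svm(s$train, y[refolds != f], C)
    pred <- predict(model, s$test)
    correct[refolds == f] <- pred == y[refolds == f]
    w <- svm_weights(model)
    d <- as.numeric(s$test %*% w) - model$rho
    # orient so larger scores favour the second class level
    if (auc_stat(as.numeric(s$train %*% w) - model$rho,
                 y[refolds != f]) < 0.5) d <- -d
    dec[refolds == f] <- d
  }
  cv_accuracy <- mean(correct)
  auc_ci <- auc_with_bootstrap_ci(dec, y, seed = stage_seed(seed, "boot"))

  per_feature <- bind_rows(lapply(selected, function(fname) {
    ci <- auc_with_bootstrap_ci(X[, fname], y, seed = stage_seed(seed, "boot"))
    tibble(feature = fname, auc = ci$auc,
           ci_low = ci$ci_low, ci_high = ci$ci_high)
  }))
  structure(list(
    selected = selected, cv_accuracy = cv_accuracy,
    panel_auc = auc_ci$auc, auc_ci = c(auc_ci$ci_low, auc_ci$ci_high),
    tuned_c = C,
    cv_curve = tibble(size = tested_sizes, accuracy = mean_acc[tested_sizes]),
    per_feature_auc = per_feature,
    fold_assignments = folds, seed = as.integer(seed),
    classes = levels(y)
  ), class = "plasma_panel")
}

#' @export
print.plasma_panel <- function(x, ...) {
  cat(sprintf(
    "<plasma_panel> %d features selected (C = %g); CV accuracy %.3f, AUC %.3f [%.3f, %.3f]\n",
    length(x$selected), x$tuned_c, x$cv_accuracy, x$panel_auc,
    x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' @describeIn rfecv_select Per-feature AUCs of the selected panel.
#' @param x,object A `plasma_panel`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.plasma_panel <- function(x, ...) x$per_feature_auc

#' @describeIn rfecv_select One-row panel summary.
#' @exportS3Method generics::glance
glance.plasma_panel <- function(x, ...) {
  tibble(
    n_selected = length(x$selected), cv_accuracy = x$cv_accuracy,
    panel_auc = x$panel_auc, auc_ci_low = x$auc_ci[1],
    auc_ci_high = x$auc_ci[2], tuned_c = x$tuned_c
  )
}

#' @describeIn rfecv_select Cross-validation accuracy against panel size.
#' @exportS3Method ggplot2::autoplot
autoplot.plasma_panel <- function(object, ...) {
  ggplot(object$cv_curve, aes(x = .data$size, y = .data$accuracy)) +
    geom_point(size = 0.8) +
    geom_vline(xintercept = length(object$selected), linetype = "dashed") +
    labs(x = "panel size", y = "mean CV accuracy",
         title = "Recursive feature elimination curve") +
    theme_minimal()
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = U / (n1 * n0)` with ties counted half, computed from rank
#' sums. The second factor level of `y` is treated as the positive
#' class.
#'
#' @param scores Numeric classifier scores.
#' @param y Binary labels.
#' @return AUC in \[0, 1\].
#' @export
auc_stat <- function(scores, y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) abort("y must have exactly two classes")
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a stratified percentile bootstrap confidence interval
#'
#' Non-parametric bootstrap (resampling within each class, so every
#' resample holds both classes) of the Mann-Whitney AUC; the 95%
#' interval is the 2.5/97.5 percentile of the bootstrap distribution.
#'
#' @param scores Numeric classifier scores.
#' @param y Binary labels.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `auc`, `ci_low`, `ci_high`, `n_boot`.
#' @export
auc_with_bootstrap_ci <- function(scores, y, n_boot = 1000, seed = 1L,
                                  conf = 0.95) {
  ok <- !is.na(scores)
  scores <- scores[ok]
  y <- droplevels(as.factor(y[ok]))
  point <- auc_stat(scores, y)
  set.seed(as.integer(seed))
  pos_ix <- which(y == levels(y)[2])
  neg_ix <- which(y == levels(y)[1])
  boots <- vapply(seq_len(n_boot), function(b) {
    ix <- c(sample(pos_ix, length(pos_ix), replace = TRUE),
            sample(neg_ix, length(neg_ix), replace = TRUE))
    auc_stat(scores[ix], y[ix])
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- quantile(boots, c(a, 1 - a), names = FALSE)
  list(auc = point, ci_low = ci[1], ci_high = ci[2], n_boot = n_boot)
}
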