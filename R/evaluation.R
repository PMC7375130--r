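#' Family-aware fold assignment
#'
#' Shuffles families with the given seed and assigns each family greedily to
#' the currently smallest fold, so that all members of a family always share
#' one fold and fold sizes are balanced to within the largest family size.
#'
#' @param subjects Cohort tibble with `subject_id` and `family_id` columns.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the family shuffle.
#' @return A `fold_assignment`: integer fold labels (1..k) named by subject,
#'   plus the family map, `k` and `seed`.
#' @export
make_family_folds <- function(subjects, k = 10, seed = 1L) {
  fam <- as.character(subjects$family_id)
  fams <- unique(fam)
  if (length(fams) < k)
    abort("fewer families than folds; cannot build family-aware folds.")
  with_stream(seed, "folds", {
    ord <- sample(fams)
    sizes <- table(fam)[ord]
    fold_of_family <- integer(length(ord))
    load <- numeric(k)
    for (i in seq_along(ord)) {
      f <- which.min(load)
      fold_of_family[i] <- f
      load[f] <- load[f] + sizes[i]
    }
    fold <- fold_of_family[match(fam, ord)]
    structure(list(fold = setNames(as.integer(fold), subjects$subject_id),
                   family = setNames(fam, subjects$subject_id),
                   k = as.integer(k), seed = as.integer(seed)),
              class = "fold_assignment")
  })
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("<fold_assignment>", length(x$fold), "subjects in", x$k, "folds; sizes:",
      paste(tabulate(x$fold, x$k), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn make_family_folds Tidy to a tibble of subject, family and fold.
#' @param x A `fold_assignment`.
#' @param ... Unused.
#' @export
tidy.fold_assignment <- function(x, ...) {
  tibble::tibble(subject_id = names(x$fold), family_id = unname(x$family),
                 fold = unname(x$fold))
}

fold_vector <- function(folds, n) {
  if (inherits(folds, "fold_assignment")) {
    f <- unname(folds$fold)
    if (any(tapply(f, folds$family, function(v) length(unique(v))) > 1))
      abort("fold assignment splits at least one family across folds.")
  } else {
    f <- as.integer(folds)
  }
  if (length(f) != n) abort("fold labels do not match the number of subjects.")
  f
}

#' Fisher-averaged correlation
#'
#' Fisher r-to-z transforms per-fold correlations, averages the z values and
#' back-transforms. Correlations at exactly +/-1 are clamped at
#' `1 - 1e-12` with a warning.
#'
#' @param rs Numeric vector of correlations.
#' @return Pooled correlation.
#' @export
fisher_average <- function(rs) {
  if (any(abs(rs) >= 1)) {
    warn("correlation(s) at +/-1 clamped before Fisher transform.")
    rs <- pmin(pmax(rs, -(1 - 1e-12)), 1 - 1e-12)
  }
  tanh(mean(atanh(rs)))
}

#' Cross-validated coefficient of determination
#'
#' `R2_cv = 1 - sum((y_adj - y_hat)^2) / sum((y_adj - ybar_train)^2)`, where
#' `ybar_train` is the covariate-adjusted train-set mean carried into the
#' test fold.
#'
#' @param y_adj Covariate-adjusted observed responses (test fold).
#' @param y_hat Predicted responses (test fold).
#' @param ybar_train Train-set mean reference.
#' @return The cross-validated R-squared.
#' @export
r2_cv <- function(y_adj, y_hat, ybar_train) {
  if (length(y_adj) != length(y_hat)) abort("length mismatch.")
  denom <- sum((y_adj - ybar_train)^2)
  if (denom == 0) abort("zero denominator in R2_cv.")
  1 - sum((y_adj - y_hat)^2) / denom
}

#' Cross-validated mean square error
#'
#' `MSE = sum((y_adj - y_hat)^2) / (n - 1)`.
#'
#' @inheritParams r2_cv
#' @return The MSE value.
#' @export
mse_cv <- function(y_adj, y_hat) {
  n <- length(y_adj)
  if (n < 2 || n != length(y_hat)) abort("need equal lengths, n >= 2.")
  sum((y_adj - y_hat)^2) / (n - 1)
}

#' Fold-based confidence interval
#'
#' Normal-theory interval `mean +/- z * spread` over the per-fold
#' correlations, with the spread being the fold SD (default, literal
#' reading) or the SEM.
#'
#' @param per_fold_rs Per-fold correlations (>= 2 folds).
#' @param level Confidence level (default 0.95).
#' @param scale `"sd"` (default) or `"sem"`.
#' @return Numeric `c(low, high)`.
#' @export
fold_ci <- function(per_fold_rs, level = 0.95, scale = c("sd", "sem")) {
  scale <- match.arg(scale)
  if (length(per_fold_rs) < 2) abort("need at least two folds for an interval.")
  z <- qnorm(1 - (1 - level) / 2)
  spread <- sd(per_fold_rs)
  if (scale == "sem") spread <- spread / sqrt(length(per_fold_rs))
  m <- mean(per_fold_rs)
  c(low = m - z * spread, high = m + z * spread)
}

# Precompute everything on the brain/covariate side that does not depend on
# the behavioral responses: per-fold basis, expression scores, covariate
# design, and the QR of the joint train design. Reused across permutation
# iterations, where only the behavior changes.
cv_precompute <- function(maps, covariates, folds, K) {
  V <- map_values(maps)
  n <- nrow(V)
  fold <- fold_vector(folds, n)
  k <- max(fold)
  pre <- list(fold = fold, k = k, n = n, folds = vector("list", k))
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    basis <- suppressWarnings(build_basis(V[train, , drop = FALSE], K))
    X_train <- expression_scores(basis, V[train, , drop = FALSE])
    X_test <- expression_scores(basis, V[test, , drop = FALSE])
    cd <- covariate_design(covariates, train)
    Z_train <- cd$Z[train, , drop = FALSE]
    Z_test <- cd$Z[test, , drop = FALSE]
    D <- cbind(X_train, Z_train)
    qrD <- qr(D)
    if (qrD$rank < ncol(D))
      abort(sprintf("fold %d: joint design [X Z] rank deficient.", f))
    pre$folds[[f]] <- list(train = train, test = test, basis = basis,
                           X_train = X_train, X_test = X_test,
                           Z_train = Z_train, Z_test = Z_test,
                           qrD = qrD, K = basis$K)
  }
  pre
}

# Run the per-fold factor fitting + BBS regression + adjusted prediction for
# one behavior matrix against a precomputed brain side.
cv_engine <- function(behavior, pre, factor_starts = 1, keep = FALSE,
                      warm = NULL) {
  behavior <- as.matrix(behavior)
  per_fold <- vector("list", pre$k)
  warm_out <- vector("list", pre$k)
  for (f in seq_len(pre$k)) {
    fd <- pre$folds[[f]]
    fm <- fit_bifactor(behavior[fd$train, , drop = FALSE],
                       n_starts = factor_starts, start = warm[[f]])
    warm_out[[f]] <- list(u1 = fm$first_order$uniquenesses,
                          u2 = fm$first_order$u2)
    y_train <- score_subjects(fm, behavior[fd$train, , drop = FALSE])
    y_test <- score_subjects(fm, behavior[fd$test, , drop = FALSE])
    coefs <- qr.coef(fd$qrD, y_train)
    K <- fd$K
    beta <- coefs[seq_len(K)]
    gamma <- coefs[K + seq_len(ncol(fd$Z_train))]
    y_adj <- as.numeric(y_test - fd$Z_test %*% gamma)
    y_hat <- as.numeric(fd$X_test %*% beta)
    ybar_train <- mean(y_train - fd$Z_train %*% gamma)
    per_fold[[f]] <- list(
      fold = f, n_test = length(fd$test), K = K,
      r = cor(y_adj, y_hat),
      r2 = r2_cv(y_adj, y_hat, ybar_train),
      mse = mse_cv(y_adj, y_hat),
      ybar_train = ybar_train,
      y_adj = y_adj, y_hat = y_hat,
      beta = if (keep) beta else NULL,
      gamma = if (keep) gamma else NULL,
      factor_model = if (keep) fm else NULL)
  }
  rs <- vapply(per_fold, `[[`, numeric(1), "r")
  list(per_fold = per_fold, rs = rs, pooled_r = fisher_average(rs),
       warm = warm_out)
}

#' Family-aware cross-validated BBS prediction
#'
#' Runs the full prediction pipeline within each fold: the bifactor model is
#' refit on the training subjects' behavior and its train-estimated scoring
#' applied to the held-out subjects; the PCA basis, covariate
#' standardization and the joint regression of GCA on expression scores and
#' covariates are all estimated on the training fold only; held-out
#' subjects receive covariate-adjusted responses and brain-based
#' predictions from the train coefficients. Per-fold correlations are
#' pooled by Fisher averaging; R2_cv and MSE are averaged arithmetically.
#'
#' @param maps A [contrast_matrix()] (or subjects x voxels matrix), rows
#'   aligned with `behavior`, `covariates` and `folds`.
#' @param behavior n x 10 matrix/data frame of behavioral battery scores.
#' @param covariates Data frame of raw covariates (see [covariate_frame()]).
#' @param folds A [make_family_folds()] assignment or integer fold vector.
#' @param K Number of basis components (default 75; clipped per fold to
#'   n_train - 1 with a warning).
#' @param factor_starts Extra random oblimin starts per fold (default 1).
#' @param ci_scale Spread used in the fold interval, `"sd"` or `"sem"`.
#' @return A `bbs_cv` object; see [tidy.bbs_cv()] and [glance.bbs_cv()].
#' @export
run_cv <- function(maps, behavior, covariates, folds, K = 75,
                   factor_starts = 1, ci_scale = "sd") {
  pre <- cv_precompute(maps, covariates, folds, K)
  res <- cv_engine(behavior, pre, factor_starts = factor_starts, keep = TRUE)
  pf <- purrr::map_dfr(res$per_fold, function(x)
    tibble::tibble(fold = x$fold, n_test = x$n_test, K = x$K, r = x$r,
                   r2 = x$r2, mse = x$mse, ybar_train = x$ybar_train))
  preds <- purrr::map_dfr(res$per_fold, function(x)
    tibble::tibble(fold = x$fold, y_adj = x$y_adj, y_hat = x$y_hat))
  structure(list(
    per_fold = pf,
    predictions = preds,
    pooled_r = res$pooled_r,
    r2_cv = mean(pf$r2),
    mse = mean(pf$mse),
    ci = fold_ci(pf$r, scale = ci_scale),
    K = K,
    contrast = if (inherits(maps, "contrast_matrix")) maps$contrast else NA_character_,
    fold_coefs = lapply(res$per_fold, function(x)
      list(beta = x$beta, gamma = x$gamma,
           lambda_g = x$factor_model$lambda_g))),
    class = "bbs_cv")
}

#' @export
print.bbs_cv <- function(x, ...) {
  cat("<bbs_cv>", if (!is.na(x$contrast)) paste0("contrast '", x$contrast, "', "),
      nrow(x$per_fold), "folds, K =", x$K, "\n",
      sprintf("  pooled r = %.3f  [%.3f, %.3f]   R2_cv = %.3f   MSE = %.3f\n",
              x$pooled_r, x$ci[1], x$ci[2], x$r2_cv, x$mse))
  invisible(x)
}

#' Tidy and summarize cross-validation results
#'
#' `tidy()` returns the per-fold metrics; `glance()` the pooled one-row
#' summary.
#'
#' @param x A `bbs_cv` object.
#' @param ... Unused.
#' @export
tidy.bbs_cv <- function(x, ...) x$per_fold

#' @rdname tidy.bbs_cv
#' @export
glance.bbs_cv <- function(x, ...) {
  tibble::tibble(contrast = x$contrast, pooled_r = x$pooled_r,
                 r2_cv = x$r2_cv, mse = x$mse,
                 ci_low = x$ci[1], ci_high = x$ci[2],
                 K = x$K, folds = nrow(x$per_fold))
}

#' @rdname tidy.bbs_cv
#' @param object A `bbs_cv` object.
#' @export
autoplot.bbs_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$y_hat, y = .data$y_adj)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~fold) +
    ggplot2::labs(x = "predicted (X beta)", y = "covariate-adjusted GCA",
                  title = sprintf("pooled r = %.3f", object$pooled_r))
}

#' Freedman-Lane permutation test for the pooled CV correlation
#'
#' Builds the null distribution of the pooled cross-validated correlation by
#' the Freedman-Lane procedure: the ten behavioral test scores are
#' residualized on the covariate design over the full sample, the residual
#' rows are permuted jointly, the permuted residuals are added back to the
#' covariate fits, and the entire cross-validation (including per-fold
#' bifactor refitting and BBS refitting) is rerun on the reconstructed
#' scores. The p-value is the rank of the observed pooled r in the null
#' (count of null values >= observed) divided by `B`; when the observed
#' value exceeds every null draw, `p` is reported as `1/B` with
#' `exceeds_all = TRUE` (i.e., p < 1/B).
#'
#' @inheritParams run_cv
#' @param B Number of permutations (study-scale default 10000; use far
#'   fewer for exploration).
#' @param seed Integer seed for the permutation stream.
#' @return A `bbs_permutation`: `null_r` (length B), `observed_r`,
#'   `p_value`, `exceeds_all`, `B`, `seed`.
#' @export
permutation_test <- function(maps, behavior, covariates, folds, K = 75,
                             B = 10000, seed = 1L, factor_starts = 1) {
  if (B < 1) abort("B must be >= 1.")
  if (B < 99)
    warn("B < 99 permutations gives a coarse p-value resolution (> 0.01).")
  behavior <- as.matrix(behavior)
  pre <- cv_precompute(maps, covariates, folds, K)
  obs <- cv_engine(behavior, pre, factor_starts = factor_starts)
  observed <- obs$pooled_r
  warm <- obs$warm

  Zfull <- covariate_design(covariates)$Z
  qrZ <- qr(Zfull)
  fitted <- qr.fitted(qrZ, behavior)
  resid <- behavior - fitted
  n <- nrow(behavior)
  null_r <- with_stream(seed, "permutation", {
    vapply(seq_len(B), function(b) {
      Yb <- fitted + resid[sample.int(n), , drop = FALSE]
      cv_engine(Yb, pre, factor_starts = factor_starts, warm = warm)$pooled_r
    }, numeric(1))
  })
  count <- sum(null_r >= observed)
  structure(list(null_r = null_r, observed_r = observed,
                 p_value = max(count, 1) / B, exceeds_all = count == 0,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "bbs_permutation")
}

#' @export
print.bbs_permutation <- function(x, ...) {
  cat("<bbs_permutation> observed pooled r =", round(x$observed_r, 3),
      "; p", if (x$exceeds_all) paste0("< ", format(1 / x$B)) else
        paste0("= ", format(x$p_value)),
      sprintf("(B = %d)\n", x$B))
  invisible(x)
}

#' @describeIn permutation_test One-row summary of the permutation test.
#' @param x A `bbs_permutation`.
#' @param ... Unused.
#' @export
glance.bbs_permutation <- function(x, ...) {
  tibble::tibble(observed_r = x$observed_r, p_value = x$p_value,
                 exceeds_all = x$exceeds_all, B = x$B,
                 null_mean = mean(x$null_r), null_sd = sd(x$null_r))
}

#' Standard covariate frame for a cohort
#'
#' Extracts the covariates used by the BBS covariate model from a synthetic
#' cohort: age, age squared, handedness, gender, brain volume,
#' reconstruction version, and mean framewise displacement (task-specific
#' when a contrast is given) plus its square.
#'
#' @param subjects Cohort tibble.
#' @param contrast Optional contrast name whose per-task FD column is used.
#' @return A tibble of raw covariates, one row per subject.
#' @export
covariate_frame <- function(subjects, contrast = NULL) {
  fdcol <- if (!is.null(contrast)) paste0("fd_", fd_key(contrast)) else "mean_fd"
  fd <- if (fdcol %in% names(subjects)) subjects[[fdcol]] else subjects$mean_fd
  tibble::tibble(
    age = subjects$age, age_sq = subjects$age_sq,
    handedness = subjects$handedness, gender = subjects$gender,
    brain_vol = subjects$brain_vol, recon_version = subjects$recon_version,
    mean_fd = fd, mean_fd_sq = fd^2)
}

#' Extract the behavioral battery columns from a cohort
#'
#' @param subjects Cohort tibble.
#' @param session `1` for the main session, `2` for the retest columns.
#' @return n x 10 matrix of test scores.
#' @export
behavior_matrix <- function(subjects, session = 1) {
  tests <- battery_tests()
  cols <- if (session == 2) paste0("retest_", tests) else tests
  m <- as.matrix(subjects[, cols])
  colnames(m) <- tests
  m
}
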