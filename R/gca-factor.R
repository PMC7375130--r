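#' Fit a bifactor model of the behavioral battery
#'
#' Implements the exploratory bifactor workflow used to construct a general
#' cognitive ability (GCA) factor from a ten-test battery: (1) maximum-
#' likelihood exploratory factor analysis with `n_group` factors on the
#' correlation matrix, (2) oblimin (quartimin) rotation, (3) a one-factor ML
#' EFA of the first-order factor correlation matrix, (4) the Schmid-Leiman
#' transformation, yielding general loadings `Lambda_g = L1 %*% l2` and group
#' loadings `Lambda_f = L1 %*% diag(sqrt(1 - l2^2))`. Factor scoring weights
#' for the general factor use the regression (Thurstone) method on the train
#' correlation matrix, `W = R^-1 Lambda_g`. Omega hierarchical is
#' `(sum Lambda_g)^2` over the implied total-score variance
#' `(sum Lambda_g)^2 + sum_f (sum Lambda_f)^2 + sum Psi`.
#'
#' @param scores Numeric matrix or data frame, n subjects x 10 tests, no
#'   missing values, columns named by test.
#' @param n_group Number of group factors (default 4).
#' @param mmse Optional numeric vector of MMSE scores; when supplied,
#'   subjects with MMSE < `mmse_min` are excluded before fitting.
#' @param mmse_min Exclusion threshold for `mmse` (default 26).
#' @param n_starts Random oblimin rotation starts in addition to the
#'   varimax warm start; the lowest-criterion solution is kept.
#' @param start Optional warm start: a list with `u1` (10 first-order
#'   uniquenesses) and `u2` (second-order uniquenesses), e.g. the
#'   `first_order` values of a previous fit on similar data. Falls back to a
#'   cold start if the warm-started likelihood optimization fails.
#' @return An object of class `gca_factor_model`: general/group loadings,
#'   uniquenesses, scoring weights, train means/SDs, `omega_h`, `srmr`,
#'   first-order loadings and factor correlations, and a `heywood` flag.
#' @export
fit_bifactor <- function(scores, n_group = 4, mmse = NULL, mmse_min = 26,
                         n_starts = 4, start = NULL) {
  scores <- as.matrix(scores)
  if (!is.null(mmse)) scores <- scores[mmse >= mmse_min, , drop = FALSE]
  if (anyNA(scores)) abort("behavioral scores must not contain missing values.")
  p <- ncol(scores)
  if (nrow(scores) < 10 * n_group)
    abort("need at least 10 * n_group subjects to fit the bifactor model.")
  mu <- colMeans(scores)
  sdv <- apply(scores, 2, sd)
  if (any(sdv == 0)) abort("zero train standard deviation for at least one test.")
  R <- cor(scores)

  fa1 <- efa_ml(R, n_group, nrow(scores), start$u1)
  A <- unclass(fa1$loadings)
  rot <- oblimin_rotate(A, n_starts = n_starts)
  L1 <- rot$loadings
  Phi <- rot$Phi
  # reflect factors so each column's dominant loadings are positive
  sgn <- sign(colSums(L1^3))
  sgn[sgn == 0] <- 1
  L1 <- sweep(L1, 2, sgn, `*`)
  Phi <- diag(sgn) %*% Phi %*% diag(sgn)

  fa2 <- efa_ml(Phi, 1, nrow(scores), start$u2)
  l2 <- as.numeric(unclass(fa2$loadings))
  if (sum(l2) < 0) l2 <- -l2

  lambda_g <- as.numeric(L1 %*% l2)
  lambda_f <- L1 %*% diag(sqrt(pmax(0, 1 - l2^2)))
  rownames(lambda_f) <- colnames(scores)
  comm <- lambda_g^2 + rowSums(lambda_f^2)
  psi <- pmax(0, 1 - comm)
  heywood <- any(fa1$uniquenesses <= 0.005 + 1e-9) || any(comm > 1 + 1e-6)

  W <- solve(R, lambda_g)
  omega_h <- sum(lambda_g)^2 /
    (sum(lambda_g)^2 + sum(colSums(lambda_f)^2) + sum(psi))
  implied <- tcrossprod(lambda_g) + tcrossprod(lambda_f) + diag(psi)

  structure(
    list(tests = colnames(scores),
         lambda_g = setNames(lambda_g, colnames(scores)),
         lambda_f = lambda_f,
         psi = setNames(psi, colnames(scores)),
         weights = setNames(as.numeric(W), colnames(scores)),
         train_means = mu, train_sds = sdv,
         omega_h = omega_h,
         srmr = srmr(R, implied),
         first_order = list(loadings = L1, Phi = Phi, l2 = l2,
                            uniquenesses = fa1$uniquenesses,
                            u2 = fa2$uniquenesses),
         heywood = heywood,
         n = nrow(scores)),
    class = "gca_factor_model")
}

#' @export
print.gca_factor_model <- function(x, ...) {
  cat("<gca_factor_model> bifactor solution,", length(x$tests), "tests, n =",
      x$n, "\n  omega_h =", round(x$omega_h, 3),
      " SRMR =", round(x$srmr, 4),
      if (x$heywood) " [Heywood case flagged]" else "", "\n")
  invisible(x)
}

#' @describeIn fit_bifactor Tidy the loading structure: one row per test with
#'   general loading, group loadings, uniqueness and scoring weight.
#' @param x A `gca_factor_model`.
#' @param ... Unused.
#' @export
tidy.gca_factor_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(test = x$tests, general = as.numeric(x$lambda_g)),
    tibble::as_tibble(x$lambda_f),
    tibble::tibble(uniqueness = as.numeric(x$psi),
                   weight = as.numeric(x$weights)))
}

#' @describeIn fit_bifactor One-row model summary (omega_h, SRMR, n, Heywood flag).
#' @export
glance.gca_factor_model <- function(x, ...) {
  tibble::tibble(omega_h = x$omega_h, srmr = x$srmr, n = x$n,
                 n_tests = length(x$tests), heywood = x$heywood)
}

#' Score subjects on the general factor
#'
#' Standardizes the test scores with the model's *train* means and SDs and
#' applies the regression scoring weights. Train-set scores have mean zero by
#' construction; held-out subjects are scored with the train statistics so no
#' test-set information enters the scoring.
#'
#' @param model A [fit_bifactor()] model.
#' @param scores n x 10 matrix/data frame with the model's test columns.
#' @param use_train_stats Standardize with the model's stored train
#'   means/SDs (default TRUE). FALSE re-standardizes on `scores` itself,
#'   which is only appropriate when `scores` *is* a training set.
#' @return Numeric vector of GCA scores.
#' @export
score_subjects <- function(model, scores, use_train_stats = TRUE) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)) || !identical(colnames(scores), model$tests))
    abort("score columns must match the model's tests (same order).")
  if (use_train_stats) {
    mu <- model$train_means
    sdv <- model$train_sds
  } else {
    mu <- colMeans(scores)
    sdv <- apply(scores, 2, sd)
  }
  if (any(sdv == 0)) abort("zero standard deviation in standardization stats.")
  z <- sweep(sweep(scores, 2, mu), 2, sdv, `/`)
  as.numeric(z %*% model$weights)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation for two sessions, from the ANOVA decomposition:
#' `(MS_R - MS_E) / (MS_R + MS_E + (2/n) (MS_C - MS_E))` with k = 2 raters
#' (sessions), MS_R the between-subject, MS_C the between-session and MS_E
#' the residual mean square.
#'
#' @param session1,session2 Numeric vectors of equal length (n >= 3).
#' @return The ICC(2,1) value.
#' @export
icc_2_1 <- function(session1, session2) {
  if (length(session1) != length(session2)) abort("sessions must have equal length.")
  n <- length(session1)
  if (n < 3) abort("need at least three subjects.")
  Y <- cbind(session1, session2)
  k <- 2
  grand <- mean(Y)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  ss_total <- sum((Y - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total == 0) abort("degenerate input: zero total variance.")
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + ms_e + (k / n) * (ms_c - ms_e))
}

#' Standardized root-mean-square residual
#'
#' Root mean square of the residual correlations over the lower triangle
#' (diagonal excluded) between an observed and a model-implied correlation
#' matrix.
#'
#' @param observed_corr,model_implied_corr Symmetric matrices of equal size.
#' @return The SRMR value.
#' @export
srmr <- function(observed_corr, model_implied_corr) {
  if (!all(dim(observed_corr) == dim(model_implied_corr)))
    abort("dimension mismatch between observed and implied matrices.")
  resid <- (observed_corr - model_implied_corr)[lower.tri(observed_corr)]
  sqrt(mean(resid^2))
}

# ML exploratory factor analysis of a correlation matrix, optionally warm-
# started at previous uniquenesses (big speedup when refitting on slightly
# perturbed data, as in permutation loops). Non-convergence is an error.
efa_ml <- function(R, factors, n_obs, u_start = NULL) {
  fit <- NULL
  if (!is.null(u_start)) {
    fit <- tryCatch(
      factanal(covmat = R, factors = factors, rotation = "none", n.obs = n_obs,
               start = matrix(pmin(pmax(u_start, 0.01), 0.99), ncol = 1)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    fit <- tryCatch(
      factanal(covmat = R, factors = factors, rotation = "none", n.obs = n_obs),
      error = function(e) abort(paste("ML EFA did not converge:",
                                      conditionMessage(e))))
  }
  fit
}

# ---- oblimin (quartimin) rotation via gradient projection ------------------

# Quartimin criterion and gradient for a loading matrix L; N is the
# off-diagonal mask (precomputed by the caller).
quartimin_vgq <- function(L, N) {
  L2 <- L * L
  X <- L2 %*% N
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

# Oblique gradient-projection rotation (Jennrich 2002) minimizing the
# quartimin criterion; gamma = 0 oblimin. Multiple random starts guard
# against local minima; the lowest-criterion solution is returned.
oblimin_rotate <- function(A, n_starts = 4, maxit = 500, eps = 1e-5) {
  m <- ncol(A)
  if (m == 1) return(list(loadings = A, Phi = matrix(1, 1, 1), f = 0))
  best <- NULL
  # warm start at the varimax rotation (orthogonal T is a valid oblique T),
  # plus a fixed set of pseudo-random orthogonal starts; the start set is
  # deterministic so fits are reproducible irrespective of caller RNG state
  vm <- tryCatch(stats::varimax(A, normalize = FALSE)$rotmat,
                 error = function(e) diag(m))
  extra <- with_stream(424243L, paste0("oblq-starts-", m), {
    lapply(seq_len(n_starts), function(i) qr.Q(qr(matrix(rnorm(m * m), m, m))))
  })
  starts <- c(list(vm), extra)
  for (Tmat in starts) {
    res <- .gpa_oblq_cpp(A, Tmat, maxit, eps)
    if (is.null(best) || res$f < best$f) best <- res
  }
  best
}

# Pure-R reference implementation of the gradient-projection step, retained
# as the correctness oracle for the compiled routine.

gpa_oblq <- function(A, Tmat, maxit = 500, eps = 1e-5) {
  m <- ncol(A)
  N <- matrix(1, m, m) - diag(m)
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- quartimin_vgq(L, N)
  f <- vg$f
  G <- -t(crossprod(L, vg$Gq) %*% Ti)
  for (iter in seq_len(maxit)) {
    Gp <- G - t(t(Tmat) * colSums(Tmat * G))
    s <- sqrt(sum(Gp * Gp))
    if (s < eps) break
    al <- 2 * al
    for (i in 0:12) {
      X <- Tmat - al * Gp
      Tt <- t(t(X) / sqrt(colSums(X * X)))
      Tti <- solve(Tt)
      Lt <- A %*% t(Tti)
      vgt <- quartimin_vgq(Lt, N)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    L <- Lt
    f <- vgt$f
    G <- -t(crossprod(L, vgt$Gq) %*% Tti)
  }
  list(loadings = L, Phi = crossprod(Tmat), f = f)
}
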