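#' Build a PCA brain basis set from training maps
#'
#' Voxel (column) means are computed on the training maps and subtracted, the
#' centered matrix is decomposed by SVD, and the top-K right singular vectors
#' are retained as orthonormal component maps ordered by descending
#' eigenvalue. Components are centered only (no variance scaling). The sign
#' of each component is fixed so that its largest-magnitude voxel loading is
#' positive. If `K > n - 1` it is clipped with a warning.
#'
#' @param train_maps A [contrast_matrix()] (or plain subjects x voxels
#'   matrix) of training maps.
#' @param K Number of components to retain (default 75).
#' @return A `basis_set`: `components` (K x m orthonormal rows),
#'   `eigenvalues` (variances of the training expression scores),
#'   `center` (train voxel means), `K`, `n_train`.
#' @export
build_basis <- function(train_maps, K = 75) {
  V <- map_values(train_maps)
  n <- nrow(V)
  kmax <- min(n - 1, ncol(V))
  if (K > kmax) {
    warn(sprintf("K = %d exceeds the PCA rank bound %d; clipped.", K, kmax))
    K <- kmax
  }
  center <- colMeans(V)
  Xc <- sweep(V, 2, center)
  sv <- svd(Xc, nu = 0, nv = K)
  comp <- t(sv$v[, seq_len(K), drop = FALSE])
  # deterministic sign: largest-|loading| voxel positive
  for (k in seq_len(K)) {
    j <- which.max(abs(comp[k, ]))
    if (comp[k, j] < 0) comp[k, ] <- -comp[k, ]
  }
  structure(list(components = comp,
                 eigenvalues = sv$d[seq_len(K)]^2 / (n - 1),
                 center = center, K = K, n_train = n),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat("<basis_set>", x$K, "components x", length(x$center), "voxels (n_train =",
      x$n_train, ")\n")
  invisible(x)
}

map_values <- function(maps) {
  if (inherits(maps, "contrast_matrix")) maps$values else as.matrix(maps)
}

#' Component expression scores
#'
#' Projects maps onto the basis: `(values - train voxel means) %*% t(components)`.
#' The train means stored in the basis are reused for any maps (train or
#' test), so no test-set statistic enters the features.
#'
#' @param basis A [build_basis()] object.
#' @param maps A [contrast_matrix()] or subjects x voxels matrix with the
#'   basis's voxel count.
#' @return n x K matrix of expression scores.
#' @export
expression_scores <- function(basis, maps) {
  V <- map_values(maps)
  if (ncol(V) != length(basis$center))
    abort("voxel count mismatch between maps and basis.")
  sweep(V, 2, basis$center) %*% t(basis$components)
}

#' Build a covariate design matrix with train-estimated standardization
#'
#' Continuous covariates are z-scored with train-set means/SDs; categorical
#' covariates (factors/characters) are dummy-coded dropping the first level;
#' an intercept column is prepended. The same train statistics are applied
#' to the test rows.
#'
#' @param covariates Data frame of covariates for all subjects.
#' @param train_idx Integer/logical index of training rows used to estimate
#'   standardization statistics (default: all rows).
#' @return A list with `Z` (full design, n x p), `stats`, and `columns`.
#' @export
covariate_design <- function(covariates, train_idx = seq_len(nrow(covariates))) {
  covariates <- as.data.frame(covariates)
  cols <- list(intercept = rep(1, nrow(covariates)))
  stats <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      mu <- mean(v[train_idx])
      s <- sd(v[train_idx])
      if (s == 0) s <- 1
      stats[[nm]] <- c(mean = mu, sd = s)
      cols[[nm]] <- (v - mu) / s
    } else {
      v <- factor(v)
      for (lev in levels(v)[-1]) cols[[paste0(nm, lev)]] <- as.numeric(v == lev)
    }
  }
  Z <- do.call(cbind, cols)
  if (qr(Z[train_idx, , drop = FALSE])$rank < ncol(Z))
    abort("covariate design is rank deficient on the training rows.")
  list(Z = Z, stats = stats, columns = colnames(Z))
}

#' Fit the BBS regression model
#'
#' Joint ordinary-least-squares fit of the response on the component
#' expression scores and the covariate design, `y = X beta + Z gamma + eps`;
#' the brain coefficients `beta` and covariate coefficients `gamma` are
#' stored separately. The intercept is expected to live in `Z`.
#'
#' @param expr n x K expression score matrix (X).
#' @param y Numeric response vector (e.g., GCA scores).
#' @param Z n x p covariate design matrix including an intercept column.
#' @return A `bbs_model` with `beta` (K), `gamma` (p), and fit info.
#' @export
fit_bbs <- function(expr, y, Z) {
  expr <- as.matrix(expr)
  Z <- as.matrix(Z)
  if (nrow(expr) != length(y) || nrow(Z) != length(y))
    abort("row counts of expr, Z and y must agree.")
  D <- cbind(expr, Z)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[seq(qrD$rank + 1, ncol(D))]]
    abort(paste("design [X Z] is rank deficient; offending columns:",
                paste(bad, collapse = ", ")))
  }
  coefs <- qr.coef(qrD, y)
  K <- ncol(expr)
  structure(list(beta = coefs[seq_len(K)],
                 gamma = coefs[K + seq_len(ncol(Z))],
                 K = K, p = ncol(Z),
                 sigma2 = sum(qr.resid(qrD, y)^2) / max(1, length(y) - ncol(D))),
            class = "bbs_model")
}

#' @export
print.bbs_model <- function(x, ...) {
  cat("<bbs_model>", x$K, "brain components +", x$p, "covariate columns\n")
  invisible(x)
}

#' @describeIn fit_bbs Tidy coefficients: one row per term with its source
#'   (brain component or covariate).
#' @param x A `bbs_model`.
#' @param ... Unused.
#' @export
tidy.bbs_model <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("PC", seq_len(x$K)), names(x$gamma) %||% paste0("Z", seq_len(x$p))),
    type = rep(c("brain", "covariate"), c(x$K, x$p)),
    estimate = c(as.numeric(x$beta), as.numeric(x$gamma)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Covariate-adjusted out-of-sample predictions
#'
#' Computes the covariate-adjusted response `y_adj = y_test - Z_test gamma_hat`
#' and the brain-based prediction `y_hat = X_test beta_hat`, using only
#' coefficients learned on the training set (no refitting).
#'
#' @param model A [fit_bbs()] model.
#' @param expr_test Test expression scores (n_test x K).
#' @param Z_test Test covariate design (n_test x p).
#' @param y_test Test responses.
#' @return A tibble with columns `y_adj` and `y_hat`; attribute `degenerate`
#'   is TRUE when the prediction has zero variance (correlation undefined).
#' @export
predict_adjusted <- function(model, expr_test, Z_test, y_test) {
  expr_test <- as.matrix(expr_test)
  Z_test <- as.matrix(Z_test)
  if (ncol(expr_test) != model$K || ncol(Z_test) != model$p)
    abort("test design shapes do not match the fitted model.")
  y_adj <- as.numeric(y_test - Z_test %*% model$gamma)
  y_hat <- as.numeric(expr_test %*% model$beta)
  out <- tibble::tibble(y_adj = y_adj, y_hat = y_hat)
  attr(out, "degenerate") <- sd(y_hat) == 0
  out
}

#' Consensus predictive map
#'
#' Multiplies each basis component map by its fitted BBS coefficient, sums
#' across components, and z-scores the resulting voxel map.
#'
#' @param basis A [build_basis()] object.
#' @param model The [fit_bbs()] model fitted on this basis.
#' @return Numeric voxel vector (z-scored).
#' @export
consensus_map <- function(basis, model) {
  if (model$K != basis$K) abort("model was not fitted on this basis.")
  m <- as.numeric(crossprod(basis$components, model$beta))
  s <- sd(m)
  if (s == 0) abort("consensus map has zero variance.")
  (m - mean(m)) / s
}
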