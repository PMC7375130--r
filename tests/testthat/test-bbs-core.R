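test_that("rank-1 data yields the generating component and zero second eigenvalue", {
  set.seed(41)
  c_pat <- rnorm(50)
  g <- rnorm(12)
  V <- g %o% c_pat
  basis <- build_basis(V, K = 3)
  cn <- c_pat - 0  # component direction of the centered matrix is still c
  expect_equal(abs(sum(basis$components[1, ] * cn / sqrt(sum(cn^2)))), 1,
               tolerance = 1e-8)
  expect_lt(basis$eigenvalues[2] / basis$eigenvalues[1], 1e-12)
})

test_that("basis eigenvalues match an independent eigendecomposition", {
  M <- matrix(c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8,
                9, 7, 9, 3, 2, 3, 8, 4, 6, 2, 6, 4), 6, 4)
  basis <- build_basis(M, K = 3)
  ev <- eigen(cov(M), symmetric = TRUE)$values
  expect_equal(basis$eigenvalues, ev[1:3], tolerance = 1e-10)
  # completeness: a full-rank basis reconstructs the centered matrix
  b5 <- suppressWarnings(build_basis(M, K = 5))
  Xc <- sweep(M, 2, colMeans(M))
  rec <- expression_scores(b5, M) %*% b5$components
  expect_equal(rec, Xc, tolerance = 1e-8, ignore_attr = TRUE)
  expect_warning(build_basis(M, K = 10), "clipped")
})

test_that("expression scores have PCA properties on the train set", {
  set.seed(42)
  V <- matrix(rnorm(30 * 80), 30, 80)
  basis <- build_basis(V, K = 5)
  X <- expression_scores(basis, V)
  expect_equal(max(abs(cor(X)[lower.tri(diag(5))])), 0, tolerance = 1e-8)
  expect_equal(apply(X, 2, var), basis$eigenvalues, tolerance = 1e-8)
  # the train mean maps to zero scores; mean + 2*component_3 to 2*e3
  expect_equal(as.numeric(expression_scores(basis, rbind(basis$center))),
               rep(0, 5), tolerance = 1e-10)
  probe <- rbind(basis$center + 2 * basis$components[3, ])
  expect_equal(as.numeric(expression_scores(basis, probe)),
               2 * as.numeric(diag(5)[3, ]), tolerance = 1e-8)
  expect_error(expression_scores(basis, V[, 1:10]), "voxel count")
})

test_that("fit_bbs matches an independent normal-equations solve", {
  set.seed(43)
  X <- matrix(rnorm(8 * 2), 8, 2)
  Z <- cbind(1, rnorm(8))
  y <- rnorm(8)
  fit <- fit_bbs(X, y, Z)
  D <- cbind(X, Z)
  ref <- solve(t(D) %*% D, t(D) %*% y)
  expect_equal(c(fit$beta, fit$gamma), as.numeric(ref), tolerance = 1e-10,
               ignore_attr = TRUE)
  # joint row permutation leaves coefficients unchanged
  p <- sample.int(8)
  fit2 <- fit_bbs(X[p, ], y[p], Z[p, ])
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-10)
  expect_equal(fit2$gamma, fit$gamma, tolerance = 1e-10)
  expect_error(fit_bbs(cbind(X, X[, 1]), y, Z), "rank deficient")
})

test_that("y linear in X with orthogonal Z gives zero covariate effects", {
  set.seed(44)
  X <- scale(matrix(rnorm(40 * 3), 40, 3), scale = FALSE)
  Z <- cbind(intercept = rep(1, 40))
  y <- X %*% c(1, -2, 0.5)
  fit <- fit_bbs(X, y, Z)
  expect_equal(as.numeric(fit$beta), c(1, -2, 0.5), tolerance = 1e-10)
  expect_equal(as.numeric(fit$gamma), 0, tolerance = 1e-10)
})

test_that("predict_adjusted applies train coefficients without refitting", {
  set.seed(45)
  n <- 60
  V <- matrix(rnorm(n * 100), n, 100)
  Z <- cbind(intercept = 1, z1 = rnorm(n))
  basis <- build_basis(V, K = 4)
  X <- expression_scores(basis, V)
  y <- X[, 1] - 0.5 * X[, 2] + Z[, 2] + rnorm(n, sd = 0.3)
  fit <- fit_bbs(X, y, Z)
  pred <- predict_adjusted(fit, X, Z, y)
  # oracle: same partial relation via lm on the joint design
  lmfit <- lm(y ~ 0 + X + Z)
  y_adj_o <- y - Z %*% coef(lmfit)[5:6]
  y_hat_o <- X %*% coef(lmfit)[1:4]
  expect_equal(cor(pred$y_adj, pred$y_hat), as.numeric(cor(y_adj_o, y_hat_o)),
               tolerance = 1e-10)
  # intercept-only Z shifts y_adj but not the correlation
  Zi <- cbind(intercept = rep(1, n))
  fi <- fit_bbs(X, y, Zi)
  pi <- predict_adjusted(fi, X, Zi, y)
  expect_equal(pi$y_adj, y - fi$gamma[1], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(cor(pi$y_adj, pi$y_hat), cor(y, pi$y_hat), tolerance = 1e-12)
  # zero betas flagged degenerate
  fz <- fi; fz$beta[] <- 0
  expect_true(attr(predict_adjusted(fz, X, Zi, y), "degenerate"))
})

test_that("predictions are invariant to a positive rescaling of all maps", {
  set.seed(46)
  V <- matrix(rnorm(40 * 60), 40, 60)
  Z <- cbind(1, rnorm(40))
  y <- rnorm(40)
  train <- 1:30; test <- 31:40
  run <- function(V) {
    b <- build_basis(V[train, ], K = 5)
    f <- fit_bbs(expression_scores(b, V[train, ]), y[train], Z[train, ])
    predict_adjusted(f, expression_scores(b, V[test, ]), Z[test, ], y[test])$y_hat
  }
  expect_equal(run(V), run(7 * V), tolerance = 1e-8)
})

test_that("consensus map equals the hand-computed z-scored weighted sum", {
  basis <- structure(list(
    components = rbind(c(1, 0, 0, 0) , c(0, 1 / sqrt(2), 1 / sqrt(2), 0)),
    eigenvalues = c(2, 1), center = rep(0, 4), K = 2, n_train = 10),
    class = "basis_set")
  model <- structure(list(beta = c(2, -1), gamma = 0, K = 2, p = 1),
                     class = "bbs_model")
  raw <- 2 * basis$components[1, ] - 1 * basis$components[2, ]
  expect_equal(consensus_map(basis, model), (raw - mean(raw)) / sd(raw),
               tolerance = 1e-12)
  m2 <- model; m2$beta <- -model$beta
  expect_equal(consensus_map(basis, m2), -consensus_map(basis, model),
               tolerance = 1e-12)
  # single nonzero beta reproduces the z-scored component
  m1 <- model; m1$beta <- c(1, 0)
  c1 <- basis$components[1, ]
  expect_equal(consensus_map(basis, m1), (c1 - mean(c1)) / sd(c1),
               tolerance = 1e-12)
})

test_that("covariate design standardizes with train statistics only", {
  cov <- data.frame(age = c(20, 30, 40, 50), sex = c("F", "M", "F", "M"))
  cd <- covariate_design(cov, train_idx = 1:3)
  expect_equal(cd$Z[, "age"], (cov$age - 30) / 10, ignore_attr = TRUE)
  expect_equal(colnames(cd$Z), c("intercept", "age", "sexM"))
  expect_error(covariate_design(data.frame(a = 1:4, b = 2 * (1:4))),
               "rank deficient")
})
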