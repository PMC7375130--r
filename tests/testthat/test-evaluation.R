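test_that("family folds never split families and balance sizes", {
  set.seed(51)
  for (i in 1:25) {
    tbl <- random_family_table(n_families = sample(12:40, 1))
    fa <- make_family_folds(tbl, k = 10, seed = i)
    td <- tidy(fa)
    spans <- tapply(td$fold, td$family_id, function(v) length(unique(v)))
    expect_true(all(spans == 1))
  }
  # singleton families, n divisible by k -> perfectly equal folds
  tbl <- tibble::tibble(subject_id = sprintf("S%03d", 1:40),
                        family_id = sprintf("F%03d", 1:40))
  fa <- make_family_folds(tbl, k = 10, seed = 3)
  expect_true(all(tabulate(fa$fold, 10) == 4))
  # 23 families of size 3: greedy bound on fold-size spread
  tbl <- tibble::tibble(subject_id = sprintf("S%03d", 1:69),
                        family_id = rep(sprintf("F%03d", 1:23), each = 3))
  fa <- make_family_folds(tbl, k = 10, seed = 4)
  sizes <- tabulate(fa$fold, 10)
  expect_lte(max(sizes) - min(sizes), 3)
  expect_error(make_family_folds(tbl[1:9, ], k = 10), "fewer families")
})

test_that("fisher averaging matches closed forms and clamps |r| = 1", {
  expect_equal(fisher_average(c(0.5, 0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(fisher_average(c(0, 0)), 0, tolerance = 1e-12)
  expect_equal(fisher_average(c(0.3, 0.7)),
               tanh((atanh(0.3) + atanh(0.7)) / 2), tolerance = 1e-12)
  expect_equal(fisher_average(c(0.3, 0.7)), 0.5288, tolerance = 1e-4)
  expect_warning(out <- fisher_average(c(1, 0)), "clamped")
  expect_true(out < 1)
})

test_that("R2_cv and MSE reproduce hand computations", {
  expect_equal(r2_cv(c(1, 2, 3), c(1, 1, 3), 2), 0.5, tolerance = 1e-12)
  expect_equal(mse_cv(c(1, 2, 3), c(1, 1, 3)), 0.5, tolerance = 1e-12)
  y <- rnorm(10)
  expect_equal(r2_cv(y, y, 0), 1)
  expect_equal(mse_cv(y, y), 0)
  # constant prediction at the train mean gives R2 = 0
  yt <- c(-1, 0, 1)
  expect_equal(r2_cv(yt, rep(0, 3), 0), 0)
  expect_error(r2_cv(rep(1, 3), rep(0, 3), 1), "zero denominator")
})

test_that("fold interval follows mean +/- z * SD and widens with noise", {
  ci <- fold_ci(c(0.4, 0.6))
  expect_equal(unname(ci), 0.5 + c(-1, 1) * qnorm(0.975) * sd(c(0.4, 0.6)),
               tolerance = 1e-12)
  expect_equal(unname(fold_ci(rep(0.3, 5))), c(0.3, 0.3))
  w1 <- diff(fold_ci(c(0.4, 0.5, 0.6)))
  w2 <- diff(fold_ci(c(0.3, 0.5, 0.7)))
  expect_gt(w2, w1)
  sem <- fold_ci(c(0.4, 0.6), scale = "sem")
  expect_lt(diff(sem), diff(ci))
  expect_error(fold_ci(0.5), "two folds")
})

test_that("run_cv is invariant to joint subject-row permutation", {
  spec <- small_spec(n = 120, m = 80, gca_coupling = 1.5, seed = 52)
  co <- generate_cohort(spec)
  parc <- generate_parcellation(80)
  mp <- generate_contrast_maps(co, parc, spec, "hi")
  fa <- make_family_folds(co, k = 5, seed = 6)
  cv1 <- run_cv(mp, behavior_matrix(co), covariate_frame(co, "hi"),
                fa, K = 6)
  set.seed(53)
  p <- sample.int(120)
  cv2 <- run_cv(mp$values[p, ], behavior_matrix(co)[p, ],
                covariate_frame(co, "hi")[p, ], unname(fa$fold)[p], K = 6)
  expect_equal(cv2$pooled_r, cv1$pooled_r, tolerance = 1e-8)
  expect_equal(cv2$r2_cv, cv1$r2_cv, tolerance = 1e-8)
})

test_that("a single dominant component carries the signal: K = 1 suffices", {
  spec <- synth_spec(n_subjects = 500, n_voxels = 150, n_signal_components = 1,
                     demand_levels = c(hi = 0.9), gca_coupling = 2,
                     confound_strength = 0, noise_sd = 0.5, seed = 54)
  co <- generate_cohort(spec)
  parc <- generate_parcellation(150)
  mp <- generate_contrast_maps(co, parc, spec, "hi")
  fa <- make_family_folds(co, k = 5, seed = 7)
  r1 <- run_cv(mp, behavior_matrix(co), covariate_frame(co, "hi"), fa, K = 1)
  r30 <- run_cv(mp, behavior_matrix(co), covariate_frame(co, "hi"), fa, K = 30)
  expect_lt(abs(r1$pooled_r - r30$pooled_r), 0.03)
  expect_gt(r1$pooled_r, 0.5)
})

test_that("corrupting held-out data leaves train-side estimates untouched", {
  spec <- small_spec(n = 100, m = 60, seed = 55)
  co <- generate_cohort(spec)
  parc <- generate_parcellation(60)
  mp <- generate_contrast_maps(co, parc, spec, "hi")
  fa <- make_family_folds(co, k = 4, seed = 8)
  beh <- behavior_matrix(co)
  cv1 <- run_cv(mp, beh, covariate_frame(co, "hi"), fa, K = 5)
  # poison fold 1's test subjects in behavior and maps (mild, so folds that
  # train on these subjects stay well-conditioned)
  test1 <- which(unname(fa$fold) == 1)
  beh2 <- beh; beh2[test1, ] <- beh2[test1, ] * 1.5 + 2
  V2 <- mp$values; V2[test1, ] <- V2[test1, ] + 5
  cv2 <- run_cv(V2, beh2, covariate_frame(co, "hi"), unname(fa$fold), K = 5)
  expect_equal(cv2$fold_coefs[[1]]$beta, cv1$fold_coefs[[1]]$beta,
               tolerance = 1e-8)
  expect_equal(cv2$fold_coefs[[1]]$gamma, cv1$fold_coefs[[1]]$gamma,
               tolerance = 1e-8)
  expect_equal(cv2$fold_coefs[[1]]$lambda_g, cv1$fold_coefs[[1]]$lambda_g,
               tolerance = 1e-8)
  # ...but the fold-1 test-side metrics do change
  expect_false(isTRUE(all.equal(cv2$per_fold$r[1], cv1$per_fold$r[1])))
})

test_that("null cohorts give pooled correlations centered at zero", {
  rs <- vapply(1:20, function(i) {
    spec <- synth_spec(n_subjects = 150, n_voxels = 60, n_signal_components = 3,
                       demand_levels = c(task = 0.8), gca_coupling = 0,
                       confound_strength = 0.15, seed = 500 + i)
    co <- generate_cohort(spec)
    parc <- generate_parcellation(60)
    mp <- generate_contrast_maps(co, parc, spec, "task")
    fa <- make_family_folds(co, k = 5, seed = i)
    run_cv(mp, behavior_matrix(co), covariate_frame(co, "task"), fa,
           K = 5)$pooled_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("permutation test is seeded, bounded and sane on null data", {
  spec <- synth_spec(n_subjects = 120, n_voxels = 50, n_signal_components = 3,
                     demand_levels = c(task = 0.8), gca_coupling = 0, seed = 57)
  co <- generate_cohort(spec)
  parc <- generate_parcellation(50)
  mp <- generate_contrast_maps(co, parc, spec, "task")
  fa <- make_family_folds(co, k = 4, seed = 9)
  args <- list(mp, behavior_matrix(co), covariate_frame(co, "task"), fa)
  p1 <- suppressWarnings(do.call(permutation_test,
                                 c(args, list(K = 4, B = 60, seed = 78))))
  p2 <- suppressWarnings(do.call(permutation_test,
                                 c(args, list(K = 4, B = 60, seed = 78))))
  expect_identical(p1$null_r, p2$null_r)
  expect_length(p1$null_r, 60)
  expect_gt(p1$p_value, 0)
  expect_lte(p1$p_value, 1)
  expect_gt(p1$p_value, 0.05)  # no signal: observed r should sit inside the null
  expect_error(permutation_test(mp, behavior_matrix(co),
                                covariate_frame(co, "task"), fa, B = 0),
               "B must be")
})
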