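test_that("spec validation rejects malformed configurations", {
  expect_error(synth_spec(family_size_probs = c(0.5, 0.4)), "probability")
  expect_error(synth_spec(demand_levels = c(a = 1.2)), "0, 1")
  expect_error(synth_spec(general_loadings = rep(0.9, 10),
                          group_loadings = default_group_loadings(0.6)),
               "negative unique variance")
  expect_error(synth_spec(n_networks = 1), "positive")
})

test_that("generators are deterministic given an identical spec", {
  spec <- small_spec(n = 80, m = 60)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  co <- generate_cohort(spec)
  parc <- generate_parcellation(60)
  m1 <- generate_contrast_maps(co, parc, spec, "hi")
  set.seed(4242)  # ambient RNG state must not matter
  m2 <- generate_contrast_maps(co, parc, spec, "hi")
  expect_identical(m1$values, m2$values)
  t1 <- generate_roi_timeseries(co[1:3, ], n_rois = 10, n_frames = 60, spec)
  t2 <- generate_roi_timeseries(co[1:3, ], n_rois = 10, n_frames = 60, spec)
  expect_identical(t1$timeseries, t2$timeseries)
})

test_that("family structure and latent-g clustering follow the spec", {
  spec0 <- small_spec(n = 2000, m = 10, family_icc = 0, confound_strength = 0,
                      seed = 7)
  co0 <- generate_cohort(spec0)
  sib <- dplyr::filter(dplyr::group_by(co0, family_id), dplyr::n() >= 2)
  pairs <- dplyr::summarise(sib, g1 = latent_g[1], g2 = latent_g[2])
  expect_lt(abs(cor(pairs$g1, pairs$g2)), 0.05)

  spec5 <- small_spec(n = 2000, m = 10, family_icc = 0.5, confound_strength = 0,
                      seed = 7)
  co5 <- generate_cohort(spec5)
  sib <- dplyr::filter(dplyr::group_by(co5, family_id), dplyr::n() >= 2)
  pairs <- dplyr::summarise(sib, g1 = latent_g[1], g2 = latent_g[2])
  expect_gt(cor(pairs$g1, pairs$g2), 0.35)
  expect_lt(abs(var(co5$latent_g) - 1), 0.1)
})

test_that("one-factor battery reproduces the closed-form inter-test correlation", {
  spec <- small_spec(n = 5000, m = 10,
                     general_loadings = rep(0.7, 10),
                     group_loadings = matrix(0, 10, 4), seed = 12)
  co <- generate_cohort(spec)
  R <- cor(behavior_matrix(co))
  off <- R[lower.tri(R)]
  expect_lt(max(abs(off - 0.49)), 0.04)
})

test_that("behavioral correlations converge to the implied bifactor structure", {
  spec <- small_spec(n = 5000, m = 10, seed = 13)
  co <- generate_cohort(spec)
  lg <- spec$general_loadings
  Lf <- spec$group_loadings
  Sigma <- tcrossprod(lg) + tcrossprod(Lf) +
    diag(as.numeric(1 - lg^2 - rowSums(Lf^2)))
  expect_lt(max(abs(cor(behavior_matrix(co)) - Sigma)), 0.05)
})

test_that("retest scores hit the target reliability per test", {
  spec <- small_spec(n = 2000, m = 10, retest_reliability = 0.78, seed = 14)
  co <- generate_cohort(spec)
  s1 <- behavior_matrix(co)
  s2 <- behavior_matrix(co, session = 2)
  rs <- vapply(1:10, function(j) cor(s1[, j], s2[, j]), numeric(1))
  expect_lt(max(abs(rs - 0.78)), 0.04)
})

test_that("parcellation labels every voxel once with nonempty FPN and DMN", {
  parc <- generate_parcellation(101, 7)
  expect_length(parc$labels, 101)
  expect_true(all(parc$labels %in% 1:7))
  expect_gt(length(taskbbs:::network_voxels(parc, "FPN")), 0)
  expect_gt(length(taskbbs:::network_voxels(parc, "DMN")), 0)
  expect_error(generate_parcellation(50, 1), "two networks")
})

test_that("demand scales mean FPN activation by the configured amplitude", {
  spec <- synth_spec(n_subjects = 400, n_voxels = 400, n_signal_components = 5,
                     demand_levels = c(on = 1, off = 0),
                     activation_amplitude = 1.5, noise_sd = 0.5,
                     gca_coupling = 0, confound_strength = 0, seed = 21)
  co <- generate_cohort(spec)
  parc <- generate_parcellation(400)
  fpn <- taskbbs:::network_voxels(parc, "FPN")
  dmn <- taskbbs:::network_voxels(parc, "DMN")
  on <- generate_contrast_maps(co, parc, spec, "on")
  off <- generate_contrast_maps(co, parc, spec, "off")
  d_fpn <- mean(on$values[, fpn]) - mean(off$values[, fpn])
  d_dmn <- mean(on$values[, dmn]) - mean(off$values[, dmn])
  expect_lt(abs(d_fpn - 1.5), 0.1)
  expect_lt(abs(d_dmn + 1.5), 0.1)
})

test_that("zero gca coupling leaves voxels uncorrelated with latent g", {
  spec <- small_spec(n = 500, m = 200, gca_coupling = 0,
                     confound_strength = 0, seed = 22)
  co <- generate_cohort(spec)
  parc <- generate_parcellation(200)
  mp <- generate_contrast_maps(co, parc, spec, "hi")
  rs <- abs(cor(mp$values, co$latent_g))
  expect_lt(mean(rs), 2 / sqrt(500))
  expect_error(generate_contrast_maps(co, parc, spec, "nope"), "unknown contrast")
})

test_that("roi time series carry seeded motion spikes and optional g coupling", {
  spec <- small_spec(n = 30, m = 10, gca_coupling = 0, seed = 23)
  co <- generate_cohort(spec)
  ts <- generate_roi_timeseries(co, n_rois = 8, n_frames = 80, spec)
  has_spike <- which(lengths(ts$spike_frames) > 0)[1]
  fd <- framewise_displacement(ts$motion[[has_spike]])
  expect_true(all(fd[ts$spike_frames[[has_spike]]] > 0.5))
  # edges are unrelated to g when coupling is off
  feats <- t(vapply(ts$timeseries, function(x) connectome(x)$z,
                    numeric(8 * 7 / 2)))
  rs <- suppressWarnings(cor(feats, co$latent_g))
  expect_lt(mean(abs(rs)), 2.5 / sqrt(30))
  expect_error(generate_roi_timeseries(co, n_rois = 8, n_frames = 40, spec),
               "n_frames")
})
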