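#' Specification for a synthetic neuroimaging-behavior cohort
#'
#' Bundles every knob of the synthetic-data generator into a validated spec
#' object. The generator emulates the statistical structure that the BBS
#' pipeline assumes in family-clustered task-fMRI studies: a bifactor-
#' structured ten-test behavioral battery (one general factor, four group
#' factors), family-shared variance in the latent general ability, spatially
#' smooth contrast maps whose component expressions couple to the latent
#' general factor in proportion to each contrast's cognitive demand, a
#' motion confound acting on both maps and ability, and a seven-network
#' voxel parcellation whose frontoparietal (FPN) and default-mode (DMN)
#' networks carry the demand-dependent activation.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param family_size_probs Probabilities over family sizes 1..length. Families
#'   are drawn from this distribution until `n_subjects` is reached.
#' @param n_voxels Number of voxels per contrast map.
#' @param n_networks Number of networks in the parcellation (>= 2; the last
#'   two are designated FPN and DMN).
#' @param n_signal_components Number of latent spatial components mixed into
#'   every map. Component 1 carries the general-ability signal.
#' @param gca_coupling Effect size coupling the first component's expression
#'   to the latent general factor; the realized coupling for a contrast is
#'   `gca_coupling * demand`.
#' @param demand_levels Named vector of per-contrast cognitive-demand scalars
#'   in \[0, 1\]. Names are the contrast names.
#' @param activation_amplitude Mean FPN activation (and DMN deactivation)
#'   injected into the maps at demand 1, in map units.
#' @param noise_sd Standard deviation of i.i.d. voxel noise.
#' @param general_loadings Length-10 general-factor loadings of the battery.
#' @param group_loadings 10 x 4 group-factor loading matrix (block structure
#'   by default: crystallized, speed, memory, visuospatial).
#' @param family_icc Proportion of latent-g variance shared within family.
#' @param confound_strength Coupling of the motion propensity into both the
#'   latent general factor (negatively) and the maps.
#' @param retest_reliability Target test-retest correlation for session-2
#'   behavioral scores.
#' @param seed Integer seed; every generator output is a pure function of the
#'   spec (including this seed).
#'
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects = 967,
                       family_size_probs = c(0.55, 0.25, 0.12, 0.06, 0.02),
                       n_voxels = 2000,
                       n_networks = 7,
                       n_signal_components = 10,
                       gca_coupling = 1,
                       demand_levels = default_demand_levels(),
                       activation_amplitude = 1,
                       noise_sd = 1,
                       general_loadings = rep(0.7, 10),
                       group_loadings = default_group_loadings(),
                       family_icc = 0.3,
                       confound_strength = 0.2,
                       retest_reliability = 0.78,
                       seed = 1L) {
  spec <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      family_size_probs = family_size_probs,
      n_voxels = as.integer(n_voxels),
      n_networks = as.integer(n_networks),
      n_signal_components = as.integer(n_signal_components),
      gca_coupling = gca_coupling,
      demand_levels = demand_levels,
      activation_amplitude = activation_amplitude,
      noise_sd = noise_sd,
      general_loadings = general_loadings,
      group_loadings = group_loadings,
      family_icc = family_icc,
      confound_strength = confound_strength,
      retest_reliability = retest_reliability,
      seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
  validate_synth_spec(spec)
}

#' Default per-contrast cognitive-demand levels
#'
#' Fifteen task contrasts named after the standard HCP task battery, with
#' demand levels (configuration, not ground truth) chosen so that executive
#' contrasts (n-back, math-story, relational-match) are the most demanding
#' and sensorimotor/control contrasts the least.
#'
#' @return Named numeric vector of demand levels in \[0, 1\].
#' @export
default_demand_levels <- function() {
  c("2bk-0bk" = 0.95, "2bk" = 0.90, "math-story" = 0.85, "rel-match" = 0.80,
    "random" = 0.62, "0bk" = 0.60, "tom" = 0.58, "reward" = 0.55,
    "rel" = 0.52, "match" = 0.50, "punish" = 0.45, "tom-random" = 0.40,
    "faces-shapes" = 0.38, "motor" = 0.15, "punish-reward" = 0.10)
}

#' @rdname synth_spec
#' @export
battery_tests <- function() {
  c("PicVocab", "ReadEng", "CardSort", "Flanker", "PatternComp",
    "ListSort", "PicSeq", "WordMem", "PMAT24", "LineOrient")
}

# Group membership of the ten battery tests: crystallized (2), processing
# speed (3), memory (3), visuospatial (2).
battery_groups <- function() {
  c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L)
}

#' @rdname synth_spec
#' @export
default_group_loadings <- function(loading = 0.4) {
  grp <- battery_groups()
  L <- matrix(0, 10, 4, dimnames = list(battery_tests(),
                                        c("crystallized", "speed", "memory", "visuospatial")))
  L[cbind(seq_len(10), grp)] <- loading
  L
}

validate_synth_spec <- function(spec) {
  p <- spec$family_size_probs
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    abort("`family_size_probs` must be a probability vector summing to 1.")
  if (spec$n_subjects < 1 || spec$n_voxels < 1 || spec$n_networks < 2 ||
      spec$n_signal_components < 1)
    abort("counts in the spec must be positive (and n_networks >= 2).")
  if (any(spec$demand_levels < 0) || any(spec$demand_levels > 1))
    abort("`demand_levels` must lie in [0, 1].")
  if (is.null(names(spec$demand_levels)))
    abort("`demand_levels` must be named by contrast.")
  if (spec$noise_sd < 0 || spec$family_icc < 0 || spec$family_icc > 1 ||
      spec$confound_strength < 0 || spec$confound_strength >= 1 ||
      spec$retest_reliability < 0 || spec$retest_reliability > 1)
    abort("variance/coupling parameters out of range.")
  lg <- spec$general_loadings
  Lf <- spec$group_loadings
  if (length(lg) != 10 || !all(dim(Lf) == c(10, 4)))
    abort("loadings must be general (10) and group (10 x 4).")
  if (any(abs(lg) > 1) || any(abs(Lf) > 1))
    abort("loading magnitudes must be <= 1.")
  uniq <- 1 - lg^2 - rowSums(Lf^2)
  if (any(uniq < 0))
    abort("loadings imply negative unique variance for at least one test.")
  spec
}

#' Generate a family-clustered synthetic cohort
#'
#' Draws families from the spec's family-size distribution until the target
#' cohort size is reached (the last family is truncated), generates a latent
#' general cognitive ability `g` with the requested within-family variance
#' share, couples a latent motion propensity negatively into `g`, and
#' produces ten behavioral test scores from the bifactor loading structure
#' (unit population variance per test), plus demographic and scanner
#' covariates and per-contrast mean framewise displacement. A retest session
#' with the configured reliability is generated for every subject.
#'
#' @param spec A [synth_spec()].
#' @return A tibble with one row per subject: `subject_id`, `family_id`,
#'   `latent_g` (ground truth, synthetic only), covariates (`age`, `age_sq`,
#'   `handedness`, `gender`, `brain_vol`, `recon_version`, `mean_fd`,
#'   `mean_fd_sq`, per-contrast `fd_*` columns), the ten test scores, and
#'   `retest_*` columns for the second session.
#' @export
generate_cohort <- function(spec) {
  validate_synth_spec(spec)
  with_stream(spec$seed, "cohort", {
    n <- spec$n_subjects
    sizes <- integer(0)
    while (sum(sizes) < n) {
      sizes <- c(sizes, sample.int(length(spec$family_size_probs), 1,
                                   prob = spec$family_size_probs))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
    family_id <- rep(seq_along(sizes), sizes)

    # latent general ability: family + individual parts, unit variance,
    # then a motion propensity folded in with weight -confound_strength
    fam_eff <- rnorm(length(sizes))[family_id]
    ind_eff <- rnorm(n)
    g_core <- sqrt(spec$family_icc) * fam_eff + sqrt(1 - spec$family_icc) * ind_eff
    motion <- rnorm(n)
    cs <- spec$confound_strength
    g <- sqrt(1 - cs^2) * g_core - cs * motion

    # behavioral battery: bifactor structure with unit total variance
    tests <- battery_tests()
    lg <- spec$general_loadings
    Lf <- spec$group_loadings
    uniq_sd <- sqrt(pmax(0, 1 - lg^2 - rowSums(Lf^2)))
    fgrp <- matrix(rnorm(n * 4), n, 4)
    eps <- matrix(rnorm(n * 10), n, 10)
    scores <- outer(g, lg) + fgrp %*% t(Lf) + sweep(eps, 2, uniq_sd, `*`)
    colnames(scores) <- tests

    rr <- spec$retest_reliability
    retest <- rr * scores + sqrt(1 - rr^2) * matrix(rnorm(n * 10), n, 10)
    colnames(retest) <- paste0("retest_", tests)

    gender <- sample(c("F", "M"), n, replace = TRUE)
    age <- pmin(36, pmax(22, round(rnorm(n, 28.8, 3.7))))
    base_fd <- exp(log(0.15) + 0.35 * motion + 0.1 * rnorm(n))
    contrasts <- names(spec$demand_levels)
    fd <- vapply(contrasts, function(cn) base_fd * exp(0.1 * rnorm(n)),
                 numeric(n))
    colnames(fd) <- paste0("fd_", fd_key(contrasts))

    tbl <- tibble::tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      family_id = sprintf("F%04d", family_id),
      latent_g = g,
      age = age,
      age_sq = age^2,
      handedness = pmin(100, pmax(-100, round(rnorm(n, 65, 40)))),
      gender = gender,
      brain_vol = round(rnorm(n, 1.1e6, 8e4) + (gender == "M") * 9e4),
      recon_version = sample(c("r177", "r227"), n, replace = TRUE),
      mean_fd = base_fd,
      mean_fd_sq = base_fd^2
    )
    tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(fd),
                            tibble::as_tibble(scores),
                            tibble::as_tibble(retest))
    attr(tbl, "synth_spec") <- spec
    tbl
  })
}

# Sanitized key used for per-contrast framewise-displacement columns.
fd_key <- function(contrast) gsub("[^A-Za-z0-9]", "_", contrast)

#' Generate a voxel-to-network parcellation
#'
#' Assigns every voxel to one of `n_networks` contiguous, near-equal blocks.
#' The last two networks are named `FPN` and `DMN`; with seven networks the
#' names follow the familiar seven-network cortical scheme.
#'
#' @param n_voxels Number of voxels.
#' @param n_networks Number of networks (>= 2).
#' @return An object of class `parcellation`: a list with integer `labels`
#'   (length `n_voxels`, values 1..n_networks) and a named `networks` map.
#' @export
generate_parcellation <- function(n_voxels, n_networks = 7) {
  if (n_networks < 2) abort("need at least two networks (FPN and DMN).")
  if (n_voxels < n_networks) abort("need at least one voxel per network.")
  nm <- if (n_networks == 7) {
    c("Visual", "Somatomotor", "DorsAttn", "VentAttn", "Limbic", "FPN", "DMN")
  } else {
    c(paste0("Net", seq_len(n_networks - 2)), "FPN", "DMN")
  }
  sizes <- diff(round(seq(0, n_voxels, length.out = n_networks + 1)))
  labels <- rep(seq_len(n_networks), sizes)
  structure(list(labels = labels, networks = setNames(seq_len(n_networks), nm)),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation>", length(x$labels), "voxels,",
      length(x$networks), "networks:",
      paste(names(x$networks), collapse = ", "), "\n")
  invisible(x)
}

# Voxel indices belonging to a named network.
network_voxels <- function(parcellation, name) {
  which(parcellation$labels == parcellation$networks[[name]])
}

# Smooth, network-localized spatial pattern: white noise on the member
# voxels, moving-average smoothed along the 1-D voxel ordering within each
# network block, zero elsewhere. Optionally unit-norm.
smooth_pattern <- function(parcellation, networks, window = 15,
                           unit_norm = TRUE) {
  m <- length(parcellation$labels)
  pat <- numeric(m)
  for (nw in networks) {
    idx <- network_voxels(parcellation, nw)
    x <- rnorm(length(idx))
    k <- min(window, length(idx))
    sm <- stats::filter(c(rev(x[seq_len(k)]), x, rev(x[length(x) - seq_len(k) + 1])),
                        rep(1 / k, k), sides = 2)
    pat[idx] <- sm[k + seq_along(idx)]
  }
  if (unit_norm && sum(pat^2) > 0) pat <- pat / sqrt(sum(pat^2))
  pat
}

# Latent spatial structure shared by all contrasts of one spec: the
# demand-driven activation pattern (mean +amplitude over FPN, -amplitude
# over DMN), the signal component patterns (component 1 localized to
# FPN+DMN, the rest cycling over networks), and the motion pattern.
map_patterns <- function(spec, parcellation) {
  with_stream(spec$seed, "patterns", {
    m <- spec$n_voxels
    amp <- spec$activation_amplitude
    fpn <- network_voxels(parcellation, "FPN")
    dmn <- network_voxels(parcellation, "DMN")
    act <- numeric(m)
    act[fpn] <- amp * (1 + 0.25 * scale_to_mean0(smooth_pattern(
      parcellation, "FPN", unit_norm = FALSE)[fpn]))
    act[dmn] <- -amp * (1 + 0.25 * scale_to_mean0(smooth_pattern(
      parcellation, "DMN", unit_norm = FALSE)[dmn]))
    nets <- names(parcellation$networks)
    comp <- matrix(0, spec$n_signal_components, m)
    comp[1, ] <- smooth_pattern(parcellation, c("FPN", "DMN"))
    if (spec$n_signal_components > 1) {
      for (k in 2:spec$n_signal_components) {
        comp[k, ] <- smooth_pattern(parcellation, nets[1 + (k - 2) %% length(nets)])
      }
    }
    motion <- smooth_pattern(parcellation, nets)
    list(activation = act, components = comp, motion = motion)
  })
}

scale_to_mean0 <- function(x) {
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x / s else x
}

#' Generate per-subject contrast maps for one task contrast
#'
#' Each subject's map is the sum of (i) a fixed demand-scaled activation
#' pattern (mean FPN activation `+demand * activation_amplitude`, DMN
#' deactivation of the same magnitude), (ii) subject-specific expressions of
#' smooth network-localized unit-norm component patterns, where component 1's
#' expression is `gca_coupling * demand * g_i` plus unit noise so the
#' g-related signal scales with demand, (iii) a motion confound
#' `confound_strength * mean_fd_i` times a fixed pattern, and (iv) i.i.d.
#' voxel noise. Patterns are fixed by the spec seed and shared across
#' contrasts; subject-level draws are seeded per contrast.
#'
#' @param subjects Cohort tibble from [generate_cohort()].
#' @param parcellation A [generate_parcellation()] object with
#'   `length(labels) == spec$n_voxels`.
#' @param spec The [synth_spec()] used for the cohort.
#' @param contrast_name One of `names(spec$demand_levels)`.
#' @return A `contrast_matrix`: subjects x voxels values with subject order
#'   and the contrast name attached.
#' @export
generate_contrast_maps <- function(subjects, parcellation, spec, contrast_name) {
  if (!contrast_name %in% names(spec$demand_levels))
    abort(paste0("unknown contrast '", contrast_name, "'; not in spec$demand_levels."))
  if (length(parcellation$labels) != spec$n_voxels)
    abort("parcellation length must equal spec$n_voxels.")
  demand <- spec$demand_levels[[contrast_name]]
  pat <- map_patterns(spec, parcellation)
  fdcol <- paste0("fd_", fd_key(contrast_name))
  fd <- if (fdcol %in% names(subjects)) subjects[[fdcol]] else subjects$mean_fd
  with_stream(spec$seed, paste0("maps:", contrast_name), {
    n <- nrow(subjects)
    K <- spec$n_signal_components
    S <- matrix(rnorm(n * K), n, K)
    S[, 1] <- spec$gca_coupling * demand * subjects$latent_g + S[, 1]
    values <- demand * matrix(pat$activation, n, spec$n_voxels, byrow = TRUE) +
      S %*% pat$components +
      spec$confound_strength * fd %o% pat$motion +
      spec$noise_sd * matrix(rnorm(n * spec$n_voxels), n, spec$n_voxels)
    rownames(values) <- subjects$subject_id
    contrast_matrix(values, contrast = contrast_name, demand = demand)
  })
}

#' Construct a contrast matrix object
#'
#' @param values Numeric subjects x voxels matrix (rownames = subject ids).
#' @param contrast Contrast name.
#' @param demand Optional demand level metadata.
#' @return A `contrast_matrix` object.
#' @export
contrast_matrix <- function(values, contrast = "contrast", demand = NA_real_) {
  if (anyNA(values)) abort("contrast matrix must not contain missing values.")
  if (nrow(values) < 2) abort("contrast matrix needs at least two subjects.")
  structure(list(values = values, subjects = rownames(values),
                 contrast = contrast, demand = demand),
            class = "contrast_matrix")
}

#' @export
print.contrast_matrix <- function(x, ...) {
  cat("<contrast_matrix>", x$contrast, ":", nrow(x$values), "subjects x",
      ncol(x$values), "voxels\n")
  invisible(x)
}

#' Generate ROI time series with motion traces
#'
#' Produces per-subject ROI time series from a low-rank latent covariance
#' whose between-ROI coupling partly depends on the subject's latent general
#' ability, plus rigid-body motion-parameter traces containing seeded spike
#' frames (so framewise-displacement screening and scrubbing are exercised)
#' and white-matter/CSF surrogate nuisance signals.
#'
#' @param subjects Cohort tibble from [generate_cohort()].
#' @param n_rois Number of regions of interest (default 264).
#' @param n_frames Frames per run (> 50).
#' @param spec The cohort's [synth_spec()].
#' @param tr Repetition time in seconds (default 0.72).
#' @param spike_rate Expected proportion of spike frames per subject.
#' @return A list of class `roi_timeseries_set` with elements `timeseries`
#'   (list of frames x R matrices), `motion` (list of frames x 6 matrices:
#'   translations mm, rotations radians), `nuisance` (list of frames x 6
#'   surrogate noise-tissue signals), `spike_frames`, `tr`, `subjects`.
#' @export
generate_roi_timeseries <- function(subjects, n_rois = 264, n_frames = 200,
                                    spec, tr = 0.72, spike_rate = 0.03) {
  if (n_rois <= 0 || n_frames <= 50) abort("need n_rois > 0 and n_frames > 50.")
  with_stream(spec$seed, "timeseries", {
    q <- 5
    B0 <- matrix(rnorm(n_rois * q), n_rois, q) / sqrt(q)
    B1 <- matrix(rnorm(n_rois * q), n_rois, q) / sqrt(q)
    B2 <- matrix(rnorm(n_rois * q), n_rois, q) / sqrt(q)
    out <- list(timeseries = list(), motion = list(), nuisance = list(),
                spike_frames = list())
    for (i in seq_len(nrow(subjects))) {
      g <- subjects$latent_g[i]
      # the g-carrying network mode is expressed with session-specific noise
      # on top of the (weak) trait coupling, capping how much trait
      # information a connectome can carry — the task/rest accuracy ordering
      # follows from this, mirroring the empirical one
      B <- B0 + (0.1 * spec$gca_coupling * g + 0.2 * rnorm(1)) * B1 +
        0.3 * rnorm(1) * B2
      Fmat <- matrix(rnorm(n_frames * q), n_frames, q)
      ts <- Fmat %*% t(B) + matrix(rnorm(n_frames * n_rois), n_frames, n_rois)
      # slow drift: ~0.01 mm translations, ~0.0002 rad rotations per frame
      drift <- cbind(matrix(rnorm(n_frames * 3, sd = 0.01), n_frames, 3),
                     matrix(rnorm(n_frames * 3, sd = 2e-4), n_frames, 3))
      motion <- apply(drift, 2, cumsum)
      nspike <- stats::rbinom(1, n_frames - 1, spike_rate)
      spikes <- if (nspike > 0) sort(sample(2:n_frames, nspike)) else integer(0)
      if (length(spikes)) {
        motion[spikes, 1] <- motion[spikes, 1] + runif(length(spikes), 0.6, 1.5)
        ts[spikes, ] <- ts[spikes, ] + rnorm(length(spikes) * n_rois, sd = 3)
      }
      nuis <- matrix(rnorm(n_frames * 6), n_frames, 6)
      out$timeseries[[i]] <- ts
      out$motion[[i]] <- motion
      out$nuisance[[i]] <- nuis
      out$spike_frames[[i]] <- spikes
    }
    names(out$timeseries) <- names(out$motion) <-
      names(out$nuisance) <- names(out$spike_frames) <- subjects$subject_id
    structure(c(out, list(tr = tr, subjects = subjects$subject_id,
                          n_rois = n_rois)),
              class = "roi_timeseries_set")
  })
}
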