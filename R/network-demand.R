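#' Mean activation per network
#'
#' Computes the subject-average map first (when given a matrix), then the
#' mean map value over each network's voxels.
#'
#' @param map A voxel vector, subjects x voxels matrix, or
#'   [contrast_matrix()].
#' @param parcellation A [generate_parcellation()] object aligned with the
#'   voxels.
#' @return Named numeric vector, one mean per network.
#' @export
network_means <- function(map, parcellation) {
  v <- if (inherits(map, "contrast_matrix")) colMeans(map$values)
       else if (is.matrix(map)) colMeans(map)
       else as.numeric(map)
  if (length(v) != length(parcellation$labels))
    abort("map and parcellation voxel spaces differ.")
  counts <- tabulate(parcellation$labels, length(parcellation$networks))
  if (any(counts == 0)) abort("parcellation contains an empty network.")
  sums <- vapply(parcellation$networks, function(l) sum(v[parcellation$labels == l]),
                 numeric(1))
  sums / counts
}

#' Assemble a per-contrast demand table
#'
#' One row per contrast with its network mean activations (from the
#' subject-average map) and its GCA prediction accuracy (pooled CV r).
#'
#' @param maps Named list of [contrast_matrix()] objects.
#' @param cv_results Named list of `bbs_cv` results aligned with `maps`.
#' @param parcellation The voxel parcellation.
#' @return A tibble: `contrast`, `accuracy`, one column per network.
#' @export
build_demand_table <- function(maps, cv_results, parcellation) {
  stopifnot(identical(names(maps), names(cv_results)))
  purrr::map_dfr(names(maps), function(cn) {
    nm <- network_means(maps[[cn]], parcellation)
    dplyr::bind_cols(
      tibble::tibble(contrast = cn, accuracy = cv_results[[cn]]$pooled_r),
      tibble::as_tibble(as.list(nm)))
  })
}

#' Correlation between network activation and prediction accuracy
#'
#' Pearson correlation, across contrasts, between the chosen network's mean
#' activation and the GCA prediction accuracy, with the two-sided t-test
#' p-value.
#'
#' @param table A [build_demand_table()] tibble (>= 4 contrasts).
#' @param network Network name (e.g., `"FPN"` or `"DMN"`).
#' @return One-row tibble: `network`, `r`, `p_value`, `n_contrasts`.
#' @export
demand_accuracy_correlation <- function(table, network) {
  if (!network %in% names(table)) abort(paste("no network column", network))
  if (nrow(table) < 4) abort("need at least four contrasts.")
  x <- table[[network]]
  y <- table$accuracy
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in activation or accuracy.")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(network = network, r = unname(ct$estimate),
                 p_value = ct$p.value, n_contrasts = nrow(table))
}

#' Joint FPN + DMN regression of prediction accuracy
#'
#' Least-squares regression of accuracy on FPN and DMN mean activation (with
#' intercept), reporting the correlation between fitted and observed
#' accuracies.
#'
#' @param table A [build_demand_table()] tibble (>= 5 contrasts).
#' @return A `demand_regression` object: the `lm` fit, coefficient tibble,
#'   and `fitted_r`.
#' @export
demand_regression <- function(table) {
  if (nrow(table) < 5) abort("need at least five contrasts.")
  if (sd(table$FPN) == 0 || sd(table$DMN) == 0)
    abort("constant FPN or DMN activation across contrasts (collinear/degenerate).")
  if (abs(cor(table$FPN, table$DMN)) > 1 - 1e-10)
    abort("FPN and DMN activations are collinear.")
  fit <- lm(accuracy ~ FPN + DMN, data = table)
  structure(list(fit = fit,
                 coefficients = tibble::tibble(term = names(coef(fit)),
                                               estimate = unname(coef(fit))),
                 fitted_r = cor(fitted(fit), table$accuracy),
                 n_contrasts = nrow(table)),
            class = "demand_regression")
}

#' @export
print.demand_regression <- function(x, ...) {
  cat("<demand_regression> accuracy ~ FPN + DMN over", x$n_contrasts,
      "contrasts; fitted-vs-actual r =", round(x$fitted_r, 3), "\n")
  invisible(x)
}

#' @describeIn demand_regression Tidy the two-predictor coefficients.
#' @param x A `demand_regression`.
#' @param ... Unused.
#' @export
tidy.demand_regression <- function(x, ...) x$coefficients

#' @describeIn demand_regression One-row summary with the fitted-vs-actual r.
#' @export
glance.demand_regression <- function(x, ...) {
  tibble::tibble(fitted_r = x$fitted_r, n_contrasts = x$n_contrasts,
                 r_squared = summary(x$fit)$r.squared)
}

#' @describeIn demand_regression Scatter of accuracy against FPN activation
#'   with the joint-model fitted values.
#' @param object A `demand_regression`.
#' @export
autoplot.demand_regression <- function(object, ...) {
  df <- object$fit$model
  df$fitted <- fitted(object$fit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$accuracy)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "fitted accuracy (FPN + DMN model)",
                  y = "observed accuracy (pooled CV r)",
                  title = sprintf("fitted-vs-actual r = %.2f", object$fitted_r))
}
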