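#' Levina-Bickel maximum-likelihood intrinsic dimension estimate
#'
#' For each point x and neighbor count k, the local ML estimate is
#' `m_k(x) = [ (1/(k-1)) * sum_{j<k} log(T_k(x) / T_j(x)) ]^-1`, with
#' `T_j(x)` the Euclidean distance from x to its j-th nearest neighbor.
#' Estimates are averaged over points for each k, then over
#' `k in [k1, k2]`. The estimator depends only on distance ratios, so it is
#' invariant to rotation, translation and positive rescaling of the data.
#'
#' @param X Numeric n x m matrix with pairwise-distinct rows.
#' @param k1,k2 Neighbor range (defaults 10 and 20, the original
#'   recommendation); requires `2 <= k1 <= k2 <= n - 1`.
#' @param average `"points"` (default; average the local estimates) or
#'   `"inverse"` (average the inverse estimates and invert, the downstream
#'   bias correction).
#' @return A `dimension_estimate`: `estimate`, `per_k` (named vector), `k1`,
#'   `k2`, `n`.
#' @export
estimate_intrinsic_dimension <- function(X, k1 = 10, k2 = 20,
                                         average = c("points", "inverse")) {
  average <- match.arg(average)
  X <- as.matrix(X)
  n <- nrow(X)
  if (k1 < 2 || k2 < k1 || k2 > n - 1)
    abort("need 2 <= k1 <= k2 <= n - 1.")
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  # n x k2 matrix of sorted nearest-neighbor distances
  Tmat <- t(apply(D, 1, function(d) sort.int(d, partial = seq_len(k2))[seq_len(k2)]))
  if (any(Tmat == 0)) abort("duplicate points give zero neighbor distances.")
  logT <- log(Tmat)
  per_k <- vapply(k1:k2, function(k) {
    inv_m <- rowMeans(logT[, k, drop = FALSE] %*% matrix(1, 1, k - 1) -
                        logT[, seq_len(k - 1), drop = FALSE])
    if (average == "points") mean(1 / inv_m) else 1 / mean(inv_m)
  }, numeric(1))
  names(per_k) <- k1:k2
  structure(list(estimate = mean(per_k), per_k = per_k,
                 k1 = k1, k2 = k2, n = n, average = average),
            class = "dimension_estimate")
}

#' @export
print.dimension_estimate <- function(x, ...) {
  cat(sprintf("<dimension_estimate> %.2f (k in [%d, %d], n = %d, %s averaging)\n",
              x$estimate, x$k1, x$k2, x$n, x$average))
  invisible(x)
}

#' @describeIn estimate_intrinsic_dimension One-row summary.
#' @param x A `dimension_estimate`.
#' @param ... Unused.
#' @export
glance.dimension_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, k1 = x$k1, k2 = x$k2, n = x$n)
}
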