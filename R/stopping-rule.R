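#' L2 distance statistic between smoothed surfaces
#'
#' The statistic `T_N = sum_{i<k} integral (m_i(x) - m_k(x))^2 w(x) dx`
#' summed over all pairs of surfaces, with the integral discretised as a
#' grid sum times the grid-cell area. With two surfaces this is the weighted
#' squared L2 distance between their smoothed time-frequency estimates.
#'
#' @param surfaces List of >= 2 `spectral_surface`s on identical grids.
#' @param weight Positive weight over the grid: a single number, a matrix of
#'   the grid dimensions, or `NULL` for the uniform weight 1.
#' @return The scalar statistic (>= 0).
#' @export
l2_statistic <- function(surfaces, weight = NULL) {
  if (length(surfaces) < 2) {
    abort("Need at least 2 surfaces.", class = "sdcl_validation_error")
  }
  dims <- lapply(surfaces, function(s) dim(s$values))
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    abort("All surfaces must share one grid.", class = "sdcl_validation_error")
  }
  w <- weight %||% 1
  if (is.matrix(w) && !identical(dim(w), dims[[1]])) {
    abort("Weight matrix dimensions must match the surface grid.",
          class = "sdcl_validation_error")
  }
  if (any(w <= 0)) abort("Weight must be positive.", class = "sdcl_validation_error")
  area <- surfaces[[1]]$cell_area
  total <- 0
  L <- length(surfaces)
  for (i in seq_len(L - 1)) {
    for (k in (i + 1):L) {
      d2 <- (surfaces[[i]]$values - surfaces[[k]]$values)^2
      total <- total + sum(d2 * w)
    }
  }
  total * area
}

new_surface_test_result <- function(statistic, p_value, n_bootstrap, alpha) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_bootstrap = as.integer(n_bootstrap), alpha = alpha,
                 reject = p_value <= alpha),
            class = "surface_test_result")
}

#' @export
print.surface_test_result <- function(x, ...) {
  cat(sprintf("Wild-bootstrap surface test: T_N = %.4g, p = %.4f (B = %d, alpha = %g) -> %s\n",
              x$statistic, x$p_value, x$n_bootstrap, x$alpha,
              if (x$reject) "reject" else "no difference detected"))
  invisible(x)
}

#' @export
glance.surface_test_result <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_bootstrap = x$n_bootstrap, alpha = x$alpha, reject = x$reject)
}

#' Wild-bootstrap test for equality of two time-frequency surfaces
#'
#' Tests the null that two surfaces estimate the same smooth regression
#' function. The observed statistic is the weighted L2 distance between the
#' smoothed surfaces. Under the null the common surface is estimated by the
#' pooled mean of the two smoothed surfaces; per-surface residuals (raw
#' observation minus pooled surface) are multiplied cellwise by independent
#' wild multipliers, the perturbed raw surfaces are re-smoothed, and the
#' statistic is recomputed, giving the null reference distribution. The
#' p-value uses the add-one convention `(1 + #(T* >= T)) / (B + 1)`.
#'
#' @param surf_a,surf_b `spectral_surface`s on identical grids.
#' @param B Number of bootstrap replicates (>= 19; default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed; the test is deterministic given it.
#' @param weight Grid weight as in [l2_statistic()].
#' @param multiplier Wild multiplier distribution: `"rademacher"` (signs
#'   +/-1 with probability 1/2, the default) or `"mammen"` (Mammen's
#'   two-point distribution).
#' @return A `surface_test_result` with fields `statistic`, `p_value`,
#'   `n_bootstrap`, `alpha`, `reject`.
#' @export
wild_bootstrap_test <- function(surf_a, surf_b, B = 1000, alpha = 0.05,
                                seed = 1, weight = NULL,
                                multiplier = c("rademacher", "mammen")) {
  multiplier <- match.arg(multiplier)
  if (!identical(dim(surf_a$values), dim(surf_b$values))) {
    abort("Surfaces must share one grid.", class = "sdcl_validation_error")
  }
  if (B < 19) abort("`B` must be >= 19.", class = "sdcl_validation_error")
  bw <- surf_a$config$smoothing_bandwidth
  nt <- nrow(surf_a$values); nf <- ncol(surf_a$values)
  st <- nw_smoother(nt, bw[1])
  sf <- nw_smoother(nf, bw[2])

  stat <- l2_statistic(list(surf_a, surf_b), weight)

  m0 <- (surf_a$values + surf_b$values) / 2
  # leverage-corrected residuals (HC2-style): each raw cell enters the
  # pooled smooth with hat weight h = (S_t)_ii (S_f)_jj / 2, shrinking the
  # naive residual; dividing by sqrt(1 - h) restores its variance
  h <- outer(diag(st), diag(sf)) / 2
  infl <- 1 / sqrt(pmax(1 - h, .Machine$double.eps))
  e_a <- (surf_a$raw_values - m0) * infl
  e_b <- (surf_b$raw_values - m0) * infl
  w <- weight %||% 1
  area <- surf_a$cell_area

  draw_mult <- function(n) {
    if (multiplier == "rademacher") {
      sample(c(-1, 1), n, replace = TRUE)
    } else {
      # Mammen's two-point distribution
      p <- (sqrt(5) + 1) / (2 * sqrt(5))
      v1 <- -(sqrt(5) - 1) / 2
      v2 <- (sqrt(5) + 1) / 2
      ifelse(runif(n) < p, v1, v2)
    }
  }

  n_cells <- nt * nf
  count <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      xi_a <- matrix(draw_mult(n_cells), nt, nf)
      xi_b <- matrix(draw_mult(n_cells), nt, nf)
      sm_a <- smooth_surface(m0 + e_a * xi_a, bw, st, sf)
      sm_b <- smooth_surface(m0 + e_b * xi_b, bw, st, sf)
      t_star <- sum((sm_a - sm_b)^2 * w) * area
      if (t_star >= stat) count <- count + 1L
    }
  })
  p <- (1 + count) / (B + 1)
  new_surface_test_result(stat, p, B, alpha)
}

#' Select the number of retained IMFs by sequential surface testing
#'
#' The stopping rule of the modified EMD: decompose the signal, then for
#' k = 2, 3, ... compare the time-frequency surface of the reconstruction
#' from the first k-1 IMFs against the reconstruction from the first k. A
#' rejection means the kth IMF changes the surface (adds information), so
#' the scan continues; the first non-rejection stops it and `K = k - 1` is
#' returned. If every test rejects, K equals the IMF count; a signal with a
#' single IMF returns K = 1 with an empty trail.
#'
#' @param signal An [audio_signal()].
#' @param emd_config An [emd_config()].
#' @param surface_config A [surface_config()].
#' @param B Bootstrap replicates per test (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed (per-test seeds are derived from it).
#' @param multiplier Wild multiplier distribution; see [wild_bootstrap_test()].
#' @return A `k_selection`: list with `K` (selected count), `trail` (list
#'   of `surface_test_result`), `n_imfs`, and the decomposition.
#' @export
select_k <- function(signal, emd_config = sdcl::emd_config(),
                     surface_config = sdcl::surface_config(),
                     B = 1000, alpha = 0.05, seed = 1,
                     multiplier = "rademacher") {
  stopifnot(inherits(signal, "audio_signal"))
  decomp <- emd(signal, emd_config)
  n_imfs <- length(decomp$imfs)
  if (n_imfs == 0) {
    abort("No IMF found; cannot form a subspace.", class = "sdcl_validation_error")
  }
  trail <- list()
  K <- 1L
  if (n_imfs >= 2) {
    surf_prev <- compute_surface(emd_reconstruct(decomp, 1), decomp$rate, surface_config)
    for (k in 2:n_imfs) {
      surf_k <- compute_surface(emd_reconstruct(decomp, k), decomp$rate, surface_config)
      res <- wild_bootstrap_test(surf_prev, surf_k, B = B, alpha = alpha,
                                 seed = seed + k, multiplier = multiplier)
      trail[[length(trail) + 1L]] <- res
      if (!res$reject) { K <- k - 1L; break }
      K <- k
      surf_prev <- surf_k
    }
  }
  structure(list(K = K, trail = trail, n_imfs = n_imfs, decomposition = decomp),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> K = %d of %d IMFs\n", x$K, x$n_imfs))
  if (length(x$trail)) print(tidy(x))
  invisible(x)
}

#' K-selection trail as a table
#'
#' One row per sequential test, mirroring a (K, T_N, p-value) trail table.
#'
#' @param x A `k_selection` from [select_k()].
#' @param ... Unused.
#' @return Tibble with columns `k`, `statistic`, `p_value`, `reject`.
#' @export
tidy.k_selection <- function(x, ...) {
  tibble(
    k = seq_along(x$trail) + 1L,
    statistic = vapply(x$trail, function(r) r$statistic, 1),
    p_value = vapply(x$trail, function(r) r$p_value, 1),
    reject = vapply(x$trail, function(r) r$reject, TRUE)
  )
}

#' @export
glance.k_selection <- function(x, ...) {
  tibble(K = x$K, n_imfs = x$n_imfs, n_tests = length(x$trail))
}

#' @export
autoplot.k_selection <- function(object, ...) {
  df <- tidy(object)
  alpha <- if (length(object$trail)) object$trail[[1]]$alpha else 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$p_value)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed", colour = "red") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$K, colour = "steelblue") +
    ggplot2::labs(x = "k (IMFs in reconstruction)", y = "bootstrap p-value",
                  title = sprintf("Stopping rule: K = %d", object$K)) +
    ggplot2::theme_minimal()
}
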