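#' Tidy a density-dependence fit
#'
#' @param x A `dd_fit`.
#' @param ... Unused.
#' @return One row per parameter (`mu`, `alpha`): estimate, SE, t statistic,
#'   p-value.
#' @export
tidy.dd_fit <- function(x, ...) {
  ct <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("mu", "alpha"),
    estimate = ct[, 1], std.error = ct[, 2],
    statistic = ct[, 3], p.value = ct[, 4])
}

#' @rdname tidy.dd_fit
#' @return `glance()`: one row with `r.squared`, `sigma`, `n_points`,
#'   `n_excluded`, `nonlinearity_p`, `K`, `s2_K`.
#' @export
glance.dd_fit <- function(x, ...) {
  k <- carrying_capacity(x)
  tibble::tibble(
    r.squared = x$r_squared, sigma = summary(x$fit)$sigma,
    n_points = x$n_points, n_excluded = nrow(x$excluded),
    nonlinearity_p = x$nonlinearity_p, K = k$K, s2_K = k$s2_K)
}

#' Tidy the linkage model comparison
#'
#' @param x A `linkage_selection`.
#' @param ... Unused.
#' @return The comparison table: one row per model x response with `AICc`,
#'   `adj_r_squared`, `delta_AICc`, `rank`, `is_best`.
#' @export
tidy.linkage_selection <- function(x, ...) x$table

#' @rdname tidy.linkage_selection
#' @return `glance()`: one row per response with the best model and its AICc
#'   and adjusted R^2.
#' @export
glance.linkage_selection <- function(x, ...) {
  x$table |>
    dplyr::filter(.data$is_best) |>
    dplyr::select("response", best_model = "model", "n", "AICc",
                  "adj_r_squared")
}
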