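#' Per-capita growth rate over a time interval
#'
#' `pcgr = ln(N_end / N_start) / (t_end - t_start)`, the response of the
#' density-dependence regression: over a short interval it equals
#' `mu + alpha N_start`.
#'
#' @param n_start,n_end Densities at the interval ends (> 0); vectorized.
#' @param t_start,t_end Times in days (`t_end > t_start`).
#' @return Per-day growth rate.
#' @examples
#' compute_pcgr(100, 200, 0, 1) # ln 2
#' @export
compute_pcgr <- function(n_start, n_end, t_start, t_end) {
  if (any(n_start <= 0) || any(n_end <= 0)) {
    abort("Densities must be positive; flag zero-count samples upstream.")
  }
  if (any(t_end <= t_start)) abort("`t_end` must exceed `t_start`.")
  log(n_end / n_start) / (t_end - t_start)
}

#' Choose the growth interval for each microcosm
#'
#' With three (or more) time points, growth over the first interval can be too
#' small to measure precisely. For each microcosm the candidate intervals are
#' scanned in the fixed preference order (t0->t1, t0->t2, t1->t2, ...) and the
#' first whose observed density fold-change reaches `min_fold_change` is
#' chosen; if none qualifies, the candidate with the largest fold-change is
#' used. Time points with zero observed density are unusable; microcosms with
#' fewer than two usable points are dropped with a logged reason.
#'
#' @param samples Tibble with columns `microcosm_id`, `time_point`,
#'   `time_days`, `density` (one row per microcosm x time point).
#' @param min_fold_change Minimum density fold-change for a precise interval.
#' @return Tibble with one row per usable microcosm: `microcosm_id`,
#'   `interval_label` (e.g. `"t0->t2"`), start/end `time_point`s, times and
#'   densities; attribute `dropped` lists unusable microcosms.
#' @export
select_interval <- function(samples, min_fold_change = 1.5) {
  stopifnot(min_fold_change > 0)
  samples <- dplyr::arrange(tibble::as_tibble(samples),
                            .data$microcosm_id, .data$time_point)
  picked <- list(); dropped <- list()
  for (sp in split(samples, samples$microcosm_id)) {
    usable <- sp[sp$density > 0, , drop = FALSE]
    if (nrow(usable) < 2) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        microcosm_id = sp$microcosm_id[1], reason = "fewer than 2 usable time points")
      next
    }
    np <- nrow(usable)
    cand <- tidyr::expand_grid(i = seq_len(np), j = seq_len(np)) |>
      dplyr::filter(.data$i < .data$j) |>
      dplyr::arrange(.data$i, .data$j)
    folds <- usable$density[cand$j] / usable$density[cand$i]
    hit <- which(folds >= min_fold_change)
    pick <- if (length(hit)) hit[1] else which.max(folds)
    i <- cand$i[pick]; j <- cand$j[pick]
    picked[[length(picked) + 1L]] <- tibble::tibble(
      microcosm_id = sp$microcosm_id[1],
      interval_label = paste0("t", usable$time_point[i], "->t",
                              usable$time_point[j]),
      start_time_point = usable$time_point[i],
      end_time_point = usable$time_point[j],
      t_start = usable$time_days[i], t_end = usable$time_days[j],
      n_start = usable$density[i], n_end = usable$density[j],
      fold_change = folds[pick])
  }
  out <- if (length(picked)) dplyr::bind_rows(picked) else
    tibble::tibble(microcosm_id = character(0))
  attr(out, "dropped") <- if (length(dropped)) dplyr::bind_rows(dropped) else
    tibble::tibble(microcosm_id = character(0), reason = character(0))
  out
}

#' Build growth observations from sample summaries
#'
#' Joins the per-microcosm interval choice back onto the design columns and
#' computes each microcosm's pcgr, producing the points of the
#' density-dependence curves.
#'
#' @param samples Sample table from [simulate_experiment()] or tracking
#'   summaries, with design columns and per-time-point `density`.
#' @param min_fold_change Passed to [select_interval()].
#' @return Tibble of growth observations (one per usable microcosm) with
#'   design columns, `interval_label`, `n_start`, `n_end`, `t_start`,
#'   `t_end`, `pcgr`.
#' @export
growth_observations <- function(samples, min_fold_change = 1.5) {
  iv <- select_interval(samples, min_fold_change)
  meta <- samples |>
    dplyr::distinct(.data$microcosm_id, .data$condition_id, .data$assay_id,
                    .data$species, .data$strain, .data$temperature,
                    .data$pollutant, .data$replicate, .data$dilution)
  obs <- dplyr::inner_join(meta, iv, by = "microcosm_id") |>
    dplyr::mutate(pcgr = compute_pcgr(.data$n_start, .data$n_end,
                                      .data$t_start, .data$t_end))
  attr(obs, "dropped") <- attr(iv, "dropped")
  obs
}

#' Fit one density-dependence curve
#'
#' Ordinary least squares of pcgr on starting density, pooled over all
#' replicate assays of a condition: the intercept estimates the intrinsic
#' growth rate mu, the slope the conspecific interaction coefficient alpha.
#' The full estimator covariance is retained for the delta-method variance of
#' K. A quadratic-term t-test is reported as a residual-nonlinearity screen
#' (diagnostic only; it never alters the fit).
#'
#' @param observations Tibble with at least `n_start` and `pcgr` (usually from
#'   [growth_observations()], one condition's rows).
#' @param condition_id Optional label; taken from the data when present.
#' @return A `dd_fit` object: fields `mu`, `alpha`, `vcov` (2x2), `s2_mu`,
#'   `s2_alpha`, `cov_mu_alpha`, `n_points`, `r_squared`, `nonlinearity_p`,
#'   `excluded` (empty tibble), plus the underlying `lm` and data.
#' @examples
#' obs <- tibble::tibble(n_start = c(200, 350, 500, 650, 800),
#'                       pcgr = 1 - 0.001 * c(200, 350, 500, 650, 800))
#' fit <- fit_curve(obs)
#' tidy(fit)
#' @export
fit_curve <- function(observations, condition_id = NULL) {
  obs <- tibble::as_tibble(observations)
  if (is.null(condition_id)) {
    condition_id <- if ("condition_id" %in% names(obs))
      as.character(obs$condition_id[1]) else NA_character_
  }
  if (nrow(obs) < 3 || length(unique(obs$n_start)) < 2) {
    abort(paste0("Condition ", condition_id,
                 ": need >= 3 observations with >= 2 distinct starting densities."))
  }
  fit <- lm(pcgr ~ n_start, data = obs)
  nl_p <- NA_real_
  if (nrow(obs) >= 4 && length(unique(obs$n_start)) >= 3) {
    qfit <- lm(pcgr ~ n_start + I(n_start^2), data = obs)
    ct <- summary(qfit)$coefficients
    if ("I(n_start^2)" %in% rownames(ct)) nl_p <- ct["I(n_start^2)", 4]
  }
  new_dd_fit(condition_id, fit, obs,
             excluded = tibble::tibble(n_start = numeric(0), pcgr = numeric(0),
                                       cooks_d = numeric(0),
                                       studentized_residual = numeric(0)),
             nonlinearity_p = nl_p)
}

new_dd_fit <- function(condition_id, fit, data, excluded, nonlinearity_p) {
  V <- vcov(fit)
  cf <- coef(fit)
  structure(list(
    condition_id = condition_id,
    mu = unname(cf[1]), alpha = unname(cf[2]),
    s2_mu = V[1, 1], s2_alpha = V[2, 2], cov_mu_alpha = V[1, 2],
    vcov = V,
    n_points = nrow(data),
    r_squared = summary(fit)$r.squared,
    nonlinearity_p = nonlinearity_p,
    excluded = excluded,
    fit = fit, data = data
  ), class = "dd_fit")
}

#' @export
print.dd_fit <- function(x, ...) {
  cat("<dd_fit>", x$condition_id, "\n")
  cat(sprintf("  mu = %.4f (SE %.4f), alpha = %.3e (SE %.2e), n = %d, R2 = %.3f\n",
              x$mu, sqrt(x$s2_mu), x$alpha, sqrt(x$s2_alpha), x$n_points,
              x$r_squared))
  if (nrow(x$excluded) > 0) {
    cat("  excluded", nrow(x$excluded), "influential point(s)\n")
  }
  invisible(x)
}

#' Exclude influential points and refit once
#'
#' A point is excluded only if it is flagged by both diagnostics: Cook's
#' distance at or beyond `cooks_threshold` (the "border" contour of standard
#' diagnostic plots) AND an externally studentized residual of magnitude at
#' least `resid_threshold`. At most `max_exclusions` points are removed, most
#' extreme Cook's distance first, and the curve is refit exactly once on the
#' survivors. Exclusion stops (with a note) if it would leave fewer than three
#' points. Excluded observations remain available to the trait pipeline.
#'
#' @param fit A [fit_curve()] result with at least 4 points.
#' @param cooks_threshold Cook's distance cut (default 0.5).
#' @param resid_threshold |studentized residual| cut (default 2).
#' @param max_exclusions Maximum removals per curve (default 2).
#' @return A refit `dd_fit` whose `excluded` tibble records the removed
#'   points; identical estimates to the input when nothing is flagged.
#' @export
exclude_influential <- function(fit, cooks_threshold = 0.5,
                                resid_threshold = 2, max_exclusions = 2) {
  stopifnot(inherits(fit, "dd_fit"))
  if (fit$n_points < 4) abort("Influence screening needs >= 4 points.")
  cd <- cooks.distance(fit$fit)
  rs <- rstudent(fit$fit)
  flagged <- which(cd >= cooks_threshold & abs(rs) >= resid_threshold)
  if (length(flagged) == 0) return(fit)
  flagged <- flagged[order(-cd[flagged])]
  n_keepable <- fit$n_points - 3L
  n_excl <- min(length(flagged), max_exclusions, n_keepable)
  if (n_excl < length(flagged)) {
    warn(paste0("Condition ", fit$condition_id, ": capped exclusions at ",
                n_excl, " of ", length(flagged), " flagged points."))
  }
  if (n_excl == 0) return(fit)
  drop <- flagged[seq_len(n_excl)]
  excluded <- dplyr::mutate(fit$data[drop, , drop = FALSE],
                            cooks_d = unname(cd[drop]),
                            studentized_residual = unname(rs[drop]))
  keep <- fit$data[-drop, , drop = FALSE]
  refit <- lm(pcgr ~ n_start, data = keep)
  new_dd_fit(fit$condition_id, refit, keep, excluded, fit$nonlinearity_p)
}

#' Carrying capacity and its delta-method variance
#'
#' `K = -mu/alpha`; its variance follows the first-order Taylor (delta
#' method) expansion of the ratio of two correlated estimators:
#' `s2(K) = (mu^2/alpha^2) (s2_mu/mu^2 - 2 cov(mu, alpha)/(mu alpha)
#' + s2_alpha/alpha^2)`. Estimates below `k_min_valid` are flagged invalid:
#' a large negative K arises from a positive alpha, i.e. positive density
#' dependence, where K is not a meaningful parameter.
#'
#' @param fit A `dd_fit` (or any list with `mu`, `alpha`, `s2_mu`,
#'   `s2_alpha`, `cov_mu_alpha`).
#' @param k_min_valid Validity threshold (default -400, in density units).
#' @return One-row tibble: `condition_id`, `K`, `s2_K`, `valid`.
#' @examples
#' f <- list(condition_id = "c", mu = 2, alpha = -0.01,
#'           s2_mu = 1e-4, s2_alpha = 1e-8, cov_mu_alpha = 0)
#' carrying_capacity(f)
#' @export
carrying_capacity <- function(fit, k_min_valid = -400) {
  if (is.null(fit$alpha) || !is.finite(fit$alpha) || fit$alpha == 0) {
    return(tibble::tibble(condition_id = fit$condition_id %||% NA_character_,
                          K = NA_real_, s2_K = NA_real_, valid = FALSE))
  }
  K <- -fit$mu / fit$alpha
  s2_K <- (fit$mu^2 / fit$alpha^2) *
    (fit$s2_mu / fit$mu^2 -
       2 * fit$cov_mu_alpha / (fit$mu * fit$alpha) +
       fit$s2_alpha / fit$alpha^2)
  tibble::tibble(condition_id = fit$condition_id %||% NA_character_,
                 K = K, s2_K = s2_K, valid = K >= k_min_valid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit demography for every condition of an experiment
#'
#' Chains [growth_observations()], [fit_curve()], [exclude_influential()] and
#' [carrying_capacity()] per condition (one pooled curve over the replicate
#' assays, matching the 15-points-per-curve design).
#'
#' @param samples Sample table (see [growth_observations()]).
#' @param min_fold_change Interval-selection threshold.
#' @param cooks_threshold,resid_threshold,max_exclusions Influence rule.
#' @param k_min_valid K validity threshold.
#' @return List with `observations`, `fits` (named list of `dd_fit`),
#'   `fit_table` (one row per condition: estimates, SEs, covariance, R^2,
#'   exclusion count, nonlinearity p), and `k_table`.
#' @export
fit_demography <- function(samples, min_fold_change = 1.5,
                           cooks_threshold = 0.5, resid_threshold = 2,
                           max_exclusions = 2, k_min_valid = -400) {
  obs <- growth_observations(samples, min_fold_change)
  fits <- purrr::map(split(obs, obs$condition_id), function(o) {
    exclude_influential(fit_curve(o), cooks_threshold, resid_threshold,
                        max_exclusions)
  })
  fit_table <- purrr::map_dfr(fits, function(f) {
    meta <- f$data[1, intersect(c("species", "strain", "temperature",
                                  "pollutant"), names(f$data))]
    dplyr::bind_cols(
      tibble::tibble(condition_id = f$condition_id), meta,
      tibble::tibble(mu = f$mu, alpha = f$alpha, s2_mu = f$s2_mu,
                     s2_alpha = f$s2_alpha, cov_mu_alpha = f$cov_mu_alpha,
                     n_points = f$n_points, n_excluded = nrow(f$excluded),
                     r_squared = f$r_squared,
                     nonlinearity_p = f$nonlinearity_p))
  })
  k_table <- purrr::map_dfr(fits, carrying_capacity, k_min_valid = k_min_valid)
  list(observations = obs, fits = fits, fit_table = fit_table,
       k_table = k_table)
}
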