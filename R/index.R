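#' Species-level trait standardization
#'
#' Pools all sample-level trait means of one species (by default restricted to
#' the time points that contribute to the density-dependence curves) and
#' records each trait's pooled mean and SD. Standardizing at the species level
#' makes the four traits unit-free and comparable before they are combined
#' into the strategy index.
#'
#' @param samples Sample table with `species`, trait `_mean` columns, and
#'   `traits_defined`.
#' @return Tibble with one row per species x trait: `species`, `trait`,
#'   `mean`, `sd`, `n`. Errors if any trait is constant (zero SD).
#' @export
fit_standardization <- function(samples) {
  s <- dplyr::filter(tibble::as_tibble(samples), .data$traits_defined)
  long <- s |>
    dplyr::select("species", "speed_mean", "linearity_mean", "size_mean",
                  "shape_mean") |>
    tidyr::pivot_longer(-"species", names_to = "trait", values_to = "value") |>
    dplyr::mutate(trait = sub("_mean$", "", .data$trait)) |>
    dplyr::filter(!is.na(.data$value))
  std <- long |>
    dplyr::group_by(.data$species, .data$trait) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  if (any(std$n < 2)) {
    abort("Each species needs >= 2 samples with defined traits.")
  }
  bad <- std$sd <= 0 | !is.finite(std$sd)
  if (any(bad)) {
    abort(paste0("Constant trait(s) in standardization pool: ",
                 paste(unique(std$trait[bad]), collapse = ", ")))
  }
  std
}

#' Survival-strategy index per sample
#'
#' Combines the four species-standardized traits with equal weight:
#' `index = z(speed) + z(linearity) - z(size) + z(shape)`. Low values indicate
#' a sit-and-wait phenotype (large, slow, tortuous), high values a flee
#' phenotype (small, fast, straight, elongated).
#'
#' Two index modes are available. `"moments"` (default) computes the mean
#' index from the sample's trait means and the index variance as the sum of
#' the species-scaled within-sample trait variances (the index variance when
#' traits are independent within a sample, since all weights are +-1).
#' `"per_trajectory"` expects per-trajectory trait values and computes the
#' index per trajectory first, then its mean and variance across
#' trajectories; use [per_trajectory_index()] for that route.
#'
#' @param samples Sample table with trait `_mean` and `_var` columns.
#' @param standardization Output of [fit_standardization()].
#' @return `samples` with `mean_index` and `variance_index` columns appended
#'   (`NA` where any trait is missing).
#' @export
compute_index <- function(samples, standardization) {
  s <- tibble::as_tibble(samples)
  wide <- standardization |>
    tidyr::pivot_wider(id_cols = "species", names_from = "trait",
                       values_from = c("mean", "sd"))
  s <- dplyr::left_join(s, wide, by = "species")
  z <- function(v, m, sd) (v - m) / sd
  s |>
    dplyr::mutate(
      mean_index =
        z(.data$speed_mean, .data$mean_speed, .data$sd_speed) +
        z(.data$linearity_mean, .data$mean_linearity, .data$sd_linearity) -
        z(.data$size_mean, .data$mean_size, .data$sd_size) +
        z(.data$shape_mean, .data$mean_shape, .data$sd_shape),
      variance_index =
        .data$speed_var / .data$sd_speed^2 +
        .data$linearity_var / .data$sd_linearity^2 +
        .data$size_var / .data$sd_size^2 +
        .data$shape_var / .data$sd_shape^2
    ) |>
    dplyr::select(-dplyr::starts_with("mean_speed"),
                  -dplyr::starts_with("mean_linearity"),
                  -dplyr::starts_with("mean_size"),
                  -dplyr::starts_with("mean_shape"),
                  -dplyr::starts_with("sd_"))
}

#' Per-trajectory strategy index
#'
#' The alternative index mode: standardizes each trajectory's traits with the
#' species pool statistics, forms the index per trajectory, and summarizes its
#' mean and unbiased variance per sample.
#'
#' @param trajectories Tibble with `sample_id`, `species`, and per-trajectory
#'   `speed`, `linearity`, `size`, `shape`.
#' @param standardization Output of [fit_standardization()].
#' @return One row per sample: `sample_id`, `mean_index`, `variance_index`,
#'   `n_trajectories`.
#' @export
per_trajectory_index <- function(trajectories, standardization) {
  tr <- tibble::as_tibble(trajectories)
  wide <- standardization |>
    tidyr::pivot_wider(id_cols = "species", names_from = "trait",
                       values_from = c("mean", "sd"))
  tr <- dplyr::left_join(tr, wide, by = "species")
  tr |>
    dplyr::mutate(index =
      (.data$speed - .data$mean_speed) / .data$sd_speed +
      (.data$linearity - .data$mean_linearity) / .data$sd_linearity -
      (.data$size - .data$mean_size) / .data$sd_size +
      (.data$shape - .data$mean_shape) / .data$sd_shape) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(mean_index = mean(.data$index),
                     variance_index = if (dplyr::n() >= 2) var(.data$index) else NA_real_,
                     n_trajectories = dplyr::n(), .groups = "drop")
}

#' Index response over the growth interval
#'
#' For each microcosm, the change in mean and variance of the strategy index
#' between the start and end of the *same* time interval used to compute its
#' pcgr: `delta = end - start`, componentwise. Swapping start and end negates
#' `delta_mean` exactly.
#'
#' @param indexed_samples Output of [compute_index()] (needs `microcosm_id`,
#'   `time_point`, `mean_index`, `variance_index`).
#' @param intervals Interval assignment per microcosm, e.g. the observations
#'   tibble from [growth_observations()] (needs `microcosm_id`,
#'   `start_time_point`, `end_time_point`, `interval_label`).
#' @return One row per microcosm with design columns, `interval_label`,
#'   `delta_mean`, `delta_variance` (`NA` when either endpoint lacks traits).
#' @export
index_response <- function(indexed_samples, intervals) {
  s <- tibble::as_tibble(indexed_samples)
  iv <- dplyr::distinct(tibble::as_tibble(intervals), .data$microcosm_id,
                        .data$start_time_point, .data$end_time_point,
                        .data$interval_label)
  start <- s |>
    dplyr::select("microcosm_id", "time_point", start_mean = "mean_index",
                  start_var = "variance_index")
  end <- s |>
    dplyr::select("microcosm_id", "time_point", end_mean = "mean_index",
                  end_var = "variance_index")
  meta_cols <- intersect(c("condition_id", "assay_id", "species", "strain",
                           "temperature", "pollutant", "replicate", "dilution"),
                         names(s))
  meta <- dplyr::distinct(s[, c("microcosm_id", meta_cols)])
  iv |>
    dplyr::inner_join(start, by = c("microcosm_id",
                                    start_time_point = "time_point")) |>
    dplyr::inner_join(end, by = c("microcosm_id",
                                  end_time_point = "time_point")) |>
    dplyr::mutate(delta_mean = .data$end_mean - .data$start_mean,
                  delta_variance = .data$end_var - .data$start_var) |>
    dplyr::left_join(meta, by = "microcosm_id") |>
    dplyr::select(dplyr::all_of(c("microcosm_id", meta_cols, "interval_label",
                                  "delta_mean", "delta_variance")))
}
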