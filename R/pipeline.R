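#' Run the full analysis pipeline on a simulated experiment
#'
#' Chains every stage: simulate the experiment (fast path), build growth
#' observations and fit the density-dependence curves with influence
#' screening, estimate K with its delta-method variance, standardize traits
#' and compute the strategy index and its responses over the growth
#' intervals, run the factorial ANOVA tables, assemble the condition-level
#' records, and run the AICc linkage selection.
#'
#' @param config A [design_config()].
#' @param profiles Strain profiles (default [default_strain_profiles()]).
#' @param seed Integer seed for all randomness.
#' @param min_fold_change,cooks_threshold,resid_threshold,max_exclusions,k_min_valid
#'   Analysis-rule parameters (see [fit_demography()]).
#' @return List with `samples`, `truth`, `demography` (observations, fits,
#'   tables), `standardization`, `responses`, `anova` (pcgr, delta-mean and
#'   delta-variance tables), `records` and `linkage`, plus a `manifest`
#'   recording seed and counts.
#' @examples
#' \donttest{
#' cfg <- design_config(rng_seed = 1)
#' res <- run_pipeline(cfg)
#' glance(res$linkage)
#' }
#' @export
run_pipeline <- function(config = design_config(),
                         profiles = default_strain_profiles(config),
                         seed = config$rng_seed,
                         min_fold_change = 1.5,
                         cooks_threshold = 0.5, resid_threshold = 2,
                         max_exclusions = 2, k_min_valid = -400) {
  sim <- simulate_experiment(config, profiles, seed = seed)
  dem <- fit_demography(sim$samples, min_fold_change, cooks_threshold,
                        resid_threshold, max_exclusions, k_min_valid)
  # only time points contributing to the curves feed the trait analysis
  contributing <- dem$observations |>
    dplyr::select("microcosm_id", "start_time_point", "end_time_point") |>
    tidyr::pivot_longer(-"microcosm_id", values_to = "time_point") |>
    dplyr::distinct(.data$microcosm_id, .data$time_point)
  pool <- dplyr::semi_join(sim$samples, contributing,
                           by = c("microcosm_id", "time_point"))
  std <- fit_standardization(pool)
  indexed <- compute_index(pool, std)
  responses <- index_response(indexed, dem$observations)
  anova_tables <- list(
    pcgr = demography_anova(dem$observations),
    delta_mean = index_anova(responses, "delta_mean"),
    delta_variance = index_anova(responses, "delta_variance"))
  records <- build_condition_records(dem$fit_table, dem$k_table, responses)
  linkage <- fit_linkage(records)
  counts <- design_counts(config)
  list(samples = sim$samples, truth = sim$truth, demography = dem,
       standardization = std, indexed_samples = indexed,
       responses = responses, anova = anova_tables, records = records,
       linkage = linkage,
       manifest = list(seed = seed, counts = counts,
                       package_version = as.character(utils::packageVersion("microcosmr")),
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}
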