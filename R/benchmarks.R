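#' Simulate one density-dependence curve for a single condition
#'
#' Generates the replicate dilution assays of one condition (default: 3
#' replicates x 5 dilutions x 3 time points) through the full observation
#' model — logistic growth, volumetric counting noise, interval selection —
#' and returns the growth observations ready for [fit_curve()].
#'
#' @param profile A [strain_profile()].
#' @param temperature,pollutant Treatment values (default: profile reference).
#' @param dilution_fractions,replicates,time_points Assay layout.
#' @param sample_volume_ml Counted volume (mL).
#' @param min_fold_change Interval-selection threshold.
#' @return Growth observations tibble (one row per microcosm) with the
#'   generative `mu` and `alpha` attached as attributes `truth`.
#' @export
simulate_condition_curve <- function(profile, temperature = NULL,
                                     pollutant = NULL,
                                     dilution_fractions = c(0.20, 0.35, 0.50,
                                                            0.65, 0.80),
                                     replicates = 3, time_points = 3,
                                     sample_volume_ml = 0.81,
                                     min_fold_change = 1.5) {
  if (is.null(temperature)) temperature <- profile$reference[["temperature"]]
  if (is.null(pollutant)) pollutant <- profile$reference[["pollutant"]]
  par <- condition_parameters(profile, temperature, pollutant)
  source_density <- profile$source_fraction * (-profile$base_mu / profile$base_alpha)
  tps <- (seq_len(time_points) - 1L)
  times <- tps * profile$sample_spacing_days
  grid <- tidyr::expand_grid(replicate = seq_len(replicates),
                             dilution = dilution_fractions)
  rows <- purrr::pmap_dfr(grid, function(replicate, dilution) {
    n0 <- dilution * source_density
    true_d <- grow_population(par$mu, par$alpha, n0, times)
    tibble::tibble(
      microcosm_id = paste0("R", replicate, "_D", dilution * 100),
      condition_id = "bench", assay_id = paste0("R", replicate),
      species = profile$species, strain = profile$strain_id,
      temperature = temperature, pollutant = pollutant,
      replicate = replicate, dilution = dilution,
      time_point = tps, time_days = times,
      density = observe_density(true_d, sample_volume_ml,
                                profile$overdispersion))
  })
  obs <- growth_observations(rows, min_fold_change)
  attr(obs, "truth") <- c(mu = par$mu, alpha = par$alpha)
  obs
}

#' Parameter-recovery benchmark for the pcgr regression
#'
#' Simulates `n_assays` independent density-dependence curves across the
#' default design's conditions (cycling over species, strains and
#' treatments), fits each with [fit_curve()], and measures relative errors of
#' mu and alpha and whether the 95% CI for mu covers the truth. Influence
#' screening is off by default: it exists to catch failed assays, and on
#' clean data it trims legitimate extreme points and distorts the estimator
#' being benchmarked.
#'
#' @param n_assays Number of curves.
#' @param config A [design_config()] providing the condition grid.
#' @param profiles Strain profiles.
#' @param screen_influence Also apply [exclude_influential()] before scoring.
#' @param seed Integer seed.
#' @return Tibble with one row per curve: truth, estimates, relative errors,
#'   `mu_covered`. Summarize with `median()` / `mean()`.
#' @export
benchmark_parameter_recovery <- function(n_assays = 200,
                                         config = design_config(),
                                         profiles = default_strain_profiles(config),
                                         screen_influence = FALSE,
                                         seed = 1) {
  set.seed(seed)
  conditions <- enumerate_design(config) |>
    dplyr::distinct(.data$species, .data$strain, .data$temperature,
                    .data$pollutant)
  purrr::map_dfr(seq_len(n_assays), function(i) {
    cond <- conditions[(i - 1L) %% nrow(conditions) + 1L, ]
    prof <- profiles[[paste(cond$species, cond$strain, sep = "_")]]
    obs <- simulate_condition_curve(prof, cond$temperature, cond$pollutant,
                                    config$dilution_fractions,
                                    config$replicates, config$time_points,
                                    config$sample_volume_ul / 1000)
    truth <- attr(obs, "truth")
    fit <- fit_curve(obs)
    if (screen_influence) fit <- exclude_influential(fit)
    ci <- confint(fit$fit)[1, ]
    tibble::tibble(
      assay = i, species = cond$species,
      mu_true = truth[["mu"]], alpha_true = truth[["alpha"]],
      mu_hat = fit$mu, alpha_hat = fit$alpha,
      mu_rel_err = abs(fit$mu - truth[["mu"]]) / abs(truth[["mu"]]),
      alpha_rel_err = abs(fit$alpha - truth[["alpha"]]) / abs(truth[["alpha"]]),
      mu_covered = ci[1] <= truth[["mu"]] && truth[["mu"]] <= ci[2])
  })
}

#' Delta-method versus Monte-Carlo variance of K
#'
#' Compares the first-order Taylor variance of `K = -mu/alpha`
#' ([carrying_capacity()]) with the sample variance of the ratio over
#' bivariate-normal draws of (mu, alpha) with the stated moments.
#'
#' @param mu,alpha Estimator means.
#' @param s2_mu,s2_alpha,cov_mu_alpha Estimator (co)variances.
#' @param n_draws Monte-Carlo size.
#' @param seed Integer seed.
#' @return One-row tibble: `s2_delta`, `s2_mc`, `rel_err`, and the CVs of mu
#'   and alpha.
#' @export
benchmark_k_variance <- function(mu, alpha, s2_mu, s2_alpha,
                                 cov_mu_alpha = 0, n_draws = 1e6, seed = 1) {
  set.seed(seed)
  fit <- list(condition_id = "mc", mu = mu, alpha = alpha, s2_mu = s2_mu,
              s2_alpha = s2_alpha, cov_mu_alpha = cov_mu_alpha)
  s2_delta <- carrying_capacity(fit)$s2_K
  S <- matrix(c(s2_mu, cov_mu_alpha, cov_mu_alpha, s2_alpha), 2)
  L <- chol(S)
  zz <- matrix(rnorm(2 * n_draws), ncol = 2) %*% L
  mus <- mu + zz[, 1]; alphas <- alpha + zz[, 2]
  s2_mc <- var(-mus / alphas)
  tibble::tibble(s2_delta = s2_delta, s2_mc = s2_mc,
                 rel_err = abs(s2_delta - s2_mc) / s2_mc,
                 cv_mu = sqrt(s2_mu) / abs(mu),
                 cv_alpha = sqrt(s2_alpha) / abs(alpha))
}

#' Tracking-fidelity benchmark on rendered stacks
#'
#' For each seed, plants `n_cells` correlated-random-walk swimmers, renders
#' the burst, runs the full tracking chain, and matches QC-passing recovered
#' tracks to ground-truth walkers by mean position distance over shared
#' frames. Reports the fraction of planted tracks recovered and the relative
#' error of the recovered mean speed.
#'
#' @param n_seeds Number of independent stacks.
#' @param n_cells Planted walkers per stack.
#' @param config A [design_config()] (frames, frame rate, arena).
#' @param profile Strain profile used for trait draws.
#' @param detection,linking,qc Tracking parameters.
#' @param noise_sd Rendering noise.
#' @param seed Base seed.
#' @return Tibble with one row per stack: `n_planted`, `n_kept`,
#'   `n_matched`, `recovery`, `speed_true`, `speed_est`, `speed_rel_err`.
#' @export
benchmark_tracking <- function(n_seeds = 10, n_cells = 20,
                               config = design_config(),
                               profile = NULL,
                               detection = detection_params(),
                               linking = linking_params(),
                               qc = qc_params(),
                               noise_sd = 4, seed = 1) {
  if (is.null(profile)) profile <- default_strain_profiles(config)[[1]]
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    set.seed(seed + s - 1L)
    sim <- simulate_sample_stack(n_cells, profile, config, render = TRUE,
                                 noise_sd = noise_sd)
    res <- track_stack(sim$stack, config$frame_rate,
                       config$sample_volume_ul / 1000,
                       detection, linking, qc)
    kept_ids <- res$kept$track_id
    matched <- match_tracks(res$trajectories[res$trajectories$track_id %in%
                                               kept_ids, ], sim$tracks)
    tibble::tibble(
      stack = s, n_planted = n_cells, n_kept = length(kept_ids),
      n_matched = matched,
      recovery = matched / n_cells,
      speed_true = mean(sim$individuals$speed),
      speed_est = mean(res$kept$speed),
      speed_rel_err = abs(mean(res$kept$speed) -
                            mean(sim$individuals$speed)) /
        mean(sim$individuals$speed))
  })
}

# number of distinct ground-truth walkers matched by recovered tracks
# (nearest mean distance over shared frames, within 10 px)
match_tracks <- function(recovered, truth) {
  if (nrow(recovered) == 0) return(0L)
  rec <- split(recovered, recovered$track_id)
  hits <- integer(0)
  for (r in rec) {
    key <- paste(r$frame)
    best_id <- NA_integer_; best_d <- Inf
    for (tid in unique(truth$track_id)) {
      tt <- truth[truth$track_id == tid, ]
      common <- intersect(r$frame, tt$frame)
      if (length(common) == 0) next
      d <- mean(sqrt((r$x[match(common, r$frame)] - tt$x[match(common, tt$frame)])^2 +
                     (r$y[match(common, r$frame)] - tt$y[match(common, tt$frame)])^2))
      if (d < best_d) { best_d <- d; best_id <- tid }
    }
    if (is.finite(best_d) && best_d <= 10) hits <- c(hits, best_id)
  }
  length(unique(hits))
}

#' Generate condition-level records under a known linkage truth
#'
#' Builds a synthetic 54-record dataset (2 species x 3 strains x 9
#' treatments by default) in which the standardized demographic parameters
#' are linked to the averaged index responses by a chosen generating model:
#' `"null"` (no association), `"mean_common"` (one common delta-mean slope),
#' `"mean_strainT"` (common slope + T-strain intercept offsets, the Mean 4
#' structure), or `"mean_strain"` (slope + intercept per strain). mu gets the
#' slope with positive sign and alpha with negative sign; K follows mu.
#'
#' @param truth Generating structure (see above).
#' @param slope Magnitude of the delta-mean slope (standardized units).
#' @param intercept_sd SD of strain intercept offsets where applicable.
#' @param sigma Residual SD of the demographic responses.
#' @param n_per_species Conditions per species (default 27).
#' @param seed Integer seed.
#' @return A records tibble compatible with [fit_linkage()].
#' @export
generate_condition_records <- function(truth = c("mean_strainT", "null",
                                                 "mean_common", "mean_strain"),
                                       slope = 1, intercept_sd = 1,
                                       sigma = 0.3, n_per_species = 27,
                                       seed = 1) {
  truth <- match.arg(truth)
  set.seed(seed)
  species <- c("C_sp", "T_sp")
  rec <- tidyr::expand_grid(species = species,
                            strain = c("S1", "S2", "S3"),
                            cell = seq_len(ceiling(n_per_species / 3))) |>
    dplyr::mutate(condition_id = paste(.data$species, .data$strain,
                                       .data$cell, sep = "_"))
  n <- nrow(rec)
  rec$delta_mean <- rnorm(n, 0, 1)
  rec$delta_variance <- rnorm(n, 0, 1)
  strain_key <- paste(rec$species, rec$strain, sep = "_")
  intercepts <- switch(truth,
    null = rep(0, n),
    mean_common = rep(0, n),
    mean_strainT = {
      off <- setNames(rnorm(3, 0, intercept_sd), c("S1", "S2", "S3"))
      ifelse(rec$species == "T_sp", off[rec$strain], 0)
    },
    mean_strain = {
      off <- setNames(rnorm(6, 0, intercept_sd), unique(strain_key))
      off[strain_key]
    })
  b <- if (truth == "null") 0 else slope
  rec$mu_z <- intercepts + b * rec$delta_mean + rnorm(n, 0, sigma)
  rec$alpha_z <- intercepts - b * rec$delta_mean + rnorm(n, 0, sigma)
  rec$K_z <- intercepts + b * rec$delta_mean + rnorm(n, 0, sigma)
  rec$k_valid <- TRUE
  rec$n_responses <- 1L
  rec$usable <- TRUE
  rec
}

#' Model-recovery benchmark for the linkage selection
#'
#' Repeatedly generates records under a known truth and records which variant
#' wins the AICc selection and the sign of the fitted delta-mean slopes for
#' mu and alpha.
#'
#' @param n_seeds Number of datasets.
#' @param truth Passed to [generate_condition_records()].
#' @param slope,intercept_sd,sigma Generative magnitudes.
#' @param seed Base seed.
#' @return Tibble per seed: best model for mu and alpha, whether the best mu
#'   model matches the generating class, and the fitted slope signs.
#' @export
benchmark_model_recovery <- function(n_seeds = 200, truth = "mean_strainT",
                                     slope = 1, intercept_sd = 1.5,
                                     sigma = 0.3, seed = 1) {
  expected <- switch(truth,
    null = "Null", mean_common = "Mean 1",
    mean_strainT = "Mean 4", mean_strain = "Mean 2")
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    rec <- generate_condition_records(truth, slope, intercept_sd, sigma,
                                      seed = seed + s - 1L)
    sel <- fit_linkage(rec, responses = c("mu", "alpha"),
                       species_c = "C_sp", species_t = "T_sp")
    best <- glance(sel)
    best_mu <- best$best_model[best$response == "mu"]
    best_alpha <- best$best_model[best$response == "alpha"]
    tibble::tibble(
      seed = s, best_mu = best_mu, best_alpha = best_alpha,
      recovered = best_mu == expected,
      mu_slope = linkage_slope(sel, "mu"),
      alpha_slope = linkage_slope(sel, "alpha"))
  })
}
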