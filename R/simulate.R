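#' Simulate a full microcosm experiment (density + trait summaries)
#'
#' Runs the generative model for every microcosm and time point of a design:
#' deterministic logistic growth at the condition's (mu, alpha), volumetric
#' counting noise on densities ([observe_density()]), and per-cell trait draws
#' whose means respond to treatment and crowding. This is the fast path used
#' for statistical work: it yields exactly the sample-level table that image
#' tracking would produce, without rendering frames. Use
#' [simulate_sample_stack()] to realize individual frames for a chosen sample.
#'
#' The source culture of each strain sits at `source_fraction` of its baseline
#' K (log phase) and is shared across treatments; the dilution series then
#' sets the starting densities. Time points are `0, spacing, 2 spacing, ...`
#' days with the species' `sample_spacing_days`.
#'
#' @param config A [design_config()].
#' @param profiles Named list from [default_strain_profiles()] (or hand-built),
#'   keyed `"<species>_<strain>"`.
#' @param seed Optional integer seed (defaults to `config$rng_seed`).
#' @param trait_sample_cap Maximum number of trajectories summarized per
#'   sample; emulates the finite number of QC-passing tracks in a burst.
#' @return List with `samples` (one row per microcosm x time point:
#'   design columns, `time_days`, `true_density`, `density`, trait
#'   means/variances, `n_trajectories`), `truth` (per-condition generative
#'   `mu`, `alpha`, `K`), and `design` (the enumerated microcosms).
#' @examples
#' cfg <- design_config(species = "sp1", strains_per_species = 1,
#'                      temperatures = 22, pollutant_levels = 0,
#'                      replicates = 1, rng_seed = 1)
#' sim <- simulate_experiment(cfg)
#' nrow(sim$samples)
#' @export
simulate_experiment <- function(config,
                                profiles = default_strain_profiles(config),
                                seed = config$rng_seed,
                                trait_sample_cap = 200L) {
  stopifnot(inherits(config, "design_config"))
  if (!is.null(seed)) set.seed(seed)
  design <- enumerate_design(config)
  vol_ml <- config$sample_volume_ul / 1000
  tps <- seq_len(config$time_points) - 1L

  truth <- design |>
    dplyr::distinct(.data$condition_id, .data$species, .data$strain,
                    .data$temperature, .data$pollutant) |>
    dplyr::rowwise() |>
    dplyr::mutate(condition_parameters(
      profiles[[paste(.data$species, .data$strain, sep = "_")]],
      .data$temperature, .data$pollutant)) |>
    dplyr::ungroup()

  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    prof <- profiles[[paste(d$species, d$strain, sep = "_")]]
    par <- truth[truth$condition_id == d$condition_id, ]
    source_density <- prof$source_fraction * (-prof$base_mu / prof$base_alpha)
    n0 <- d$dilution * source_density
    times <- tps * prof$sample_spacing_days
    true_d <- grow_population(par$mu, par$alpha, n0, times)
    obs_d <- observe_density(true_d, vol_ml, prof$overdispersion)
    Kc <- -par$mu / par$alpha
    crowding <- (true_d - n0) / Kc
    tr <- purrr::map(seq_along(tps), function(ti) {
      n_tr <- min(round(obs_d[ti] * vol_ml), trait_sample_cap)
      if (n_tr < 1) {
        return(tibble::tibble(
          n_trajectories = 0L,
          speed_mean = NA_real_, speed_var = NA_real_,
          linearity_mean = NA_real_, linearity_var = NA_real_,
          size_mean = NA_real_, size_var = NA_real_,
          shape_mean = NA_real_, shape_var = NA_real_,
          traits_defined = FALSE))
      }
      ind <- draw_individual_traits(n_tr, prof, d$temperature, d$pollutant,
                                    crowding[ti])
      v <- function(x) if (n_tr >= 2) var(x) else NA_real_
      tibble::tibble(
        n_trajectories = as.integer(n_tr),
        speed_mean = mean(ind$speed), speed_var = v(ind$speed),
        linearity_mean = mean(ind$linearity), linearity_var = v(ind$linearity),
        size_mean = mean(ind$size), size_var = v(ind$size),
        shape_mean = mean(ind$shape), shape_var = v(ind$shape),
        traits_defined = n_tr >= 2)
    })
    rows[[i]] <- dplyr::bind_cols(
      d[rep(1, length(tps)), ],
      tibble::tibble(
        time_point = tps,
        time_days = times,
        sample_id = paste0(d$microcosm_id, "_t", tps),
        true_density = true_d,
        density = obs_d),
      dplyr::bind_rows(tr))
  }
  list(samples = dplyr::bind_rows(rows), truth = truth, design = design)
}

#' Realize one sample as walkers and (optionally) rendered frames
#'
#' Draws per-cell traits for the requested number of cells, simulates their
#' correlated random walks over a burst, and optionally rasterizes the frames,
#' giving the tracking stage a ground-truth benchmark.
#'
#' @param n_cells Number of cells in the arena.
#' @param profile A [strain_profile()].
#' @param config A [design_config()] (frames, frame rate, arena).
#' @param temperature,pollutant Treatment values.
#' @param crowding Relative density change passed to the trait model.
#' @param render If `TRUE`, also return the rendered stack.
#' @param noise_sd Background noise SD for rendering.
#' @return List with `individuals` (drawn traits), `tracks` (ground truth)
#'   and, when `render = TRUE`, `stack`.
#' @export
simulate_sample_stack <- function(n_cells, profile, config,
                                  temperature = NULL, pollutant = NULL,
                                  crowding = 0, render = TRUE, noise_sd = 4) {
  stopifnot(inherits(config, "design_config"))
  if (is.null(temperature)) temperature <- profile$reference[["temperature"]]
  if (is.null(pollutant)) pollutant <- profile$reference[["pollutant"]]
  ind <- draw_individual_traits(n_cells, profile, temperature, pollutant, crowding)
  tracks <- simulate_individuals(ind, config$frames_per_sample,
                                 config$frame_rate, config$arena)
  out <- list(individuals = ind, tracks = tracks)
  if (render) out$stack <- render_frames(tracks, config$arena, noise_sd)
  out
}
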