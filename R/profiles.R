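#' Strain-level generative profile
#'
#' A strain profile fixes the generative truth for one clonal strain: its
#' intrinsic growth rate and conspecific interaction coefficient, how both
#' respond (linearly, on centred covariates) to temperature and pollutant, the
#' baseline movement/morphology trait distribution among cells, and the assay
#' schedule used for that species. Per-cell trait variation (`trait_sd`) is the
#' plasticity among genetically identical cells; traits are drawn once per cell
#' and held fixed within a burst.
#'
#' @param strain_id Strain label.
#' @param species Species label the strain belongs to.
#' @param base_mu Intrinsic per-capita growth rate at reference conditions
#'   (per day).
#' @param base_alpha Conspecific interaction coefficient (per day per cell/mL);
#'   negative means self-limitation.
#' @param mu_response Named numeric `c(temperature=, pollutant=)`: linear
#'   effects on mu per degree C and per ug/mL, on centred covariates.
#' @param alpha_response Same structure for alpha.
#' @param interaction_coef Temperature x pollutant product term on mu
#'   (default 0: no interactive effect of the two drivers).
#' @param trait_means Named numeric baseline for `speed` (px/s), `linearity`
#'   (net/gross, in (0, 1]), `size` (px^2) and `shape` (aspect ratio >= 1).
#' @param trait_responses Numeric matrix, rows = the four traits, columns
#'   `temperature` and `pollutant`: linear treatment effects on trait means.
#' @param trait_sd Named numeric per-cell SD for each trait (>= 0).
#' @param trait_crowding Named numeric: shift of each trait mean per unit
#'   change in density relative to K since the assay start. Positive speed /
#'   linearity / shape and negative size coefficients move growing populations
#'   towards a flee phenotype.
#' @param source_fraction Source-culture density as a fraction of K at assay
#'   start (log-phase culture).
#' @param sample_spacing_days Time between consecutive imaging time points
#'   (days).
#' @param overdispersion Extra relative SD of density counts beyond Poisson
#'   (gamma-Poisson mixing; 0 = pure Poisson).
#' @param reference Named numeric `c(temperature=, pollutant=)` used to centre
#'   covariates.
#'
#' @return An object of class `strain_profile`.
#' @examples
#' strain_profile("S1", "C_striatum", base_mu = 1.2, base_alpha = -1.2e-4)
#' @export
strain_profile <- function(strain_id,
                           species,
                           base_mu,
                           base_alpha,
                           mu_response = c(temperature = 0, pollutant = 0),
                           alpha_response = c(temperature = 0, pollutant = 0),
                           interaction_coef = 0,
                           trait_means = c(speed = 60, linearity = 0.8,
                                           size = 400, shape = 2.5),
                           trait_responses = NULL,
                           trait_sd = c(speed = 12, linearity = 0.08,
                                        size = 60, shape = 0.3),
                           trait_crowding = c(speed = 10, linearity = 0.05,
                                              size = -40, shape = 0.2),
                           source_fraction = 0.6,
                           sample_spacing_days = 0.2,
                           overdispersion = 0.02,
                           reference = c(temperature = 22, pollutant = 10)) {
  traits <- c("speed", "linearity", "size", "shape")
  if (is.null(trait_responses)) {
    trait_responses <- matrix(0, nrow = 4, ncol = 2,
                              dimnames = list(traits, c("temperature", "pollutant")))
  }
  p <- structure(list(
    strain_id = as.character(strain_id),
    species = as.character(species),
    base_mu = as.numeric(base_mu),
    base_alpha = as.numeric(base_alpha),
    mu_response = mu_response[c("temperature", "pollutant")],
    alpha_response = alpha_response[c("temperature", "pollutant")],
    interaction_coef = as.numeric(interaction_coef),
    trait_means = trait_means[traits],
    trait_responses = trait_responses[traits, c("temperature", "pollutant"), drop = FALSE],
    trait_sd = trait_sd[traits],
    trait_crowding = trait_crowding[traits],
    source_fraction = as.numeric(source_fraction),
    sample_spacing_days = as.numeric(sample_spacing_days),
    overdispersion = as.numeric(overdispersion),
    reference = reference[c("temperature", "pollutant")]
  ), class = "strain_profile")
  validate_strain_profile(p)
  p
}

validate_strain_profile <- function(p) {
  if (any(p$trait_sd < 0)) abort("`trait_sd` entries must be >= 0.")
  lin <- p$trait_means[["linearity"]]
  if (lin <= 0 || lin > 1) abort("`linearity` mean must lie in (0, 1].")
  if (p$trait_means[["shape"]] < 1) abort("`shape` mean must be >= 1.")
  if (p$trait_means[["size"]] <= 0) abort("`size` mean must be positive.")
  if (p$source_fraction <= 0 || p$source_fraction > 1) {
    abort("`source_fraction` must lie in (0, 1].")
  }
  if (p$sample_spacing_days <= 0) abort("`sample_spacing_days` must be positive.")
  if (p$overdispersion < 0) abort("`overdispersion` must be >= 0.")
  invisible(p)
}

#' @export
print.strain_profile <- function(x, ...) {
  cat("<strain_profile>", x$species, "/", x$strain_id, "\n")
  cat(sprintf("  mu = %.3g /day, alpha = %.3g /day/(cells/mL), K = %.4g cells/mL\n",
              x$base_mu, x$base_alpha, -x$base_mu / x$base_alpha))
  cat("  traits:", paste(sprintf("%s=%.3g", names(x$trait_means), x$trait_means),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Default strain profiles for a design
#'
#' Builds one profile per (species, strain). The first species is a
#' Colpidium-like large slow ciliate (mu 1.2/day, K 1e4 cells/mL, sampled every
#' 0.2 day), the second a Tetrahymena-like small fast one (mu 2.0/day, K 5e4
#' cells/mL, sampled every 0.1 day); further species recycle these templates.
#' Strains within a species differ in their baseline mu, alpha and trait means;
#' temperature raises and atrazine depresses growth; trait means respond weakly
#' to both drivers and to crowding. The temperature x pollutant interaction is
#' zero by default, so the generative mu surface is exactly additive.
#'
#' @param config A [design_config()].
#' @return A named list of [strain_profile()] objects, keyed
#'   `"<species>_<strain>"`.
#' @export
default_strain_profiles <- function(config) {
  stopifnot(inherits(config, "design_config"))
  traits <- c("speed", "linearity", "size", "shape")
  templates <- list(
    list(base_mu = 1.2, K = 1e4,
         mu_response = c(temperature = 0.05, pollutant = -0.012),
         alpha_rel_response = c(temperature = 0.02, pollutant = -0.005),
         trait_means = c(speed = 60, linearity = 0.80, size = 400, shape = 2.5),
         trait_sd = c(speed = 12, linearity = 0.08, size = 60, shape = 0.3),
         trait_responses = rbind(speed = c(2, -1), linearity = c(0.01, -0.005),
                                 size = c(-5, 3), shape = c(0.02, -0.01)),
         trait_crowding = c(speed = 10, linearity = 0.05, size = -40, shape = 0.2),
         spacing = 0.2),
    list(base_mu = 2.0, K = 5e4,
         mu_response = c(temperature = 0.08, pollutant = -0.02),
         alpha_rel_response = c(temperature = 0.02, pollutant = -0.005),
         trait_means = c(speed = 90, linearity = 0.70, size = 150, shape = 1.6),
         trait_sd = c(speed = 18, linearity = 0.10, size = 25, shape = 0.2),
         trait_responses = rbind(speed = c(3, -1.5), linearity = c(0.01, -0.005),
                                 size = c(-2, 1), shape = c(0.01, -0.005)),
         trait_crowding = c(speed = 15, linearity = 0.05, size = -15, shape = 0.1),
         spacing = 0.1)
  )
  mu_off <- c(-0.1, 0, 0.1)        # strain offsets on mu (per day)
  alpha_mult <- c(0.9, 1, 1.1)     # strain multipliers on alpha
  speed_off <- c(-5, 0, 5)
  size_off_frac <- c(-0.05, 0, 0.05)
  profiles <- list()
  for (si in seq_along(config$species)) {
    tpl <- templates[[(si - 1L) %% length(templates) + 1L]]
    for (gi in seq_len(config$strains_per_species)) {
      k <- (gi - 1L) %% 3L + 1L
      tm <- tpl$trait_means
      tm[["speed"]] <- tm[["speed"]] + speed_off[k]
      tm[["size"]] <- tm[["size"]] * (1 + size_off_frac[k])
      mu <- tpl$base_mu + mu_off[k]
      alpha <- -tpl$base_mu / tpl$K * alpha_mult[k]
      tr <- tpl$trait_responses
      dimnames(tr) <- list(traits, c("temperature", "pollutant"))
      id <- paste0("S", gi)
      profiles[[paste(config$species[si], id, sep = "_")]] <- strain_profile(
        strain_id = id,
        species = config$species[si],
        base_mu = mu,
        base_alpha = alpha,
        mu_response = tpl$mu_response,
        alpha_response = abs(alpha) * tpl$alpha_rel_response,
        trait_means = tm,
        trait_responses = tr,
        trait_sd = tpl$trait_sd,
        trait_crowding = tpl$trait_crowding,
        sample_spacing_days = tpl$spacing,
        reference = c(temperature = mean(config$temperatures),
                      pollutant = mean(config$pollutant_levels))
      )
    }
  }
  profiles
}

#' Generative demographic parameters of a strain under a treatment
#'
#' Evaluates the linear (centred) treatment model of a [strain_profile()]:
#' `mu = base_mu + b_T (T - T_ref) + b_A (A - A_ref) + c (T - T_ref)(A - A_ref)`
#' and the analogous surface for alpha (without product term).
#'
#' @param profile A [strain_profile()].
#' @param temperature,pollutant Treatment values.
#' @return A one-row tibble with `mu`, `alpha` and implied `K = -mu/alpha`.
#' @export
condition_parameters <- function(profile, temperature, pollutant) {
  stopifnot(inherits(profile, "strain_profile"))
  dT <- temperature - profile$reference[["temperature"]]
  dA <- pollutant - profile$reference[["pollutant"]]
  mu <- profile$base_mu + profile$mu_response[["temperature"]] * dT +
    profile$mu_response[["pollutant"]] * dA + profile$interaction_coef * dT * dA
  alpha <- profile$base_alpha + profile$alpha_response[["temperature"]] * dT +
    profile$alpha_response[["pollutant"]] * dA
  tibble::tibble(mu = mu, alpha = alpha,
                 K = ifelse(alpha != 0, -mu / alpha, NA_real_))
}

#' Generative trait means of a strain under a treatment and crowding level
#'
#' @inheritParams condition_parameters
#' @param crowding Change in density since assay start, relative to K.
#' @return Named numeric of the four trait means (linearity clipped to
#'   (0, 1], shape to >= 1, size and speed to > 0).
#' @export
condition_trait_means <- function(profile, temperature, pollutant, crowding = 0) {
  stopifnot(inherits(profile, "strain_profile"))
  dT <- temperature - profile$reference[["temperature"]]
  dA <- pollutant - profile$reference[["pollutant"]]
  m <- profile$trait_means +
    profile$trait_responses[, "temperature"] * dT +
    profile$trait_responses[, "pollutant"] * dA +
    profile$trait_crowding * crowding
  m[["speed"]] <- max(m[["speed"]], 1e-3)
  m[["linearity"]] <- min(max(m[["linearity"]], 1e-3), 1)
  m[["size"]] <- max(m[["size"]], 1)
  m[["shape"]] <- max(m[["shape"]], 1)
  m
}
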