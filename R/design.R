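#' Experimental design configuration
#'
#' Describes a fully crossed microcosm experiment: species x strain x
#' temperature x pollutant, with replicate dilution assays, a fixed dilution
#' series, and repeated imaging time points. The defaults mirror a two-species,
#' three-strain design with three temperatures (20, 22, 24 degrees C), three
#' atrazine concentrations (0, 10, 20 ug/mL), five dilutions (20-80% source
#' culture), three replicate assays, three time points, and 100-frame dark-field
#' bursts at 10 frames/s covering 810 uL of sample.
#'
#' @param species Character vector of species labels.
#' @param strains_per_species Number of clonal strains per species.
#' @param temperatures Numeric vector of incubation temperatures (degrees C).
#' @param pollutant_levels Numeric vector of pollutant concentrations (ug/mL).
#' @param dilution_fractions Strictly increasing fractions in (0, 1]: the
#'   proportion of source culture in each microcosm of the dilution series.
#' @param replicates Number of independent dilution assays per condition.
#' @param time_points Number of imaging time points per microcosm (>= 2).
#' @param frames_per_sample Frames per imaging burst (>= 2).
#' @param frame_rate Frames per second.
#' @param sample_volume_ul Imaged sample volume in microlitres.
#' @param arena Integer vector `c(width, height)` of the imaging arena, pixels.
#' @param rng_seed Optional integer seed attached to the design.
#'
#' @return An object of class `design_config` (a validated list).
#' @examples
#' cfg <- design_config()
#' design_counts(cfg)
#' @export
design_config <- function(species = c("C_striatum", "T_thermophila"),
                          strains_per_species = 3,
                          temperatures = c(20, 22, 24),
                          pollutant_levels = c(0, 10, 20),
                          dilution_fractions = c(0.20, 0.35, 0.50, 0.65, 0.80),
                          replicates = 3,
                          time_points = 3,
                          frames_per_sample = 100,
                          frame_rate = 10,
                          sample_volume_ul = 810,
                          arena = c(512L, 512L),
                          rng_seed = NULL) {
  cfg <- list(
    species = as.character(species),
    strains_per_species = as.integer(strains_per_species),
    temperatures = as.numeric(temperatures),
    pollutant_levels = as.numeric(pollutant_levels),
    dilution_fractions = as.numeric(dilution_fractions),
    replicates = as.integer(replicates),
    time_points = as.integer(time_points),
    frames_per_sample = as.integer(frames_per_sample),
    frame_rate = as.numeric(frame_rate),
    sample_volume_ul = as.numeric(sample_volume_ul),
    arena = as.integer(arena),
    rng_seed = if (!is.null(rng_seed)) as.integer(rng_seed)
  )
  validate_design_config(cfg)
  structure(cfg, class = "design_config")
}

validate_design_config <- function(cfg) {
  if (length(cfg$species) < 1) abort("`species` must be non-empty.")
  if (anyDuplicated(cfg$species)) abort("`species` labels must be unique.")
  if (length(cfg$temperatures) < 1) abort("`temperatures` must be non-empty.")
  if (length(cfg$pollutant_levels) < 1) abort("`pollutant_levels` must be non-empty.")
  d <- cfg$dilution_fractions
  if (length(d) < 1 || any(d <= 0) || any(d > 1)) {
    abort("`dilution_fractions` must lie in (0, 1].")
  }
  if (is.unsorted(d, strictly = TRUE)) {
    abort("`dilution_fractions` must be strictly increasing.")
  }
  if (cfg$strains_per_species < 1) abort("`strains_per_species` must be >= 1.")
  if (cfg$replicates < 1) abort("`replicates` must be >= 1.")
  if (cfg$time_points < 2) abort("`time_points` must be >= 2.")
  if (cfg$frames_per_sample < 2) abort("`frames_per_sample` must be >= 2.")
  if (cfg$frame_rate <= 0) abort("`frame_rate` must be positive.")
  if (cfg$sample_volume_ul <= 0) abort("`sample_volume_ul` must be positive.")
  if (length(cfg$arena) != 2 || any(cfg$arena < 8)) {
    abort("`arena` must be two pixel dimensions >= 8.")
  }
  invisible(cfg)
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat("  species:            ", paste(x$species, collapse = ", "), "\n")
  cat("  strains/species:    ", x$strains_per_species, "\n")
  cat("  temperatures (C):   ", paste(x$temperatures, collapse = ", "), "\n")
  cat("  pollutant (ug/mL):  ", paste(x$pollutant_levels, collapse = ", "), "\n")
  cat("  dilutions:          ", paste(x$dilution_fractions, collapse = ", "), "\n")
  cat("  replicates:         ", x$replicates, "\n")
  cat("  time points:        ", x$time_points, "\n")
  cat("  frames x rate:      ", x$frames_per_sample, "@", x$frame_rate, "fps\n")
  cnt <- design_counts(x)
  cat("  conditions/assays/series:", cnt$conditions, "/", cnt$assays, "/",
      cnt$picture_series, "\n")
  invisible(x)
}

#' Enumerate every assay descriptor of a design
#'
#' Expands a [design_config()] into one row per microcosm: every combination of
#' species, strain, temperature, pollutant level, replicate assay and dilution
#' fraction. Condition, assay and sample identifiers are attached so downstream
#' stages can join on them.
#'
#' @param config A [design_config()].
#' @return A tibble with one row per (species, strain, temperature, pollutant,
#'   replicate, dilution) and columns `condition_id`, `assay_id`,
#'   `microcosm_id`.
#' @examples
#' nrow(enumerate_design(design_config())) # 810 microcosms
#' @export
enumerate_design <- function(config) {
  stopifnot(inherits(config, "design_config"))
  strains <- paste0("S", seq_len(config$strains_per_species))
  grid <- tidyr::expand_grid(
    species = config$species,
    strain = strains,
    temperature = config$temperatures,
    pollutant = config$pollutant_levels,
    replicate = seq_len(config$replicates),
    dilution = config$dilution_fractions
  )
  grid |>
    dplyr::mutate(
      condition_id = paste(.data$species, .data$strain,
                           paste0("T", .data$temperature),
                           paste0("A", .data$pollutant), sep = "_"),
      assay_id = paste(.data$condition_id, paste0("R", .data$replicate), sep = "_"),
      microcosm_id = paste(.data$assay_id,
                           paste0("D", format(.data$dilution * 100)), sep = "_")
    )
}

#' Design arithmetic: conditions, assays, sample pairs and picture series
#'
#' @param config A [design_config()].
#' @return A one-row tibble with the exact integer counts implied by the
#'   design: distinct `conditions` (density-dependence curves), `assays`
#'   (condition x replicate), `sample_pairs` (assay x dilution),
#'   `picture_series` (sample pairs x time points), `points_per_curve`
#'   (dilutions x replicates) and `frames_per_sample`.
#' @examples
#' design_counts(design_config())
#' @export
design_counts <- function(config) {
  stopifnot(inherits(config, "design_config"))
  conditions <- length(config$species) * config$strains_per_species *
    length(config$temperatures) * length(config$pollutant_levels)
  assays <- conditions * config$replicates
  sample_pairs <- assays * length(config$dilution_fractions)
  tibble::tibble(
    conditions = as.integer(conditions),
    assays = as.integer(assays),
    sample_pairs = as.integer(sample_pairs),
    picture_series = as.integer(sample_pairs * config$time_points),
    points_per_curve = as.integer(length(config$dilution_fractions) * config$replicates),
    frames_per_sample = config$frames_per_sample
  )
}

#' Read or write a design configuration as YAML
#'
#' @param path File path.
#' @return `read_design_config()` returns a [design_config()];
#'   `write_design_config()` returns `path` invisibly.
#' @export
read_design_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(design_config, raw)
}

#' @rdname read_design_config
#' @param config A [design_config()].
#' @export
write_design_config <- function(config, path) {
  stopifnot(inherits(config, "design_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
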