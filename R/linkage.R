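#' The candidate model family linking demography to index responses
#'
#' Fifteen linear-model variants per demographic response: a Null
#' (intercept-only) model and, for each of the two predictors (`delta_mean`,
#' `delta_variance` of the strategy index, averaged to condition level), seven
#' structures in which the intercept and/or slope is common, differs among all
#' strains, or differs only among the strains of one species while the other
#' species' strains are pooled (`strainC` / `strainT` codings).
#'
#' @param species_c,species_t Species labels taken as the "C" and "T" sides of
#'   the pooled codings (defaults: first and second species in the data).
#' @return Tibble with `model`, `predictor`, `intercept_structure`,
#'   `slope_structure` and the model formula label.
#' @export
model_variants <- function(species_c = NULL, species_t = NULL) {
  structures <- tibble::tibble(
    suffix = as.character(1:7),
    intercept_structure = c("common", "strain", "strainC", "strainT",
                            "strain", "strainC", "strainT"),
    slope_structure = c("common", "common", "common", "common",
                        "strain", "strainC", "strainT"))
  fam <- function(pred, label) {
    dplyr::mutate(structures,
      model = paste(label, .data$suffix),
      predictor = pred,
      formula_label = paste0("~ ", label, " ",
        ifelse(.data$slope_structure == "common",
               ifelse(.data$intercept_structure == "common", "",
                      paste0("+ ", .data$intercept_structure)),
               paste0("* ", .data$slope_structure))))
  }
  dplyr::bind_rows(
    tibble::tibble(suffix = "0", intercept_structure = "common",
                   slope_structure = "none", model = "Null",
                   predictor = "none", formula_label = "~ 1"),
    fam("delta_mean", "Mean"),
    fam("delta_variance", "Variance")) |>
    dplyr::select("model", "predictor", "intercept_structure",
                  "slope_structure", "formula_label")
}

#' Build the condition-level records joining demography to index responses
#'
#' One record per condition (species x strain x temperature x pollutant):
#' the demographic parameters z-standardized at the species level (mu and
#' alpha over all of the species' conditions; K over its valid conditions
#' only), and the index responses averaged over replicates and dilutions.
#'
#' @param fit_table Per-condition demography estimates
#'   (`fit_demography()$fit_table`).
#' @param k_table Per-condition K estimates (`fit_demography()$k_table`).
#' @param responses Microcosm-level index responses ([index_response()]).
#' @return Tibble with one row per condition: design columns, `mu_z`,
#'   `alpha_z`, `K_z`, `k_valid`, `delta_mean`, `delta_variance`,
#'   `n_responses`.
#' @export
build_condition_records <- function(fit_table, k_table, responses) {
  z <- function(x) (x - mean(x)) / sd(x)
  dem <- fit_table |>
    dplyr::left_join(dplyr::select(k_table, "condition_id", "K", "valid"),
                     by = "condition_id") |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(
      mu_z = z(.data$mu),
      alpha_z = z(.data$alpha),
      K_z = {
        kv <- .data$K[.data$valid]
        (.data$K - mean(kv)) / sd(kv)
      },
      K_z = ifelse(.data$valid, .data$K_z, NA_real_)) |>
    dplyr::ungroup()
  resp <- responses |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      delta_mean = mean(.data$delta_mean, na.rm = TRUE),
      delta_variance = mean(.data$delta_variance, na.rm = TRUE),
      n_responses = sum(!is.na(.data$delta_mean)), .groups = "drop")
  out <- dem |>
    dplyr::left_join(resp, by = "condition_id") |>
    dplyr::mutate(k_valid = .data$valid,
                  usable = !is.na(.data$delta_mean) & .data$n_responses > 0) |>
    dplyr::select(dplyr::any_of(c("condition_id", "species", "strain",
                                  "temperature", "pollutant")),
                  "mu_z", "alpha_z", "K_z", "k_valid",
                  "delta_mean", "delta_variance", "n_responses", "usable")
  out
}

# strain codings: "strain" = species:strain (all distinct); "strainC"/"strainT"
# = focal species' strains distinct, other species pooled into one level.
strain_codings <- function(records, species_c = NULL, species_t = NULL) {
  sp <- unique(records$species)
  if (is.null(species_c)) species_c <- sp[1]
  if (is.null(species_t)) species_t <- if (length(sp) > 1) sp[2] else sp[1]
  full <- factor(paste(records$species, records$strain, sep = "_"))
  pool <- function(focal) {
    factor(ifelse(records$species == focal,
                  paste(records$species, records$strain, sep = "_"), "other"))
  }
  list(strain = full, strainC = pool(species_c), strainT = pool(species_t))
}

#' Small-sample Akaike information criterion
#'
#' `AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with `k` counting every mean
#' coefficient plus the residual-variance parameter. The additive
#' normal-likelihood constant is dropped, so values are comparable within one
#' response, which is how the selection uses them.
#'
#' @param fit An `lm` fit.
#' @return Named numeric: `aicc`, `aic`, `k`, `n`.
#' @export
aicc <- function(fit) {
  rss <- sum(residuals(fit)^2)
  n <- length(residuals(fit))
  k <- length(coef(fit)) + 1
  if (n - k - 1 <= 0) {
    return(c(aicc = NA_real_, aic = NA_real_, k = k, n = n))
  }
  aic <- n * log(rss / n) + 2 * k
  c(aicc = aic + 2 * k * (k + 1) / (n - k - 1), aic = aic, k = k, n = n)
}

#' Fit one linkage model variant
#'
#' @param records Condition records ([build_condition_records()]).
#' @param variant One row of [model_variants()].
#' @param response `"mu"`, `"alpha"` or `"K"` (z-standardized columns are
#'   used; K models drop K-invalid records).
#' @param species_c,species_t Passed to the strain codings.
#' @return List with `row` (model, response, n, k, AICc, adjusted R^2) and
#'   `fit` (the `lm`), or `NULL` if the variant is not estimable.
#' @export
fit_variant <- function(records, variant, response = c("mu", "alpha", "K"),
                        species_c = NULL, species_t = NULL) {
  response <- match.arg(response)
  ycol <- c(mu = "mu_z", alpha = "alpha_z", K = "K_z")[[response]]
  d <- dplyr::filter(records, .data$usable, !is.na(.data[[ycol]]))
  cod <- strain_codings(d, species_c, species_t)
  df <- tibble::tibble(y = d[[ycol]])
  if (variant$predictor != "none") df$x <- d[[variant$predictor]]
  for (nm in names(cod)) df[[nm]] <- droplevels(cod[[nm]])
  fml <- if (variant$predictor == "none") {
    "y ~ 1"
  } else if (variant$slope_structure == "none" ||
             variant$slope_structure == "common") {
    if (variant$intercept_structure == "common") "y ~ x"
    else paste0("y ~ x + ", variant$intercept_structure)
  } else {
    paste0("y ~ x * ", variant$slope_structure)
  }
  fit <- lm(as.formula(fml), data = df)
  ic <- aicc(fit)
  if (!is.finite(ic[["aicc"]])) {
    warn(paste0("Variant ", variant$model, " (", response,
                "): n - k - 1 <= 0; skipped."))
    return(NULL)
  }
  list(row = tibble::tibble(
    model = variant$model, response = response, n = ic[["n"]],
    k = ic[["k"]], rss = sum(residuals(fit)^2),
    AICc = ic[["aicc"]], adj_r_squared = summary(fit)$adj.r.squared),
    fit = fit)
}

#' AICc selection across the variant family
#'
#' Fits every variant of [model_variants()] for the requested demographic
#' responses and ranks them by AICc (ties below 1e-9 broken by fewer
#' parameters, then by the fixed variant order).
#'
#' @param records Condition records ([build_condition_records()]).
#' @param responses Character subset of `c("mu", "K", "alpha")`.
#' @param species_c,species_t Species labels for the pooled codings
#'   (defaults: first and second species present).
#' @return A `linkage_selection` object; `tidy()` returns the comparison
#'   table (one row per model x response with `AICc`, `adj_r_squared`,
#'   `rank`, `is_best`), `$fits` holds the underlying `lm` objects.
#' @export
fit_linkage <- function(records, responses = c("mu", "K", "alpha"),
                        species_c = NULL, species_t = NULL) {
  variants <- model_variants()
  rows <- list(); fits <- list()
  for (resp in responses) {
    res <- purrr::map(seq_len(nrow(variants)), function(i) {
      fit_variant(records, variants[i, ], resp, species_c, species_t)
    })
    res <- purrr::compact(res)
    tab <- purrr::map_dfr(res, "row")
    tab <- select_best(tab)
    rows[[resp]] <- tab
    fits[[resp]] <- setNames(purrr::map(res, "fit"),
                             purrr::map_chr(res, ~ .x$row$model))
  }
  structure(list(table = dplyr::bind_rows(rows), fits = fits,
                 records = records),
            class = "linkage_selection")
}

#' Rank a set of fitted variants by AICc
#'
#' @param rows Tibble with at least `model`, `AICc` and `k` for one response.
#' @return The rows ordered and annotated with `delta_AICc`, `rank`,
#'   `is_best`.
#' @export
select_best <- function(rows) {
  stopifnot(nrow(rows) >= 2)
  name_order <- match(rows$model, model_variants()$model)
  ord <- order(round(rows$AICc / 1e-9) * 1e-9, rows$k, name_order)
  rows <- rows[ord, , drop = FALSE]
  rows$delta_AICc <- rows$AICc - rows$AICc[1]
  rows$rank <- seq_len(nrow(rows))
  rows$is_best <- rows$rank == 1
  rows
}

#' @export
print.linkage_selection <- function(x, ...) {
  cat("<linkage_selection>\n")
  best <- dplyr::filter(x$table, .data$is_best)
  for (i in seq_len(nrow(best))) {
    cat(sprintf("  %-6s best: %-11s AICc %8.2f  adjR2 %5.2f  (n = %d)\n",
                best$response[i], best$model[i], best$AICc[i],
                best$adj_r_squared[i], best$n[i]))
  }
  invisible(x)
}

#' Slope of the index predictor in a fitted linkage model
#'
#' Returns the common (reference-level) slope coefficient of `delta_mean` /
#' `delta_variance` in a variant fitted by [fit_linkage()]; `NA` for the Null
#' model.
#'
#' @param selection A `linkage_selection`.
#' @param response `"mu"`, `"alpha"` or `"K"`.
#' @param model Model name; default the best-ranked one.
#' @return Numeric slope (named by model).
#' @export
linkage_slope <- function(selection, response, model = NULL) {
  stopifnot(inherits(selection, "linkage_selection"))
  tab <- dplyr::filter(selection$table, .data$response == !!response)
  if (is.null(model)) model <- tab$model[tab$is_best][1]
  fit <- selection$fits[[response]][[model]]
  cf <- coef(fit)
  setNames(if ("x" %in% names(cf)) unname(cf[["x"]]) else NA_real_, model)
}
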