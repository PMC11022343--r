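#' Factorial ANOVA of pcgr against strain, temperature and pollutant
#'
#' Fits, per species, the fixed-effects linear model of per-capita growth rate
#' with starting density as a covariate and the three design factors (coded as
#' unordered categoricals) up to their three-way interaction, plus each
#' factor term's interaction with starting density. Main factor terms express
#' differences in mu (intercept) while their interactions with starting
#' density express differences in alpha (slope). Sums of squares are
#' sequential (Type I) in the fixed term order: `n_start`, pollutant,
#' temperature, strain, the two-way factor interactions, the three-way, then
#' the same factor terms crossed with `n_start`. Each term carries F, p
#' against the residual mean square, and partial eta squared
#' `SS_effect / (SS_effect + SS_residual)`.
#'
#' @param observations Growth observations ([growth_observations()]) with
#'   `species`, `strain`, `temperature`, `pollutant`, `n_start`, `pcgr`.
#' @param ss_type `"I"` (sequential, default) or `"III"` (partial, via
#'   sum-to-zero contrasts; requires the car package).
#' @return Tibble with one row per term (plus a Residuals row) per species:
#'   `species`, `term`, `df`, `sum_sq`, `statistic`, `p_value`, `eta_p2`.
#' @export
demography_anova <- function(observations, ss_type = c("I", "III")) {
  ss_type <- match.arg(ss_type)
  factor_terms <- c("pollutant", "temperature", "strain",
                    "pollutant:temperature", "pollutant:strain",
                    "temperature:strain", "pollutant:temperature:strain")
  terms <- c("n_start", factor_terms, paste0("n_start:", factor_terms))
  run_anova_by_species(observations, terms, ss_type, response = "pcgr")
}

#' Factorial ANOVA of index responses
#'
#' Per species, tests strain, temperature and pollutant (and all their
#' interactions) on the change in mean or variance of the strategy index over
#' the growth interval. Term order: pollutant, temperature, strain, two-way
#' interactions, three-way.
#'
#' @param responses Output of [index_response()].
#' @param which `"delta_mean"` or `"delta_variance"`.
#' @inheritParams demography_anova
#' @return As [demography_anova()], with a `response` column.
#' @export
index_anova <- function(responses, which = c("delta_mean", "delta_variance"),
                        ss_type = c("I", "III")) {
  which <- match.arg(which)
  ss_type <- match.arg(ss_type)
  terms <- c("pollutant", "temperature", "strain",
             "pollutant:temperature", "pollutant:strain",
             "temperature:strain", "pollutant:temperature:strain")
  out <- run_anova_by_species(responses, terms, ss_type, response = which)
  dplyr::mutate(out, response = which, .after = "species")
}

run_anova_by_species <- function(data, terms, ss_type, response) {
  data <- tibble::as_tibble(data)
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  purrr::map_dfr(split(data, data$species), function(d) {
    for (f in c("strain", "temperature", "pollutant")) {
      if (!is.factor(d[[f]])) d[[f]] <- factor(d[[f]])
      lv <- levels(droplevels(d[[f]]))
      if (length(lv) < length(levels(d[[f]]))) {
        missing <- setdiff(levels(d[[f]]), lv)
        abort(paste0("Species ", d$species[1], ": empty level(s) of ", f, ": ",
                     paste(missing, collapse = ", ")))
      }
    }
    # constant factors (single level, e.g. one-way fixtures) cannot enter the
    # model; drop every term touching them but keep the canonical order
    inactive <- Filter(function(f) nlevels(droplevels(d[[f]])) < 2,
                       c("strain", "temperature", "pollutant"))
    keep <- terms
    for (f in inactive) keep <- keep[!grepl(f, keep, fixed = TRUE)]
    fml <- as.formula(paste(response, "~", paste(keep, collapse = " + ")))
    tab <- if (ss_type == "I") {
      a <- anova(lm(fml, data = d))
      tibble::tibble(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                     statistic = a$`F value`, p_value = a$`Pr(>F)`)
    } else {
      if (!requireNamespace("car", quietly = TRUE)) {
        abort("Type III sums of squares require the 'car' package.")
      }
      old <- options(contrasts = c("contr.sum", "contr.poly"))
      on.exit(options(old), add = TRUE)
      a <- car::Anova(lm(fml, data = d), type = 3)
      keep <- setdiff(rownames(a), "(Intercept)")
      a <- a[keep, , drop = FALSE]
      tibble::tibble(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                     statistic = a$`F value`, p_value = a$`Pr(>F)`)
    }
    ss_res <- tab$sum_sq[tab$term == "Residuals"]
    tab$eta_p2 <- ifelse(tab$term == "Residuals", NA_real_,
                         tab$sum_sq / (tab$sum_sq + ss_res))
    # canonical printed order (anova keeps formula order; enforce anyway)
    tab$term <- sub("^I\\(", "", tab$term)
    ord <- match(tab$term, c(terms, "Residuals"))
    tab <- tab[order(ord), , drop = FALSE]
    dplyr::bind_cols(tibble::tibble(species = rep(d$species[1], nrow(tab))), tab)
  })
}

#' Tukey-adjusted pairwise contrasts for one factor
#'
#' Post-hoc pairwise comparisons of factor-level means on a fitted ANOVA
#' response, Tukey HSD adjusted. Not part of the headline tables.
#'
#' @param data Data used for the ANOVA (one species).
#' @param response Response column name.
#' @param factor_name One of `"strain"`, `"temperature"`, `"pollutant"`.
#' @return Tibble of pairwise differences with adjusted p-values.
#' @export
pairwise_contrasts <- function(data, response, factor_name) {
  d <- tibble::as_tibble(data)
  d$.f <- factor(d[[factor_name]])
  fit <- stats::aov(as.formula(paste(response, "~ .f")), data = d)
  tk <- stats::TukeyHSD(fit)$`.f`
  tibble::tibble(contrast = rownames(tk), estimate = tk[, "diff"],
                 conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
                 p_adjusted = tk[, "p adj"])
}
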