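test_that("the variant family matches the published table structure", {
  v <- model_variants()
  expect_identical(nrow(v), 15L)
  expect_identical(v$model[1], "Null")
  expect_identical(sum(v$predictor == "delta_mean"), 7L)
  expect_identical(sum(v$predictor == "delta_variance"), 7L)
})

test_that("condition records are standardized within species", {
  rec <- generate_condition_records("mean_strainT", seed = 1)
  expect_identical(nrow(rec), 54L)
  # build_condition_records path: feed synthetic fits/responses
  fit_table <- tibble::tibble(
    condition_id = rec$condition_id, species = rec$species,
    strain = rec$strain, temperature = 22, pollutant = 0,
    mu = rec$mu_z * 0.3 + 1.2, alpha = rec$alpha_z * 1e-5 - 1e-4,
    s2_mu = 1e-4, s2_alpha = 1e-12, cov_mu_alpha = 0,
    n_points = 15, n_excluded = 0, r_squared = 0.9, nonlinearity_p = 0.5)
  k_table <- tibble::tibble(condition_id = rec$condition_id,
                            K = -fit_table$mu / fit_table$alpha,
                            s2_K = 1, valid = TRUE)
  k_table$valid[1:3] <- FALSE
  responses <- tibble::tibble(condition_id = rep(rec$condition_id, each = 3),
                              delta_mean = rnorm(54 * 3),
                              delta_variance = rnorm(54 * 3))
  out <- build_condition_records(fit_table, k_table, responses)
  expect_identical(nrow(out), 54L)
  expect_identical(sum(out$k_valid), 51L)
  for (sp in unique(out$species)) {
    mu_z <- out$mu_z[out$species == sp]
    expect_equal(mean(mu_z), 0, tolerance = 1e-12)
    expect_equal(sd(mu_z), 1, tolerance = 1e-12)
  }
  expect_true(all(is.na(out$K_z[!out$k_valid])))
  # averaging: three values collapse to their mean
  r3 <- tibble::tibble(condition_id = "c", delta_mean = c(0.1, 0.2, 0.3),
                       delta_variance = 0)
  f1 <- fit_table[1, ]; f1$condition_id <- "c"
  f2 <- fit_table[2, ]; f2$condition_id <- "c2"
  k1 <- k_table[1:2, ]; k1$condition_id <- c("c", "c2"); k1$valid <- TRUE
  avg <- build_condition_records(rbind(f1, f2), k1,
                                 rbind(r3, tibble::tibble(condition_id = "c2",
                                                          delta_mean = 0,
                                                          delta_variance = 0)))
  expect_equal(avg$delta_mean[avg$condition_id == "c"], 0.2, tolerance = 1e-12)
})

test_that("K models use only valid-K records", {
  rec <- generate_condition_records("mean_common", seed = 2)
  rec$k_valid[1:3] <- FALSE
  rec$K_z[1:3] <- NA_real_
  sel <- fit_linkage(rec, species_c = "C_sp", species_t = "T_sp")
  tab <- tidy(sel)
  expect_true(all(tab$n[tab$response == "K"] == 51))
  expect_true(all(tab$n[tab$response == "mu"] == 54))
})

test_that("AICc matches an independent textbook recomputation", {
  rec <- generate_condition_records("null", seed = 3)
  sel <- fit_linkage(rec, responses = "mu",
                     species_c = "C_sp", species_t = "T_sp")
  tab <- tidy(sel)
  null_row <- tab[tab$model == "Null", ]
  expect_identical(null_row$k, 2)
  fit <- sel$fits$mu$Null
  n <- nrow(rec); rss <- sum(residuals(fit)^2); k <- 2
  oracle <- n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  expect_equal(null_row$AICc, oracle, tolerance = 1e-9)
  # strainC/strainT codings pool the other species into one level: 4 levels
  m3 <- sel$fits$mu$`Mean 3`
  expect_identical(length(coef(m3)), 5L)  # intercept + slope + 3 strainC
})

test_that("duplicating the dataset changes AICc but not the estimates", {
  rec <- generate_condition_records("mean_common", seed = 4)
  v <- model_variants()[2, ]  # Mean 1
  single <- fit_variant(rec, v, "mu", "C_sp", "T_sp")
  doubled <- fit_variant(dplyr::bind_rows(rec, rec), v, "mu", "C_sp", "T_sp")
  expect_equal(coef(single$fit), coef(doubled$fit), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(single$row$AICc, doubled$row$AICc)))
})

test_that("ranking minimizes AICc with deterministic tie-breaks", {
  rows <- tibble::tibble(model = c("Null", "Mean 1", "Mean 2"),
                         AICc = c(150, 143, 155), k = c(2, 3, 8))
  ranked <- select_best(rows)
  expect_identical(ranked$model[1], "Mean 1")
  expect_equal(ranked$AICc[1], 143)
  ties <- tibble::tibble(model = c("Mean 5", "Mean 1"),
                         AICc = c(100, 100), k = c(8, 3))
  expect_identical(select_best(ties)$model[1], "Mean 1")
})

test_that("nested variants never increase fit badness", {
  rec <- generate_condition_records("mean_strainT", seed = 5)
  sel <- fit_linkage(rec, responses = "mu",
                     species_c = "C_sp", species_t = "T_sp")
  tab <- tidy(sel)
  rss <- setNames(tab$rss, tab$model)
  # adding parameters along each nesting chain cannot increase RSS
  chains <- list(c("Null", "Mean 1", "Mean 4", "Mean 7"),
                 c("Mean 1", "Mean 2", "Mean 5"),
                 c("Mean 1", "Mean 3", "Mean 6"),
                 c("Null", "Variance 1", "Variance 2", "Variance 5"))
  for (ch in chains) {
    expect_true(all(diff(rss[ch]) <= 1e-8))
  }
})

test_that("AICc converges to AIC for large n", {
  set.seed(6)
  d <- data.frame(y = rnorm(1e4), x = rnorm(1e4))
  ic <- aicc(lm(y ~ x, data = d))
  expect_lt(abs(ic[["aicc"]] - ic[["aic"]]), 0.01 * ic[["k"]])
})

test_that("strong common-slope signal beats the null decisively", {
  set.seed(7)
  wins <- replicate(30, {
    rec <- generate_condition_records("mean_common", slope = 1, sigma = 0.3,
                                      seed = sample.int(1e6, 1))
    sel <- fit_linkage(rec, responses = "mu",
                       species_c = "C_sp", species_t = "T_sp")
    tab <- tidy(sel)
    tab$AICc[tab$model == "Null"] - tab$AICc[tab$model == "Mean 1"] > 2
  })
  expect_gte(mean(wins), 0.95)
})

test_that("pure-noise records select the null most often", {
  set.seed(8)
  best <- replicate(60, {
    rec <- generate_condition_records("null", seed = sample.int(1e6, 1))
    sel <- fit_linkage(rec, responses = "mu",
                       species_c = "C_sp", species_t = "T_sp")
    glance(sel)$best_model
  })
  counts <- sort(table(best), decreasing = TRUE)
  expect_identical(names(counts)[1], "Null")
})
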