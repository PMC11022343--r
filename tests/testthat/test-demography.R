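test_that("pcgr reproduces hand-computed log ratios", {
  expect_equal(compute_pcgr(100, 200, 0, 1), log(2), tolerance = 1e-9)
  expect_equal(compute_pcgr(500, 500, 0, 2), 0)
  expect_equal(compute_pcgr(100, exp(1) * 100, 0, 2), 0.5, tolerance = 1e-12)
  expect_error(compute_pcgr(0, 100, 0, 1), "positive")
  expect_error(compute_pcgr(100, 200, 1, 1), "exceed")
})

interval_fixture <- function(d0, d1, d2) {
  tibble::tibble(microcosm_id = "m1", time_point = 0:2,
                 time_days = c(0, 1, 2), density = c(d0, d1, d2))
}

test_that("interval selection follows the fold-change preference rule", {
  # first interval already precise -> chosen
  iv <- select_interval(interval_fixture(100, 300, 600), 1.5)
  expect_identical(iv$interval_label, "t0->t1")
  # t0->t1 too shallow (1.1), t0->t2 first to clear 1.5
  iv2 <- select_interval(interval_fixture(100, 110, 240), 1.5)
  expect_identical(iv2$interval_label, "t0->t2")
  expect_equal(iv2$fold_change, 2.4)
  # nothing clears the bar -> maximal fold-change candidate
  iv3 <- select_interval(interval_fixture(100, 105, 120), 1.5)
  expect_identical(iv3$interval_label, "t0->t2")
  # zero count at t0 forces the only remaining pair
  iv4 <- select_interval(interval_fixture(0, 110, 240), 1.5)
  expect_identical(iv4$interval_label, "t1->t2")
  # a single usable point drops the microcosm with a reason
  iv5 <- select_interval(interval_fixture(0, 0, 240), 1.5)
  expect_identical(nrow(iv5), 0L)
  expect_match(attr(iv5, "dropped")$reason, "usable")
})

test_that("noiseless linear data are recovered exactly", {
  obs <- linear_observations(mu = 1, alpha = -0.001)
  fit <- suppressWarnings(fit_curve(obs))  # "perfect fit" summary warnings
  expect_equal(fit$mu, 1, tolerance = 1e-10)
  expect_equal(fit$alpha, -0.001, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # constant response: slope exactly zero
  flat <- suppressWarnings(fit_curve(linear_observations(mu = 0.7, alpha = 0)))
  expect_equal(flat$alpha, 0, tolerance = 1e-12)
  expect_equal(flat$mu, 0.7, tolerance = 1e-12)
})

test_that("perturbed two-level data match the closed-form OLS oracle", {
  # symmetric +-eps at two N_start values: hand OLS on two cell means
  eps <- 0.05
  obs <- tibble::tibble(
    condition_id = "fx",
    n_start = c(200, 200, 800, 800),
    pcgr = c(0.8 + eps, 0.8 - eps, 0.2 + eps, 0.2 - eps))
  fit <- fit_curve(obs)
  slope_oracle <- (0.2 - 0.8) / (800 - 200)
  intercept_oracle <- 0.8 - slope_oracle * 200
  expect_equal(fit$alpha, slope_oracle, tolerance = 1e-12)
  expect_equal(fit$mu, intercept_oracle, tolerance = 1e-12)
})

test_that("degenerate curves raise informative errors", {
  expect_error(fit_curve(linear_observations(n_start = rep(500, 5))),
               "distinct")
  expect_error(fit_curve(linear_observations(n_start = c(200, 400))),
               ">= 3")
})

test_that("the nonlinearity screen flags quadratic truth and stays silent otherwise", {
  set.seed(1)
  n <- rep(c(200, 350, 500, 650, 800), 3)
  quad <- tibble::tibble(condition_id = "q", n_start = n,
                         pcgr = 1 - 1e-3 * n + 2e-6 * (n - 500)^2 +
                           rnorm(15, 0, 0.01))
  expect_lt(fit_curve(quad)$nonlinearity_p, 0.05)
  lin <- tibble::tibble(condition_id = "l", n_start = n,
                        pcgr = 1 - 1e-3 * n + rnorm(15, 0, 0.01))
  expect_gt(fit_curve(lin)$nonlinearity_p, 0.05)
  flat2 <- suppressWarnings(fit_curve(linear_observations(alpha = 0)))
  expect_true(is.na(flat2$nonlinearity_p) || flat2$nonlinearity_p > 0.05)
})

test_that("influence screening removes exactly the engineered outlier", {
  set.seed(42)
  obs <- linear_observations(mu = 1, alpha = -0.001,
                             noise = rnorm(15, 0, 0.02))
  obs$pcgr[15] <- obs$pcgr[15] - 0.8   # gross outlier at extreme N_start
  fit <- fit_curve(obs)
  # leave-one-out brute-force oracle: only point 15 crosses both thresholds
  cd_oracle <- cooks_oracle(obs)
  expect_equal(unname(cooks.distance(fit$fit)), cd_oracle, tolerance = 1e-8)
  expect_identical(unname(which(cd_oracle >= 0.5 & abs(rstudent(fit$fit)) >= 2)),
                   15L)
  refit <- exclude_influential(fit)
  expect_identical(nrow(refit$excluded), 1L)
  expect_equal(refit$excluded$n_start, 800)
  expect_identical(refit$n_points, 14L)
  expect_equal(refit$mu, 1, tolerance = 0.05)
  # clean data: identity
  clean <- fit_curve(linear_observations(noise = rnorm(15, 0, 0.02)))
  expect_identical(nrow(exclude_influential(clean)$excluded), 0L)
})

test_that("a central large residual with low leverage is retained", {
  set.seed(7)
  obs <- linear_observations(noise = rnorm(15, 0, 0.02))
  mid <- which(obs$n_start == 500)[1]
  obs$pcgr[mid] <- obs$pcgr[mid] + 0.12  # clear residual, centre of design
  fit <- fit_curve(obs)
  cd <- cooks_oracle(obs)
  expect_lt(cd[mid], 0.5)
  expect_gt(abs(rstudent(fit$fit))[mid], 2)
  refit <- exclude_influential(fit)
  expect_identical(nrow(refit$excluded), 0L)
})

test_that("exclusion never leaves fewer than three points", {
  obs <- linear_observations(n_start = c(100, 200, 300, 900),
                             noise = c(0, 0, 0, -0.5))[1:4, ]
  fit <- fit_curve(obs)
  refit <- suppressWarnings(exclude_influential(fit, cooks_threshold = 0.01,
                                                resid_threshold = 0.1,
                                                max_exclusions = 3))
  expect_gte(refit$n_points, 3L)
})

test_that("carrying capacity and its Taylor variance match hand values", {
  f <- list(condition_id = "c", mu = 2, alpha = -0.01, s2_mu = 0,
            s2_alpha = 0, cov_mu_alpha = 0)
  expect_equal(carrying_capacity(f)$K, 200)
  f2 <- list(condition_id = "c", mu = 1, alpha = -1, s2_mu = 0.01,
             s2_alpha = 0.01, cov_mu_alpha = 0)
  expect_equal(carrying_capacity(f2)$s2_K, 0.02, tolerance = 1e-12)
  # alpha = 0: undefined and flagged
  f3 <- list(condition_id = "c", mu = 1, alpha = 0, s2_mu = 0, s2_alpha = 0,
             cov_mu_alpha = 0)
  expect_false(carrying_capacity(f3)$valid)
  expect_true(is.na(carrying_capacity(f3)$K))
  # extremely negative K flagged invalid at the -400 default
  f4 <- list(condition_id = "c", mu = 1, alpha = 2e-3, s2_mu = 0,
             s2_alpha = 0, cov_mu_alpha = 0)
  expect_false(carrying_capacity(f4)$valid)
})

test_that("delta-method variance tracks a Monte-Carlo oracle", {
  b <- benchmark_k_variance(1.2, -0.002, 0.0025, 1e-8, -4e-6,
                            n_draws = 2e5, seed = 1)
  expect_lt(b$rel_err, 0.05)
})

test_that("K is positive whenever growth is positive and self-limited", {
  set.seed(9)
  for (i in 1:20) {
    mu <- runif(1, 0.2, 3); alpha <- -10^runif(1, -5, -2)
    f <- list(condition_id = "c", mu = mu, alpha = alpha, s2_mu = 0,
              s2_alpha = 0, cov_mu_alpha = 0)
    expect_gt(carrying_capacity(f)$K, 0)
  }
})

test_that("one influence pass is idempotent on its own refit", {
  set.seed(11)
  obs <- linear_observations(noise = rnorm(15, 0, 0.02))
  obs$pcgr[15] <- obs$pcgr[15] - 0.8
  once <- exclude_influential(fit_curve(obs))
  twice <- exclude_influential(once)
  expect_lte(nrow(twice$excluded), 2L)
})
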