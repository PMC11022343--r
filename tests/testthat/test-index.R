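test_that("standardization pools match two-point and split-pool oracles", {
  std <- fit_standardization(trait_samples(speed = c(40, 60)))
  sp <- std[std$trait == "speed", ]
  expect_equal(sp$mean, 50)
  expect_equal(sp$sd, sqrt(200), tolerance = 1e-6)
  # split pool in halves: pooled moments equal brute-force over concatenation
  set.seed(1)
  all_speed <- rnorm(20, 50, 8)
  std_all <- fit_standardization(trait_samples(all_speed))
  expect_equal(std_all$mean[std_all$trait == "speed"], mean(all_speed))
  expect_equal(std_all$sd[std_all$trait == "speed"], sd(all_speed))
})

test_that("constant traits raise an error naming the trait", {
  s <- trait_samples(speed = c(50, 50, 50))
  expect_error(fit_standardization(s), "speed")
})

test_that("z-standardization is self-consistent to machine precision", {
  set.seed(2)
  s <- trait_samples(speed = rnorm(12, 60, 10),
                     linearity = runif(12, 0.5, 0.9),
                     size = rnorm(12, 400, 50), shape = rnorm(12, 2.5, 0.2))
  std <- fit_standardization(s)
  idx <- compute_index(s, std)
  zs <- (s$speed_mean - std$mean[std$trait == "speed"]) /
    std$sd[std$trait == "speed"]
  expect_equal(mean(zs), 0, tolerance = 1e-12)
  expect_equal(sd(zs), 1, tolerance = 1e-12)
  # index of a sample sitting exactly at the species means is zero
  at_mean <- s[1, ]
  for (tr in c("speed", "linearity", "size", "shape")) {
    at_mean[[paste0(tr, "_mean")]] <- std$mean[std$trait == tr]
    at_mean[[paste0(tr, "_var")]] <- 0
  }
  idx0 <- compute_index(at_mean, std)
  expect_equal(idx0$mean_index, 0, tolerance = 1e-12)
  expect_equal(idx0$variance_index, 0)
})

test_that("all-unit z-scores compose to an index of two", {
  set.seed(3)
  s <- trait_samples(speed = rnorm(10, 60, 10),
                     linearity = runif(10, 0.4, 0.9),
                     size = rnorm(10, 400, 50), shape = rnorm(10, 2.5, 0.2))
  std <- fit_standardization(s)
  one_up <- s[1, ]
  for (tr in c("speed", "linearity", "size", "shape")) {
    one_up[[paste0(tr, "_mean")]] <- std$mean[std$trait == tr] +
      std$sd[std$trait == tr]
  }
  # speed + linearity - size + shape at z = 1 each: 1 + 1 - 1 + 1 = 2
  expect_equal(compute_index(one_up, std)$mean_index, 2, tolerance = 1e-12)
})

test_that("the index is invariant to affine trait rescaling", {
  set.seed(4)
  s <- trait_samples(speed = rnorm(15, 60, 10),
                     linearity = runif(15, 0.4, 0.9),
                     size = rnorm(15, 400, 50), shape = rnorm(15, 2.5, 0.2))
  idx1 <- compute_index(s, fit_standardization(s))
  s10 <- dplyr::mutate(s, speed_mean = speed_mean * 10,
                       speed_var = speed_var * 100)
  idx10 <- compute_index(s10, fit_standardization(s10))
  expect_equal(idx10$mean_index, idx1$mean_index, tolerance = 1e-9)
})

test_that("per-trajectory index mode matches hand enumeration", {
  traj <- tibble::tibble(
    sample_id = "s1", species = "spA",
    speed = c(40, 50, 60), linearity = c(0.6, 0.8, 1.0),
    size = c(300, 400, 500), shape = c(2, 2.5, 3))
  std <- tibble::tibble(
    species = "spA", trait = c("speed", "linearity", "size", "shape"),
    mean = c(50, 0.8, 400, 2.5), sd = c(10, 0.2, 100, 0.5), n = 3)
  res <- per_trajectory_index(traj, std)
  by_hand <- c(-1 + -1 - -1 + -1, 0, 1 + 1 - 1 + 1)
  expect_equal(res$mean_index, mean(by_hand), tolerance = 1e-12)
  expect_equal(res$variance_index, var(by_hand), tolerance = 1e-12)
})

response_fixture <- function(mean_t0, mean_t1, var_t0 = 0.5, var_t1 = 0.8) {
  samples <- tibble::tibble(
    microcosm_id = "m1", condition_id = "c1", assay_id = "a1",
    species = "spA", strain = "S1", temperature = 22, pollutant = 0,
    replicate = 1, dilution = 0.5,
    time_point = c(0L, 1L),
    mean_index = c(mean_t0, mean_t1), variance_index = c(var_t0, var_t1))
  intervals <- tibble::tibble(microcosm_id = "m1", start_time_point = 0L,
                              end_time_point = 1L, interval_label = "t0->t1")
  index_response(samples, intervals)
}

test_that("index responses difference end minus start", {
  r <- response_fixture(0.5, 1.25)
  expect_equal(r$delta_mean, 0.75)
  expect_equal(r$delta_variance, 0.3, tolerance = 1e-12)
  expect_identical(r$interval_label, "t0->t1")
  same <- response_fixture(0.4, 0.4, 0.2, 0.2)
  expect_equal(same$delta_mean, 0)
  expect_equal(same$delta_variance, 0)
})

test_that("delta_mean is exactly antisymmetric under time reversal", {
  fwd <- response_fixture(0.2, 1.1)
  rev <- response_fixture(1.1, 0.2)
  expect_equal(fwd$delta_mean, -rev$delta_mean, tolerance = 1e-15)
})

test_that("a generative flee shift raises the mean index", {
  # raise speed & shape, lower size between time points; sign test over seeds
  cfg <- tiny_config()
  prof <- default_strain_profiles(cfg)[[1]]
  set.seed(5)
  deltas <- replicate(60, {
    start <- draw_individual_traits(80, prof, 22, 10, crowding = 0)
    end <- draw_individual_traits(80, prof, 22, 10, crowding = 0.6)
    mk <- function(ind, id) tibble::tibble(
      sample_id = id, species = "spA",
      speed_mean = mean(ind$speed), speed_var = var(ind$speed),
      linearity_mean = mean(ind$linearity), linearity_var = var(ind$linearity),
      size_mean = mean(ind$size), size_var = var(ind$size),
      shape_mean = mean(ind$shape), shape_var = var(ind$shape),
      traits_defined = TRUE)
    pool <- dplyr::bind_rows(mk(start, "s0"), mk(end, "s1"))
    std <- fit_standardization(pool)
    idx <- compute_index(pool, std)
    idx$mean_index[2] - idx$mean_index[1]
  })
  expect_lt(binom.test(sum(deltas > 0), length(deltas),
                       alternative = "greater")$p.value, 0.01)
})
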