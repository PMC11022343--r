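# Shared fixtures and independent oracles used across test files.

# Tiny degenerate design: cheap to simulate, still exercises every stage.
tiny_config <- function(...) {
  design_config(species = c("spA", "spB"), strains_per_species = 2,
                temperatures = c(20, 24), pollutant_levels = c(0, 20),
                dilution_fractions = c(0.2, 0.5, 0.8), replicates = 2,
                time_points = 3, frames_per_sample = 20, frame_rate = 10,
                arena = c(128L, 128L), ...)
}

# Independent ODE oracle: classic fixed-step RK4 on dN/dt = N (mu + alpha N).
rk4_growth <- function(mu, alpha, n0, dt, n_steps = 20000) {
  h <- dt / n_steps
  f <- function(n) n * (mu + alpha * n)
  n <- n0
  for (i in seq_len(n_steps)) {
    k1 <- f(n); k2 <- f(n + h * k1 / 2); k3 <- f(n + h * k2 / 2)
    k4 <- f(n + h * k3)
    n <- n + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  n
}

# Straight-line track fixture: n detections, fixed step, along +x.
straight_track <- function(n = 10, step = 5, track_id = 1L) {
  tibble::tibble(track_id = track_id, frame = 0:(n - 1),
                 x = step * (0:(n - 1)), y = 0,
                 area = 400, aspect = 2)
}

# Brute-force per-step path summation oracle for gross/net displacement.
path_oracle <- function(x, y) {
  list(gross = sum(sqrt(diff(x)^2 + diff(y)^2)),
       net = sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2))
}

# Leave-one-out Cook's distance oracle (definition, not the hat-matrix
# shortcut used by stats::cooks.distance).
cooks_oracle <- function(data) {
  fit <- lm(pcgr ~ n_start, data = data)
  p <- 2
  s2 <- sum(residuals(fit)^2) / (nrow(data) - p)
  yhat <- predict(fit)
  vapply(seq_len(nrow(data)), function(i) {
    fit_i <- lm(pcgr ~ n_start, data = data[-i, ])
    yhat_i <- predict(fit_i, newdata = data)
    sum((yhat - yhat_i)^2) / (p * s2)
  }, numeric(1))
}

# Noiseless 15-point dilution fixture on a known line, with design columns.
linear_observations <- function(mu = 1, alpha = -0.001,
                                n_start = rep(c(200, 350, 500, 650, 800), 3),
                                noise = 0) {
  tibble::tibble(
    condition_id = "fx", n_start = n_start,
    pcgr = mu + alpha * n_start + noise)
}

# One-species sample table carrying trait summaries, for index tests.
# Unspecified traits get small deterministic spread (pools must not be
# constant).
trait_samples <- function(speed, linearity = NULL, size = NULL, shape = NULL,
                          species = "spA") {
  n <- length(speed)
  spread <- seq_len(n) - (n + 1) / 2
  if (is.null(linearity)) linearity <- 0.8 + 0.01 * spread
  if (is.null(size)) size <- 400 + 5 * spread
  if (is.null(shape)) shape <- 2.5 + 0.05 * spread
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)), species = species,
    speed_mean = speed, speed_var = 0,
    linearity_mean = linearity, linearity_var = 0,
    size_mean = size, size_var = 0,
    shape_mean = shape, shape_var = 0,
    traits_defined = TRUE)
}
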