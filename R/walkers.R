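#' Map path linearity to a turning-angle concentration
#'
#' The correlated random walk draws successive turning angles from a von Mises
#' distribution with concentration `kappa`. Its mean cosine
#' `A(kappa) = I1(kappa)/I0(kappa)` is the per-step directional persistence;
#' the generator uses `A(kappa) = linearity` so a straight swimmer
#' (linearity 1) has infinite concentration and an uncorrelated one
#' (linearity about 0) turns uniformly.
#'
#' @param linearity Persistence target in (0, 1]; may be a vector.
#' @return Concentration `kappa` (possibly `Inf`).
#' @export
linearity_to_kappa <- function(linearity) {
  stopifnot(all(linearity > 0), all(linearity <= 1))
  vapply(linearity, function(l) {
    if (l >= 0.999999) return(Inf)
    stats::uniroot(function(k) kappa_to_linearity(k) - l,
                   interval = c(1e-8, 1e4), tol = 1e-10)$root
  }, numeric(1))
}

#' @rdname linearity_to_kappa
#' @param kappa von Mises concentration (>= 0).
#' @return `kappa_to_linearity()`: the mean cosine `A(kappa)`.
#' @export
kappa_to_linearity <- function(kappa) {
  ifelse(is.infinite(kappa), 1,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# von Mises(0, kappa) sampler, Best & Fisher rejection scheme.
rvonmises0 <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (is.infinite(kappa)) return(rep(0, n))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(max(min(f, 1), -1))
      i <- i + 1L
    }
  }
  out
}

#' Simulate correlated-random-walk swimmers
#'
#' Generates ground-truth tracks for `nrow(individuals)` cells over
#' `n_frames` frames. Each cell keeps a fixed ellipse (area, aspect ratio) and
#' a fixed speed; it moves with constant step length `speed / frame_rate` and
#' turning angles drawn von Mises with concentration mapped from its linearity
#' trait via [linearity_to_kappa()], so gross-displacement speed equals the
#' drawn speed and path straightness increases with linearity. Walkers reflect
#' at the arena border (reflected steps are flagged `clipped`).
#'
#' @param individuals Tibble/data frame with one row per cell and columns
#'   `speed` (px/s), `linearity` in (0, 1], `size` (area, px^2) and `shape`
#'   (aspect ratio >= 1).
#' @param n_frames Number of frames (>= 2).
#' @param frame_rate Frames per second.
#' @param arena `c(width, height)` in pixels.
#' @return A tibble with columns `track_id`, `frame` (0-based), `time` (s),
#'   `x`, `y` (pixels, top-left origin), `heading` (radians), `area`,
#'   `aspect`, `clipped`.
#' @examples
#' set.seed(1)
#' cells <- tibble::tibble(speed = 50, linearity = 0.99, size = 400, shape = 2)
#' tr <- simulate_individuals(cells, n_frames = 10, frame_rate = 10)
#' @export
simulate_individuals <- function(individuals, n_frames, frame_rate,
                                 arena = c(512L, 512L)) {
  if (n_frames < 2) abort("`n_frames` must be >= 2.")
  individuals <- tibble::as_tibble(individuals)
  need <- c("speed", "linearity", "size", "shape")
  if (!all(need %in% names(individuals))) {
    abort(paste("`individuals` needs columns:", paste(need, collapse = ", ")))
  }
  w <- arena[1]; h <- arena[2]
  out <- purrr::imap(split(individuals, seq_len(nrow(individuals))), function(ind, id) {
    step <- ind$speed / frame_rate
    kappa <- linearity_to_kappa(min(max(ind$linearity, 1e-6), 1))
    x <- numeric(n_frames); y <- numeric(n_frames)
    heading <- numeric(n_frames); clipped <- logical(n_frames)
    # start away from the border by one step where possible
    m <- min(step + 1, w / 4)
    x[1] <- runif(1, m, w - m); y[1] <- runif(1, m, h - m)
    heading[1] <- runif(1, -pi, pi)
    turns <- rvonmises0(n_frames - 1, kappa)
    for (f in 2:n_frames) {
      heading[f] <- heading[f - 1] + turns[f - 1]
      nx <- x[f - 1] + step * cos(heading[f])
      ny <- y[f - 1] + step * sin(heading[f])
      cl <- FALSE
      if (nx < 0) { nx <- -nx; heading[f] <- pi - heading[f]; cl <- TRUE }
      if (nx > w) { nx <- 2 * w - nx; heading[f] <- pi - heading[f]; cl <- TRUE }
      if (ny < 0) { ny <- -ny; heading[f] <- -heading[f]; cl <- TRUE }
      if (ny > h) { ny <- 2 * h - ny; heading[f] <- -heading[f]; cl <- TRUE }
      x[f] <- nx; y[f] <- ny; clipped[f] <- cl
    }
    tibble::tibble(
      track_id = as.integer(id),
      frame = 0:(n_frames - 1),
      time = (0:(n_frames - 1)) / frame_rate,
      x = x, y = y, heading = heading,
      area = ind$size, aspect = ind$shape, clipped = clipped
    )
  })
  dplyr::bind_rows(out)
}

#' Draw per-cell traits for a microcosm sample
#'
#' Traits are drawn independently per cell around the condition- and
#' crowding-adjusted strain means ([condition_trait_means()]), normal with the
#' profile's plasticity SDs; linearity is clipped to (0, 1], shape to >= 1,
#' size and speed to positive values.
#'
#' @param n Number of cells.
#' @param profile A [strain_profile()].
#' @param temperature,pollutant Treatment values.
#' @param crowding Density change since assay start relative to K.
#' @return Tibble with columns `speed`, `linearity`, `size`, `shape`.
#' @export
draw_individual_traits <- function(n, profile, temperature, pollutant,
                                   crowding = 0) {
  m <- condition_trait_means(profile, temperature, pollutant, crowding)
  s <- profile$trait_sd
  tibble::tibble(
    speed = pmax(rnorm(n, m[["speed"]], s[["speed"]]), 1e-3),
    linearity = pmin(pmax(rnorm(n, m[["linearity"]], s[["linearity"]]), 1e-3), 1),
    size = pmax(rnorm(n, m[["size"]], s[["size"]]), 1),
    shape = pmax(rnorm(n, m[["shape"]], s[["shape"]]), 1)
  )
}
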