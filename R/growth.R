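#' Logistic population growth, closed form
#'
#' Integrates `dN/dt = N (mu + alpha N)` exactly. With `alpha < 0` this is the
#' logistic curve with carrying capacity `K = -mu/alpha`; with `alpha = 0` it
#' reduces to exponential growth. The short-interval linearization of this
#' model, `ln(N(dt)/n0)/dt ~ mu + alpha n0`, is the per-capita growth-rate
#' regression fitted by [fit_curve()].
#'
#' @param mu Intrinsic per-capita growth rate (per day).
#' @param alpha Conspecific interaction coefficient (per day per cell/mL).
#' @param n0 Starting density (cells/mL, > 0).
#' @param dt Elapsed time (days); may be a vector.
#' @return Density after `dt` days (same length as `dt`).
#' @examples
#' grow_population(log(2), 0, 100, 1)        # doubles
#' grow_population(1, -0.001, 1000, 5)       # pinned at K = 1000
#' @export
grow_population <- function(mu, alpha, n0, dt) {
  if (!all(is.finite(c(mu, alpha, n0))) || !all(is.finite(dt))) {
    abort("`mu`, `alpha`, `n0` and `dt` must all be finite.")
  }
  if (n0 <= 0) abort("`n0` must be positive.")
  if (alpha == 0) return(n0 * exp(mu * dt))
  if (mu == 0) {
    # dN/dt = alpha N^2
    return(n0 / (1 - alpha * n0 * dt))
  }
  K <- -mu / alpha
  K / (1 + (K / n0 - 1) * exp(-mu * dt))
}

#' Observe a density through volumetric counting
#'
#' Draws the number of individuals counted in a finite sample volume and
#' converts it back to a density. Counts are Poisson with mean
#' `density x volume`; a positive `overdispersion` adds extra relative
#' variability via gamma-Poisson mixing (negative-binomial counts), emulating
#' cell clustering during sampling. The returned density has variance
#' `d / v + (overdispersion x d)^2` around the true density `d`.
#'
#' @param true_density True density (cells/mL, >= 0); may be a vector.
#' @param sample_volume_ml Counted volume in mL.
#' @param overdispersion Extra relative SD beyond Poisson (0 = pure Poisson).
#' @return Observed density (counted cells / volume), same length as input.
#' @examples
#' set.seed(1)
#' observe_density(1000, 0.81)
#' @export
observe_density <- function(true_density, sample_volume_ml, overdispersion = 0) {
  stopifnot(all(true_density >= 0), sample_volume_ml > 0, overdispersion >= 0)
  lambda <- true_density * sample_volume_ml
  if (overdispersion > 0) {
    shp <- 1 / overdispersion^2
    lambda <- lambda * rgamma(length(lambda), shape = shp, rate = shp)
  }
  rpois(length(lambda), lambda) / sample_volume_ml
}
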