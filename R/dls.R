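#' Scattering vector magnitude
#'
#' `q = (4 pi n / lambda) sin(theta / 2)` for light of vacuum wavelength
#' `lambda` scattered at angle `theta` in a medium of refractive index `n`.
#'
#' @param wavelength vacuum wavelength, nm.
#' @param angle scattering angle, degrees, in (0, 180).
#' @param refractive_index refractive index of the dispersant.
#' @return q, 1/m.
#' @export
scattering_vector <- function(wavelength = 633, angle = 173,
                              refractive_index = 1.33) {
  if (angle <= 0 || angle >= 180) stop("angle must be in (0, 180) degrees")
  if (wavelength <= 0 || refractive_index <= 0)
    stop("wavelength and refractive_index must be positive")
  4 * pi * refractive_index / (wavelength * 1e-9) * sin(angle * pi / 360)
}

#' DLS correlogram container
#'
#' Holds an intensity autocorrelation trace `g2(t)` together with the
#' long-time baseline, the coherence factor beta and the scattering vector.
#'
#' @param lag_times lag times, s, strictly increasing and positive.
#' @param g2 measured intensity autocorrelation values.
#' @param baseline long-time asymptote of g2 (typically 1).
#' @param beta coherence (intercept) factor, in (0, 1.2].
#' @param q scattering vector magnitude, 1/m.
#' @return A `hc_correlogram`.
#' @export
correlogram <- function(lag_times, g2, baseline = 1, beta = 0.9, q) {
  if (any(diff(lag_times) <= 0) || any(lag_times <= 0))
    stop("lag_times must be strictly increasing and positive")
  if (length(g2) != length(lag_times)) stop("g2 and lag_times lengths differ")
  if (beta <= 0 || beta > 1.2) stop("beta must be in (0, 1.2]")
  if (q <= 0) stop("q must be positive")
  structure(list(lag_times = as.numeric(lag_times), g2 = as.numeric(g2),
                 baseline = baseline, beta = beta, q = q),
            class = "hc_correlogram")
}

#' @export
print.hc_correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> %d lags [%.2g, %.2g] s, beta %.3g, q %.4g 1/m\n",
              length(x$lag_times), min(x$lag_times), max(x$lag_times),
              x$beta, x$q))
  invisible(x)
}

#' @export
as_tibble.hc_correlogram <- function(x, ...) {
  tibble::tibble(lag_s = x$lag_times, g2 = x$g2,
                 g1_squared = g1_squared(x))
}

#' Squared field autocorrelation via the Siegert relation
#'
#' `[g1(t)]^2 = (g2(t) - baseline) / beta`, clipped below at zero.
#'
#' @param corr a [correlogram()].
#' @param tolerance allowed overshoot above 1 before warning.
#' @return Numeric vector of `[g1]^2` values.
#' @export
g1_squared <- function(corr, tolerance = 0.05) {
  if (corr$beta <= 0) stop("beta must be positive")
  g1s <- pmax((corr$g2 - corr$baseline) / corr$beta, 0)
  if (any(g1s > 1 + tolerance))
    warning("[g1]^2 exceeds 1 beyond tolerance; check baseline/beta")
  g1s
}

#' Cumulant analysis of a DLS trace
#'
#' Weighted least-squares fit of
#' `ln g1 = c0 - Gamma t + (mu2/2) t^2 (- (mu3/6) t^3)`.  The fit is done
#' in two passes: a first-order fit on the high-amplitude points
#' (`[g1]^2 >= 0.1`) pins down the decay rate, which then defines both the
#' usable window (points where the *fitted* decay is above `floor`,
#' default 0.01, i.e. decay to 1% of the intercept -- using the fitted
#' rather than the measured amplitude keeps noise-bounced tail points from
#' entering the window) and the delog weights (squared predicted
#' amplitude, the inverse variance of `ln g1` under additive noise on
#' `g2`).  The polydispersity index is `mu2 / Gamma^2`.
#'
#' @param g1sq `[g1]^2` series (from [g1_squared()]).
#' @param lag_times lag times, s.
#' @param order 2 (default) or 3 cumulants.
#' @param floor usable-window floor on the fitted `[g1]^2` decay.
#' @return A `hc_cumulant` object with `gamma` (1/s), `pdi`, `mu2`, and the
#'   underlying `lm` fit; supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
cumulant_fit <- function(g1sq, lag_times, order = 2, floor = 0.01) {
  if (!order %in% c(2, 3)) stop("order must be 2 or 3")
  use0 <- which(g1sq >= max(floor, 0.1))
  if (length(use0) < 3)
    stop("too few high-amplitude points for the initial decay estimate (flat trace?)")
  f0 <- stats::lm(y ~ t, data = data.frame(y = 0.5 * log(g1sq[use0]),
                                           t = lag_times[use0]),
                  weights = g1sq[use0]^2)
  g0 <- -unname(stats::coef(f0)[2])
  if (!is.finite(g0) || g0 <= 0)
    stop("cumulant fit produced a non-positive decay rate (flat or rising trace?)")
  pred <- exp(-2 * g0 * lag_times)
  use <- which(pred >= floor & g1sq > 0)
  if (length(use) < 10)
    stop(sprintf("only %d usable points above the %.3g floor (need >= 10)",
                 length(use), floor))
  t <- lag_times[use]
  y <- 0.5 * log(g1sq[use])
  w <- pred[use]^2
  dat <- data.frame(y = y, t = t)
  fml <- if (order == 2) y ~ t + I(t^2) else y ~ t + I(t^2) + I(t^3)
  fit <- stats::lm(fml, data = dat, weights = w)
  cf <- stats::coef(fit)
  gamma <- -unname(cf[["t"]])
  mu2 <- 2 * unname(cf[["I(t^2)"]])
  if (!is.finite(gamma) || gamma <= 0)
    stop("cumulant fit produced a non-positive decay rate (flat or rising trace?)")
  structure(list(gamma = gamma, mu2 = mu2, pdi = max(mu2, 0) / gamma^2,
                 order = order, n_used = length(use), floor = floor,
                 fit = fit, lag_times = t, g1sq = g1sq[use]),
            class = "hc_cumulant")
}

#' @export
print.hc_cumulant <- function(x, ...) {
  cat(sprintf("<cumulant fit> Gamma = %.5g 1/s, PDI = %.4f (order %d, %d points)\n",
              x$gamma, x$pdi, x$order, x$n_used))
  invisible(x)
}

#' @export
tidy.hc_cumulant <- function(x, ...) {
  tibble::tibble(term = c("gamma", "mu2", "pdi"),
                 estimate = c(x$gamma, x$mu2, x$pdi))
}

#' @export
glance.hc_cumulant <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, mu2 = x$mu2, pdi = x$pdi,
                 n_used = x$n_used, order = x$order)
}

#' Diffusion coefficient from a DLS decay rate
#'
#' `D = Gamma / q^2`, converted to cm^2/s.
#'
#' @param gamma mean decay rate, 1/s.
#' @param q scattering vector, 1/m.
#' @return D, cm^2/s.
#' @export
diffusion_from_gamma <- function(gamma, q) {
  if (any(gamma <= 0) || any(q <= 0)) stop("gamma and q must be positive")
  gamma / q^2 * 1e4
}

#' Full DLS reduction: correlogram to D and r_h
#'
#' Siegert inversion, cumulant fit, `D = Gamma/q^2`, Stokes-Einstein
#' radius.
#'
#' @param corr a [correlogram()].
#' @param conditions a [solvent_conditions()].
#' @param order cumulant order (2 or 3).
#' @return One-row tibble: `gamma`, `pdi`, `D` (cm^2/s), `r_h` (nm).
#' @export
dls_analyze <- function(corr, conditions = solvent_conditions(), order = 2) {
  fit <- cumulant_fit(g1_squared(corr), corr$lag_times, order = order)
  D <- diffusion_from_gamma(fit$gamma, corr$q)
  tibble::tibble(gamma = fit$gamma, pdi = fit$pdi, D = D,
                 r_h = stokes_einstein_radius(D, conditions))
}
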