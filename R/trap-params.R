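#' Trap-insect system parameters
#'
#' Bundles the three quantities that characterise a trap-insect system:
#' `sptfer0`, the probability of catching an insect located in the immediate
#' proximity of the trap; `d50`, the distance (m) at which the catch
#' probability falls to half of `sptfer0`; and `rmax`, the radius (m) of the
#' trap collection area, beyond which the catch probability is zero.
#'
#' `rmax < d50` is mathematically admissible but suspicious (the half-catch
#' distance would lie outside the collection disk), so it triggers a warning
#' rather than an error.
#'
#' @param sptfer0 Catch probability at the trap, in (0, 1].
#' @param d50 Half-catch distance in meters, > 0.
#' @param rmax Collection-area radius in meters, > 0.
#' @param d50_sem Standard error of `d50` in meters (0 when unknown).
#' @param label Free-text name of the trap-insect system.
#' @return An object of class `"trap_params"`.
#' @examples
#' cm <- trap_params(sptfer0 = 0.7, d50 = 6.5, rmax = 260,
#'                   label = "codling moth / pheromone")
#' sp_t_fer(c(0, 6.5, 300), cm)
#' @export
trap_params <- function(sptfer0, d50, rmax, d50_sem = 0, label = "") {
  stopifnot(is.numeric(sptfer0), length(sptfer0) == 1L,
            is.numeric(d50), length(d50) == 1L,
            is.numeric(rmax), length(rmax) == 1L,
            is.numeric(d50_sem), length(d50_sem) == 1L)
  if (!is.finite(sptfer0) || sptfer0 <= 0 || sptfer0 > 1)
    stop("'sptfer0' must be a probability in (0, 1], got ", sptfer0)
  if (!is.finite(d50) || d50 <= 0)
    stop("'d50' must be a positive distance in meters, got ", d50)
  if (!is.finite(rmax) || rmax <= 0)
    stop("'rmax' must be a positive distance in meters, got ", rmax)
  if (d50_sem < 0)
    stop("'d50_sem' must be >= 0")
  if (rmax < d50)
    warning("rmax (", rmax, " m) is smaller than d50 (", d50,
            " m): the half-catch distance lies outside the collection area")
  structure(
    list(sptfer0 = sptfer0, d50 = d50, d50_sem = d50_sem,
         rmax = rmax, label = as.character(label)),
    class = "trap_params")
}

#' @export
print.trap_params <- function(x, ...) {
  cat("Trap-insect system", if (nzchar(x$label)) paste0(": ", x$label), "\n")
  cat(sprintf("  spTfer(0) = %.4g\n", x$sptfer0))
  cat(sprintf("  D50       = %.4g m%s\n", x$d50,
              if (x$d50_sem > 0) sprintf(" (SEM %.3g)", x$d50_sem) else ""))
  cat(sprintf("  Rmax      = %.4g m\n", x$rmax))
  cat(sprintf("  mu        = %.4g insects/m2 per caught insect (%.4g /ha)\n",
              compute_mu(x), compute_mu(x) * 1e4))
  invisible(x)
}

#' Catch probability at distance r
#'
#' The universal catch-probability curve: an insect located `r` meters from
#' the trap is eventually caught (over the converged-catch interval) with
#' probability `sptfer0 / (1 + (r/d50)^2)` for distances up to `rmax`, and 0 beyond
#' `rmax`. The boundary distance `rmax` itself uses the non-zero branch (closed
#' interval).
#'
#' @param r Distance(s) from the trap in meters, >= 0. Vectorised.
#' @param params A [trap_params()] object.
#' @return Catch probabilities in `[0, sptfer0]`.
#' @export
sp_t_fer <- function(r, params) {
  stopifnot(inherits(params, "trap_params"), is.numeric(r))
  if (any(!is.finite(r)) || any(r < 0))
    stop("distances 'r' must be finite and >= 0")
  p <- params$sptfer0 / (1 + (r / params$d50)^2)
  p[r > params$rmax] <- 0
  p
}

#' Log catch probability at distance r
#'
#' Natural logarithm of [sp_t_fer()], the form fitted to log-transformed
#' recapture proportions. Undefined beyond `rmax` (log of zero), so
#' distances beyond `rmax` are an error.
#'
#' @inheritParams sp_t_fer
#' @return `log(sptfer0) - log(1 + (r/d50)^2)`, vectorised over `r`.
#' @export
ln_sp_t_fer <- function(r, params) {
  stopifnot(inherits(params, "trap_params"), is.numeric(r))
  if (any(!is.finite(r)) || any(r < 0))
    stop("distances 'r' must be finite and >= 0")
  if (any(r > params$rmax))
    stop("ln_sp_t_fer is undefined beyond rmax (catch probability is 0)")
  log(params$sptfer0) - log1p((r / params$d50)^2)
}

#' Catch-to-density conversion constant mu
#'
#' The constant that converts a trap catch into an average population
#' density over the collection area:
#' \deqn{\mu = \frac{1}{spTfer(0)\,\pi D_{50}^2 \ln(1 + (R_{max}/D_{50})^2)}}
#' so that the most probable density given a catch of `M` insects is
#' `mu * M` (insects per square meter; multiply by 10,000 for per hectare).
#' `1/mu` equals the integral of the catch-probability curve over the
#' collection disk, i.e. the expected catch per unit density.
#'
#' The dependence on `rmax` is only logarithmic, so a rough estimate of the
#' collection radius suffices in practice.
#'
#' @param params A [trap_params()] object.
#' @return mu in insects per m2 per caught insect (> 0).
#' @examples
#' compute_mu(trap_params(1, 1, 1))   # 1 / (pi * log(2))
#' @export
compute_mu <- function(params) {
  stopifnot(inherits(params, "trap_params"))
  1 / (params$sptfer0 * pi * params$d50^2 *
         log1p((params$rmax / params$d50)^2))
}

#' Expected trap catch for a radial density profile
#'
#' Numerically integrates the catch-probability curve against a radially
#' symmetric density profile rho(r) over the collection disk:
#' `2 * pi * integral_0^rmax sp_t_fer(r) * rho(r) * r dr`.
#' For a spatially constant density `rho_bar` this equals
#' `rho_bar / compute_mu(params)` (the quadrature cross-check of the
#' closed-form mu).
#'
#' @param profile Either a single non-negative number (a constant density,
#'   insects per m2) or a function of distance `r` (m) returning density.
#' @param params A [trap_params()] object.
#' @param rel.tol,abs.tol Quadrature tolerances passed to
#'   [stats::integrate()].
#' @return Expected number of insects caught over the converged-catch
#'   interval.
#' @export
expected_catch <- function(profile, params, rel.tol = 1e-9, abs.tol = 1e-9) {
  stopifnot(inherits(params, "trap_params"))
  if (is.numeric(profile) && length(profile) == 1L) {
    rho_bar <- profile
    if (!is.finite(rho_bar) || rho_bar < 0)
      stop("constant density must be finite and >= 0")
    profile <- function(r) rep_len(rho_bar, length(r))
  }
  if (!is.function(profile))
    stop("'profile' must be a constant density or a function of distance")
  integrand <- function(r) {
    rho <- profile(r)
    if (any(!is.finite(rho)))
      stop("density profile returned non-finite values")
    if (any(rho < 0))
      stop("density profile returned negative values")
    sp_t_fer(r, params) * rho * r
  }
  q <- stats::integrate(integrand, 0, params$rmax,
                        rel.tol = rel.tol, abs.tol = abs.tol,
                        subdivisions = 500L)
  2 * pi * q$value
}
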