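check_catch <- function(m) {
  if (!is.numeric(m) || length(m) < 1L || any(!is.finite(m)) ||
      any(m < 0) || any(m != round(m)))
    stop("trap catch 'M' must be a non-negative integer count ",
         "(the degrees of freedom of the bounds are 2M and 2M+2)")
  as.integer(round(m))
}

#' Exact confidence bounds for the population density
#'
#' Garwood-type exact bounds for the average population density over the
#' trap collection area, given an observed trap catch `M` (a Poisson
#' count):
#' \deqn{\frac{\mu}{2}\chi^2\!\left(\frac{1-p}{2};\,2M\right)
#'   \le \bar\rho \le
#'   \frac{\mu}{2}\chi^2\!\left(1-\frac{1-p}{2};\,2M+2\right)}
#' where \eqn{\chi^2(q; n)} is the lower-tail quantile of the chi-squared
#' distribution with `n` degrees of freedom, taken as identically 0 at
#' `n = 0` so the `M = 0` lower bound is 0. The interval is exact and
#' conservative: its coverage is at least `p` for every true density.
#'
#' @param m Observed trap catch(es), non-negative integer(s). Vectorised.
#' @param mu Catch-to-density constant from [compute_mu()], per m2.
#' @param p Confidence level in (0, 1); default 0.95.
#' @return A two-column matrix with columns `lower` and `upper`
#'   (insects per m2), one row per element of `m`.
#' @export
density_bounds <- function(m, mu, p = 0.95) {
  m <- check_catch(m)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single positive number")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("confidence level 'p' must be in (0, 1)")
  alpha <- (1 - p) / 2
  lower <- ifelse(m == 0, 0, mu / 2 * stats::qchisq(alpha, df = 2 * m))
  upper <- mu / 2 * stats::qchisq(1 - alpha, df = 2 * m + 2)
  cbind(lower = lower, upper = upper)
}

#' Most probable population density given a trap catch
#'
#' The mode of the density given the observed count: `mu * M` insects per
#' m2 (multiply by 10,000 for insects per hectare).
#'
#' @inheritParams density_bounds
#' @return Density in insects per m2, vectorised over `m`.
#' @export
most_probable_density <- function(m, mu) {
  m <- check_catch(m)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single positive number")
  mu * m
}

#' Estimate the absolute population density from a single trap catch
#'
#' Composes the catch-to-density constant, the most probable density and
#' its exact bounds into one report. All densities are carried both in SI
#' units (insects per m2) and in the management-friendly insects per
#' hectare (x 10,000).
#'
#' A zero catch still carries information: the most probable density is 0
#' but the upper bound is positive, i.e. the population density cannot
#' exceed a specific detection threshold at the stated confidence.
#'
#' @param m Observed trap catch, a non-negative integer.
#' @param params A [trap_params()] object.
#' @param p Confidence level in (0, 1); default 0.95.
#' @return An object of class `"density_estimate"`: a list with `m_caught`,
#'   `mu`, `rho_mp`, `lower`, `upper` (per m2), the same four per ha, and
#'   `confidence`.
#' @examples
#' estimate_density(3, trap_preset("codling_moth"))
#' @export
estimate_density <- function(m, params, p = 0.95) {
  stopifnot(inherits(params, "trap_params"))
  m <- check_catch(m)
  if (length(m) != 1L) stop("'m' must be a single catch; see density_table()")
  mu <- compute_mu(params)
  b <- density_bounds(m, mu, p)
  lower <- unname(b[1L, "lower"]); upper <- unname(b[1L, "upper"])
  structure(
    list(label = params$label, params = params,
         m_caught = m, confidence = p,
         mu = mu, rho_mp = most_probable_density(m, mu),
         lower = lower, upper = upper,
         mu_per_ha = mu * 1e4,
         rho_mp_per_ha = most_probable_density(m, mu) * 1e4,
         lower_per_ha = lower * 1e4,
         upper_per_ha = upper * 1e4),
    class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat("Population density from a single trap catch\n")
  if (nzchar(x$label)) cat("  system:    ", x$label, "\n")
  cat("  catch M =", x$m_caught,
      sprintf("  (confidence %.3g)\n", x$confidence))
  cat(sprintf("  mu        = %.4g /m2 per insect  (%.4g /ha)\n",
              x$mu, x$mu_per_ha))
  cat(sprintf("  rho_mp    = %.4g /m2  (%.4g /ha)\n",
              x$rho_mp, x$rho_mp_per_ha))
  cat(sprintf("  bounds    = [%.4g, %.4g] /m2  ([%.4g, %.4g] /ha)\n",
              x$lower, x$upper, x$lower_per_ha, x$upper_per_ha))
  invisible(x)
}

#' Density bounds over a range of catches
#'
#' The lower bound, most probable density and upper bound as a function of
#' the trap count, i.e. the table behind density-versus-catch band plots.
#'
#' @param params A [trap_params()] object.
#' @param m Vector of catches (default `0:30`).
#' @param p Confidence level.
#' @param units `"m2"` or `"ha"`.
#' @return A data frame with columns `m`, `lower`, `rho_mp`, `upper`.
#' @export
density_table <- function(params, m = 0:30, p = 0.95,
                          units = c("ha", "m2")) {
  stopifnot(inherits(params, "trap_params"))
  units <- match.arg(units)
  m <- check_catch(m)
  mu <- compute_mu(params)
  b <- density_bounds(m, mu, p)
  scale <- if (units == "ha") 1e4 else 1
  data.frame(m = m,
             lower = unname(b[, "lower"]) * scale,
             rho_mp = most_probable_density(m, mu) * scale,
             upper = unname(b[, "upper"]) * scale)
}

#' Serialize a density estimate to JSON
#'
#' @param est A `"density_estimate"` object.
#' @param path Optional output path.
#' @return The JSON string, invisibly when `path` is given.
#' @export
density_to_json <- function(est, path = NULL) {
  stopifnot(inherits(est, "density_estimate"))
  obj <- list(
    label = est$label,
    sptfer0 = est$params$sptfer0,
    d50_m = est$params$d50,
    rmax_m = est$params$rmax,
    M = est$m_caught,
    confidence = est$confidence,
    mu_per_ha = est$mu_per_ha,
    rho_mp_per_ha = est$rho_mp_per_ha,
    lower_per_ha = est$lower_per_ha,
    upper_per_ha = est$upper_per_ha)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
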