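#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# Deterministic, scale-aware starting values: sptfer0 from the largest
# observed proportion, d50 from the median distance whose proportion is
# still at least half of that maximum.
start_values <- function(distance, proportion) {
  p0 <- max(proportion, na.rm = TRUE)
  high <- distance[proportion >= p0 / 2 & !is.na(proportion)]
  d0 <- stats::median(high)
  if (!is.finite(d0) || d0 <= 0)
    d0 <- max(min(distance[distance > 0]), 1)
  list(sptfer0 = min(p0, 1), d50 = d0)
}

# Bounded Levenberg-Marquardt on an explicit residual function. The
# low-level optimizer is used (rather than an nls wrapper) so that
# boundary and rank-deficient solutions -- e.g. perfectly flat recapture
# data, where d50 is unidentifiable -- still return the least-squares
# point instead of erroring while post-processing.
run_lm <- function(resid_fn, start, lower, upper, step) {
  out <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (out$info == 0L || out$info == 5L)
    stop(step, " fit did not converge: ", out$message,
         " (", out$niter, " iterations)")
  out
}

fit_weights <- function(ds, weighted, scale = c("linear", "log")) {
  if (!weighted) return(NULL)
  scale <- match.arg(scale)
  if (all(is.na(ds$sem)))
    stop("weighted fitting requested but the dataset carries no SEM")
  sem <- ds$sem
  if (scale == "log") sem <- sem / ds$proportion  # delta method for ln p
  if (any(!is.finite(sem)) || any(sem <= 0))
    stop("weighted fitting needs finite positive SEM for every record used")
  1 / sem^2
}

# Model-based (delta-method) variance of ln(sptfer0-hat) from the step-1
# fit: sandwich form A^-1 B A^-1 with binomial variances p(1-p)/n at the
# fitted proportions. Returns 0 when the curvature matrix is singular.
var_ln_sptfer0_step1 <- function(ds, sptfer0, d50) {
  use <- ds[ds$released > 0, , drop = FALSE]
  u <- (use$distance / d50)^2
  G <- cbind(1 / (1 + u), sptfer0 * 2 * u / (d50 * (1 + u)^2))
  phat <- sptfer0 / (1 + u)
  sig2 <- phat * (1 - phat) / use$released
  tryCatch({
    A <- solve(crossprod(G))
    V <- A %*% crossprod(G * sig2, G) %*% A
    max(V[1, 1], 0) / sptfer0^2
  }, error = function(e) 0)
}

# Mean squared error of ln(X/n) about ln(p) for X ~ Binomial(n, p)
# conditioned on X > 0 (zero-catch records never reach the log fit),
# summed over the pmf. For well-sampled records (np >> 1) this reduces to
# the familiar (1-p)/(np); for sparse records (np << 1, e.g. one recapture
# out of 100 at a far distance) the log proportion is dominated by
# zero-truncation bias rather than variance, and the first-order delta
# value understates the record's contribution to the d50 error by orders
# of magnitude.
mse_ln_prop <- function(n, p) {
  mapply(function(n, p) {
    lam <- n * p
    if (!is.finite(lam) || lam <= 0) return(Inf)
    sdx <- sqrt(lam * (1 - p))
    x <- 1:min(n, max(20, ceiling(lam + 10 * sdx + 10)))
    w <- stats::dbinom(x, n, p)
    if (sum(w) <= 0) return((1 - p) / lam)
    w <- w / sum(w)
    sum(w * (log(x) - log(lam))^2)
  }, n, p)
}

# Model-based SEM of the step-2 d50 estimate. The unweighted log-scale
# least-squares estimator has sampling variance
#   sum(J_i^2 s_i^2) / (sum J_i^2)^2
# with J_i the model gradient in d50 and s_i^2 the mean squared error of
# the log recapture proportion under binomial sampling at the fitted
# proportion (exact, zero-truncated). An sptfer0 estimated in step 1
# shifts the log curve bodily, moving d50 by (sum J_i / sum J_i^2) per
# unit of ln sptfer0; its variance is propagated through that factor.
# The naive OLS covariance (homoscedastic residual variance x inverse
# curvature) understates the replicate-to-replicate SD of d50 by roughly
# a factor 2 under binomial recapture noise, because the noisiest (far,
# low-catch) records are also the most informative about d50.
sem_d50_model <- function(use, sptfer0, d50, var_ln_sptfer0 = 0) {
  u <- (use$distance / d50)^2
  J <- (2 / d50) * u / (1 + u)
  phat <- sptfer0 / (1 + u)
  sig2 <- mse_ln_prop(use$released, phat)
  if (any(!is.finite(sig2)) || sum(J^2) == 0) return(NA_real_)
  sqrt(sum(J^2 * sig2) / sum(J^2)^2 +
         (sum(J) / sum(J^2))^2 * var_ln_sptfer0)
}

#' Step 1: estimate spTfer(0) and D50 from untransformed proportions
#'
#' Bounded nonlinear least squares of the catch-probability curve
#' `p = sptfer0 / (1 + (d/d50)^2)` on the untransformed (distance,
#' proportion) pairs, both parameters free, `sptfer0` constrained to (0, 1]
#' and `d50 > 0`. In the two-step protocol only the `sptfer0` estimate is
#' retained from this step; short-distance points dominate the
#' untransformed loss, so its `d50` is provisional.
#'
#' @param ds A [release_recapture()] dataset with at least 4 distances and
#'   at least 2 non-zero proportions.
#' @param weighted Weight records by `1/sem^2` (requires SEM).
#' @return A list with `sptfer0`, `d50` and the underlying `nls` fit.
#' @export
fit_step1_untransformed <- function(ds, weighted = FALSE) {
  stopifnot(inherits(ds, "release_recapture"))
  use <- ds[ds$released > 0, , drop = FALSE]
  if (length(unique(use$distance)) < 4L)
    stop("step 1 needs at least 4 distances with releases")
  if (sum(use$proportion > 0) < 2L)
    stop("step 1 needs at least 2 non-zero recapture proportions")
  st <- start_values(use$distance, use$proportion)
  w <- fit_weights(use, weighted, "linear")
  sw <- if (is.null(w)) 1 else sqrt(w)
  d <- use$distance; p <- use$proportion
  fit <- run_lm(
    function(par) sw * (p - par[1] / (1 + (d / par[2])^2)),
    start = c(sptfer0 = st$sptfer0, d50 = st$d50),
    lower = c(1e-9, 1e-9), upper = c(1, Inf), step = "step-1")
  co <- stats::coef(fit)
  list(sptfer0 = unname(co["sptfer0"]), d50 = unname(co["d50"]),
       var_ln_sptfer0 = var_ln_sptfer0_step1(use, unname(co["sptfer0"]),
                                             unname(co["d50"])),
       fit = fit)
}

#' Step 2: estimate D50 from log-transformed proportions at fixed spTfer(0)
#'
#' One-parameter least squares of `ln p = ln sptfer0 - ln(1 + (d/d50)^2)`
#' on the log-transformed proportions, with `sptfer0` held fixed. The log
#' transform gives the (small) catches at large distances equal weight to
#' the catches near the trap, which is what makes `d50` well determined by
#' unbalanced field designs. Zero-proportion records are excluded (their
#' log is undefined); no pseudo-count is added, as that would silently
#' change the estimator.
#'
#' The reported `d50_sem` is model-based: the sampling variance of the
#' least-squares estimator under binomial recapture noise at the fitted
#' proportions (delta method on the log scale), plus, when `sptfer0` was
#' itself estimated in step 1, the variance propagated from that estimate.
#' This keeps the SEM calibrated against the true replicate-to-replicate
#' spread, which the homoscedastic least-squares covariance understates for
#' recapture data.
#'
#' @param ds A [release_recapture()] dataset.
#' @param sptfer0 The fixed catch probability at the trap, in (0, 1].
#' @param weighted Weight records by the delta-method log-scale SEM.
#' @param var_ln_sptfer0 Variance of `log(sptfer0)` when `sptfer0` carries
#'   estimation uncertainty (0, the default, treats it as known exactly).
#' @return A list with `d50`, `d50_sem`, the indices of `excluded`
#'   records, and the `nls` fit.
#' @export
fit_step2_log <- function(ds, sptfer0, weighted = FALSE,
                          var_ln_sptfer0 = 0) {
  stopifnot(inherits(ds, "release_recapture"))
  if (!is.numeric(sptfer0) || length(sptfer0) != 1L ||
      !is.finite(sptfer0) || sptfer0 <= 0 || sptfer0 > 1)
    stop("'sptfer0' must be a probability in (0, 1]")
  excluded <- which(!(ds$proportion > 0) | !is.finite(ds$proportion))
  use <- if (length(excluded)) ds[-excluded, , drop = FALSE] else ds
  if (nrow(use) < 2L)
    stop("step 2 needs at least 2 records with positive catch")
  st <- start_values(use$distance, use$proportion)
  w <- fit_weights(use, weighted, "log")
  sw <- if (is.null(w)) 1 else sqrt(w)
  d <- use$distance; lnp <- log(use$proportion); ln0 <- log(sptfer0)
  fit <- run_lm(
    function(par) sw * (lnp - (ln0 - log1p((d / par[1])^2))),
    start = c(d50 = st$d50),
    lower = 1e-9, upper = Inf, step = "step-2")
  d50 <- unname(stats::coef(fit))
  sem <- sem_d50_model(use, sptfer0, d50, var_ln_sptfer0)
  if (!is.finite(sem)) {
    # fall back to the homoscedastic least-squares covariance
    u <- (d / d50)^2
    J <- sw * (2 / d50) * u / (1 + u)
    rss <- sum((sw * (lnp - ln0 + log1p(u)))^2)
    sem <- sqrt(rss / max(length(d) - 1L, 1L) / sum(J^2))
  }
  list(d50 = d50, d50_sem = sem, excluded = excluded, fit = fit)
}

trap_fit_result <- function(ds, params, method, excluded, step2_fit,
                            weighted) {
  use <- if (length(excluded)) ds[-excluded, , drop = FALSE] else ds
  # continuous branch of the curve: the fit itself has no rmax cutoff
  predicted <- params$sptfer0 / (1 + (use$distance / params$d50)^2)
  r_corr <- if (nrow(use) >= 3L && stats::sd(use$proportion) > 0)
    stats::cor(use$proportion, predicted) else NA_real_
  residuals <- stats::setNames(log(predicted) - log(use$proportion),
                               use$distance)
  structure(
    list(params = params, method = method,
         r_correlation = r_corr,
         residuals = residuals,           # model - observed, log scale
         n_points_used = nrow(use),
         excluded_points = data.frame(
           distance = ds$distance[excluded],
           reason = rep_len("zero catch (log undefined in step 2)",
                            length(excluded))),
         weighted = weighted,
         dataset = ds),
    class = "trap_fit")
}

#' @export
print.trap_fit <- function(x, ...) {
  cat("Catch-probability curve fit (method:", x$method, "\b)\n")
  cat(sprintf("  spTfer(0) = %.4g\n", x$params$sptfer0))
  cat(sprintf("  D50       = %.4g +/- %.3g m\n",
              x$params$d50, x$params$d50_sem))
  cat(sprintf("  R         = %.3f  (observed vs predicted proportions)\n",
              x$r_correlation))
  cat(sprintf("  points used: %d; excluded: %d\n",
              x$n_points_used, nrow(x$excluded_points)))
  invisible(x)
}

#' Two-step fit of the catch-probability curve
#'
#' The fitting protocol for release-recapture data that lack an empirical
#' measurement of `spTfer(0)`. Step 1 fits the untransformed proportions
#' with both parameters free and retains the `sptfer0` estimate; step 2
#' fixes that `sptfer0` and refits `d50` alone on the log-transformed
#' proportions, so that catches at large distances carry weight equal to
#' catches near the trap. When `spTfer(0)` has been measured in the field,
#' use [fit_fixed_sptfer0()] instead.
#'
#' @param ds A [release_recapture()] dataset.
#' @param rmax Collection-area radius (m) for the resulting parameter set;
#'   it is not estimable from recapture proportions alone, so it defaults
#'   to the largest release distance.
#' @param weighted Weight records by their SEM (opt-in; default is ordinary
#'   least squares in both steps).
#' @return A `"trap_fit"` object: the fitted [trap_params()], the method
#'   tag, the goodness-of-fit correlation R between observed and predicted
#'   proportions (untransformed scale, non-excluded points), per-record
#'   log-scale residuals and the list of excluded records.
#' @export
fit_two_step <- function(ds, rmax = max(ds$distance), weighted = FALSE) {
  stopifnot(inherits(ds, "release_recapture"))
  validate_recapture(ds)
  s1 <- fit_step1_untransformed(ds, weighted = weighted)
  s2 <- fit_step2_log(ds, sptfer0 = s1$sptfer0, weighted = weighted,
                      var_ln_sptfer0 = s1$var_ln_sptfer0)
  params <- trap_params(sptfer0 = s1$sptfer0, d50 = s2$d50, rmax = rmax,
                        d50_sem = s2$d50_sem,
                        label = attr(ds, "species"))
  trap_fit_result(ds, params, "two_step", s2$excluded, s2$fit, weighted)
}

#' Fit D50 with an empirically measured spTfer(0)
#'
#' Single-step variant of [fit_two_step()] for datasets where the catch
#' probability at the trap was measured directly in the field: only the
#' log-scale step is run, with `sptfer0` fixed at the measured value.
#'
#' @inheritParams fit_two_step
#' @param sptfer0 The measured catch probability at the trap, in (0, 1].
#' @return A `"trap_fit"` object with method `"fixed_sptfer0"`.
#' @export
fit_fixed_sptfer0 <- function(ds, sptfer0, rmax = max(ds$distance),
                              weighted = FALSE) {
  stopifnot(inherits(ds, "release_recapture"))
  validate_recapture(ds)
  s2 <- fit_step2_log(ds, sptfer0 = sptfer0, weighted = weighted)
  params <- trap_params(sptfer0 = sptfer0, d50 = s2$d50, rmax = rmax,
                        d50_sem = s2$d50_sem,
                        label = attr(ds, "species"))
  trap_fit_result(ds, params, "fixed_sptfer0", s2$excluded, s2$fit, weighted)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `"trap_fit"` object.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "trap_fit"))
  obj <- list(
    label = fit$params$label,
    method = fit$method,
    sptfer0 = fit$params$sptfer0,
    d50_m = fit$params$d50,
    d50_sem_m = fit$params$d50_sem,
    rmax_m = fit$params$rmax,
    r_correlation = fit$r_correlation,
    n_points_used = fit$n_points_used,
    excluded = fit$excluded_points,
    residuals_log_scale = as.list(fit$residuals))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
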