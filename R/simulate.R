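#' Simulate a release-recapture experiment
#'
#' Draws synthetic recapture counts for a ladder of release distances under
#' the catch-probability curve: at each distance the number recaptured is
#' Binomial(`n_released`, `sp_t_fer(distance)`). Cohorts at different
#' distances are independent (a single trap, no competition). Recapture is
#' binomial rather than Poisson because each release cohort is finite and
#' the recapture proportion is bounded by 1.
#'
#' Releases beyond `rmax` are allowed (they yield structurally zero
#' catches) but warned about, since they carry no information about the
#' curve.
#'
#' @param params A [trap_params()] object (the ground truth).
#' @param distances Release distances in meters.
#' @param n_released Insects released per distance; recycled to
#'   `length(distances)`.
#' @param seed Optional integer seed; identical seeds give identical
#'   datasets.
#' @param replicates Number of independent datasets to draw.
#' @return A [release_recapture()] dataset, or a list of them when
#'   `replicates > 1`.
#' @examples
#' truth <- trap_params(0.37, 27.3, 1600)
#' sim <- simulate_recapture(truth, c(0, 15, 50, 150, 500), 100, seed = 1)
#' @export
simulate_recapture <- function(params, distances, n_released, seed = NULL,
                               replicates = 1L) {
  stopifnot(inherits(params, "trap_params"), is.numeric(distances),
            is.numeric(n_released), replicates >= 1L)
  if (any(distances > params$rmax))
    warning("release distance(s) beyond rmax yield structurally zero catch")
  n_released <- rep_len(n_released, length(distances))
  if (!is.null(seed)) set.seed(seed)
  prob <- sp_t_fer(distances, params)
  one <- function() {
    caught <- stats::rbinom(length(distances), size = n_released, prob = prob)
    release_recapture(distances, n_released, caught,
                      species = params$label, trap_type = "simulated")
  }
  if (replicates == 1L) one() else replicate(replicates, one(),
                                             simplify = FALSE)
}

#' Simulate trap catches from a uniform wild population
#'
#' Draws trap counts for a spatially uniform population of density `rho`:
#' `M ~ Poisson(rho / mu)`, whose mean equals the expected catch of the
#' constant-density profile. The wild population is unbounded, so the count
#' is Poisson -- the sampling model under which the chi-square density
#' bounds are exact.
#'
#' @param rho True average density in insects per m2, >= 0.
#' @param params A [trap_params()] object.
#' @param seed Optional integer seed.
#' @param n Number of independent catches to draw.
#' @return Integer vector of length `n`.
#' @export
simulate_trap_catch <- function(rho, params, seed = NULL, n = 1L) {
  stopifnot(inherits(params, "trap_params"))
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho < 0)
    stop("'rho' must be a single finite density >= 0")
  if (!is.null(seed)) set.seed(seed)
  stats::rpois(n, lambda = rho / compute_mu(params))
}
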