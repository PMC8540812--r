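# Exact (noiseless) recapture dataset: proportions equal the model curve.
noiseless_ds <- function(params, distances) {
  release_recapture(distances, released = 1,
                    caught = sp_t_fer(distances, params))
}

# Random admissible parameter sets for property-style loops.
random_params <- function(n) {
  lapply(seq_len(n), function(i) {
    d50 <- stats::runif(1, 2, 300)
    trap_params(sptfer0 = stats::runif(1, 0.02, 1),
                d50 = d50,
                rmax = d50 * stats::runif(1, 1.2, 30))
  })
}

# Distance ladder used in recovery experiments: multiples of d50, capped at
# the collection radius.
recovery_ladder <- function(params)
  unique(pmin(params$d50 * c(0, 0.25, 0.5, 1, 2, 4, 8, 16), params$rmax))

# Release distances of the reference pheromone-trap experiment design.
ldispar_distances <- c(0, 15, 25, 30, 45, 50, 60, 75, 80, 100, 150, 200,
                       250, 300, 500, 600, 900, 1000, 1200, 1500)
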