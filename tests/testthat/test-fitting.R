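test_that("noiseless data identify both parameters to solver tolerance", {
  truth <- trap_params(0.4, 30, 1000)
  ds <- noiseless_ds(truth, c(0, 10, 20, 40, 80, 160, 320, 640))
  s1 <- fit_step1_untransformed(ds)
  expect_equal(s1$sptfer0, 0.4, tolerance = 1e-4)
  expect_equal(s1$d50, 30, tolerance = 1e-4)
  f <- fit_two_step(ds, rmax = 1000)
  expect_equal(f$params$sptfer0, 0.4, tolerance = 1e-4)
  expect_equal(f$params$d50, 30, tolerance = 1e-4)
  expect_equal(f$method, "two_step")
  expect_equal(f$r_correlation, 1, tolerance = 1e-6)
})

test_that("log-scale step recovers d50 alone, on any >=2-point subset", {
  truth <- trap_params(0.37, 27.3, 1600)
  d <- c(0, 15, 30, 60, 120, 240, 480, 960)
  ds <- noiseless_ds(truth, d)
  s2 <- fit_step2_log(ds, sptfer0 = 0.37)
  expect_equal(s2$d50, 27.3, tolerance = 1e-4)
  # any two-point subset identifies the one-parameter log fit exactly
  sub <- noiseless_ds(truth, c(120, 960))
  expect_equal(fit_step2_log(sub, 0.37)$d50, 27.3, tolerance = 1e-4)
  # an sptfer0 above every observed proportion only shifts the intercept
  expect_no_error(fit_step2_log(ds, sptfer0 = 0.9))
})

test_that("rescaling distances rescales d50 exactly", {
  truth <- trap_params(0.2, 50, 2000)
  d <- c(0, 25, 50, 100, 200, 400, 800)
  ds_m <- noiseless_ds(truth, d)
  km <- release_recapture(d / 1000, 1, sp_t_fer(d, truth))
  expect_equal(fit_step2_log(km, 0.2)$d50 * 1000,
               fit_step2_log(ds_m, 0.2)$d50, tolerance = 1e-6)
})

test_that("flat proportions near the origin pin sptfer0 at their level", {
  # all distances far below d50: the curve is flat at sptfer0
  ds <- release_recapture(c(0, 1, 2, 3, 4), 1000, 300)
  s1 <- fit_step1_untransformed(ds)
  expect_equal(s1$sptfer0, 0.3, tolerance = 1e-3)
})

test_that("zero-catch records are excluded from the log step, with bookkeeping", {
  truth <- trap_params(0.3, 20, 500)
  d <- c(0, 10, 20, 40, 80, 160, 320)
  p <- sp_t_fer(d, truth)
  caught <- round(p * 500)
  caught[5] <- 0  # interior zero
  ds <- release_recapture(d, 500, caught)
  expect_warning(f <- fit_two_step(ds, rmax = 500), "criterion 3")
  expect_equal(nrow(f$excluded_points), 1L)
  expect_equal(f$excluded_points$distance, 80)
  expect_equal(f$n_points_used + nrow(f$excluded_points), nrow(ds))
  expect_match(f$excluded_points$reason, "zero catch")
})

test_that("two-step fit recovers d50 within 3 SEM on simulated cohorts", {
  truth <- trap_params(0.09, 250, 1040, label = "sawfly-like")
  ds <- simulate_recapture(truth, recovery_ladder(truth), 1e4, seed = 11)
  f <- fit_two_step(ds, rmax = 1040)
  expect_lt(abs(f$params$d50 - 250), 3 * f$params$d50_sem)
  expect_gt(f$r_correlation, 0.9)
  # single-step variant with the true sptfer0
  ff <- fit_fixed_sptfer0(ds, 0.09, rmax = 1040)
  expect_equal(ff$method, "fixed_sptfer0")
  expect_lt(abs(ff$params$d50 - 250), 3 * ff$params$d50_sem)
})

test_that("reported SEM tracks the replicate-to-replicate spread", {
  truth <- trap_params(0.37, 27.3, 1600)
  d <- recovery_ladder(truth)
  withr::with_seed(13, {
    est <- sem <- numeric(30)
    for (i in seq_along(est)) {
      ds <- simulate_recapture(truth, d, 5000)
      f <- fit_two_step(ds, rmax = 1600)
      est[i] <- f$params$d50
      sem[i] <- f$params$d50_sem
    }
  })
  ratio <- sd(est) / mean(sem)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("degenerate inputs fail with informative errors", {
  expect_error(fit_step1_untransformed(
    release_recapture(c(0, 10, 20), 100, c(5, 3, 1))), "at least 4")
  expect_error(fit_step1_untransformed(
    release_recapture(c(0, 10, 20, 40), 100, 0)), "non-zero")
  ds1 <- release_recapture(c(0, 10, 20, 40), 100, c(30, 0, 0, 0))
  expect_error(fit_step2_log(ds1, 0.3), "at least 2")
  ds <- noiseless_ds(trap_params(0.3, 20, 500), c(0, 10, 20, 40))
  expect_error(fit_step2_log(ds, 0), "\\(0, 1\\]")
  expect_error(fit_step2_log(ds, 1.5), "\\(0, 1\\]")
  expect_error(suppressWarnings(fit_fixed_sptfer0(ds, -0.2)), "\\(0, 1\\]")
})

test_that("weighted fitting is available when SEMs are present", {
  truth <- trap_params(0.3, 40, 800)
  ds <- simulate_recapture(truth, recovery_ladder(truth), 2000, seed = 5)
  fw <- fit_two_step(ds, rmax = 800, weighted = TRUE)
  expect_lt(abs(fw$params$d50 - 40), 3 * fw$params$d50_sem)
  # and refused when the dataset carries no usable SEM
  bare <- release_recapture(c(0, 20, 40, 80), 1,
                            sp_t_fer(c(0, 20, 40, 80), truth),
                            sem = rep(NA_real_, 4))
  expect_error(fit_two_step(bare, rmax = 800, weighted = TRUE), "SEM")
})

test_that("dataset design criteria are screened as warnings, not errors", {
  clean <- release_recapture(c(0, 15, 25, 30, 50), 100,
                             c(40, 30, 20, 15, 8))
  expect_length(validate_recapture(clean, warn = FALSE), 0L)
  short <- release_recapture(c(0, 15, 25), 100, c(40, 30, 20))
  expect_match(validate_recapture(short, warn = FALSE), "criterion 1")
  shrinking <- release_recapture(c(0, 15, 25, 30), c(200, 150, 100, 50),
                                 c(40, 30, 20, 10))
  expect_match(validate_recapture(shrinking, warn = FALSE), "criterion 2")
  holes <- release_recapture(c(0, 15, 25, 30), 100, c(5, 0, 3, 1))
  expect_match(validate_recapture(holes, warn = FALSE), "criterion 3")
  expect_warning(validate_recapture(holes), "criterion 3")
})

test_that("duplicate distances are pooled with a warning", {
  expect_warning(
    ds <- release_recapture(c(0, 10, 10, 20), c(50, 50, 100, 50),
                            c(20, 10, 20, 5)),
    "pooled")
  expect_equal(nrow(ds), 3L)
  # catch-weighted: (10 + 20) recaptured of (50 + 100) released
  expect_equal(ds$proportion[ds$distance == 10], 30 / 150)
})
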