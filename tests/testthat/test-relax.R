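test_that("noiseless exponential decays are fit exactly and match a grid-search oracle", {
  delays <- relax_delays("R1")
  for (R_true in c(0.7, 2.0, 6.862, 15)) {
    y <- 100 * exp(-R_true * delays)
    fit <- fit_exponential(decay_series(1, delays, y), n_boot = 0)
    expect_true(fit$converged)
    expect_equal(fit$R_hz, R_true, tolerance = 1e-6)
    expect_equal(fit$I0, 100, tolerance = 1e-6)
    oracle <- grid_search_rate(delays, y, lo = max(0.1, R_true - 1),
                               hi = R_true + 1)
    expect_equal(fit$R_hz, oracle, tolerance = 2e-4)
  }
})

test_that("rate recovery at 1% noise stays within 2% of truth", {
  set.seed(11)
  delays_r1 <- relax_delays("R1")
  y <- 100 * exp(-1.928 * delays_r1) + rnorm(length(delays_r1), 0, 1)
  fit <- fit_exponential(decay_series(1, delays_r1, y), n_boot = 200)
  expect_lt(abs(fit$R_hz - 1.928) / 1.928, 0.02)
  expect_gt(fit$rate_error_hz, 0)

  # median relative error over many seeds and rates spanning the R1/R2 range
  errs <- sapply(1:40, function(s) {
    set.seed(s)
    R_true <- runif(1, 1, 20)
    sched <- if (R_true > 4) relax_delays("R2") else relax_delays("R1")
    y <- 100 * exp(-R_true * sched) + rnorm(length(sched), 0, 1)
    f <- fit_exponential(decay_series(1, sched, y), n_boot = 0)
    abs(f$R_hz - R_true) / R_true
  })
  expect_lt(median(errs), 0.02)
})

test_that("degenerate decay inputs are handled as specified", {
  expect_error(decay_series(1, c(0.1, 0.1, 0.2), c(3, 2, 1)),
               "strictly increasing")
  expect_error(decay_series(1, c(0.1, 0.2), c(2, 1)), "at least 3")
  expect_warning(fit <- fit_exponential(decay_series(1, c(.1, .2, .3),
                                                     c(50, 50, 50))),
                 "lower clip")
  expect_true(fit$converged)
  expect_equal(fit$R_hz, 1e-3)
})

test_that("hetNOE is the saturated/unsaturated ratio with quadrature errors", {
  sat <- data.frame(residue = 1:3, height = c(78, 100, 0.5),
                    height_error = c(2, 1, 0.1))
  unsat <- data.frame(residue = 1:3, height = c(100, 100, 1),
                      height_error = c(2, 1, 0.1))
  noe <- compute_hetnoe(sat, unsat)
  expect_equal(noe$hetNOE, c(0.78, 1.0, 0.5))
  expect_equal(noe$hetNOE_error[1],
               0.78 * sqrt((2 / 78)^2 + (2 / 100)^2))

  # duplicated spectra give exactly 1 everywhere
  dup <- data.frame(residue = 1:20, height = runif(20, 10, 100))
  expect_true(all(compute_hetnoe(dup, dup)$hetNOE == 1))

  # zero unsaturated height marks the residue invalid
  z <- compute_hetnoe(data.frame(residue = 1, height = 5),
                      data.frame(residue = 1, height = 0))
  expect_false(z$valid)
})

test_that("profile summary flags only genuine outliers and refuses tiny profiles", {
  mk <- function(r1, r2, noe = NULL) {
    f1 <- data.frame(residue = seq_along(r1), residue_name = "A", R_hz = r1,
                     rate_error_hz = 0.01, I0 = 100, converged = TRUE,
                     overlapped = FALSE)
    f2 <- transform(f1, R_hz = r2)
    nn <- if (!is.null(noe)) data.frame(residue = seq_along(r1), hetNOE = noe,
                                        hetNOE_error = 0.01, valid = TRUE)
    summarize_profile(f1, f2, nn)
  }
  # identical residues: zero SD, nothing flagged
  p <- mk(rep(2, 10), rep(7, 10), rep(0.8, 10))
  expect_equal(p$summary$R1_sd, 0)
  expect_false(any(p$residues$low_R1 | p$residues$low_R2 |
                     p$residues$low_hetNOE))

  # one residue far below the mean of a tight profile is the only flag
  set.seed(31)
  r1 <- c(rnorm(19, 2, 0.05), NA)
  r1[20] <- mean(r1[1:19]) - 3 * sd(r1[1:19]) * 4
  p2 <- mk(r1, rep(7, 20), rep(0.8, 20))
  expect_equal(which(p2$residues$low_R1), 20L)
  expect_equal(p2$residues$R1_direction[20], "below")

  # hetNOE below 0.6 flags regardless of the rate profile
  p3 <- mk(rep(2, 10), rep(7, 10), c(rep(0.8, 9), 0.45))
  expect_equal(which(p3$residues$low_hetNOE), 10L)

  expect_error(mk(rep(2, 4), rep(7, 4)), "at least 5")
})

test_that("tumbling time follows the R2/R1 formula and its edge cases", {
  # frozen direct evaluations of the closed form
  expect_equal(estimate_tau_c(1.078, 17.66, 60.81e6)$tau_c_ns, 12.5036,
               tolerance = 1e-4)
  expect_equal(estimate_tau_c(1.928, 6.862, 60.81e6)$tau_c_ns, 4.9581,
               tolerance = 1e-4)

  # radicand root gives tau_c = 0; below it, flagged undefined (never NaN)
  expect_equal(estimate_tau_c(6, 7)$tau_c_s, 0)
  und <- estimate_tau_c(2, 2)
  expect_false(und$defined)
  expect_true(is.na(und$tau_c_s))

  # tau_c strictly increases with R2/R1 above the root
  ratios <- seq(7 / 6 + 0.01, 20, length.out = 50)
  taus <- vapply(ratios,
                 function(r) estimate_tau_c(1, r, 60.81e6)$tau_c_s,
                 numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("profile-level tau_c agrees across conventions on uniform rates and recovers a 5 ns truth", {
  mk_prof <- function(r1, r2) {
    f1 <- data.frame(residue = seq_along(r1), residue_name = "A", R_hz = r1,
                     rate_error_hz = 0.01, I0 = 100, converged = TRUE,
                     overlapped = FALSE)
    summarize_profile(f1, transform(f1, R_hz = r2))
  }
  p <- mk_prof(rep(1.9, 12), rep(7.1, 12))
  tc <- profile_tau_c(p)
  expect_equal(tc$per_residue_mean$tau_c_s, tc$from_mean_rates$tau_c_s,
               tolerance = 1e-12)

  # rates chosen so the true isotropic tau_c is 5.0 ns at 60.81 MHz
  tau_target <- 5e-9
  rad <- (4 * pi * 60.81e6 * tau_target)^2
  r1 <- 2.0
  r2 <- r1 * (rad + 7) / 6
  set.seed(21)
  p5 <- mk_prof(rnorm(40, r1, 0.02), rnorm(40, r2, 0.07))
  tc5 <- profile_tau_c(p5)
  expect_lt(abs(tc5$per_residue_mean$tau_c_ns - 5) / 5, 0.03)
  expect_lt(abs(tc5$from_mean_rates$tau_c_ns - 5) / 5, 0.03)

  # a residue below the 7/6 root is excluded and counted
  r1v <- rep(2, 10); r2v <- rep(7.2, 10); r2v[4] <- 2.0
  tc_ex <- profile_tau_c(mk_prof(r1v, r2v))
  expect_equal(tc_ex$n_excluded, 1L)
  expect_equal(tc_ex$n_used, 9L)
})
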