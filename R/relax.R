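#' Construct a peak-height decay series
#'
#' One residue's peak heights as a function of relaxation delay, the input
#' to single-exponential R1/R2 fitting.
#'
#' @param residue Residue number (1-based).
#' @param delays Relaxation delays in seconds, strictly increasing, >= 3.
#' @param heights Peak heights (arbitrary units), finite.
#' @param residue_name One-letter amino-acid code.
#' @param height_errors Optional per-point height uncertainties.
#' @param overlapped Peak overlap flag; overlapped residues are excluded
#'   from profile averages.
#' @return A list of class `"decay_series"`.
#' @export
decay_series <- function(residue, delays, heights, residue_name = "X",
                         height_errors = NULL, overlapped = FALSE) {
  assert_that(length(delays) >= 3, "need at least 3 delay points")
  assert_that(all(diff(delays) > 0), "delays must be strictly increasing")
  assert_that(all(delays > 0), "delays must be positive")
  assert_that(length(heights) == length(delays),
              "heights and delays differ in length")
  assert_that(all(is.finite(heights)), "heights must be finite")
  if (!is.null(height_errors)) {
    assert_that(length(height_errors) == length(delays) &&
                  all(height_errors >= 0), "invalid height_errors")
  }
  structure(list(residue = as.integer(residue), residue_name = residue_name,
                 delays = as.numeric(delays), heights = as.numeric(heights),
                 height_errors = height_errors,
                 overlapped = isTRUE(overlapped)),
            class = "decay_series")
}

#' Fit a single-exponential decay
#'
#' Nonlinear least-squares fit of \eqn{I(t) = I_0 e^{-Rt}} to a peak-height
#' decay, the standard extraction of \eqn{^{15}}N R1/R2 from pseudo-3D
#' relaxation series. Initial guesses are `I0 = max(heights)` and
#' `R = log(I_first/I_last)/(t_last - t_first)` clipped to (1e-3, 1e3) Hz;
#' the rate uncertainty comes from `n_boot` Monte-Carlo refits with
#' synthetic noise at the residual scale (or the supplied height errors),
#' under a fixed seed. A failed optimisation returns `converged = FALSE`
#' rather than an error.
#'
#' @param series A [decay_series()].
#' @param n_boot Monte-Carlo resamples for the rate error (0 skips it).
#' @param boot_seed Seed for the Monte-Carlo noise draws.
#' @return A list of class `"rate_fit"`: `R_hz`, `I0`, `rate_error_hz`,
#'   `converged`, plus the residue id.
#' @export
fit_exponential <- function(series, n_boot = 200, boot_seed = 1234) {
  stopifnot(inherits(series, "decay_series"))
  t <- series$delays
  y <- series$heights

  if (diff(range(y)) < .Machine$double.eps * max(abs(y), 1)) {
    warning("all heights equal; rate at lower clip")
    fit0 <- list(R = 1e-3, I0 = mean(y))
    return(structure(list(residue = series$residue, R_hz = fit0$R,
                          I0 = fit0$I0, rate_error_hz = 0,
                          converged = TRUE, at_bound = TRUE),
                     class = "rate_fit"))
  }

  one_fit <- function(yy, start) {
    df <- data.frame(t = t, yy = yy)
    tryCatch({
      fit <- minpack.lm::nlsLM(yy ~ I0 * exp(-R * t), data = df,
                               start = start,
                               lower = c(I0 = 0, R = 1e-3),
                               upper = c(I0 = Inf, R = 1e3),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      as.list(coef(fit))
    }, error = function(e) NULL)
  }

  R0 <- log(max(y[1], 1e-12) / max(y[length(y)], 1e-12)) /
    (t[length(t)] - t[1])
  if (!is.finite(R0) || R0 <= 0) R0 <- 1
  R0 <- min(max(R0, 1e-3), 1e3)
  start <- list(I0 = max(y), R = R0)

  best <- one_fit(y, start)
  if (is.null(best)) {
    return(structure(list(residue = series$residue, R_hz = NA_real_,
                          I0 = NA_real_, rate_error_hz = NA_real_,
                          converged = FALSE, at_bound = FALSE),
                     class = "rate_fit"))
  }

  rate_error <- NA_real_
  if (n_boot > 0) {
    fitted <- best$I0 * exp(-best$R * t)
    sigma <- series$height_errors %||%
      rep(sqrt(mean((y - fitted)^2)), length(t))
    rates <- with_seed_local(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        yb <- fitted + rnorm(length(t), 0, sigma)
        fb <- one_fit(yb, best)
        if (is.null(fb)) NA_real_ else fb$R
      }, numeric(1))
    })
    rate_error <- stats::sd(rates, na.rm = TRUE)
  }

  structure(list(residue = series$residue, R_hz = best$R, I0 = best$I0,
                 rate_error_hz = rate_error, converged = TRUE,
                 at_bound = best$R <= 1e-3 * (1 + 1e-9)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("rate_fit residue %d: R = %.4f Hz (err %.4f), I0 = %.2f, converged %s\n",
              x$residue, x$R_hz, x$rate_error_hz, x$I0, x$converged))
  invisible(x)
}

#' Fit every residue of a decay collection
#'
#' @param series_list List of [decay_series()].
#' @inheritParams fit_exponential
#' @return Data frame: residue, R_hz, rate_error_hz, I0, converged,
#'   overlapped.
#' @export
fit_rate_profile <- function(series_list, n_boot = 200, boot_seed = 1234) {
  rows <- lapply(series_list, function(s) {
    f <- fit_exponential(s, n_boot = n_boot, boot_seed = boot_seed)
    data.frame(residue = s$residue, residue_name = s$residue_name,
               R_hz = f$R_hz, rate_error_hz = f$rate_error_hz, I0 = f$I0,
               converged = f$converged, overlapped = s$overlapped)
  })
  do.call(rbind, rows)
}

#' Heteronuclear NOE from paired peak heights
#'
#' hetNOE = I_sat / I_unsat per residue, with the uncertainty propagated in
#' quadrature from the two height errors. Residues with zero unsaturated
#' height are marked invalid and excluded from downstream averages.
#'
#' @param sat,unsat Data frames with columns `residue` and `height`
#'   (optional `height_error`, `residue_name`, `overlapped`).
#' @return Data frame: residue, hetNOE, hetNOE_error, valid, overlapped.
#' @export
compute_hetnoe <- function(sat, unsat) {
  assert_that(all(c("residue", "height") %in% names(sat)) &&
                all(c("residue", "height") %in% names(unsat)),
              "sat/unsat need columns residue, height")
  assert_that(setequal(sat$residue, unsat$residue),
              "saturated and unsaturated tables cover different residues")
  m <- merge(sat, unsat, by = "residue", suffixes = c("_sat", "_unsat"))
  m <- m[order(m$residue), ]
  valid <- m$height_unsat != 0
  noe <- ifelse(valid, m$height_sat / m$height_unsat, NA_real_)
  es <- m[["height_error_sat"]] %||% rep(0, nrow(m))
  eu <- m[["height_error_unsat"]] %||% rep(0, nrow(m))
  err <- ifelse(valid,
                abs(noe) * sqrt((es / m$height_sat)^2 +
                                  (eu / m$height_unsat)^2), NA_real_)
  ovl <- (m[["overlapped_sat"]] %||% rep(FALSE, nrow(m))) |
    (m[["overlapped_unsat"]] %||% rep(FALSE, nrow(m)))
  data.frame(residue = m$residue,
             residue_name = m[["residue_name_sat"]] %||% "X",
             hetNOE = noe, hetNOE_error = err, valid = valid,
             overlapped = ovl)
}

#' Summarize per-residue relaxation into a profile
#'
#' Joins R1 fits, R2 fits and hetNOE values into one per-residue table,
#' computes ensemble means and SDs over usable residues (converged fits,
#' non-overlapped, valid hetNOE), and flags flexibility: `low_R1`/`low_R2`
#' mark residues whose rate deviates from the ensemble mean by more than
#' `k_sd` standard deviations (direction recorded; the biologically
#' interesting case is below the mean), `low_hetNOE` marks hetNOE below an
#' absolute cutoff (default 0.6, the conventional threshold for fast ps-ns
#' backbone motion).
#'
#' @param r1,r2 Data frames from [fit_rate_profile()].
#' @param hetnoe Data frame from [compute_hetnoe()] (optional).
#' @param k_sd SD multiple for the rate flags.
#' @param hetnoe_threshold Absolute hetNOE cutoff.
#' @return A list of class `"relaxation_profile"` with `residues` (the
#'   per-residue table), `summary` (means/SDs/counts) and the thresholds.
#' @export
summarize_profile <- function(r1, r2, hetnoe = NULL, k_sd = 2,
                              hetnoe_threshold = 0.6) {
  tab <- merge(r1[, c("residue", "residue_name", "R_hz", "rate_error_hz",
                      "converged", "overlapped")],
               r2[, c("residue", "R_hz", "rate_error_hz", "converged",
                      "overlapped")],
               by = "residue", suffixes = c("_1", "_2"), all = TRUE)
  names(tab)[names(tab) == "R_hz_1"] <- "R1_hz"
  names(tab)[names(tab) == "R_hz_2"] <- "R2_hz"
  names(tab)[names(tab) == "rate_error_hz_1"] <- "R1_error_hz"
  names(tab)[names(tab) == "rate_error_hz_2"] <- "R2_error_hz"
  tab$overlapped <- (tab$overlapped_1 %in% TRUE) | (tab$overlapped_2 %in% TRUE)
  tab$converged <- (tab$converged_1 %in% TRUE) & (tab$converged_2 %in% TRUE)
  tab$overlapped_1 <- tab$overlapped_2 <- NULL
  tab$converged_1 <- tab$converged_2 <- NULL

  if (!is.null(hetnoe)) {
    tab <- merge(tab, hetnoe[, c("residue", "hetNOE", "hetNOE_error", "valid")],
                 by = "residue", all = TRUE)
  } else {
    tab$hetNOE <- NA_real_; tab$hetNOE_error <- NA_real_; tab$valid <- NA
  }

  tab$usable <- !tab$overlapped & tab$converged &
    is.finite(tab$R1_hz) & is.finite(tab$R2_hz)
  tab$R2_R1 <- ifelse(tab$converged, tab$R2_hz / tab$R1_hz, NA_real_)

  n_usable <- sum(tab$usable, na.rm = TRUE)
  if (n_usable < 5) {
    stop_input("only %d usable residues; need at least 5 for a profile",
               n_usable)
  }

  u <- tab$usable
  noe_ok <- u & !is.na(tab$hetNOE) & (tab$valid %in% TRUE)
  s <- list(
    n_usable = n_usable,
    R1_mean = mean(tab$R1_hz[u]), R1_sd = stats::sd(tab$R1_hz[u]),
    R2_mean = mean(tab$R2_hz[u]), R2_sd = stats::sd(tab$R2_hz[u]),
    R2_R1_mean = mean(tab$R2_R1[u]), R2_R1_sd = stats::sd(tab$R2_R1[u]),
    hetNOE_mean = if (any(noe_ok)) mean(tab$hetNOE[noe_ok]) else NA_real_,
    hetNOE_sd = if (any(noe_ok)) stats::sd(tab$hetNOE[noe_ok]) else NA_real_)

  dev1 <- tab$R1_hz - s$R1_mean
  dev2 <- tab$R2_hz - s$R2_mean
  tab$low_R1 <- u & abs(dev1) > k_sd * s$R1_sd
  tab$R1_direction <- ifelse(tab$low_R1, ifelse(dev1 < 0, "below", "above"), "")
  tab$low_R2 <- u & abs(dev2) > k_sd * s$R2_sd
  tab$R2_direction <- ifelse(tab$low_R2, ifelse(dev2 < 0, "below", "above"), "")
  tab$low_hetNOE <- noe_ok & tab$hetNOE < hetnoe_threshold

  structure(list(residues = tab[order(tab$residue), ], summary = s,
                 k_sd = k_sd, hetnoe_threshold = hetnoe_threshold),
            class = "relaxation_profile")
}

#' @export
print.relaxation_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Relaxation profile over %d usable residues\n", s$n_usable))
  cat(sprintf("  R1 %.3f +/- %.3f Hz | R2 %.3f +/- %.3f Hz | hetNOE %.3f +/- %.3f\n",
              s$R1_mean, s$R1_sd, s$R2_mean, s$R2_sd, s$hetNOE_mean,
              s$hetNOE_sd))
  fl <- x$residues$residue[x$residues$low_R1 | x$residues$low_R2 |
                             x$residues$low_hetNOE]
  cat(sprintf("  flagged residues: %s\n",
              if (length(fl)) paste(fl, collapse = ", ") else "none"))
  invisible(x)
}

#' Rotational correlation time from R2/R1
#'
#' \deqn{\tau_c = \frac{1}{4\pi\nu_N}\sqrt{6 R_2/R_1 - 7}}
#' valid for isotropic tumbling when the radicand is positive. `nu_N` is
#' the \eqn{^{15}}N resonance frequency in Hz (default 60.81 MHz, a 600 MHz
#' spectrometer).
#'
#' @param R1,R2 Relaxation rates in Hz (positive scalars).
#' @param nu_N 15N resonance frequency in Hz.
#' @param method Provenance of the rates, recorded in the result.
#' @return A list of class `"tumbling_estimate"` with `tau_c_s`,
#'   `tau_c_ns`, `defined` (FALSE when `6 R2/R1 - 7 < 0`; exactly 0 gives
#'   the limiting `tau_c = 0`).
#' @export
estimate_tau_c <- function(R1, R2, nu_N = NU_N_DEFAULT,
                           method = c("from_mean_rates", "per_residue_mean")) {
  method <- match.arg(method)
  assert_that(is_number(R1) && R1 > 0, "R1 must be a positive number")
  assert_that(is_number(R2) && R2 > 0, "R2 must be a positive number")
  assert_that(is_number(nu_N) && nu_N > 0, "nu_N must be positive")
  rad <- 6 * R2 / R1 - 7
  if (rad < 0) {
    out <- list(tau_c_s = NA_real_, tau_c_ns = NA_real_, defined = FALSE,
                nu_N = nu_N, method = method, radicand = rad)
  } else {
    tau <- sqrt(rad) / (4 * pi * nu_N)
    out <- list(tau_c_s = tau, tau_c_ns = tau * 1e9, defined = TRUE,
                nu_N = nu_N, method = method, radicand = rad)
  }
  class(out) <- "tumbling_estimate"
  out
}

#' @export
print.tumbling_estimate <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("tau_c = %.3f ns (%s, nu_N = %.4g Hz)\n", x$tau_c_ns,
                x$method, x$nu_N))
  } else {
    cat(sprintf("tau_c undefined: 6 R2/R1 - 7 = %.3f <= 0\n", x$radicand))
  }
  invisible(x)
}

#' Profile-level tumbling time, both averaging conventions
#'
#' Computes tau_c two ways from a relaxation profile: (i) per-residue tau_c
#' averaged over usable, unflagged residues with a positive radicand, after
#' optional symmetric trimming; (ii) tau_c of the profile-mean R1 and R2.
#' Both are reported because the two conventions differ by about a percent
#' on realistic profiles (Jensen's inequality: tau_c is concave-convex in
#' the rates) and published values rarely say which was used.
#'
#' @param profile A [summarize_profile()] result.
#' @param nu_N 15N frequency in Hz.
#' @param trim Symmetric trim fraction for the per-residue mean (default 0).
#' @return List of class `"profile_tau_c"`: `per_residue_mean`,
#'   `from_mean_rates` (both [estimate_tau_c()] results), `n_used`,
#'   `n_excluded` (non-positive radicand).
#' @export
profile_tau_c <- function(profile, nu_N = NU_N_DEFAULT, trim = 0) {
  stopifnot(inherits(profile, "relaxation_profile"))
  tab <- profile$residues
  use <- tab$usable & !tab$low_R1 & !tab$low_R2 & !(tab$low_hetNOE %in% TRUE)
  rad <- 6 * tab$R2_R1 - 7
  pos <- use & rad > 0
  n_excluded <- sum(tab$usable & !(rad > 0), na.rm = TRUE)
  if (!any(pos, na.rm = TRUE)) {
    stop_input("no usable residue has 6 R2/R1 - 7 > 0; tau_c undefined")
  }
  tau <- sqrt(rad[pos %in% TRUE]) / (4 * pi * nu_N)
  per_res <- mean(tau, trim = trim)
  pr <- list(tau_c_s = per_res, tau_c_ns = per_res * 1e9, defined = TRUE,
             nu_N = nu_N, method = "per_residue_mean", radicand = NA_real_)
  class(pr) <- "tumbling_estimate"
  fm <- estimate_tau_c(mean(tab$R1_hz[use], na.rm = TRUE),
                       mean(tab$R2_hz[use], na.rm = TRUE),
                       nu_N, method = "from_mean_rates")
  structure(list(per_residue_mean = pr, from_mean_rates = fm,
                 n_used = sum(pos, na.rm = TRUE), n_excluded = n_excluded,
                 trim = trim),
            class = "profile_tau_c")
}

#' @export
print.profile_tau_c <- function(x, ...) {
  cat(sprintf("tau_c: %.3f ns (per-residue mean, n=%d) | %.3f ns (from mean rates)\n",
              x$per_residue_mean$tau_c_ns, x$n_used,
              x$from_mean_rates$tau_c_ns))
  if (x$n_excluded > 0) {
    cat(sprintf("  %d residue(s) excluded: non-positive radicand\n",
                x$n_excluded))
  }
  invisible(x)
}
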