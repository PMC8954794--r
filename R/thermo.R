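#' Two-state excess heat capacity model
#'
#' Forward model for a scaled two-state (van 't Hoff) DSC transition:
#' \deqn{C_p(T) = b(T) + A \frac{\Delta H^2}{R T^2} \frac{K(T)}{(1+K(T))^2},
#'  \qquad K(T) = \exp\left[-\frac{\Delta H}{R}
#'  \left(\frac{1}{T}-\frac{1}{T_m}\right)\right]}
#' with R = 1.98720425e-3 kcal mol-1 K-1. The scale factor `A` absorbs the
#' calorimetric / van 't Hoff enthalpy discrepancy. The polynomial baseline
#' `b(T)` is evaluated on the centered temperature `T - T_center` to keep
#' its coefficients well conditioned.
#'
#' At `T = T_m`, `K = 1` and the excess term equals
#' `A * dH^2 / (4 R T_m^2)`; the integral of the excess term over the full
#' transition equals `A * dH`.
#'
#' @param T_K Temperatures in Kelvin.
#' @param Tm_K Midpoint temperature in Kelvin.
#' @param dH_kcal van 't Hoff enthalpy in kcal/mol (positive).
#' @param A Dimensionless scale factor.
#' @param baseline Baseline polynomial coefficients, increasing powers of
#'   `(T_K - T_center)`, in kcal mol-1 K-1.
#' @param T_center Centering temperature for the baseline (default `Tm_K`).
#' @return Heat capacity in kcal mol-1 K-1 at each `T_K`.
#' @export
dsc_two_state_cp <- function(T_K, Tm_K, dH_kcal, A = 1, baseline = 0,
                             T_center = Tm_K) {
  K <- exp(-(dH_kcal / R_GAS_KCAL) * (1 / T_K - 1 / Tm_K))
  excess <- A * dH_kcal^2 / (R_GAS_KCAL * T_K^2) * K / (1 + K)^2
  polyval_inc(baseline, T_K - T_center) + excess
}

#' Construct a DSC thermogram object
#'
#' @param T_K Strictly increasing temperature grid in Kelvin (at least 20
#'   points spanning more than 20 K).
#' @param Cp Heat capacity in kcal mol-1 K-1.
#' @param scan_rate_K_min Scan rate metadata.
#' @return A list of class `"thermogram"`.
#' @export
thermogram <- function(T_K, Cp, scan_rate_K_min = 1) {
  assert_that(length(T_K) == length(Cp), "T_K and Cp lengths differ")
  assert_that(all(diff(T_K) > 0), "temperature grid must be strictly increasing")
  assert_that(length(T_K) >= 20 && diff(range(T_K)) > 20,
              "thermogram needs >= 20 points spanning > 20 K")
  assert_that(all(is.finite(Cp)), "Cp values must be finite")
  structure(list(T_K = T_K, Cp = Cp, scan_rate_K_min = scan_rate_K_min),
            class = "thermogram")
}

#' Fit the two-state scaled DSC model
#'
#' Least-squares fit of [dsc_two_state_cp()] plus a polynomial baseline to a
#' thermogram. The initial midpoint is the grid maximum of the
#' baseline-detrended signal (baseline pre-estimated from the outer 15% of
#' the grid); the initial enthalpy comes from the peak height via
#' `dH = 2 T_m sqrt(R h)`.
#'
#' @param tg A [thermogram()].
#' @param baseline_degree Baseline polynomial degree, 0..3.
#' @return A list of class `"melt_fit"` with `Tm_K`, `Tm_C`, `dH_kcal`, `A`,
#'   `baseline`, `fit_rms`, `converged`.
#' @export
fit_dsc_two_state <- function(tg, baseline_degree = 2) {
  stopifnot(inherits(tg, "thermogram"))
  assert_that(baseline_degree %in% 0:3, "baseline_degree must be in 0..3")
  T_K <- tg$T_K; Cp <- tg$Cp
  n <- length(T_K)

  # crude baseline from the flanks, then locate the peak
  edge <- unique(c(seq_len(max(3, round(0.15 * n))),
                   seq(n - max(3, round(0.15 * n)) + 1, n)))
  Tc <- mean(range(T_K))
  deg0 <- max(1, baseline_degree)
  Bc <- outer(T_K - Tc, 0:deg0, `^`)
  cb <- qr.coef(qr(Bc[edge, , drop = FALSE]), Cp[edge])
  detr <- Cp - as.numeric(Bc %*% cb)
  ipk <- which.max(detr)
  edge_rms <- sqrt(mean(detr[edge]^2))
  if (ipk <= 2 || ipk >= n - 1 || detr[ipk] < 5 * edge_rms + 1e-9) {
    stop_input("no interior peak in the thermogram; two-state fit undefined")
  }
  Tm0 <- T_K[ipk]
  h0 <- max(detr[ipk], 1e-6)
  dH0 <- 2 * Tm0 * sqrt(R_GAS_KCAL * h0)

  nb <- baseline_degree + 1L
  B <- outer(T_K - Tm0, 0:baseline_degree, `^`)
  b_init <- qr.coef(qr(B[edge, , drop = FALSE]), Cp[edge])
  start <- c(Tm0, dH0, 1, as.numeric(b_init))
  names(start) <- c("Tm", "dH", "A", paste0("b", 0:baseline_degree))

  model <- function(p) {
    dsc_two_state_cp(T_K, p[["Tm"]], p[["dH"]], p[["A"]],
                     baseline = unname(p[paste0("b", 0:baseline_degree)]),
                     T_center = Tm0)
  }
  resid_fun <- function(p) Cp - model(p)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fun,
                       lower = c(min(T_K), 1, 1e-4, rep(-Inf, nb)),
                       upper = c(max(T_K), 5000, 1e4, rep(Inf, nb)),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) stop_input("two-state DSC fit did not converge")
  p <- fit$par
  out <- list(Tm_K = p[["Tm"]], Tm_C = p[["Tm"]] - 273.15,
              dH_kcal = p[["dH"]], A = p[["A"]],
              baseline = unname(p[paste0("b", 0:baseline_degree)]),
              baseline_center_K = Tm0,
              fit_rms = sqrt(mean(resid_fun(p)^2)),
              converged = fit$info %in% 1:4)
  class(out) <- "melt_fit"
  out
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Two-state DSC fit: Tm = %.2f degC (%.2f K), dH = %.1f kcal/mol, A = %.3f\n",
              x$Tm_C, x$Tm_K, x$dH_kcal, x$A))
  cat(sprintf("  fit RMS %.4g kcal mol-1 K-1, converged: %s\n",
              x$fit_rms, x$converged))
  invisible(x)
}

#' Construct an ITC isotherm object
#'
#' @param inj_vol_uL Injection volumes in microliters.
#' @param heats_ucal Integrated injection heats in microcalories.
#' @param V0_mL Calorimeter cell volume in mL.
#' @param cell_M Initial macromolecule (cell) concentration, mol/L.
#' @param syringe_M Titrant (syringe) concentration, mol/L.
#' @param temperature_K Experiment temperature.
#' @return A list of class `"itc_isotherm"`.
#' @export
itc_isotherm <- function(inj_vol_uL, heats_ucal, V0_mL = 1.0,
                         cell_M, syringe_M, temperature_K = 298.15) {
  assert_that(length(inj_vol_uL) == length(heats_ucal),
              "injection volumes and heats differ in length")
  assert_that(all(inj_vol_uL > 0) && V0_mL > 0 && cell_M > 0 && syringe_M > 0,
              "volumes and concentrations must be positive")
  assert_that(all(is.finite(heats_ucal)), "heats must be finite")
  structure(list(inj_vol_uL = inj_vol_uL, heats_ucal = heats_ucal,
                 V0_mL = V0_mL, cell_M = cell_M, syringe_M = syringe_M,
                 temperature_K = temperature_K),
            class = "itc_isotherm")
}

#' Independent-site ITC forward model
#'
#' Computes the per-injection heats of the single-class (Wiseman)
#' independent-site binding model. Displacement bookkeeping uses the
#' exponential-dilution convention: after cumulative injected volume
#' \eqn{\Delta V}, the cell macromolecule concentration is
#' \eqn{M = M_0 e^{-\Delta V/V_0}} and the titrant concentration
#' \eqn{X = X_{syr}(1-e^{-\Delta V/V_0})}. After injection k the complex
#' concentration is the smaller root of the binding quadratic
#' \deqn{[PL]_k = \tfrac12\left[(nM_k+X_k+K_d) -
#'   \sqrt{(nM_k+X_k+K_d)^2-4nM_kX_k}\right]}
#' and the measured heat of injection k is
#' \eqn{q_k = Q_k - Q_{k-1} + \frac{v_k}{V_0}\frac{Q_k+Q_{k-1}}{2} +
#' \mathrm{offset}} with \eqn{Q_k = \Delta H\, V_0\, [PL]_k}.
#'
#' @param iso An [itc_isotherm()] (heats are ignored; geometry is used).
#' @param Kd_M Dissociation constant, mol/L.
#' @param n Stoichiometry (sites per macromolecule).
#' @param dH_kcal Binding enthalpy, kcal per mole of ligand.
#' @param offset_ucal Constant per-injection dilution-heat offset, ucal.
#' @return List with `heats_ucal`, `complex_M`, `molar_ratio`.
#' @export
itc_forward <- function(iso, Kd_M, n, dH_kcal, offset_ucal = 0) {
  stopifnot(inherits(iso, "itc_isotherm"))
  assert_that(Kd_M > 0 && n > 0, "Kd and n must be positive")
  V0_L <- iso$V0_mL / 1000
  v_L <- iso$inj_vol_uL * 1e-6
  cumV <- cumsum(v_L)
  dil <- exp(-cumV / V0_L)
  M <- iso$cell_M * dil
  X <- iso$syringe_M * (1 - dil)
  b <- n * M + X + Kd_M
  PL <- (b - sqrt(pmax(b^2 - 4 * n * M * X, 0))) / 2
  Q <- dH_kcal * V0_L * PL * 1e9   # kcal -> ucal
  Qprev <- c(0, Q[-length(Q)])
  q <- Q - Qprev + (v_L / V0_L) * (Q + Qprev) / 2 + offset_ucal
  list(heats_ucal = q, complex_M = PL, molar_ratio = X / (n * M))
}

#' Fit the independent-site ITC model
#'
#' Nonlinear least-squares fit of [itc_forward()] to measured injection
#' heats, in (log Kd, n, dH, offset). Initial guesses: `n` from the molar
#' ratio at the half-height of the initial heat plateau, `dH` from the
#' first-injection heat per mole of injected titrant, `Kd` at one tenth of
#' the cell concentration.
#'
#' @param iso An [itc_isotherm()].
#' @param discard_first Drop the first injection from the residuals (classic
#'   first-injection artifact); off by default.
#' @return A list of class `"binding_fit"` with `Kd_M`, `n`, `dH_kcal`,
#'   `offset_ucal`, `fit_rms`, `converged`.
#' @export
fit_itc_independent <- function(iso, discard_first = FALSE) {
  stopifnot(inherits(iso, "itc_isotherm"))
  q <- iso$heats_ucal
  assert_that(length(q) >= 6, "need at least 6 injections")
  if (iso$syringe_M * sum(iso$inj_vol_uL) * 1e-6 / (iso$V0_mL / 1000) <
      iso$cell_M) {
    warning("isotherm may never saturate: total titrant below cell content")
  }

  v_L <- iso$inj_vol_uL * 1e-6
  V0_L <- iso$V0_mL / 1000
  # molar ratio grid for the n guess
  dil <- exp(-cumsum(v_L) / V0_L)
  ratio <- iso$syringe_M * (1 - dil) / (iso$cell_M * dil)
  base <- mean(q[seq(max(1, length(q) - 2), length(q))])
  amp0 <- q[1] - base
  half <- which(abs(q - base) <= abs(amp0) / 2)
  n0 <- if (length(half)) max(0.2, min(5, ratio[half[1]])) else 1
  dH0 <- amp0 / (iso$syringe_M * v_L[1] * 1e9 / 1)   # per mol injected
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -5
  start <- c(lKd = log(iso$cell_M / 10), n = n0, dH = dH0, off = base)

  keep <- if (discard_first) -1L else seq_along(q)
  resid_fun <- function(p) {
    pred <- itc_forward(iso, exp(p[["lKd"]]), p[["n"]], p[["dH"]],
                        p[["off"]])$heats_ucal
    (q - pred)[keep]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fun,
                       lower = c(log(1e-12), 0.05, -Inf, -Inf),
                       upper = c(log(1), 20, Inf, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit)) stop_input("independent-site ITC fit did not converge")
  p <- fit$par
  out <- list(Kd_M = exp(p[["lKd"]]), n = p[["n"]], dH_kcal = p[["dH"]],
              offset_ucal = p[["off"]],
              fit_rms = sqrt(mean(resid_fun(p)^2)),
              converged = fit$info %in% 1:4)
  class(out) <- "binding_fit"
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Independent-site ITC fit: Kd = %.3g M (%.2f uM), n = %.3f, dH = %.2f kcal/mol\n",
              x$Kd_M, x$Kd_M * 1e6, x$n, x$dH_kcal))
  cat(sprintf("  dilution offset %.3g ucal/inj, fit RMS %.3g ucal, converged: %s\n",
              x$offset_ucal, x$fit_rms, x$converged))
  invisible(x)
}
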