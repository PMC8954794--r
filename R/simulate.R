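#' Simulate peak-height decay series
#'
#' Per-residue pseudo-3D peak heights \eqn{I(t) = I_0 e^{-Rt} +
#' \epsilon}, \eqn{\epsilon \sim N(0, (\mathrm{noise\_sd}\cdot I_0)^2)},
#' with the per-residue true rate taken from the ground truth. At
#' `noise_sd = 0` the heights are the exact exponential.
#'
#' @param truth A [ground_truth()].
#' @param delays Relaxation delays in seconds (strictly positive, >= 3);
#'   defaults to the experiment's preset schedule.
#' @param cfg A [sim_config()].
#' @param rate `"R1"` or `"R2"` (selects the truth column and default
#'   delay schedule).
#' @param I0 Reference peak height (arbitrary units).
#' @return List of [decay_series()], one per residue. With
#'   `cfg$output_dir` set, writes `decay_<rate>.tsv` and
#'   `ground_truth.json` there.
#' @export
sim_decay_series <- function(truth, delays = NULL, cfg = sim_config(),
                             rate = c("R1", "R2"), I0 = 100) {
  rate <- match.arg(rate)
  delays <- delays %||% relax_delays(rate)
  assert_that(length(delays) >= 3, "need at least 3 delays")
  assert_that(all(delays > 0), "delays must be strictly positive")
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))

  R <- truth$relax[[rate]]
  series <- with_seed_local(cfg$seed + 101L, {
    lapply(seq_len(nrow(truth$relax)), function(i) {
      h <- I0 * exp(-R[i] * delays) +
        rnorm(length(delays), 0, cfg$noise_sd * I0)
      decay_series(truth$relax$residue[i], delays, h,
                   residue_name = truth$relax$residue_name[i])
    })
  })
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_decay_table(series, file.path(cfg$output_dir,
                                        sprintf("decay_%s.tsv", rate)))
    write_ground_truth(truth, file.path(cfg$output_dir, "ground_truth.json"))
  }
  series
}

#' Simulate saturated/unsaturated hetNOE height pairs
#'
#' `I_unsat = I0 + noise`, `I_sat = hetNOE * I0 + noise`, so the noiseless
#' ratio equals the true hetNOE exactly.
#'
#' @inheritParams sim_decay_series
#' @param I0 Reference peak height.
#' @return List with `sat` and `unsat` data frames (residue, height,
#'   height_error).
#' @export
sim_hetnoe_pairs <- function(truth, cfg = sim_config(), I0 = 100) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  noe <- truth$relax$hetNOE
  assert_that(all(noe > -1 & noe <= 1), "truth hetNOE must lie in (-1, 1]")
  n <- length(noe)
  out <- with_seed_local(cfg$seed + 202L, {
    list(sat = data.frame(residue = truth$relax$residue,
                          residue_name = truth$relax$residue_name,
                          height = noe * I0 + rnorm(n, 0, cfg$noise_sd * I0),
                          height_error = rep(cfg$noise_sd * I0, n)),
         unsat = data.frame(residue = truth$relax$residue,
                            residue_name = truth$relax$residue_name,
                            height = I0 + rnorm(n, 0, cfg$noise_sd * I0),
                            height_error = rep(cfg$noise_sd * I0, n)))
  })
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- data.frame(residue = out$sat$residue,
                      residue_name = out$sat$residue_name,
                      sat_height = out$sat$height,
                      unsat_height = out$unsat$height,
                      sat_error = out$sat$height_error,
                      unsat_error = out$unsat$height_error)
    utils::write.table(tab, file.path(cfg$output_dir, "hetnoe.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_ground_truth(truth, file.path(cfg$output_dir, "ground_truth.json"))
  }
  out
}

#' Fractional saturation of one-site binding (closed form)
#'
#' Bound fraction of the protein for total protein `P`, total ligand `L`
#' and dissociation constant `Kd`, from the smaller root of the binding
#' quadratic. Exposed because the titration generator and its tests both
#' need it.
#'
#' @param P_M,L_M,Kd_M Concentrations and Kd in mol/L.
#' @return Fraction of protein bound, in `[0, 1]`.
#' @export
fractional_saturation <- function(P_M, L_M, Kd_M) {
  b <- P_M + L_M + Kd_M
  pmin(pmax((b - sqrt(pmax(b^2 - 4 * P_M * L_M, 0))) / (2 * P_M), 0), 1)
}

#' Simulate a fast-exchange titration series
#'
#' Builds assigned shift tables at each molar ratio. Binding-site residues
#' move linearly from their apo position toward a bound position, scaled by
#' the fractional saturation of one-site binding at the stated Kd and
#' protein concentration (fast exchange); the bound-state endpoints are
#' chosen so the combined CSP at full saturation equals the site's true
#' amplitude (split between \eqn{^{15}}N and \eqn{^1}H). Non-site residues
#' keep their apo shifts. Gaussian assignment noise of `noise_H_ppm` /
#' `noise_N_ppm` is added to every entry.
#'
#' @inheritParams sim_decay_series
#' @param ratios Molar ratios, ascending, starting at 0.
#' @param protein_M Protein concentration, mol/L.
#' @param noise_H_ppm,noise_N_ppm Assignment noise SDs (typical
#'   assignment-grade precision by default).
#' @return List of [shift_table()]s, one per ratio.
#' @export
sim_titration_tables <- function(truth, ratios = c(0, 0.25, 0.5, 1, 2),
                                 cfg = sim_config(), protein_M = 500e-6,
                                 noise_H_ppm = 0.002, noise_N_ppm = 0.01) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  assert_that(length(ratios) >= 2 && ratios[1] == 0,
              "ratios must start at 0 (apo reference)")
  assert_that(all(diff(ratios) > 0), "ratios must be strictly increasing")

  n <- truth$n_residues
  with_seed_local(cfg$seed + 303L, {
    # synthetic but spectrally plausible apo positions
    apo_H <- runif(n, 6.5, 10.0)
    apo_N <- runif(n, 105, 130)
    site <- truth$binding_site
    # side-chain NeH entries are extra rows beyond the backbone set
    sc <- site[site$site == "trp_sidechain_NeH", , drop = FALSE]
    bb_rows <- data.frame(residue = seq_len(n), site = "backbone_NH",
                          delta_H_ppm = apo_H, delta_N_ppm = apo_N)
    sc_rows <- if (nrow(sc)) data.frame(residue = sc$residue,
                                        site = "trp_sidechain_NeH",
                                        delta_H_ppm = runif(nrow(sc), 9.9, 10.4),
                                        delta_N_ppm = runif(nrow(sc), 128, 131))
      else bb_rows[0, ]
    base <- rbind(bb_rows, sc_rows)
    base$residue_name <- synthetic_sequence(n)[base$residue]

    # split each site's saturating CSP amplitude between 1H and 15N such
    # that sqrt((dN/5.88)^2 + dH^2) = amplitude
    key <- paste(base$residue, base$site)
    skey <- paste(site$residue, site$site)
    amp <- site$amplitude[match(key, skey)]
    amp[is.na(amp)] <- 0
    frac_H <- runif(nrow(base), 0.3, 0.7)
    dH_max <- amp * sqrt(frac_H)
    dN_max <- 5.88 * amp * sqrt(1 - frac_H)

    Kd <- truth$itc$Kd_M
    lapply(seq_along(ratios), function(k) {
      r <- ratios[k]
      f <- if (r == 0) 0 else
        fractional_saturation(protein_M, r * protein_M, Kd)
      d <- base
      d$delta_H_ppm <- d$delta_H_ppm + f * dH_max +
        rnorm(nrow(d), 0, noise_H_ppm)
      d$delta_N_ppm <- d$delta_N_ppm + f * dN_max +
        rnorm(nrow(d), 0, noise_N_ppm)
      tb <- shift_table(d, ratio = r)
      if (!is.null(cfg$output_dir)) {
        dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
        write_shift_table(tb, file.path(cfg$output_dir,
                                        sprintf("shifts_ratio_%g.tsv", r)))
        write_ground_truth(truth, file.path(cfg$output_dir,
                                            "ground_truth.json"))
      }
      tb
    })
  })
}

#' Simulate a DSC thermogram
#'
#' Evaluates the two-state excess-heat-capacity model
#' [dsc_two_state_cp()] at the truth's Tm, enthalpy, scale and baseline,
#' and adds Gaussian noise with SD `noise_sd` times the transition peak
#' height.
#'
#' @inheritParams sim_decay_series
#' @param T_grid_K Strictly increasing temperature grid in Kelvin
#'   (defaults to the truth's scan range at 0.1 K steps).
#' @return A [thermogram()].
#' @export
sim_dsc_thermogram <- function(truth, T_grid_K = NULL, cfg = sim_config()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  d <- truth$dsc
  T_grid_K <- T_grid_K %||%
    seq(d$T_range_C[1] + 273.15, d$T_range_C[2] + 273.15, by = 0.1)
  assert_that(all(diff(T_grid_K) > 0),
              "temperature grid must be strictly increasing")
  cp <- dsc_two_state_cp(T_grid_K, d$Tm_K, d$dH_kcal, d$A,
                         baseline = d$baseline, T_center = d$Tm_K)
  peak <- d$A * d$dH_kcal^2 / (4 * R_GAS_KCAL * d$Tm_K^2)
  cp <- with_seed_local(cfg$seed + 404L,
                        cp + rnorm(length(cp), 0, cfg$noise_sd * peak))
  tg <- thermogram(T_grid_K, cp, scan_rate_K_min = 1)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_thermogram(tg, file.path(cfg$output_dir,
                                   sprintf("dsc_%s.csv", truth$construct)))
    write_ground_truth(truth, file.path(cfg$output_dir, "ground_truth.json"))
  }
  tg
}

#' Simulate an ITC injection-heat series
#'
#' Generates injection heats from the independent-site forward model
#' [itc_forward()] — the same model the fitter uses, so zero-noise
#' round-trips are exact — with exponential-dilution volume bookkeeping and
#' an optional constant dilution-heat offset. Noise SD is `noise_sd` times
#' the largest absolute heat. Warns when the planned injections cannot
#' saturate the cell.
#'
#' @inheritParams sim_decay_series
#' @return An [itc_isotherm()] carrying the noisy heats.
#' @export
sim_itc_isotherm <- function(truth, cfg = sim_config()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  p <- truth$itc
  iso <- itc_isotherm(p$inj_vol_uL, rep(0, length(p$inj_vol_uL)),
                      V0_mL = p$V0_mL, cell_M = p$cell_M,
                      syringe_M = p$syringe_M,
                      temperature_K = p$temperature_K)
  if (p$syringe_M * sum(p$inj_vol_uL) * 1e-6 / (p$V0_mL / 1000) <
      p$n * p$cell_M) {
    warning("syringe load cannot saturate the cell; isotherm has no inflection")
  }
  q <- itc_forward(iso, p$Kd_M, p$n, p$dH_kcal, p$offset_ucal)$heats_ucal
  q <- with_seed_local(cfg$seed + 505L,
                       q + rnorm(length(q), 0, cfg$noise_sd * max(abs(q))))
  iso$heats_ucal <- q
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_isotherm(iso, file.path(cfg$output_dir, "itc.csv"))
    write_ground_truth(truth, file.path(cfg$output_dir, "ground_truth.json"))
  }
  iso
}

#' Simulate a two-state CD melt
#'
#' Heating (and optional cooling) traces of observed ellipticity at one
#' wavelength, from a two-state van 't Hoff transition between folded and
#' unfolded molar ellipticities. `reversible = TRUE` generates a cooling
#' trace on the same curve (full signal recovery); `FALSE` keeps the
#' cooled protein at the unfolded baseline.
#'
#' @inheritParams sim_decay_series
#' @param T_heat_C,T_cool_C Temperature grids for the two ramps.
#' @param reversible Whether cooling retraces the transition.
#' @return A [cd_data()] melt.
#' @export
sim_cd_melt <- function(truth, cfg = sim_config(),
                        T_heat_C = seq(20, 80, by = 2),
                        T_cool_C = seq(80, 20, by = -5),
                        reversible = TRUE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  p <- truth$cd_melt
  two_state <- function(T_C) {
    T_K <- T_C + 273.15
    K <- exp(-(p$dH_kcal / R_GAS_KCAL) * (1 / T_K - 1 / (p$midpoint_C + 273.15)))
    f <- K / (1 + K)
    p$theta_folded + (p$theta_unfolded - p$theta_folded) * f
  }
  to_mdeg <- function(theta) theta * 10 * p$conc_M * p$path_cm
  amp <- abs(to_mdeg(p$theta_unfolded - p$theta_folded))
  rows <- with_seed_local(cfg$seed + 606L, {
    heat <- data.frame(wavelength_nm = p$wavelength_nm, T_C = T_heat_C,
                       theta_mdeg = to_mdeg(two_state(T_heat_C)) +
                         rnorm(length(T_heat_C), 0, cfg$noise_sd * amp),
                       phase = "heat")
    cool_theta <- if (reversible) to_mdeg(two_state(T_cool_C)) else
      rep(to_mdeg(two_state(max(T_heat_C))), length(T_cool_C))
    cool <- data.frame(wavelength_nm = p$wavelength_nm, T_C = T_cool_C,
                       theta_mdeg = cool_theta +
                         rnorm(length(T_cool_C), 0, cfg$noise_sd * amp),
                       phase = "cool")
    rbind(heat, cool)
  })
  cd <- cd_data(rows, conc_M = p$conc_M, path_cm = p$path_cm)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_cd(cd, file.path(cfg$output_dir, "cd_melt.csv"))
    write_ground_truth(truth, file.path(cfg$output_dir, "ground_truth.json"))
  }
  cd
}

#' Idealized reference model for ensemble simulation
#'
#' A synthetic compact backbone (N, CA, C, O per residue along a smooth
#' superhelical curve) used as the reference when no experimental structure
#' is supplied. It is a stand-in, not a real protein fold.
#'
#' @param n_residues Number of residues.
#' @return A single-model [structure_ensemble()].
#' @export
reference_model <- function(n_residues = 60) {
  n <- as.integer(n_residues)
  t <- seq_len(n)
  # CA trace: helix wound on a slowly bending tube, ~3.8 A spacing
  ca <- cbind(8 * cos(t / 3.6) + 0.5 * t,
              8 * sin(t / 3.6) + 6 * sin(t / 25),
              1.2 * t + 6 * cos(t / 25))
  # place N/C/O near each CA with fixed local offsets
  offs <- list(N = c(-1.2, 0.6, 0.3), CA = c(0, 0, 0),
               C = c(1.2, 0.5, -0.3), O = c(1.8, 1.5, -0.4))
  atoms <- do.call(rbind, lapply(t, function(i) {
    data.frame(resno = i, resid = "ALA",
               elety = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"), chain = "A")
  }))
  xyz <- do.call(rbind, lapply(t, function(i) {
    do.call(rbind, lapply(offs, function(o) ca[i, ] + o))
  }))
  structure_ensemble(atoms, array(xyz, dim = c(nrow(xyz), 3, 1)),
                     source = "synthetic reference")
}

#' Simulate a coordinate ensemble with controlled dispersion
#'
#' Each model is the reference plus i.i.d. per-atom Gaussian displacement
#' with per-coordinate SD `dispersion / sqrt(6)`, chosen so the expected
#' pairwise backbone RMSD between two models is approximately `dispersion`
#' (the difference of two independent N(0, s^2) draws has variance 2 s^2
#' per coordinate, so E[RMSD^2] = 6 s^2).
#'
#' @param reference A single-model ensemble (default [reference_model()]).
#' @param n_models Number of models (>= 2).
#' @param dispersion Target pairwise RMSD, Angstroms (0 gives identical
#'   models).
#' @param cfg A [sim_config()].
#' @return An [structure_ensemble()] of `n_models` members. With
#'   `cfg$output_dir`, writes `ensemble.pdb`.
#' @export
sim_ensemble <- function(reference = reference_model(), n_models = 20,
                         dispersion = 1.0, cfg = sim_config()) {
  stopifnot(inherits(reference, "ensemble"), inherits(cfg, "sim_config"))
  assert_that(n_models >= 2, "n_models must be >= 2")
  assert_that(dispersion >= 0, "dispersion must be >= 0")
  ref <- reference$xyz[, , 1]
  s <- dispersion / sqrt(6)
  xyz <- with_seed_local(cfg$seed + 707L, {
    vapply(seq_len(n_models), function(m) {
      ref + matrix(rnorm(length(ref), 0, s), nrow(ref), 3)
    }, ref)
  })
  ens <- structure_ensemble(reference$atoms, xyz,
                            source = sprintf("synthetic ensemble (%g A)",
                                             dispersion))
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_ensemble(ens, file.path(cfg$output_dir, "ensemble.pdb"))
  }
  ens
}

#' Rigid-transformed copies of a model
#'
#' Applies random proper rotations and translations to model 1 of the
#' reference: superposition must recover each transform and report zero
#' RMSD, which makes these the canonical fixture for superposition tests.
#'
#' @inheritParams sim_ensemble
#' @param n_copies Number of transformed copies.
#' @param max_shift_A Translation magnitude bound per axis.
#' @return An ensemble of `n_copies + 1` models (model 1 is the original);
#'   attribute `transforms` holds the applied rotations/translations.
#' @export
sim_rigid_copies <- function(reference = reference_model(), n_copies = 3,
                             max_shift_A = 10, cfg = sim_config()) {
  stopifnot(inherits(reference, "ensemble"), inherits(cfg, "sim_config"))
  ref <- reference$xyz[, , 1]
  out <- with_seed_local(cfg$seed + 808L, {
    transforms <- lapply(seq_len(n_copies), function(i) {
      M <- matrix(rnorm(9), 3, 3)
      qr_ <- qr(M)
      R <- qr.Q(qr_)
      if (det(R) < 0) R[, 1] <- -R[, 1]
      list(rotation = R, translation = runif(3, -max_shift_A, max_shift_A))
    })
    xyz <- vapply(c(list(NULL), transforms), function(tr) {
      if (is.null(tr)) ref else sweep(ref %*% tr$rotation, 2,
                                      -tr$translation)
    }, ref)
    list(xyz = xyz, transforms = transforms)
  })
  ens <- structure_ensemble(reference$atoms, out$xyz,
                            source = "rigid copies")
  attr(ens, "transforms") <- out$transforms
  ens
}
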