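# Stage runners: thin orchestration over the analysis modules. Each takes a
# validated config (a named list or a YAML file path), runs one stage
# end-to-end on files, writes its outputs into the run directory, and
# returns the results invisibly. run_report() then aggregates whatever
# stage outputs a run directory holds.

validate_config <- function(config, known, required = character(0)) {
  if (is.character(config) && length(config) == 1) {
    assert_that(file.exists(config), "no such config file: %s", config)
    config <- yaml::read_yaml(config)
  }
  assert_that(is.list(config), "config must be a list or YAML path")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop_input("unknown config key(s): %s (known: %s)",
               paste(unknown, collapse = ", "), paste(known, collapse = ", "))
  }
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop_input("config lacks required key(s): %s",
               paste(missing, collapse = ", "))
  }
  config
}

out_dir_of <- function(config) {
  dir <- config$output_dir %||% "."
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run the relaxation stage on files
#'
#' Reads an R1 and an R2 decay table (and optionally a hetNOE pair table),
#' fits every residue, summarizes the profile, estimates the tumbling time
#' by both conventions, and writes `relax_profile.tsv` plus
#' `relax_summary.json` into the output directory.
#'
#' @param config Named list or YAML path. Keys: `r1_table`, `r2_table`
#'   (required), `hetnoe_table`, `nu_N` (Hz, default 60.81e6), `k_sd`,
#'   `hetnoe_threshold`, `n_boot`, `boot_seed`, `trim`, `output_dir`.
#' @return Invisibly, a list with the profile and both tau_c estimates.
#' @export
run_relax <- function(config) {
  config <- validate_config(config,
    known = c("r1_table", "r2_table", "hetnoe_table", "nu_N", "k_sd",
              "hetnoe_threshold", "n_boot", "boot_seed", "trim",
              "output_dir"),
    required = c("r1_table", "r2_table"))
  n_boot <- config$n_boot %||% 200
  boot_seed <- config$boot_seed %||% 1234
  r1 <- fit_rate_profile(read_decay_table(config$r1_table), n_boot, boot_seed)
  r2 <- fit_rate_profile(read_decay_table(config$r2_table), n_boot, boot_seed)
  noe <- if (!is.null(config$hetnoe_table)) {
    pair <- read_hetnoe_table(config$hetnoe_table)
    compute_hetnoe(pair$sat, pair$unsat)
  }
  profile <- summarize_profile(r1, r2, noe,
                               k_sd = config$k_sd %||% 2,
                               hetnoe_threshold = config$hetnoe_threshold %||% 0.6)
  nu_N <- config$nu_N %||% NU_N_DEFAULT
  tau <- profile_tau_c(profile, nu_N = nu_N, trim = config$trim %||% 0)

  dir <- out_dir_of(config)
  utils::write.table(profile$residues,
                     file.path(dir, "relax_profile.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  fl <- profile$residues
  write_json_report(list(
    summary = profile$summary,
    tau_c_ns = list(per_residue_mean = tau$per_residue_mean$tau_c_ns,
                    from_mean_rates = tau$from_mean_rates$tau_c_ns,
                    nu_N = nu_N, n_used = tau$n_used,
                    n_excluded = tau$n_excluded),
    flagged = list(low_R1 = fl$residue[fl$low_R1],
                   low_R2 = fl$residue[fl$low_R2],
                   low_hetNOE = fl$residue[fl$low_hetNOE %in% TRUE])),
    file.path(dir, "relax_summary.json"))
  invisible(list(profile = profile, tau_c = tau))
}

#' Run the CSP stage on files
#'
#' Computes per-site CSPs between an apo and a bound shift table,
#' classifies the binding surface with SD thresholds, and writes
#' `csp_profile.tsv` plus `csp_summary.json`. With `structure` set, also
#' writes a CSP-colored PDB.
#'
#' @param config Keys: `apo_table`, `bound_table` (required), `k_low`,
#'   `k_high`, `include_sidechain`, `structure` (PDB path), `output_dir`.
#' @return Invisibly, the [classify_csp()] profile.
#' @export
run_csp <- function(config) {
  config <- validate_config(config,
    known = c("apo_table", "bound_table", "k_low", "k_high",
              "include_sidechain", "structure", "output_dir"),
    required = c("apo_table", "bound_table"))
  apo <- read_shift_table(config$apo_table)
  bound <- read_shift_table(config$bound_table)
  profile <- classify_csp(compute_csp(apo, bound),
                          k_low = config$k_low %||% 1,
                          k_high = config$k_high %||% 2,
                          include_sidechain = config$include_sidechain %||% TRUE)
  dir <- out_dir_of(config)
  utils::write.table(profile$data, file.path(dir, "csp_profile.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_json_report(list(
    mean_ppm = profile$mean_ppm, sd_ppm = profile$sd_ppm,
    threshold_1sd = profile$threshold_1sd,
    threshold_2sd = profile$threshold_2sd,
    gt1sd = profile$data$residue[profile$data$class == "gt1sd"],
    gt2sd = profile$data$residue[profile$data$class == "gt2sd"],
    unmatched = nrow(profile$unmatched)),
    file.path(dir, "csp_summary.json"))
  if (!is.null(config$structure)) {
    map_csp_to_structure(profile, read_ensemble(config$structure),
                         file.path(dir, "csp_colored.pdb"))
  }
  invisible(profile)
}

#' Run the structure stage on files
#'
#' Verbs: `"stats"` (classify an XPLOR restraint file), `"rmsd"` (pairwise
#' ensemble RMSD over a selection), `"displace"` (probe-atom displacement
#' between two superposed ensembles). Writes `struct_<verb>.json`.
#'
#' @param config Keys: `verb` (required), `restraints` (stats),
#'   `ensemble` / `selection` / `atoms` (rmsd), plus `ensemble_b`,
#'   `probe_residue`, `probe_atom` (displace), `output_dir`. `selection`
#'   uses the `"3-97,104-113"` range syntax; `selection = "7wcg_ordered"`
#'   picks the ordered-residue preset.
#' @return Invisibly, the verb's result object.
#' @export
run_struct <- function(config) {
  config <- validate_config(config,
    known = c("verb", "restraints", "ensemble", "ensemble_b", "selection",
              "atoms", "probe_residue", "probe_atom", "output_dir"),
    required = "verb")
  dir <- out_dir_of(config)
  sel <- function() {
    atoms <- config$atoms %||% "backbone"
    if (identical(config$selection, "7wcg_ordered")) {
      selection_preset("7wcg_ordered", atoms)
    } else {
      residue_selection(config$selection, atoms)
    }
  }
  res <- switch(config$verb,
    stats = {
      stats <- classify_restraints(read_restraints_xplor(config$restraints))
      write_json_report(list(counts = as.list(stats$counts),
                             noe_total = stats$noe_total,
                             medium_share_pct = stats$medium_share_pct),
                        file.path(dir, "struct_stats.json"))
      stats
    },
    rmsd = {
      r <- ensemble_pairwise_rmsd(read_ensemble(config$ensemble), sel())
      write_json_report(list(mean_A = r$mean, sd_A = r$sd,
                             n_models = r$n_models, n_atoms = r$n_atoms,
                             atoms = r$atoms),
                        file.path(dir, "struct_rmsd.json"))
      r
    },
    displace = {
      d <- residue_displacement(read_ensemble(config$ensemble),
                                read_ensemble(config$ensemble_b), sel(),
                                probe_residue = config$probe_residue,
                                probe_atom = config$probe_atom %||% "CA")
      write_json_report(list(designated_A = d$designated, mean_A = d$mean,
                             sd_A = d$sd, probe_residue = d$probe_residue,
                             probe_atom = d$probe_atom),
                        file.path(dir, "struct_displace.json"))
      d
    },
    stop_input("unknown struct verb '%s' (stats, rmsd, displace)",
               config$verb))
  invisible(res)
}

#' Run the thermodynamics stage on files
#'
#' Verbs: `"dsc"` (two-state melt fit of a thermogram), `"itc"`
#' (independent-site fit of an isotherm), `"cd"` (molar-ellipticity melt
#' analysis). Writes `thermo_<verb>.json`.
#'
#' @param config Keys: `verb` (required); `thermogram`, `baseline_degree`
#'   (dsc); `isotherm`, `discard_first` (itc); `cd`, `wavelength_nm` (cd);
#'   `output_dir`.
#' @return Invisibly, the verb's fit object.
#' @export
run_thermo <- function(config) {
  config <- validate_config(config,
    known = c("verb", "thermogram", "baseline_degree", "isotherm",
              "discard_first", "cd", "wavelength_nm", "output_dir"),
    required = "verb")
  dir <- out_dir_of(config)
  res <- switch(config$verb,
    dsc = {
      fit <- fit_dsc_two_state(read_thermogram(config$thermogram),
                               baseline_degree = config$baseline_degree %||% 2)
      write_json_report(list(Tm_C = fit$Tm_C, Tm_K = fit$Tm_K,
                             dH_kcal = fit$dH_kcal, A = fit$A,
                             fit_rms = fit$fit_rms,
                             converged = fit$converged),
                        file.path(dir, "thermo_dsc.json"))
      fit
    },
    itc = {
      fit <- fit_itc_independent(read_isotherm(config$isotherm),
                                 discard_first = config$discard_first %||% FALSE)
      write_json_report(list(Kd_M = fit$Kd_M, Kd_uM = fit$Kd_M * 1e6,
                             n = fit$n, dH_kcal = fit$dH_kcal,
                             offset_ucal = fit$offset_ucal,
                             fit_rms = fit$fit_rms,
                             converged = fit$converged),
                        file.path(dir, "thermo_itc.json"))
      fit
    },
    cd = {
      ma <- melt_analysis(read_cd(config$cd),
                          wavelength_nm = config$wavelength_nm %||% 228)
      write_json_report(list(wavelength_nm = ma$wavelength_nm,
                             total_change = ma$total_change,
                             midpoint_C = ma$midpoint_C,
                             reversibility = ma$reversibility,
                             convention = ma$ellipticity_convention),
                        file.path(dir, "thermo_cd.json"))
      ma
    },
    stop_input("unknown thermo verb '%s' (dsc, itc, cd)", config$verb))
  invisible(res)
}

#' Aggregate stage outputs into one report
#'
#' Collects every `*_summary.json` / `struct_*.json` / `thermo_*.json` a
#' run directory holds into a single `report.json` and a human-readable
#' `report.md` mirroring the study's summary block (restraint table,
#' ensemble RMSD, tau_c, CSP classes, Tm, Kd/n). Missing stages are
#' listed as absent, never fatal. Re-running on the same directory is
#' byte-identical.
#'
#' @param config Keys: `run_dir` (required), `output_dir` (default:
#'   `run_dir`).
#' @return Invisibly, the report list.
#' @export
run_report <- function(config) {
  config <- validate_config(config, known = c("run_dir", "output_dir"),
                            required = "run_dir")
  rd <- config$run_dir
  assert_that(dir.exists(rd), "no such run directory: %s", rd)
  sections <- c(relax = "relax_summary.json", csp = "csp_summary.json",
                restraints = "struct_stats.json", rmsd = "struct_rmsd.json",
                displacement = "struct_displace.json",
                dsc = "thermo_dsc.json", itc = "thermo_itc.json",
                cd = "thermo_cd.json")
  report <- lapply(sections, function(f) {
    p <- file.path(rd, f)
    if (file.exists(p)) jsonlite::read_json(p) else "absent"
  })
  report$package_version <- as.character(utils::packageVersion("ssbnmr"))
  dir <- config$output_dir %||% rd
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_json_report(report, file.path(dir, "report.json"))

  md <- c("# Analysis report", "")
  for (nm in names(sections)) {
    md <- c(md, sprintf("## %s", nm))
    sec <- report[[nm]]
    if (identical(sec, "absent")) {
      md <- c(md, "absent", "")
    } else {
      md <- c(md, "```", jsonlite::toJSON(sec, auto_unbox = TRUE,
                                          pretty = TRUE, digits = NA,
                                          na = "null"), "```", "")
    }
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(report)
}
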