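# Plain-text I/O for every table the pipeline consumes or emits. All
# tables are TSV/CSV with documented column schemas; metadata that a bare
# table cannot carry (concentrations, volumes) travels in '#'-prefixed
# header comments.

read_table_checked <- function(path, need, sep = "\t") {
  assert_that(file.exists(path), "no such file: %s", path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) stop_input("cannot read %s: %s", path, conditionMessage(e)))
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_input("%s lacks column(s) %s; expected schema: %s", path,
               paste(missing, collapse = ", "), paste(need, collapse = ", "))
  }
  tab
}

read_meta_comments <- function(path) {
  lines <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  kv <- regmatches(lines, regexec("^#\\s*([A-Za-z0-9_]+)\\s*[:=]\\s*(.+)$",
                                  lines))
  out <- list()
  for (m in kv) {
    if (length(m) == 3) out[[m[2]]] <- as.numeric(m[3])
  }
  out
}

#' Read/write peak-height decay tables
#'
#' Schema: `residue`, `residue_name`, `delay_s`, `height`,
#' `height_error` (optional values may be NA), `overlapped`.
#'
#' @param path TSV path.
#' @return `read_decay_table()`: a list of [decay_series()].
#' @export
read_decay_table <- function(path) {
  tab <- read_table_checked(path, c("residue", "delay_s", "height"))
  if (nrow(tab) == 0) stop_input("%s is empty; schema: residue, residue_name, delay_s, height[, height_error, overlapped]", path)
  lapply(split(tab, tab$residue), function(d) {
    d <- d[order(d$delay_s), ]
    he <- d[["height_error"]]
    if (!is.null(he) && all(is.na(he))) he <- NULL
    decay_series(d$residue[1], d$delay_s, d$height,
                 residue_name = (d[["residue_name"]] %||% "X")[1],
                 height_errors = he,
                 overlapped = isTRUE(d[["overlapped"]][1]))
  })
}

#' @rdname read_decay_table
#' @param series_list List of [decay_series()].
#' @export
write_decay_table <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(residue = s$residue, residue_name = s$residue_name,
               delay_s = s$delays, height = s$heights,
               height_error = s$height_errors %||% NA_real_,
               overlapped = s$overlapped)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a saturated/unsaturated hetNOE table
#'
#' Schema: `residue`, `residue_name`, `sat_height`, `unsat_height`,
#' `sat_error`, `unsat_error`.
#'
#' @param path TSV path.
#' @return List with `sat` and `unsat` data frames for [compute_hetnoe()].
#' @export
read_hetnoe_table <- function(path) {
  tab <- read_table_checked(path, c("residue", "sat_height", "unsat_height"))
  list(sat = data.frame(residue = tab$residue,
                        residue_name = tab[["residue_name"]] %||% "X",
                        height = tab$sat_height,
                        height_error = tab[["sat_error"]] %||% 0),
       unsat = data.frame(residue = tab$residue,
                          residue_name = tab[["residue_name"]] %||% "X",
                          height = tab$unsat_height,
                          height_error = tab[["unsat_error"]] %||% 0))
}

#' Read/write assigned shift tables
#'
#' Schema: `residue`, `residue_name`, `site`, `delta_H_ppm`,
#' `delta_N_ppm`, `ratio` (constant per file).
#'
#' @param path TSV path.
#' @return `read_shift_table()`: a [shift_table()].
#' @export
read_shift_table <- function(path) {
  tab <- read_table_checked(path, c("residue", "site", "delta_H_ppm",
                                    "delta_N_ppm"))
  ratio <- if ("ratio" %in% names(tab)) tab$ratio[1] else 0
  shift_table(tab[, setdiff(names(tab), "ratio")], ratio = ratio)
}

#' @rdname read_shift_table
#' @param tb A [shift_table()].
#' @export
write_shift_table <- function(tb, path) {
  d <- tb$data
  d$ratio <- tb$ratio
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write DSC thermograms
#'
#' Schema: `T_C`, `Cp_kcal_mol_K` (CSV). Temperatures are degrees Celsius
#' on disk, Kelvin in memory.
#'
#' @param path CSV path.
#' @return `read_thermogram()`: a [thermogram()].
#' @export
read_thermogram <- function(path) {
  tab <- read_table_checked(path, c("T_C", "Cp_kcal_mol_K"), sep = ",")
  thermogram(tab$T_C + 273.15, tab$Cp_kcal_mol_K)
}

#' @rdname read_thermogram
#' @param tg A [thermogram()].
#' @export
write_thermogram <- function(tg, path) {
  utils::write.table(data.frame(T_C = tg$T_K - 273.15,
                                Cp_kcal_mol_K = tg$Cp),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write ITC isotherms
#'
#' Schema: `inj_vol_uL`, `heat_ucal` (CSV), with cell geometry in header
#' comments: `# V0_mL:`, `# cell_M:`, `# syringe_M:`, `# temperature_K:`.
#'
#' @param path CSV path.
#' @return `read_isotherm()`: an [itc_isotherm()].
#' @export
read_isotherm <- function(path) {
  tab <- read_table_checked(path, c("inj_vol_uL", "heat_ucal"), sep = ",")
  meta <- read_meta_comments(path)
  for (k in c("V0_mL", "cell_M", "syringe_M")) {
    assert_that(!is.null(meta[[k]]), "%s lacks '# %s:' header metadata",
                path, k)
  }
  itc_isotherm(tab$inj_vol_uL, tab$heat_ucal, V0_mL = meta$V0_mL,
               cell_M = meta$cell_M, syringe_M = meta$syringe_M,
               temperature_K = meta$temperature_K %||% 298.15)
}

#' @rdname read_isotherm
#' @param iso An [itc_isotherm()].
#' @export
write_isotherm <- function(iso, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %.10g",
                     c("V0_mL", "cell_M", "syringe_M", "temperature_K"),
                     c(iso$V0_mL, iso$cell_M, iso$syringe_M,
                       iso$temperature_K)), con)
  utils::write.table(data.frame(inj_vol_uL = iso$inj_vol_uL,
                                heat_ucal = iso$heats_ucal),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write CD data
#'
#' Schema: `wavelength_nm`, `theta_mdeg` and, for melts, `T_C` and
#' `phase`; geometry in header comments `# conc_M:`, `# path_cm:`.
#'
#' @param path CSV path.
#' @return `read_cd()`: a [cd_data()].
#' @export
read_cd <- function(path) {
  tab <- read_table_checked(path, c("wavelength_nm", "theta_mdeg"), sep = ",")
  meta <- read_meta_comments(path)
  assert_that(!is.null(meta$conc_M) && !is.null(meta$path_cm),
              "%s lacks '# conc_M:' / '# path_cm:' header metadata", path)
  cd_data(tab, conc_M = meta$conc_M, path_cm = meta$path_cm)
}

#' @rdname read_cd
#' @param cd A [cd_data()].
#' @export
write_cd <- function(cd, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %.10g", c("conc_M", "path_cm"),
                     c(cd$conc_M, cd$path_cm)), con)
  cols <- intersect(c("wavelength_nm", "theta_mdeg", "T_C", "phase"),
                    names(cd$data))
  utils::write.table(cd$data[, cols], con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
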