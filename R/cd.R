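#' Construct a CD measurement object
#'
#' Holds observed far-UV circular-dichroism ellipticities (mdeg) on a
#' wavelength grid, optionally across a temperature series (a melt), with
#' the sample geometry needed to convert to molar ellipticity.
#'
#' @param data Data frame with columns `wavelength_nm`, `theta_mdeg`, and
#'   optionally `T_C` and `phase` (`"heat"`/`"cool"`) for melts.
#' @param conc_M Protein concentration, mol/L.
#' @param path_cm Cuvette path length, cm.
#' @return A list of class `"cd_data"`.
#' @export
cd_data <- function(data, conc_M, path_cm) {
  assert_that(is.data.frame(data) &&
                all(c("wavelength_nm", "theta_mdeg") %in% names(data)),
              "data needs columns wavelength_nm, theta_mdeg")
  assert_that(is_number(conc_M) && conc_M > 0, "conc_M must be > 0")
  assert_that(is_number(path_cm) && path_cm > 0, "path_cm must be > 0")
  structure(list(data = data, conc_M = conc_M, path_cm = path_cm),
            class = "cd_data")
}

#' Molar ellipticity from observed ellipticity
#'
#' \deqn{[\theta] = \frac{\theta_{obs}(\mathrm{mdeg})}{10\, c\, l}}
#' with concentration `c` in mol/L and path length `l` in cm, giving
#' per-protein molar ellipticity in deg cm2 dmol-1.
#'
#' @param cd A [cd_data()] object.
#' @return The same object with a `theta_molar` column added.
#' @export
cd_molar_ellipticity <- function(cd) {
  stopifnot(inherits(cd, "cd_data"))
  cd$data$theta_molar <- cd$data$theta_mdeg / (10 * cd$conc_M * cd$path_cm)
  cd
}

#' Thermal-melt analysis of a CD temperature series
#'
#' Extracts the molar-ellipticity trace at one wavelength from a CD melt,
#' reports the endpoint-to-endpoint change over the heating ramp, fits a
#' two-state (van 't Hoff) sigmoid to locate the melt midpoint, and, when a
#' cooling ramp is present, scores reversibility as
#' \eqn{1 - |[\theta]_{final,cooled} - [\theta]_{initial}| / |\Delta[\theta]_{total}|}.
#'
#' @param cd A [cd_data()] melt (columns `T_C` and `phase` required).
#' @param wavelength_nm Wavelength to analyse (must be on the grid).
#' @return A list of class `"melt_analysis"` with the heating/cooling
#'   traces, `total_change` (deg cm2 dmol-1), `midpoint_C` (NA when the
#'   sigmoid fit fails), and `reversibility` (NA without cooling data).
#' @export
melt_analysis <- function(cd, wavelength_nm = 228) {
  stopifnot(inherits(cd, "cd_data"))
  assert_that("T_C" %in% names(cd$data), "melt requires a T_C column")
  cd <- cd_molar_ellipticity(cd)
  d <- cd$data
  if (!"phase" %in% names(d)) d$phase <- "heat"
  wl <- unique(d$wavelength_nm)
  if (!any(abs(wl - wavelength_nm) < 1e-6)) {
    stop_input("wavelength %.1f nm not on the measured grid", wavelength_nm)
  }
  d <- d[abs(d$wavelength_nm - wavelength_nm) < 1e-6, , drop = FALSE]
  heat <- d[d$phase == "heat", ]
  heat <- heat[order(heat$T_C), ]
  assert_that(nrow(heat) >= 5, "heating series too short")
  cool <- d[d$phase == "cool", ]
  cool <- cool[order(cool$T_C), ]

  total_change <- heat$theta_molar[nrow(heat)] - heat$theta_molar[1]

  midpoint_C <- tryCatch({
    T_K <- heat$T_C + 273.15
    y <- heat$theta_molar
    start <- c(tf = y[1], tu = y[length(y)],
               Tm = mean(range(T_K)), dH = 50)
    fn <- function(p) {
      K <- exp(-(p[["dH"]] / R_GAS_KCAL) * (1 / T_K - 1 / p[["Tm"]]))
      f <- K / (1 + K)
      y - (p[["tf"]] + (p[["tu"]] - p[["tf"]]) * f)
    }
    fit <- minpack.lm::nls.lm(par = start, fn = fn,
                              lower = c(-Inf, -Inf, min(T_K), 1),
                              upper = c(Inf, Inf, max(T_K), 2000))
    unname(fit$par[["Tm"]] - 273.15)
  }, error = function(e) NA_real_)

  reversibility <- NA_real_
  if (nrow(cool) >= 2 && abs(total_change) > 0) {
    # after cooling back down, how much of the signal change was recovered
    final_cooled <- cool$theta_molar[which.min(cool$T_C)]
    reversibility <- 1 - abs(final_cooled - heat$theta_molar[1]) /
      abs(total_change)
  }

  structure(list(wavelength_nm = wavelength_nm, heating = heat,
                 cooling = if (nrow(cool)) cool else NULL,
                 total_change = total_change, midpoint_C = midpoint_C,
                 reversibility = reversibility,
                 ellipticity_convention = "per-protein molar"),
            class = "melt_analysis")
}

#' @export
print.melt_analysis <- function(x, ...) {
  cat(sprintf("CD melt at %.0f nm (%s ellipticity)\n", x$wavelength_nm,
              x$ellipticity_convention))
  cat(sprintf("  total change %.4g deg cm2 dmol-1, midpoint %.1f degC\n",
              x$total_change, x$midpoint_C))
  if (!is.na(x$reversibility)) {
    cat(sprintf("  reversibility %.2f\n", x$reversibility))
  }
  invisible(x)
}
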