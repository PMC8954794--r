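#' Construct an assigned chemical-shift table
#'
#' Backbone amide (and Trp side-chain NeH) \eqn{^1}H/\eqn{^{15}}N shifts at
#' one titration point. Sites are keyed by `(residue, site)` and must be
#' unique within a table.
#'
#' @param data Data frame with columns `residue`, `site`
#'   (`"backbone_NH"` or `"trp_sidechain_NeH"`), `delta_H_ppm`,
#'   `delta_N_ppm`; optional `residue_name`.
#' @param ratio Molar ratio (ligand:protein) of this titration point.
#' @param temperature_C Condition label.
#' @return A list of class `"shift_table"`.
#' @export
shift_table <- function(data, ratio = 0, temperature_C = NA_real_) {
  need <- c("residue", "site", "delta_H_ppm", "delta_N_ppm")
  assert_that(is.data.frame(data) && all(need %in% names(data)),
              "data needs columns %s", paste(need, collapse = ", "))
  key <- paste(data$residue, data$site)
  assert_that(!anyDuplicated(key), "(residue, site) keys must be unique")
  assert_that(all(is.finite(data$delta_H_ppm)) &&
                all(is.finite(data$delta_N_ppm)), "shifts must be finite")
  structure(list(data = data, ratio = ratio, temperature_C = temperature_C),
            class = "shift_table")
}

#' Per-site chemical-shift perturbation
#'
#' Combined amide CSP between two assigned shift tables:
#' \deqn{\Delta\delta_{avg} = \sqrt{(\Delta\delta_N/5.88)^2 +
#'   (\Delta\delta_H)^2}}
#' where 5.88 is the conventional \eqn{^{15}}N-to-\eqn{^1}H scaling. Sites
#' present in only one table (e.g. broadened beyond detection on binding)
#' are returned in `unmatched`, never silently dropped or imputed.
#'
#' @param apo,bound [shift_table()]s (reference and perturbed states).
#' @return A list of class `"csp_values"`: `data` (residue, site,
#'   delta_H/N differences, `csp_ppm`) and `unmatched`.
#' @export
compute_csp <- function(apo, bound) {
  stopifnot(inherits(apo, "shift_table"), inherits(bound, "shift_table"))
  a <- apo$data; b <- bound$data
  m <- merge(a, b, by = c("residue", "site"), suffixes = c("_apo", "_bound"))
  if (nrow(m) == 0) stop_input("no shared (residue, site) keys between tables")
  dH <- m$delta_H_ppm_bound - m$delta_H_ppm_apo
  dN <- m$delta_N_ppm_bound - m$delta_N_ppm_apo
  res <- data.frame(residue = m$residue, site = m$site,
                    residue_name = m[["residue_name_apo"]] %||% "X",
                    delta_H = dH, delta_N = dN,
                    csp_ppm = sqrt((dN / 5.88)^2 + dH^2))
  res <- res[order(res$residue, res$site), ]
  keys_a <- paste(a$residue, a$site)
  keys_b <- paste(b$residue, b$site)
  unmatched <- data.frame(
    residue = c(a$residue[!keys_a %in% keys_b], b$residue[!keys_b %in% keys_a]),
    site = c(a$site[!keys_a %in% keys_b], b$site[!keys_b %in% keys_a]),
    missing_in = c(rep("bound", sum(!keys_a %in% keys_b)),
                   rep("apo", sum(!keys_b %in% keys_a))))
  structure(list(data = res, unmatched = unmatched,
                 ratio = bound$ratio, temperature_C = bound$temperature_C),
            class = "csp_values")
}

#' Classify the binding surface by SD thresholds
#'
#' Computes the mean and SD of the CSP over all quantified sites (backbone
#' and Trp side-chain pooled by default) and assigns each site a class:
#' `gt2sd` if the CSP exceeds `mean + k_high * SD`, else `gt1sd` if it
#' exceeds `mean + k_low * SD`, else `below`. Thresholds are one-sided:
#' the CSP is non-negative by construction, so only the upper tail marks
#' binding-site residues.
#'
#' @param csp A [compute_csp()] result.
#' @param k_low,k_high SD multiples for the two classes (defaults 1 and 2).
#' @param include_sidechain Pool Trp side-chain sites into the statistics.
#' @return A list of class `"csp_profile"`: per-site table with `class`,
#'   `mean_ppm`, `sd_ppm`, the thresholds, and the unmatched-site list.
#' @export
classify_csp <- function(csp, k_low = 1, k_high = 2,
                         include_sidechain = TRUE) {
  stopifnot(inherits(csp, "csp_values"))
  d <- csp$data
  pool <- if (include_sidechain) rep(TRUE, nrow(d)) else
    d$site == "backbone_NH"
  assert_that(sum(pool) >= 5, "need at least 5 sites to classify")
  mu <- mean(d$csp_ppm[pool])
  sdv <- stats::sd(d$csp_ppm[pool])
  thr_low <- mu + k_low * sdv
  thr_high <- mu + k_high * sdv
  d$class <- ifelse(d$csp_ppm > thr_high, "gt2sd",
                    ifelse(d$csp_ppm > thr_low, "gt1sd", "below"))
  structure(list(data = d, mean_ppm = mu, sd_ppm = sdv,
                 threshold_1sd = thr_low, threshold_2sd = thr_high,
                 k_low = k_low, k_high = k_high,
                 unmatched = csp$unmatched, ratio = csp$ratio),
            class = "csp_profile")
}

#' @export
print.csp_profile <- function(x, ...) {
  cat(sprintf("CSP profile at ratio %.2g: mean %.4f ppm, SD %.4f ppm\n",
              x$ratio, x$mean_ppm, x$sd_ppm))
  g2 <- x$data$residue[x$data$class == "gt2sd"]
  g1 <- x$data$residue[x$data$class == "gt1sd"]
  cat(sprintf("  > mean+%gSD (%.4f ppm): %s\n", x$k_high, x$threshold_2sd,
              if (length(g2)) paste(g2, collapse = ", ") else "none"))
  cat(sprintf("  > mean+%gSD (%.4f ppm): %s\n", x$k_low, x$threshold_1sd,
              if (length(g1)) paste(g1, collapse = ", ") else "none"))
  if (nrow(x$unmatched)) {
    cat(sprintf("  %d unmatched site(s)\n", nrow(x$unmatched)))
  }
  invisible(x)
}

#' CSP trajectory along a titration
#'
#' CSP of every table against the ratio-0 (apo) reference, per site, plus a
#' per-site monotonicity check: sites whose CSP decreases between
#' consecutive ratios by more than `noise_floor` are flagged (fast-exchange
#' one-site binding predicts monotone growth toward saturation).
#'
#' @param tables List of [shift_table()]s ordered by ascending molar ratio;
#'   the first must be ratio 0.
#' @param noise_floor Allowed CSP decrease (ppm) before flagging.
#' @return List of class `"csp_trajectory"`: long data frame (residue,
#'   site, ratio, csp_ppm) and `nonmonotone` site list.
#' @export
titration_trajectory <- function(tables, noise_floor = 0.005) {
  assert_that(length(tables) >= 2, "need at least 2 titration points")
  ratios <- vapply(tables, function(x) x$ratio, numeric(1))
  assert_that(ratios[1] == 0, "first table must be the apo reference (ratio 0)")
  assert_that(all(diff(ratios) > 0), "ratios must be strictly increasing")
  apo <- tables[[1]]
  traj <- do.call(rbind, lapply(tables[-1], function(tb) {
    v <- compute_csp(apo, tb)
    cbind(v$data[, c("residue", "site", "csp_ppm")], ratio = tb$ratio)
  }))
  key <- paste(traj$residue, traj$site)
  nonmono <- unique(key[unlist(lapply(split(seq_len(nrow(traj)), key),
    function(idx) {
      v <- traj$csp_ppm[idx][order(traj$ratio[idx])]
      idx[any(diff(v) < -noise_floor)]
    }))])
  structure(list(trajectory = traj, ratios = ratios[-1],
                 nonmonotone = nonmono),
            class = "csp_trajectory")
}

#' Write a CSP-colored structure
#'
#' Writes model 1 of an ensemble as a PDB file with each residue's CSP (ppm,
#' scaled x100) in the B-factor column — the conventional trick for painting
#' a binding surface in molecular-graphics programs — plus a sidecar TSV
#' with the class labels. Atoms of residues without a CSP get B = 0.
#'
#' @param profile A [classify_csp()] result.
#' @param ensemble A [read_ensemble()] structure.
#' @param path Output PDB path (sidecar written as `<path>.classes.tsv`).
#' @return Invisibly, the output path.
#' @export
map_csp_to_structure <- function(profile, ensemble, path) {
  stopifnot(inherits(profile, "csp_profile"), inherits(ensemble, "ensemble"))
  d <- profile$data[profile$data$site == "backbone_NH", ]
  if (nrow(d) == 0) stop_input("profile has no backbone sites to map")
  if (!any(d$residue %in% ensemble$atoms$resno)) {
    stop_input("no residue overlap between CSP profile and structure")
  }
  b <- rep(0, nrow(ensemble$atoms))
  idx <- match(ensemble$atoms$resno, d$residue)
  hit <- !is.na(idx)
  b[hit] <- round(100 * d$csp_ppm[idx[hit]], 2)
  write_ensemble(ensemble, path, models = 1L, b_factors = b)
  utils::write.table(d[, c("residue", "site", "csp_ppm", "class")],
                     paste0(path, ".classes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
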