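#' Relaxation-delay presets
#'
#' Named delay schedules (in seconds) for the pseudo-3D \eqn{^{15}}N R1 and
#' R2 experiments: ten delays from 20 to 1600 ms for R1 and ten delays from
#' 16.96 to 547.72 ms for R2, the schedules used to record the data this
#' package analyses.
#'
#' @param experiment `"R1"` or `"R2"`.
#' @return Numeric vector of relaxation delays in seconds.
#' @examples
#' relax_delays("R1")
#' @export
relax_delays <- function(experiment = c("R1", "R2")) {
  experiment <- match.arg(experiment)
  switch(experiment,
    R1 = c(20, 60, 100, 200, 400, 600, 800, 1000, 1200, 1600) / 1000,
    R2 = c(16.96, 33.92, 67.84, 101.76, 135.68, 203.52, 271.36, 339.2,
           407.04, 547.72) / 1000
  )
}

#' Default 15N resonance frequency (Hz)
#'
#' 60.81 MHz, the \eqn{^{15}}N Larmor frequency on the 600 MHz (1H)
#' spectrometer the relaxation data were recorded on. Every function taking
#' `nu_N` accepts an override.
#' @export
NU_N_DEFAULT <- 60.81e6

#' Residue-selection presets
#'
#' `"7wcg_ordered"` is the ordered-residue set used for ensemble RMSD:
#' residues 3-97 and 104-113 (the disordered L12 tip, the 98-103 loop and
#' the chain termini are excluded).
#'
#' @param name Preset name.
#' @param atoms Atom class for the selection.
#' @return A [residue_selection()] object.
#' @export
selection_preset <- function(name = "7wcg_ordered",
                             atoms = c("backbone", "heavy", "calpha", "all")) {
  atoms <- match.arg(atoms)
  if (name != "7wcg_ordered") {
    stop_input("unknown selection preset '%s'", name)
  }
  residue_selection(list(c(3, 97), c(104, 113)), atoms = atoms)
}
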