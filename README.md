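# ssbnmr

Quantitative analysis pipeline for the high-temperature biophysical
characterization of a thermophilic single-stranded-DNA-binding (SSB)
protein: NMR backbone relaxation, chemical-shift-perturbation (CSP)
mapping of the ssDNA-binding surface, NOE distance-restraint statistics
and ensemble geometry, and thermal/binding thermodynamics (DSC, ITC, CD).
It is aimed at structural-biology groups who have extracted per-residue
peak-height tables, assigned shift tables, deposited-style restraint and
coordinate files, or calorimetry traces, and want the standard derived
quantities with tested, reproducible numerics. A synthetic-data generator
with known ground truth makes every stage verifiable by parameter
recovery, without downloading anything.

## What it computes

**Backbone relaxation.** Per-residue ¹⁵N R₁ and R₂ from single-exponential
fits of peak height vs relaxation delay, I(t) = I₀·e^(−Rt), with
Monte-Carlo rate errors; heteronuclear NOE as the saturated/unsaturated
peak-height ratio; ensemble means ± SD; flexibility flags (rates deviating
> 2 SD from the mean, hetNOE < 0.6). The rotational correlation time comes
from the R₂/R₁ ratio,

    τ_c = 1/(4π·ν_N) · sqrt(6·R₂/R₁ − 7),

with ν_N the ¹⁵N resonance frequency (default 60.81 MHz), reported both
from the profile-mean rates and as the per-residue average.

**CSP mapping.** Combined amide perturbation
Δδ_avg = sqrt((Δδ_N/5.88)² + Δδ_H²) per (residue, site) key, including Trp
side-chain NεH sites; binding-surface classification at mean + 1·SD and
mean + 2·SD; titration trajectories against the quadratic-root fractional
saturation of one-site binding; B-factor painting of a structure for
molecular graphics.

**Restraints and ensembles.** An XPLOR `assign`-statement parser;
classification by sequence separation |i−j| (intra / sequential / medium
1<|i−j|≤5 / long >5, H-bonds separate) with the medium-range share of NOE
restraints; Kabsch (SVD, reflection-corrected) superposition; pairwise
ensemble RMSD over residue/atom-class selections; probe-atom displacement
between superposed structures (e.g. a binding-loop Cα between apo and
DNA-bound forms).

**Thermodynamics.** Two-state scaled DSC fit
Cp(T) = b(T) + A·ΔH²/(RT²)·K/(1+K)², K = exp[−(ΔH/R)(1/T − 1/T_m)];
independent-site (Wiseman) ITC fit with exponential-dilution volume
bookkeeping returning K_d, n, ΔH and a dilution offset; CD molar
ellipticity [θ] = θ_obs/(10·c·l) with melt-midpoint and reversibility
analysis.

## Worked example

Simulate the 50 °C study condition (1% spectral noise), fit everything,
and read off the recovered parameters:

```r
library(ssbnmr)
truth <- ground_truth(condition = "50C")         # known true parameters
cfg   <- sim_config(seed = 42, noise_sd = 0.01)

r1 <- fit_rate_profile(sim_decay_series(truth, cfg = cfg, rate = "R1"), n_boot = 0)
r2 <- fit_rate_profile(sim_decay_series(truth, cfg = cfg, rate = "R2"), n_boot = 0)
hp <- sim_hetnoe_pairs(truth, cfg)
prof <- summarize_profile(r1, r2, compute_hetnoe(hp$sat, hp$unsat))
print(prof)
print(profile_tau_c(prof))
print(fit_itc_independent(sim_itc_isotherm(truth, cfg)))
print(fit_dsc_two_state(sim_dsc_thermogram(truth, cfg = cfg)))
```

```
Relaxation profile over 114 usable residues
  R1 1.875 +/- 0.240 Hz | R2 6.695 +/- 1.119 Hz | hetNOE 0.739 +/- 0.108
  flagged residues: 32, 34, 35, 36, 91, 97, 98, 99, 108, 110
tau_c: 4.952 ns (per-residue mean, n=104) | 4.959 ns (from mean rates)
Independent-site ITC fit: Kd = 1.79e-06 M (1.79 uM), n = 1.014, dH = -10.02 kcal/mol
  dilution offset 0.0951 ucal/inj, fit RMS 0.528 ucal, converged: TRUE
Two-state DSC fit: Tm = 84.16 degC (357.31 K), dH = 100.0 kcal/mol, A = 1.000
  fit RMS 0.09612 kcal mol-1 K-1, converged: TRUE
```

The profile means sit a few percent below the rigid-residue truth because
the planted flexible loop/terminus residues (32–36, 97–99, 110) pull the
ensemble average down — exactly the residues the 2-SD and hetNOE < 0.6
flags then pick out (plus the occasional statistical outlier, 91 and 108
here). τ_c ≈ 5 ns is the fast tumbling of a small protein at 50 °C; the
ITC fit recovers K_d = 1.79 μM and n = 1.01 from 24 injections at 1%
noise; the DSC fit recovers the 84.16 °C melting midpoint to two decimals.

File-based workflows use the same machinery through `run_relax()`,
`run_csp()`, `run_struct()`, `run_thermo()` (YAML or list configs,
TSV/CSV/PDB in, TSV + JSON out) and `run_report()` to aggregate a run
directory into one report.

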