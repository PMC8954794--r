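---
title: "Models and methods behind ssbnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssbnmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbnmr)
```

ssbnmr implements the quantitative analyses used to characterize a
thermophilic single-stranded-DNA-binding protein at elevated temperature.
This vignette explains each model, its assumptions, the tunable
parameters, the synthetic-data generator that stands behind the tests,
and the numerical and design choices a careful user should know about.

## Backbone relaxation

Peak-height decays from pseudo-3D ¹⁵N relaxation experiments are fit to a
single exponential $I(t) = I_0 e^{-Rt}$ by Levenberg–Marquardt least
squares (`minpack.lm`). The model assumes mono-exponential relaxation —
valid for amide ¹⁵N R₁/R₂ in the absence of strong conformational
exchange — and treats peak height as proportional to magnetization.
Initial guesses are $I_0 = \max I$ and the two-point log-slope estimate of
$R$, clipped to $(10^{-3}, 10^{3})$ Hz; the clip bounds also serve as hard
optimizer bounds, so a pathological series (all heights equal) converges
to the lower clip with a warning instead of diverging. Rate uncertainties
come from 200 Monte-Carlo refits with synthetic Gaussian noise at the
scale of the fit residuals (or the supplied per-point errors), under a
fixed internal seed (1234) so repeated calls agree. A failed optimization
returns `converged = FALSE`, never an exception, so one bad residue cannot
abort a profile.

The heteronuclear NOE is the ratio of saturated to unsaturated peak
heights with errors propagated in quadrature. Profile summaries exclude
overlapped peaks and unconverged fits, and require at least five usable
residues — below that, means and SDs are not meaningful and the function
refuses.

Flexibility flags follow the conventional criteria: rates deviating more
than `k_sd` (default 2) standard deviations from the ensemble mean — the
detection is two-sided but the direction is recorded, since depressed
rates are the biologically interesting tail at high temperature — and
hetNOE below an absolute threshold (default 0.6, the usual cutoff for
fast ps–ns backbone motion; configurable).

### Rotational correlation time

For isotropic tumbling in the slow-motion limit,

$$\tau_c = \frac{1}{4\pi\nu_N}\sqrt{6\,R_2/R_1 - 7},$$

with $\nu_N$ the ¹⁵N resonance frequency in Hz (default 60.81 MHz, i.e. a
600 MHz ¹H spectrometer, overridable everywhere it appears). The radicand
must be non-negative: at $R_2/R_1 = 7/6$ the formula gives the limiting
$\tau_c = 0$, and below it the estimate is returned as flagged-undefined
rather than a silent `NaN`. `profile_tau_c()` reports the estimate under
*both* averaging conventions — per-residue $\tau_c$ averaged over usable,
unflagged residues (with optional symmetric trimming, default 0), and
$\tau_c$ of the profile-mean rates — because the two differ by roughly a
percent on realistic profiles and published values rarely state which was
used. Downstream comparisons should therefore carry a ~2% tolerance on
$\tau_c$.

## Chemical-shift perturbation

The combined amide CSP is
$\Delta\delta_{avg} = \sqrt{(\Delta\delta_N/5.88)^2 + (\Delta\delta_H)^2}$,
with 5.88 the conventional nitrogen-to-proton scaling. Matching between
apo and bound tables is strictly by `(residue, site)` key — the inputs are
assigned tables, not raw peak lists, so no chemical-shift-distance
tracking is attempted. Sites present in only one table (typically peaks
broadened beyond detection during the titration) are reported as
unmatched; no imputation rule is applied, because any single choice (drop,
or assign a large sentinel CSP) silently biases the profile statistics.

Classification computes the mean and SD over all quantified sites —
pooling Trp side-chain NεH entries with backbone amides by default, since
side-chain sites belong to the same binding surface; `include_sidechain =
FALSE` restricts the statistics to backbone sites. Thresholds are
one-sided (`mean + 1·SD`, `mean + 2·SD`): the CSP is non-negative by
construction, so only the upper tail is informative. Titration
trajectories additionally flag sites whose CSP *decreases* between
consecutive ratios by more than a noise floor (default 0.005 ppm), since
fast-exchange one-site binding predicts monotone growth toward
saturation.

Whether published profile statistics were computed at the titration
endpoint or pooled over ratios is often unstated; this package computes
per-ratio profiles and uses the endpoint by default.

## Restraints and ensemble geometry

The XPLOR `assign` parser accepts the dialect of deposited `.mr` files:
statements may span lines, `!` and `{...}` comments are stripped,
OR-grouped ambiguous selections take the first `(resid … name …)` pair and
are flagged, and unparseable statements are collected into a line-numbered
error report without aborting the parse. A restraint counts once
regardless of how many atom pairs its pseudo-atom or OR-group selection
expands to — restraint tables count restraints, not pairs. Hydrogen-bond
restraints are recognized by a comment block announcing them plus a
donor–acceptor-like atom pair (N/H/HN against O*), and are tallied outside
the NOE categories.

Classification bins NOE records by sequence separation $s = |i-j|$:
intra ($s=0$), sequential ($s=1$), medium ($1 < s \le 5$), long
($s > 5$); the four categories partition the NOE set exactly, and the
medium-range share (percent of NOE-derived distance restraints) is the
reported fingerprint of helical vs β-sheet content.

Superposition is the Kabsch algorithm: SVD of the covariance of centered
coordinate pairs, with the determinant sign correction guaranteeing a
proper rotation (det = +1). It requires at least three non-collinear atom
pairs. The test suite checks it against an independent quaternion
eigen-method oracle. Pairwise ensemble RMSD superposes every unordered
model pair on the selection and reports mean ± SD over all
$\binom{n}{2}$ pairs — the "pairwise RMSD" convention of NMR structure
statistics tables, not RMSD to a mean structure. Atom classes:
`backbone` = N, Cα, C (carbonyl O excluded — the most common
validation-suite convention, chosen because published tables rarely state
theirs; the class is configurable), `heavy` = all non-hydrogen atoms,
plus `calpha` and `all`. The ordered-residue preset `7wcg_ordered`
(residues 3–97 and 104–113) reflects the converged core of the deposited
high-temperature ensemble.

Residue numbering is taken verbatim from coordinate files; no renumbering
or alignment-based mapping is attempted across entries, and cross-entry
comparisons fail loudly when atoms cannot be paired by `(residue, atom
name)`. Probe-atom displacement (e.g. a loop Cα between apo and bound
structures) depends on the chosen superposition frame, which published
numbers usually leave unstated — treat such comparisons as qualitative
unless the frame is known.

## Thermodynamic fits

**DSC.** The two-state scaled excess heat capacity is
$$C_p(T) = b(T) + A\,\frac{\Delta H^2}{R T^2}\,\frac{K(T)}{(1+K(T))^2},
\qquad K(T) = \exp\!\left[-\frac{\Delta H}{R}\Bigl(\frac 1T -
\frac 1{T_m}\Bigr)\right],$$
with $R = 1.98720425\times10^{-3}$ kcal mol⁻¹ K⁻¹ (fixed across all
thermodynamic models in the package). $\Delta H$ is the van 't Hoff
enthalpy; the scale factor $A$ absorbs the calorimetric/van 't Hoff
discrepancy, in the style of instrument-vendor "scaled" two-state fits.
The polynomial baseline $b(T)$ (default degree 2 — vendors say only
"polynomial baseline correction", and degree 2 handles the usual gentle
curvature without eating the peak) is evaluated on centered temperature
for conditioning. Initialisation: baseline from the outer 15% of the
grid, $T_m$ at the detrended maximum, $\Delta H$ from the peak height via
$h = \Delta H^2/(4RT_m^2)$. A thermogram whose detrended maximum is at
the grid edge or within 5× the flank residual scale is rejected as
peakless rather than fit. Temperatures are Kelvin internally, Celsius at
every I/O boundary. Useful identities for checking: the excess term at
$T_m$ equals $A\Delta H^2/(4RT_m^2)$, and its integral over the full
transition equals $A\,\Delta H$.

**ITC.** The independent-site (Wiseman) model. After cumulative injected
volume $\Delta V$ the exponential-dilution convention gives cell
concentrations $M = M_0 e^{-\Delta V/V_0}$ and
$X = X_{syr}(1 - e^{-\Delta V/V_0})$; the complex concentration is the
smaller root of the binding quadratic
$[PL] = \tfrac12[(nM + X + K_d) - \sqrt{(nM + X + K_d)^2 - 4nMX}]$, and
the measured heat of injection $k$ is
$q_k = Q_k - Q_{k-1} + \frac{v_k}{V_0}\frac{Q_k + Q_{k-1}}{2} +
\text{offset}$ with $Q_k = \Delta H\,V_0\,[PL]_k$. The fit runs in
$(\log K_d, n, \Delta H, \text{offset})$ — the log keeps $K_d$ positive
and the optimizer well-scaled. The dilution heat is a constant
per-injection offset fitted jointly, since a blank titration is rarely
available. First-injection discard is off by default (24 reported
injections with no discard statement in the motivating experiment) but
available as a flag. Exothermic heats are negative. The default cell
volume (1.0 mL) is the nominal standard-volume cell of the instrument
class used; it is metadata on the isotherm, not a fit parameter.

**CD.** Molar ellipticity $[\theta] = \theta_{obs}/(10\,c\,l)$ (mdeg, M,
cm → deg cm² dmol⁻¹), reported *per protein molecule*, not per residue —
published ellipticity changes do not always say which, and the reports
carry the convention label. Melt analysis reports the trace at one
wavelength, the endpoint-to-endpoint change, a van 't Hoff sigmoid fit
for the midpoint, and — when a cooling ramp exists — reversibility
$= 1 - |[\theta]_{final,cooled} - [\theta]_{initial}|/|\Delta\theta_{total}|$,
which is 1 for full recovery and 0 when the signal stays at the hot
endpoint.

## The synthetic-data generator

Every generator draws from a `ground_truth()` object and a `sim_config()`
(seed, noise level, size): identical configurations produce byte-identical
files, noise level 0 reduces every generator to an exact evaluation of its
forward model, and the truth is serialized as JSON next to the data so
recovery tests read it only from disk. Noise is additive Gaussian with SD
expressed as a fraction of the generator's reference amplitude (peak
$I_0$, DSC peak height, largest injection heat, total melt amplitude) —
one knob, matching how spectral noise is usually quoted. Shift-table
noise defaults to 0.002 ppm (¹H) and 0.01 ppm (¹⁵N), typical
assignment-grade precision; spectral noise levels are conventions chosen
here, not published values.

Ground-truth defaults are the study conditions: per-residue relaxation
rates scattered about the measured ensemble averages (25 °C: R₁ 1.078 Hz,
R₂ 17.66 Hz, hetNOE 0.780; 50 °C: R₁ 1.928 Hz, R₂ 6.862 Hz, hetNOE 0.766)
with the measured SDs, and a planted flexible set (residues 32, 34–36,
97–99, 110 — the L₁₂ loop, the β5–H3 loop, the C-terminus) at depressed
rates and hetNOE in 0.25–0.45; a 12-site ssDNA-binding surface (including
a Trp side-chain site) with saturating CSP amplitudes of 0.20–0.45 ppm
against a zero-CSP background; DSC truths of 84.16 °C (full length,
ΔH = 100 kcal/mol) and 53.12 °C (N-terminal deletion, ΔH = 80 kcal/mol);
ITC truth K_d = 1.75 μM, n = 1.009, ΔH = −10 kcal/mol with 24 × 10 μL
injections of 500 μM titrant into 50 μM protein; a two-state CD melt with
midpoint 66 °C and a 452,000 deg cm² dmol⁻¹ folded-to-unfolded span at
228 nm; and a 1.0 Å ensemble dispersion target. Titration tables use the
one-site quadratic for fractional saturation at the stated K_d and
protein concentration (fast exchange — peaks move, they do not split).

Ensemble simulation perturbs a reference model with i.i.d. per-atom
Gaussian displacements of per-coordinate SD $\sigma = d/\sqrt 6$, so that
the expected pairwise RMSD between two models is the dispersion target
$d$ (the difference of two independent $N(0,\sigma^2)$ draws has variance
$2\sigma^2$ per coordinate). Rigid-transformed copies (random proper
rotations + translations) are generated separately as the canonical
superposition fixture. The default reference model is an idealized
synthetic backbone curve, clearly labeled as such — not a real fold.

What the generator deliberately does **not** emulate: raw FIDs, spectra,
peak picking or assignment; slow/intermediate-exchange lineshapes;
correlated (anisotropic) coordinate dispersion or actual protein
stereochemistry; instrument drift or non-Gaussian noise. Passing recovery
tests therefore demonstrate the correctness of the fitting and
classification machinery under the stated noise model, not robustness to
every artifact of real spectrometer data.

## Test and verification scale

The suite verifies each fitted quantity against the generator's ground
truth and each numerical engine against an independent oracle: a
10⁴-point grid search for exponential rates, Horn's quaternion method for
superposition (1000 random instances at 10⁻⁶ tolerance), trapezoid
integration of the excess heat capacity against ΔH (0.1%), and a
mass-action root-finder for the ITC equilibrium (10⁻¹⁰ M). Recovery runs
use profiles of 114 residues, 20-model ensembles of 25–60 residues, and
50–200 noise seeds for the Monte-Carlo calibrations — sizes chosen to
make sampling error a small fraction of each test's tolerance while the
whole suite stays interactive (tens of seconds).

## Known limitations

- No model-free (Lipari–Szabo) analysis, spectral-density mapping,
  exchange (CPMG) analysis, or anisotropic diffusion tensors: the
  pipeline stops at R₁/R₂/hetNOE/τ_c, as the motivating study did.
- No K_d estimation from CSP titrations (affinity comes from ITC), and
  no exchange-regime analysis of shift trajectories.
- Single-class ITC model only; no sequential or cooperative schemes, and
  no multi-state DSC deconvolution.
- PDB only (no mmCIF); restraint parsing covers the XPLOR `assign`
  dialect, not CYANA/AMBER formats.
- The τ_c formula assumes isotropic tumbling and breaks down
  (radicand ≤ 0) for very fast local motion; such residues are excluded
  with a reported count, not silently dropped.
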