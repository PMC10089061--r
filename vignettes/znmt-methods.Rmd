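---
title: "Methods: gas-phase species, CIU analysis and the coarse-grained unfolding engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gas-phase species, CIU analysis and the coarse-grained unfolding engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znmt)
```

This vignette documents the models behind `znmt`, their assumptions, the
tunable parameters, and the choices made where the design was genuinely
open. The package targets partially metalated zinc metallothionein-2
(Zn₄–₇MT2): a small, cysteine-rich, natively unstructured protein whose
two metal–thiolate clusters make it a demanding test case for native ion
mobility mass spectrometry (IM-MS), collision-induced unfolding (CIU) and
gas-phase simulation.

## The species mass model

An ion species is specified by the neutral reduced protein composition
plus five integers: bound Zn²⁺ (`n_zn`, 0–7), disulfides (`n_ss`), charge
(`z`), sodium charge carriers (`n_na`) and a proton-retention offset. The
hydrogen bookkeeping is

\[
\Delta H = -2\,n_{\mathrm{Zn}} - 2\,n_{\mathrm{SS}} - n_{\mathrm{Na}}
          + \mathrm{retention} + z .
\]

Each Zn²⁺ is taken to displace exactly two thiol protons in the fully
displaced reference state; partial retention of protons within the
clusters is modelled as a single integer offset for the whole ion because
per-site retention is not resolvable from a charge-state envelope.
Retention and disulfide count are exactly confounded modulo (1, −2) —
one extra disulfide cancels two retained protons — so `fit_species()`
reports the fewest-disulfide representative of each mass-equivalence
class (the member with retention 0 or 1). The class invariant
\(2 n_{\mathrm{SS}} - \mathrm{retention}\) is what the data determine.

Isotope patterns are computed by per-element convolution of the IUPAC
natural-abundance tables (binary exponentiation over atom counts), with
peaks merged below `merge_tol` (default 10⁻³ Da, far below any envelope
width used here) and isotopologues pruned below an absolute probability
`threshold` (default 10⁻⁶). On compositions of ≤ 10 atoms the pattern
agrees with brute-force enumeration of all isotopologues to 10⁻⁹ relative
abundance — that enumeration is kept in the test suite as the oracle.
Envelopes are rendered as Gaussians of FWHM = (m/z)/R; Lorentzian and
pseudo-Voigt shapes are out of scope. Electron mass is neglected in m/z
(0.5 mDa at z = 5, three orders below the instrument precision modelled).
Both average-mass and monoisotopic pathways are exposed; nominal
instrument m/z values (e.g. the 1298 m/z of reduced Zn₇MT2⁵⁺) are
average-mass quantities.

The residual metric of `fit_species()` is the sum of squared intensity
differences on the observed grid after optimal linear scaling of each
candidate envelope — the natural choice when the only statement available
is that spectra were fitted to simulated isotopic distributions, with no
published metric.

## Cluster maps

The Zn₄→Zn₇ ladder fills the two domains in the experimentally
established order: Zn₄ holds Zn₂Cys₆ in each domain, the fifth and sixth
Zn²⁺ extend the α-domain (Zn₃Cys₉, then Zn₄Cys₁₁), the seventh completes
the β-domain Zn₃Cys₉. The β pool is the nine N-terminal cysteines and the
α pool the eleven C-terminal ones, as in the known metallothionein fold.
Which cysteines bridge within a cluster is not established experimentally;
the packaged maps use a fixed, documented assignment that satisfies the
degree arithmetic (every metal tetrathiolate; 8 edges on 6 thiolates force
2 bridging, 12 on 9 force 3, 16 on 11 force 5). The maps are data — they
can be replaced by any JSON file with the same schema.

## Ion-mobility analysis

**Calibration.** Travelling-wave CCS calibration follows the standard
power-law protocol: drift times corrected for the mass-dependent transfer
delay (EDC coefficient, default 1.41), reference CCS reduced by
\(\sqrt{\mu}/z\) with μ the ion–gas reduced mass (N₂ by default, He
selectable — the instrument gas is configurable because published figures
rarely state it), and a log–log least-squares fit of CCS′ = A·t′^B.
Calibrations below R² = 0.98 are flagged as not accepted. The ATD→CCS
transform applies the calibration pointwise with the exact Jacobian, so
densities keep unit area.

**CIU50.** The fingerprint's intensity-weighted centroid per energy
column is fitted with a sum of logistic steps between plateau CCS levels
(the convention of the CIU analysis tools in this field; no functional
form is standard in the literature). Midpoints initialise at the
steepest-gradient energies, plateaus at the first/last column centroids,
and all parameters are bounded by the energy span and CCS range.
Under the generator's sequential hand-off model the two-state centroid
curve is exactly logistic, so noiseless recovery is exact; at 2% intensity
noise the fitted midpoint is unbiased with an SD below 3 eV on the default
50–150 eV grid of 2.5 eV steps (property-tested over 200 seeds).

**Conformers.** CCS distributions are smoothed (Gaussian kernel, default
1.5 grid steps), peaks picked by topographic prominence (default 5% of the
maximum — low enough to keep a 5% minor extended conformer), then refined
as a Gaussian mixture by bounded nonlinear least squares; components stay
tied to their picked peaks so refinement sharpens rather than reassigns.
Labels α, β, γ, … ascend in CCS. KDE bandwidth defaults to Silverman's
rule and is recorded in the output.

**Gating.** `gate_select()` zeroes intensity outside a CCS (or drift-time)
window and renormalises — an emulation of the selection outcomes of
multistage cyclic-mobility workflows, not of the multipass path-length
physics.

## Projection-approximation CCS

The CCS read-out is the orientation-averaged shadow area of the union of
spheres (atom/bead radius + probe radius), estimated by Monte Carlo:
uniformly random rotations from unit quaternions, `n_mc` points per
orientation over the projected bounding box, SE over orientations. The
projection approximation ignores gas scattering and long-range
interactions, so absolute values underestimate experimental TWIMS CCS of
rough surfaces; a documented global scale factor (default 1.0) permits
empirical correction. Relative trends — the only quantities the
coarse-grained engine is asked to reproduce — are insensitive to that
scale. Defaults: probe 1.0 Å (He-like; 1.82 Å N₂ preset), residue beads
3.8 Å, Zn 1.4 Å, all in an editable table. The implementation is verified
against the analytic sphere and a 0.05 Å rasterised projection oracle on
identical orientations.

## The coarse-grained engine

The gas-phase engine is a desk-scale *emulator*, not a replacement for
atomistic force fields: one bead per residue (plus one per metal),
harmonic bonds and angles at native geometry, 12–10 Gō contacts between
residues ≥ 3 apart within 8 Å of the native structure (partitioned into
intra-α, intra-β and inter-domain sets), WCA excluded volume, in-vacuo
Coulomb between unit charges, and harmonic Zn–S links (k = 50 kcal mol⁻¹
Å⁻², r₀ = 2.3 Å) mirroring the cluster map. Its acceptance surface is
deliberately qualitative orderings plus its own analytic oracles.

Defaults (all in `cg_params()` / `md_schedule()`): timestep 10 fs,
friction 1 ps⁻¹, bond k = 100 kcal mol⁻¹ Å⁻², angle k = 5 kcal mol⁻¹
rad⁻², contact ε = 1 kcal mol⁻¹, dielectric 1 (vacuum). Integration is
BAOAB-discretised Langevin dynamics in Rcpp; kinetic energy satisfies
equipartition at 300 K within 5% over 10⁵ steps, and with the thermostat
off the integrator conserves energy to better than 0.1% over 10⁴ steps at
a 1 fs step. Overlapping beads produce large finite energies (distances
floored at 0.1 Å), never NaN; protocols pre-relax start structures by
damped descent.

**Charges.** The z unit charges go on the z most peripheral basic
residues (Lys/Arg by distance from the centre of mass) — a documented
heuristic standing in for gas-phase charge partitioning; uniform smearing
is selectable. MT2's many lysines make the heuristic well-posed.

**Collective variables.** R_g is mass-weighted over protein beads only
(metals excluded — conformation metrics describe the protein), and
end-to-end is the first-to-last backbone bead distance.

**Steered pulls** use a moving harmonic restraint with force constants
quoted in kcal mol⁻¹ nm⁻² (presets 10/25/50) and report |−k(s − s₀(t))|
in pN, per-replicate peak forces and trapezoidal work integrals, with 25
replicates by default. The published pulling speeds and durations for
this system are not stated anywhere; the default schedule (30 000 steps
to 1.8–2× the initial R_g) was chosen so apo MT2 completes its extension
while Zn-loaded species visibly strain their Zn–S network — pulls that
cannot reach the target are flagged truncated rather than forced, since
harmonic links do not rupture (bond breaking is out of scope; the strain
is recorded as Zn–S energy).

**Well-tempered metadynamics** deposits Gaussian hills at a fixed stride
with height h₀·exp(−V_b/((γ−1)k_BT)) on a tabulated CV grid (O(1) bias
lookup; hills are skipped while the CV is off-grid, which would otherwise
pile spurious weight onto the boundary bins). The free energy estimate is
−γ/(γ−1)·V_b, shifted to minimum zero; convergence is diagnosed by
hill-height decay (late/early ratio < 0.5). Hill defaults (height 0.5
kcal/mol, σ 0.5 Å, stride 500, γ = 10) are documented choices — none are
published for this system. On a two-bead analytic double-well the
recovered barrier matches the closed form within 10%; note the closed
form on a distance CV includes the radial-measure entropy −2k_BT ln s.

**Thermal unfolding** runs a stepwise 300/500/800 K ramp with per-frame
projection CCS and per-temperature KDE slices. ΔCCS (the spread of
sampled CCS) is the heterogeneity read-out: apo MT2 unfolds broadly while
Zn-loaded species are pinned by their harmonic Zn–S network — the same
ordering seen experimentally, and the reason thermal ramps alone cannot
reach the extended conformations that collisional activation produces.

## The synthetic-data generator

The generator supplies every input with controlled ground truth:
the canonical human MT2 sequence (UniProt P02795, initiator Met retained,
no acetylation — the isoform-level choice is documented so any FASTA can
be substituted), cluster maps per the ladder above, dumbbell bead
structures (self-avoiding chain grown in two compact spherical domains,
β N-terminal, joined by a linker; 22 Å centre separation chosen so the
compact R_g falls in 10–13 Å; Zn beads relaxed onto their thiolates at
2.3 Å), spectra with seeded additive Gaussian intensity noise truncated
at zero (the simplest model adequate for recovery testing), and CIU
fingerprints built by sequential logistic hand-off between Gaussian CCS
states with column-max normalisation. Fixed seeds give byte-identical
outputs; a clashed chain growth perturbs the seed and reports it.

What the generator does *not* emulate: real CIU data have
energy-dependent peak widths, drifting baselines, charge stripping and
overlapping proteoforms; real spectra have correlated (not i.i.d.) noise
and detector saturation. Passing the recovery tests therefore shows the
estimators are correct and well-conditioned under the stated noise model,
not that they are robust to every instrumental artefact.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale sizes chosen
as the package's own defaults: 50 seeded fingerprints per CIU50 recovery,
200 seeds for the bias/SD property, 10⁵-step equipartition runs, 2×10⁶
steps for the metadynamics oracle (about two seconds on one core), and
three-temperature thermal ramps of 1.2–2×10⁴ steps per slice for the
qualitative orderings. Tie-breaks: equal-residual species fits resolve
toward fewer disulfides; conformer labels resolve by ascending CCS.
Degenerate inputs (flat spectra, zero-variance samples, empty gates,
non-increasing ramps) raise typed errors or warnings rather than
returning silently wrong numbers.

## Known limitations

- The cluster-map bridging assignments are plausible placeholders.
- The proton-retention/disulfide confound is intrinsic to mass-only data;
  only the equivalence class is identified.
- PA-CCS absolute values carry the projection-approximation bias.
- The coarse-grained engine makes no claim to atomistic accuracy: no
  water, no mobile protons, no Na⁺ ejection, no covalent rupture. Its
  role is to reproduce orderings (ΔCCS by metalation, irreversibility,
  R_g–CCS correlation) and to pass its own physics oracles.
- The cyclic-mobility emulation reproduces selection outcomes, not
  multipass scheduling physics.
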