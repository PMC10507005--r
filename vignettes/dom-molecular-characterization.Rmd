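---
title: "Molecular characterization of DOM and its bioactivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular characterization of DOM and its bioactivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`domchar` implements the computational chain used to characterize dissolved
organic matter (DOM) at the molecular-formula level from ultrahigh-resolution
negative-mode mass spectra, and to relate that composition to bioassay
activity. The chain has five stages, each exposed as ordinary functions and
orchestrated by `run_pipeline()`:

1. **simulate** (`generate_formula_library()`, `render_peak_lists()`,
   `generate_bioassay_plate()`) — synthetic ground-truth data;
2. **assign** (`assign_formulas()`) — peak lists to a consensus
   formula-by-sample relative-intensity table;
3. **compose** (`summarize_table()`) — per-sample descriptors, compound
   categories, heteroatom groups, exclusivity;
4. **ordinate** (`pcoa()`, `envfit_pcoa()`) — Bray–Curtis principal
   coordinates with permutation-tested descriptor fits;
5. **bioactivity** (`ic50()`, `teac()`, `regress_bioactivity()`) — dose–
   response quantification and descriptor–activity regressions.

The numbered scripts under `analysis/` run these stages as a narrative
workflow on a simulated two-source study and write all tables under
`results/`.

## Formula arithmetic and classification

A molecular formula is an integer composition over C, H, N, O, S, P. Neutral
monoisotopic masses come from a fixed isotope-mass table; observed m/z of
singly deprotonated ions maps to the neutral scale by adding a proton mass
(1.00727645 Da — the H atom minus an electron). Electrospray of DOM in
negative mode produces essentially only such `[M−H]⁻` ions, so no other ion
types are modeled.

Two derived indices drive the classification:

* **DBE** `= 1 + C − H/2 + (N + P)/2`, rings plus double bonds with N and P
  treated as trivalent;
* **AImod** `= (1 + C − 0.5·O − S − 0.5·(N + P + H)) / (C − 0.5·O − N − S −
  P)`, the aromaticity index under the assumption that half the oxygen is
  carbonyl-like. A non-positive denominator or a negative ratio yields 0.

Compound categories use the standard threshold table: aromatic
(AImod ≥ 0.5), highly unsaturated (AImod < 0.5, H/C < 1.5), unsaturated
(1.5 ≤ H/C ≤ 2, reported separately when the formula carries nitrogen), and
saturated (DBE = 0), each non-nitrogen class split at O/C > 0.5 into O-rich
vs O-poor. The raw thresholds overlap for heteroatom-rich formulas, so a
fixed precedence resolves them: saturated first, then aromatic, then
unsaturated-with-N, then unsaturated, then highly unsaturated. Formulas with
H/C > 2 but DBE > 0 (possible with N or P) fit no window and are routed to
the saturated split; this is logged behavior, not silent.

For pure CHO formulas DBE = 0 forces H = 2C + 2 and hence H/C > 2, so the
saturated and unsaturated CHO classes are provably disjoint; the test suite
verifies this by exhaustive sweep.

## Formula assignment

`assign_formulas()` reproduces the standard attribution chain:

* **Noise filtering.** The method-detection-limit (MDL) threshold is
  `median(band) + level × madsd(band)` with `level = 4` by default, where
  `band` is the lowest-intensity quantile band of the replicate's peaks and
  `madsd` the MAD-based robust SD. The band must undershoot the spectrum's
  true noise proportion: if it reaches into the faint analyte signal, the
  robust SD inflates and the threshold lands inside the signal distribution.
  The default band is therefore the lowest 5% of peaks, a deliberately
  conservative choice appropriate for spectra in which at least ~5% of peaks
  are instrumental noise; it is configurable (`noise_band`) and should be
  raised for noisier spectra. The filter presumes a noise population exists:
  when modeling noiseless spectra, pass `mdl_level = NULL` to skip it.
* **Recalibration.** Optional: the median ppm offset of reference formulas
  matched within 2 ppm (at least 5 matches) is divided out of all m/z.
* **Alignment.** Single-linkage grouping of the pooled sorted masses at
  0.5 ppm: consecutive masses within tolerance join one group; each group
  keeps at most one peak per replicate (nearest to the group's
  intensity-weighted mean; the rest split into singleton groups).
* **Enumeration.** For each group's neutral mass, all N, S, P, O, C
  combinations within bounds (defaults C 1–100, H 0–200, N 0–4, O 0–80,
  S 0–2, P 0–1) are scanned in compiled code with H solved from the mass
  remainder. Candidates must fall within the ppm tolerance and pass the
  validity screens 0.3 ≤ H/C ≤ 2.5, O/C ≤ 1.2 and nonnegative integer DBE —
  which, for these elements, is algebraically the nitrogen rule. All screens
  are configurable.
* **Heteroatom plausibility.** Candidates exceeding N ≤ 4, S ≤ 2, P ≤ 1, or
  combining two or more heteroatom species with N+S+P > 5, are removed
  unless verified by a ¹³C isotope satellite (a peak at +1.0033548 Da whose
  intensity is within 0.5–2× of `0.0107 × C × parent`).
* **Series resolution.** Each candidate's support is the number of other
  aligned groups holding a candidate reachable by 1–10 units of the CH₂,
  CO₂, H₂, H₂O or O homologous series. The winner per group maximizes
  support, with ties broken by smallest |ppm error|, then fewest
  heteroatoms, then lexicographic formula. Support is initialized against
  each group's ppm-best candidate and then iterated against the current
  winners to a fixed point (bounded at 8 passes; non-convergence keeps the
  last pass with a warning). The ppm-best initialization matters: whole
  ladders of near-degenerate substitution "shadows" (a few tenths of a mDa
  off) otherwise support one another exactly as strongly as the true series.
* **Consensus and normalization.** A formula counts for a sample only when
  every replicate of that sample contributes a peak to it; retained
  intensities are averaged over replicates and normalized per sample to
  sum 1.

## The synthetic-data generator

Because the study's raw spectra are not public, every stage is validated by
parameter recovery on simulated data whose defaults define the study
conditions:

* **Sources.** Two groups with contrasting category weights: a terrestrial,
  aromatic-rich pool (40% aromatic, 45% highly unsaturated) and a marine
  pool dominated by highly unsaturated O-poor formulas (80% highly
  unsaturated, 3% aromatic).
* **Library structure.** Formulas are generated per category as
  CH₂-homologous ladders (geometric lengths, mean ≈ 3, capped at 8) rooted
  at rejection-sampled seeds, drawn from a group-level pool from which each
  sample takes 70% of its formulas (`shared_fraction`), generating the rest
  privately. Both choices mimic real DOM data — spectra dense in homologous
  series (the very structure the resolution step exploits) and heavy
  between-sample overlap, which keeps exclusivity percentages at the few-
  percent level seen in real multi-sample datasets. Category target counts
  follow the group weights by largest-remainder apportionment, so empirical
  composition matches the weights to within 1/n. The generator stays inside
  the assignment validity screens so that every true formula is recoverable
  in principle.
* **Intensities.** True relative intensities are lognormal (sdlog 1) —
  FT-ICR intensity distributions are heavy-tailed — with multiplicative
  lognormal replicate noise (sdlog 0.1).
* **Mass error.** Gaussian, 0.1 ppm SD per peak, matching sub-0.1-ppm
  calibrated spectra.
* **Noise peaks.** 10% of each rendered peak list, uniform in m/z, with
  intensities on a tight lognormal floor at 20% of the 10th percentile of
  that replicate's signal (sdlog 0.15) — just beneath the faintest analyte
  peaks, so MDL filtering is meaningful but not trivial.
* **Bioassay.** Per sample, a 2-fold dilution series from 200 µg/mL with
  duplicate wells; percent inhibition follows a four-parameter logistic
  (floor 0, ceiling 100, Hill slope 1) around the sample's true IC50 with
  3% Gaussian well noise, plus negative-control wells. True IC50 obeys
  `log10(IC50) = log10(150) − 4 × aromatic_fraction`, spanning roughly
  4–115 µg/mL across the two sources — the order of magnitude reported for
  active DOM extracts — and making −log10(IC50) linear in the aromatic
  fraction by construction.

What the simulation does **not** model: isotopologue fine structure beyond
the single ¹³C satellite, adducts and multiple charging, space-charge or
transient effects, correlated (structured) mass error, intensity-dependent
mass error, or chemically meaningful isomer structure. Passing recovery
tests therefore demonstrates the correctness of the computational chain
under idealized instrument behavior, not performance on any particular real
instrument.

## Ordination and permutation inference

`bray_curtis()` implements `Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)` directly; `pcoa()` is the
classical Gower construction (double-centering of −d²/2, symmetric
eigendecomposition, scores scaled by √λ for positive eigenvalues). Negative
eigenvalues are reported but not corrected (no Lingoes/Cailliez adjustment),
matching common ordination practice; explained proportions are taken over
the positive part of the spectrum. Axis signs are fixed by making each
axis's largest-magnitude score positive, so results are deterministic.

`envfit_pcoa()` regresses a per-sample descriptor on the first two axes
(configurable) and tests r² by permuting the descriptor across samples with
`p = (1 + #{r²_perm ≥ r²}) / (1 + n_perm)`, 10,000 permutations and α = 0.1
by default. The +1 smoothing makes the test valid at any permutation count.
A constant descriptor has no direction and returns a flagged null row. Two
axes are fitted because the ordination is interpreted as a 2-D plot; the
`axes` argument generalizes this.

## Bioactivity quantification

Percent inhibition is `100 × (1 − signal/control)`. IC50 defaults to
log-linear interpolation between the two points bracketing 50% — the
natural estimator for screening dilution series — with a 4-parameter
logistic fit (`minpack.lm`) as the alternative; on noise-free Hill-slope-1
curves the two agree within 10%. Series never reaching 50% are censored at
the top tested concentration and reported as `">Cmax"`; replicate curves
are fitted independently and reported as mean ± SD, and censored samples
are excluded (and counted) in regressions. TEAC conversion fits the Trolox
calibration line (≥ 3 points) and normalizes by extract dry weight.
Descriptor–activity regressions are ordinary least squares with the
two-sided slope test, starred `**`/`*` at p < 0.01/0.05.

## Numerical choices and degenerate inputs

* Isotope masses are fixed CODATA/AME values; canonical formula strings use
  element order C, H, N, O, S, P with zero counts omitted.
* Weighted sample descriptors renormalize internally, so they are invariant
  to intensity rescaling; MW_w uses neutral (not ion) mass.
* Category percentages are computed on formula **counts** while heteroatom
  group abundances weight by **intensity** — deliberately different bases,
  matching how such tables and figures are conventionally reported.
* Exclusivity percentages are relative to the number of distinct formulas
  in the whole dataset, not the sample.
* Empty samples, all-zero intensity vector pairs, constant descriptors,
  sub-2-point dose series and degenerate calibrations all raise explicit
  errors rather than returning silently wrong numbers.

## Validation strategy and problem sizes

The test suite validates each operation against an independent oracle:
enumeration against a naive full-grid brute force, classification against a
straight-line threshold re-implementation, OLS against the normal
equations, PCoA against metric recovery and `stats::cmdscale`, Bray–Curtis
and descriptor fits against `vegan`, the permutation test against its
nominal type-I rate (1,000 null repeats at 10,000 permutations), and the
full assignment chain by recall/precision against simulated ground truth
(4 samples × 2,000 formulas with noise; exact recovery required in the
noiseless CHO-only case). These sizes keep the default validation run at a
few minutes on one core while leaving the stochastic checks comfortable
margins; all seeds are fixed in the tests and settable everywhere in the
API.

## Known limitations

* The MDL interpretation (robust threshold over a low-intensity band) is
  one reasonable reading of "detection-limit filtering at level 4"; vendor
  implementations differ, and the band fraction must be chosen with the
  expected noise load in mind.
* Contaminant removal is supported only as a user-supplied exclusion mass
  list; no contaminant database ships with the package.
* Series-support resolution is a heuristic: it provably helps when true
  spectra are series-dense, and the iteration is bounded rather than
  guaranteed to converge (ties can oscillate; the last pass is kept).
* Negative-eigenvalue magnitudes are reported but the user must judge
  whether a correction is warranted.
* The polyphenol-like sub-classification sometimes reported alongside these
  categories has no generally agreed formula-level definition and is not
  computed.
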