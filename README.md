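# domchar

Molecular-level characterization of dissolved organic matter (DOM) and its
relation to bioactivity.

DOM is one of the most complex mixtures on Earth: a single ultrahigh-
resolution FT-ICR mass spectrum of a water extract resolves thousands of
exact masses, each attributable to an elemental composition over C, H, N, O,
S, P. `domchar` implements, as a tested R package plus a numbered analysis
workflow, the full computational chain from raw per-replicate peak lists to
compositional and bioactivity statistics. It is aimed at aquatic
geochemists and natural-product researchers who have negative-mode peak
lists and plate-reader dose–response data and want a reproducible,
inspectable alternative to opaque vendor pipelines.

## What it computes

**Formula attribution** (`assign_formulas()`): detection-limit noise
filtering, optional recalibration, 0.5 ppm cross-replicate mass alignment,
exhaustive CHNOSP enumeration (compiled core) under validity screens
(0.3 ≤ H/C ≤ 2.5, O/C ≤ 1.2, integer DBE ≥ 0 / nitrogen rule), heteroatom
caps with ¹³C-satellite escape, homologous-series resolution
(CH₂/CO₂/H₂/H₂O/O, support-maximizing with ppm tie-breaks), duplicate
consensus and per-sample normalization.

**Composition** (`summarize_table()`): per-formula descriptors

    DBE   = 1 + C − H/2 + (N+P)/2
    AImod = (1 + C − 0.5·O − S − 0.5·(N+P+H)) / (C − 0.5·O − N − S − P)

with the van Krevelen style categories — aromatic (AImod ≥ 0.5), highly
unsaturated (AImod < 0.5, H/C < 1.5), unsaturated (1.5 ≤ H/C ≤ 2, "with N"
separately), saturated (DBE = 0), each split O-rich/O-poor at O/C > 0.5 —
plus intensity-weighted MW, DBE, AImod, heteroatom-group abundances
(CHO/CHON/CHOS/CHOP/others) and exclusivity statistics.

**Ordination** (`pcoa()`, `envfit_pcoa()`): principal coordinate analysis of
Bray–Curtis dissimilarities `Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ)`, with molecular descriptors
fitted post hoc to the first two axes and tested by descriptor permutation
(default 10,000 permutations, significance at p < 0.1).

**Bioactivity** (`ic50()`, `teac()`, `regress_bioactivity()`): percent
inhibition against a negative control, IC50 by log-linear interpolation of
the dilution series (censored as `">200"` when inhibition never reaches
50%) or by 4-parameter logistic fit, Trolox-equivalent antioxidant capacity
per gram dry weight, and OLS regressions of bioactivity on molecular
descriptors.

**Synthetic data** (`synth_config()`, `generate_formula_library()`, ...): a
first-class generator of ground-truth libraries with source-dependent
category composition, CH₂-ladder structure, lognormal intensities, Gaussian
ppm error, noise peaks, duplicate measurements and bioassay plates whose
IC50 is log-linearly linked to the aromatic formula fraction — so every
stage is validated by parameter recovery. See the methods vignette
(`vignettes/dom-molecular-characterization.Rmd`) for all modeling choices.

## Worked example

```r
library(domchar)

cfg   <- synth_config(n_samples = 8, n_formulas_per_sample = 400, seed = 42)
truth <- generate_formula_library(cfg)       # ground-truth library
tab   <- assign_formulas(render_peak_lists(truth))
evaluate_assignment(tab, truth)[c("recall", "precision")]
#> recall 0.983, precision 0.988

st <- summarize_table(tab)
st[, c("sample_id", "n_formulas", "pct_exclusive", "dbe_w", "aimod_w", "A_Op")]
#>   sample_id n_formulas pct_exclusive dbe_w aimod_w  A_Op
#> 1       S01        397          7.15  15.6   0.378 29.47
#> 2       S02        400          7.49  16.3   0.397 29.00
#> ...
#> 8       S08        397          6.97  12.0   0.225  2.77
```

Samples S01–S04 simulate a terrestrial, aromatic-rich source (≈29% aromatic
O-poor formulas, weighted AImod ≈ 0.38); S05–S08 a marine source dominated
by highly unsaturated formulas (≈3% aromatics). Ordination separates the
two sources and the weighted aromaticity index fits the plot significantly:

```r
ord <- pcoa(bray_curtis_matrix(tab))
100 * sum(ord$explained[1:2])                # 49.6% on the first two axes
envfit_pcoa(ord, st$aimod_w, n_perm = 10000, seed = 1)
#>     d1      d2    r2      p significant
#>  0.999 -0.0547 0.944 0.0233        TRUE
```

The simulated bioassay links IC50 to aromaticity; the regression of
−log10(IC50) on the aromatic percentage recovers it:

```r
ic <- ic50_table(generate_bioassay_plate(truth))
ic$label
#> "3.8 (± 0.3)" "3.5 (± 0.5)" ... "124.5 (± 0.9)" "113.8 (± 7.2)"
regress_bioactivity(st$A_Or + st$A_Op,
                    -log10(ic$ic50_mean))
#>   slope intercept    r2        p stars n
#>  0.0414     -2.22 0.997 6.91e-09    ** 8
```

Aromatic-rich terrestrial samples are roughly 30× more potent (IC50
≈ 4 µg/mL vs ≈ 115 µg/mL), exactly the configured link
(`log10(IC50) = log10(150) − 4 × aromatic_fraction`).

The same flow, at study scale and stage by stage, is in
`analysis/01_simulate.R` … `analysis/05_bioactivity.R`, each writing its
tables under `results/`.

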