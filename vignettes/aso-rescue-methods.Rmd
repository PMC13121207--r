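---
title: "Models and methods behind asorescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind asorescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asorescue)
```

# The experimental design

The package targets a complementation design used to study recessive
splicing disorders: amniocytes (or other patient-derived cells) from a
proband carrying a splice-disrupting variant and from a healthy control are
each treated with a targeting antisense oligonucleotide (ASO-T) that blocks
the aberrant splice site, or with a scrambled control oligo (ASO-S). The
four arms — proband/control × ASO-S/ASO-T, typically four replicates each —
are profiled by quantitative (phospho)proteomics on the log2 scale.
Features whose disease-state alteration is reverted by ASO-T, without
being perturbed by ASO-T in control cells, constitute the *rescue set*:
the proteins and phosphosites causally downstream of the restored gene
product.

# Differential statistics

All abundance matrices are log2-scale; a fold-change is a difference of arm
means, `log2FC = mean(test) − mean(ref)`. The test statistic is a Welch
two-sample t (pooled variance available via `method = "pooled"`); we use
Welch as the default because arm variances in small-replicate designs are
not exchangeable and Welch is conservative under heteroscedasticity.
Moderated (empirical-Bayes) variance shrinkage is deliberately out of
scope: with the package's four-replicate defaults it would change power
substantially, and we prefer the classical test whose behaviour under the
null is exactly known. Multiple testing is controlled by Benjamini–Hochberg
across all features *within one contrast and one dataset* (proteome and
phosphoproteome adjusted separately); q-values are never pooled across
contrasts.

Missing values are handled complete-case per feature and contrast: a
feature needs two observations per arm for a statistic, is reported with
`NA` statistics otherwise, and `NA` p-values are excluded from the BH
denominator. No imputation is performed — imputed values fabricate
precision exactly where the data are weakest. Degenerate inputs are
resolved explicitly: zero variance in both arms gives `t = 0, p = 1` when
means agree and the smallest representable positive p (flagged) when they
differ; constant features standardise to all-zero z-scores with a flag.

The significance rule is `|log2FC| ≥ lfc_min` and `q ≤ q_max`, defaults
0.2 and 0.05. A second knob `lfc_min_primary` exists because set-level
filtering (0.2, permissive by design, to keep partially restored features)
and single-protein claims (often held to 0.5) legitimately use different
fold-change bars; both default to 0.2.

# The rescue classifier

`classify_rescue()` runs four contrasts — C_S vs P_S, C_T vs P_S (the two
disease comparisons), P_T vs P_S (treatment response) and C_T vs C_S
(off-target screen) — where P/C is proband/control and S/T the oligo. The
criteria combine as

> in rescue set ⇔ disease-altered ∧ treatment-responsive ∧
> shifted-toward-control ∧ ¬off-target.

*Disease-altered* is a disjunction over the two disease comparisons: a
feature suppressed in the proband qualifies whether the control reference
was ASO-S- or ASO-T-treated. *Shifted toward control* is quantified on the
z-score scale. With per-arm means `z̄_PS, z̄_PT, z̄_CS, z̄_CT`, the
restoration fraction toward control arm c is

$$ r_c = \frac{\bar z_{PT} - \bar z_{PS}}{\bar z_c - \bar z_{PS}}, $$

defined when the denominator exceeds 1e-9 in magnitude. Any positive
`r_c`, toward either control arm, sets the shift flag — a disjunction, and
the flag is not magnitude-thresholded, because partial restoration is
precisely what the permissive design wants to keep. The reported `r` comes
from the control arm with the larger baseline separation `|z̄_c − z̄_PS|`,
which is the better-conditioned denominator. The `full`/`partial`/
`overshoot` labels (cutoffs 0.8 and 1.2 on `r`) are a reporting convention
of this package, not a published definition; the cutoffs are configurable
in `rescue_config()`. Off-target thresholds default to the rescue
thresholds since nothing argues for asymmetry.

Statistical power deserves an honest note. With four replicates, noise
sd 0.25 and a 1-log2-unit effect, a single Welch test at p ≤ 0.05 detects
the effect essentially always; but BH across 2000 mostly-null features
drives the effective per-test threshold to ~1e-3, where the same test has
well under half power, and 0.5-unit partial effects are rarely recovered.
The rescue set that survives all four criteria is therefore
high-confidence but far from exhaustive at these problem sizes — the
classifier trades recall for a controlled false-discovery rate, and the
acceptance script measures the realised recall rather than assuming it.

# Enrichment and kinase inference

`ora()` is a plain one-sided hypergeometric over-representation test on
user-supplied GMT collections: no database retrieval, no redundancy
collapsing into "summary terms". Terms are intersected with the universe
before sizes are computed, only terms overlapping the selection are
reported, and BH runs across the reported terms. `RichFactor = k/K` and
`InTerm = k` mirror the dot-plot conventions of enrichment figures.

`kinase_activity()` infers kinase activity from substrate phosphosite
fold-changes with the KSEA z-statistic
`z = (mean_S − mean_all)·√m / sd_all`, requiring `m ≥ 3` mapped substrate
sites, and calibrates it by drawing `n_perm = 10^4` random size-m site
sets (two-sided, add-one-corrected `p = (b+1)/(n_perm+1)`). This is an
approximation chosen for transparency — it assumes substrate sites are
exchangeable under the null and ignores site–site correlation within a
protein.

# Genetics

Coordinates are 1-based inclusive everywhere (VCF convention); a position
is within `w` bp of an interval `[a, b]` iff `max(a − p, p − b, 0) ≤ w`.
Boundary conventions are deliberate and asymmetric because each mirrors
the wording of the corresponding filter: MAF strictly `< 0.01`, SpliceAI
delta inclusive `≥ 0.10`, genotype quality strictly `> 35`, outlier
proximity inclusive `≤ 250`.

**ROH.** There is no single canonical ROH definition at exome marker
density, so the package uses the simplest auditable one: the maximal run
of consecutive homozygous calls containing the focal variant, extending
greedily in both directions and consuming at most `max_het` heterozygous
calls (default 0). Boundaries always sit on homozygous markers — a
trailing heterozygote is never absorbed. Missing calls and calls failing
an optional GQ floor are transparent: skipped without being consumed and
without terminating the run, since a no-call carries no evidence either
way. The minimal shared region across individuals is the intersection of
their ROH, i.e. the span of the smallest.

**Relatedness.** The score
`(N_both-het − 2·N_opposite-hom)/min(N_het)` has expectation ~0 for
unrelated pairs under Hardy–Weinberg (both-het probability `4p²q²` exactly
balances twice the opposite-homozygote probability `2p²q²`) and 1 for
identical genotypes; pairs below 0.05 are called unrelated. One caveat the
simulation makes visible: individuals who share an IBD haplotype over a
fraction f of the marker panel score ≈ f/2, because the shared segment
contributes excess both-het sites and forbids opposite homozygotes. On a
genome-wide panel a single founder segment is negligible; on the package's
compact simulated panels (where the planted segment spans ~20% of
markers) founder carriers are measurably related — which is the true state
of those simulated genomes, not an artefact of the statistic.

**Segregation.** `recessive_hom` requires affected individuals homozygous
alternate, parents of affected individuals heterozygous, and unaffected
siblings carrying at most one allele; `comp_het` requires at least two
retained heterozygous variants per gene with at least one inherited from
each parent; `de_novo` requires absence from unaffected members. A missing
genotype degrades the call to `"unknown"` and keeps the variant flagged —
a discovery pipeline must not drop candidates silently for lack of data.

# qPCR

Technical replicates are averaged on the Ct scale (the scale on which
noise is approximately additive), with a warning when replicates spread
more than 0.5 cycles. The normalised quantity is
`NQ = E^(−Ct_target) / geomean(E^(−Ct_ref))` with amplification efficiency
fixed at `E = 2` (configurable but validated `> 1`), so a per-sample
pipetting offset cancels. Percent-of-control rescales NQ so the control
group mean is exactly 100; biological replicates are normalised per sample
first and summarised per group afterwards.

# The synthetic-data generators

`simulate_omics()` emulates the four-arm design: per-feature baselines
~N(20, 2), Gaussian replicate noise (sd 0.25) on the log2 scale — chosen
as the simplest model consistent with thresholding on log2FC — and planted
categories: 1780 null, 100 fully rescued (disease shift ±1 log2 unit under
ASO-S, none under ASO-T), 50 partially rescued (half the shift remains),
50 disease-altered-not-rescued, and 20 off-target features. Off-target
effects are applied to *both* ASO-T arms so that the off-target exclusion
criterion, not the genotype contrast, is what must remove them. The
generator does not emulate TMT missingness patterns, batch structure or
heavy-tailed noise, so green tests certify the logic of the pipeline, not
its behaviour on messy real matrices.

`simulate_pedigrees()` builds two trios whose founders each carry one copy
of a shared ancestral haplotype spanning a planted segment (default
markers 200–400 of 1000); both probands inherit it biparentally, making
them homozygous across the segment with the focal variant hom-alt (parents
het, background MAF 0). The two markers flanking the segment are forced
heterozygous in the probands, so the planted span is identifiable exactly
at marker resolution; without such obligate boundaries, chance flanking
homozygosity would extend each ROH by a geometric-tailed flank and exact
recovery would be seed luck rather than a property. Genotype qualities are
N(60, 10) with a 10% low-GQ fraction uniform on 10–35, exercising the
strict `> 35` filter.

`simulate_ct()` plants true expressed fractions (e.g. 0.044 for a severe
hypomorph) as extra target cycles; `simulate_variant_table()` plants one
causal variant among decoys that each violate exactly one prioritisation
filter, so a correct filter chain keeps exactly the causal row.

# Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale: 2000-feature
matrices with 16 samples, 20-seed null batteries, 1000-marker pedigree
panels, exhaustive hypergeometric enumeration to N = 12, and 10^3–10^4
permutations — sizes chosen so the full suite completes in well under a
minute per module while keeping Monte-Carlo error small relative to the
tolerances tested. Every stochastic routine takes an explicit seed, scopes
it locally, and restores the caller's RNG state, so identical
configurations give byte-identical outputs.

# Known limitations

- No moderated variance estimation or batch correction; matrices are
  assumed normalised upstream.
- The kinase permutation null ignores within-protein site correlation.
- ROH detection is genotype-run based; no LD, genetic-map or
  IBD-probability modelling.
- The relatedness screen is a single concordance statistic, not a full
  kinship estimator; it inherits the IBD-fraction caveat above.
- qPCR efficiency is assumed constant per assay; no standard-curve
  calibration or melt-curve QC.
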