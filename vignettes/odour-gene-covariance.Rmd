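---
title: "Odour-gene covariance: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Odour-gene covariance: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scentmhc)
```

`scentmhc` tests whether the volatile chemicals a bird carries on its
feathers encode information about its major histocompatibility complex
(MHC) genotype — the odour–gene covariance hypothesis that underlies
olfactory MHC-based mate choice. The package implements the full chain of
analyses for a two-locus MHC class IIB study design (loci called DAB1 and
DAB2 throughout, after the storm-petrel loci that motivated the design):
GC–MS peak-table processing, functional genotype distances, individual-level
interaction models, dyadic permutation tests, and BIO-ENV compound-subset
selection, together with a synthetic cohort generator used to validate the
statistical machinery.

This vignette documents the models, the tunable parameters, the numerical
conventions, and the places where the design was genuinely open and a
choice had to be made.

## Chemical pipeline

A replicate-level peak table holds, for each bird × replicate, the sample
mass (g), the internal-standard peak area, and one peak area per compound.
The processing order is fixed:

1. **standardize** each replicate: area / (internal-standard area × mass),
   removing instrument drift and sample-size differences (units g⁻¹);
2. **average** the replicate vectors within each bird;
3. **log(x + 1)** transform, so a few highly abundant compounds do not
   dominate.

Standardization must precede averaging because the internal standard is a
property of the replicate run, not of the bird; the log comes last so the
average is taken on the measurement scale. `aggregate_profiles()` enforces
this order.

PCA (`chem_pca()`) is centred and, by default, unit-variance scaled
(a correlation PCA, matching the default of the implementation this class
of studies typically cites). Whether the original analyses scaled is
ambiguous — transformed peak areas are "on similar scales" — so a
covariance PCA is available via `scale = FALSE`. Zero-variance compounds
are dropped with a warning when scaling. Component signs are made
reproducible by flipping each component so its largest-magnitude loading
is positive.

How many components to keep (`retain_components()`) is decided by the
median of three standard rules — Kaiser–Guttman, the broken-stick model,
and Horn's parallel analysis (199 simulated datasets, 95th percentile,
seeded) — unless the analyst fixes the count a priori with `override`
(the pipeline default is `override = 2`, reproducing the common
two-component reporting layout). The three rules often disagree by one;
the median is a conservative compromise that never follows a single
outlier rule.

## Functional MHC distances

Amino acids are embedded in the five-dimensional z-descriptor space of
Sandberg et al. (1998): hydrophobicity (z1), steric bulk (z2), polarity
(z3) and two electronic-effect scores (z4, z5). Distances are Euclidean in
that space (`aa_distance()`); the distance between two aligned alleles is
the mean per-position residue distance (`allele_distance()`), optionally
restricted to a position mask (e.g. peptide-binding-region codons).
The embedded table is exported (`z_descriptors()`) and any user table with
the same shape is accepted, so alternative descriptor sets can be swapped
in. The residue distance is a true metric; the test suite verifies the
triangle inequality over all 8000 residue triples.

Individual **diversity** (`genotype_diversity()`) is the functional
distance between the two allele copies at one locus (0 for homozygotes).
Across both loci the four copies are reduced over all six unordered copy
pairs, by mean (default) or max; how four alleles reduce to one number is
not fixed by the literature, so the rule is explicit in the results. Note
that the six pairs include cross-locus pairs: both-loci diversity measures
the functional breadth of the whole class IIB repertoire an individual
carries, and a bird homozygous at both loci still has nonzero both-loci
diversity when its two loci differ.

Dyadic **genotype distance** (`dyad_mhc_distance()`) compares allele
copies *within* locus only — DAB1 against DAB1, DAB2 against DAB2 — since
the two loci are different genes and a cross-gene residue comparison does
not measure genotype similarity; in practice a cross-locus maximum is a
near-constant that erases all dyadic information. The default rule is the
maximum over the (4 or 8) within-locus cross pairs, so 0 means no copy
comparison can tell the two birds apart. The mean rule is provided as a
sensitivity option and is worth running alongside: under additive allele
effects on chemistry (the generator's model, and arguably the most
plausible biology), the mean is the matched statistic and has visibly
higher power than the max, which only responds to the most divergent copy
pair.

## Individual-level models

`fit_interaction_model()` fits, for one chemical response (a PC score),

    response ~ diversity + sex + breeding_status
             + diversity:sex + diversity:breeding_status

by OLS. Breeding status is days from sampling to hatch (sample date minus
hatch date: negative during incubation, larger = later), entered as a
continuous covariate; the early/mid/late split seen in figures is
presentation only and is implemented as prediction slices at the mean and
mean ± 1 s.d., not as a categorical refit. Term p-values use a Type III
ANOVA with sum-to-zero contrasts on sex (the orthodox coding for Type
III); because published tables rarely state their factor coding, `tidy()`
reports the treatment coding too. Per-sex simple slopes come from the
model's gradient at the mean breeding status, and are algebraically
identical to the coefficient combinations (the tests assert equality, not
approximation). A perfect, zero-residual fit has no error stratum; the
coefficients are still reported, with undefined (NA) Type III p-values.

## Dyadic permutation tests

Within-sex dyads form square symmetric matrices (n(n−1)/2 dyads; 435 for
40 birds of one sex), mixed-sex dyads a rectangular males × females matrix
(900 for 40 + 40). `partial_mantel()` correlates unfolded lower triangles,
controlling covariate matrices (the other chemical component and the
breeding-status difference, in the standard layout); significance comes
from relabelling individuals — simultaneous row-and-column permutation —
with the add-one p-value estimator, so p is never 0 and its floor is
1/(n_perm + 1). The default is 10 000 permutations, two-sided.

One deliberate departure from the convention of several distance-matrix
packages: with covariates, what is permuted by default is the
covariate-*residualized* chemical matrix, re-residualized at each draw
(the Freedman–Lane scheme), not the raw matrix. Permuting the raw matrix
is anticonservative exactly when the chemical matrix is strongly
correlated with a covariate — which is the usual situation here, since
the leading chemical axis tracks breeding stage. In calibration runs on
500 null cohorts the raw scheme rejected at 0.09; the residual scheme at
0.04–0.06. `permute = "raw"` remains available for comparison with
raw-permutation implementations.

Rectangular matrices get a partial Spearman test
(`partial_spearman_rect()`): all matrices are unfolded and average-ranked,
the statistic is the partial Pearson correlation of ranks, and the default
null permutes the entries of the (residualized) chemical dyad vector,
mirroring the permutation scheme of standard partial rank-correlation
tests. Entry permutation ignores the dyadic non-independence of the
design, so a restricted mode that permutes row labels (`null = "rows"`)
is provided; when the two disagree qualitatively, both should be reported.

Bonferroni corrections are plain α/m (`bonferroni_alpha()`): the standard
families are 6 linear models and 9 dyadic tests (3 dyad groups × 3 locus
modes), giving 0.05/6 ≈ 0.008 and 0.05/9 ≈ 0.0056.

## BIO-ENV subset selection

`bioenv_search()` enumerates every compound subset of size ≤ k_max,
computes the Euclidean between-individual distance on the subset, and
returns the subset maximizing the Mantel correlation with a target genetic
distance matrix. Defaults: plain Pearson Mantel r (a rank-based variant is
available), no re-standardization of the already log-scaled profiles
(`scale = TRUE` restores the classic procedure's normalization), ties
broken to the smallest, lexicographically first subset. A partial variant
controls a covariate matrix and flags itself in the output. The winning
correlation is a maximum over many subsets and is selection-biased: it
carries no significance value, and none is reported. Exhaustive search
over 80 compounds at k ≤ 6 is ~3 × 10⁸ subsets and is not desk-scale;
the pipeline therefore pre-filters to the compounds most correlated with
the component under test (reported as `prefiltered`), and a greedy
forward-selection fallback exists but labels itself non-exhaustive.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions the analysis assumes:
80 incubating adults (40 per sex), 80 compounds measured in triplicate
against a naphthalene-d8-style internal standard, two loci with two allele
copies each from per-locus pools, and breeding status uniform over a
45-day incubation window. Defaults the data do not pin down were chosen
once: pools of 6 alleles per locus (giving 2–4 distinct alleles per bird,
matching the reported repertoire sizes), replicate noise 0.3 log-units,
individual-identity variance 0.3 log-units, sex effect 0.5, breeding
trend 0.02 per day. Effect sizes for the MHC signal are not estimable
from published summaries, so the generator's `effect_size` is calibrated
for validation power rather than field realism.

Two structural choices matter and deserve their rationale:

* **Allele pools are divergence ladders** (`generate_related_pool()`):
  each locus has a founder sequence and a shared substitution path over a
  hypervariable fraction of positions; allele k carries the first m_k
  substitutions. Substitution sets are nested, so within-pool functional
  distance equals the difference in founder divergence — the pool's
  functional geometry is one-dimensional and pairwise distances are
  strongly graded. Independent uniform-random sequences (available as
  `generate_allele_pool()`) are nearly equidistant from one another in
  z-space, which makes every dyadic genotype distance almost constant and
  leaves nothing for a dyadic test to detect. Real MHC allele pools lie
  between these extremes; the ladder is the structure that lets a scalar
  latent odour axis reflect genotype, and that limitation should be kept
  in mind when generalizing simulation results to field data.

* **Signal compounds form one MHC-driven block.** Each allele shifts a
  latent odour axis in proportion to its (centred) functional divergence
  from the locus founder; an individual's axis value is the mean over its
  four copies; each signal compound loads on the axis with a loading of
  magnitude 0.75–1.25 and random sign, scaled by `effect_size`, on top of
  a diversity term shared by all signal compounds. This mirrors the
  empirical observation that MHC-associated compounds cluster on a single
  principal component, and it is what makes subset-selection recovery
  possible: an earlier design with independent random contribution
  vectors per compound made each compound an independent 1-D projection
  of a high-dimensional genotype difference — individually almost
  uninformative (dyadic r ≈ 0.1) and collectively redundant, so neither
  power nor BIO-ENV recovery targets could be met at any plausible effect
  size.

Log standardized abundance per compound is baseline + sex + breeding +
individual effect (+ MHC terms for signal compounds) + replicate noise;
peak areas are reconstructed by multiplying by each replicate's log-normal
internal-standard area and mass, so all areas are strictly positive and
standardization inverts exactly. Identical configs give bit-identical
cohorts.

What the generator does **not** emulate: retention-time structure,
censoring/detection limits, compound co-elution, diet or microbiome
effects, population allele-frequency skew (uniform by default, a
frequency vector is accepted), and any relatedness structure among
individuals. Passing the validation suite therefore shows the statistics
behave correctly under the assumed data-generating model, not that field
data meet those assumptions.

## Validation at the study conditions

The acceptance suite (also re-runnable via `scripts/acceptance.R`) checks,
at fixed problem sizes chosen to keep a full run in minutes:

* type-I error of the F–F partial Mantel test on 500 null cohorts
  (20 per sex, 199 permutations) within [0.03, 0.07];
* power ≥ 90% on 100 cohorts with a strong planted effect
  (`effect_size = 2`, chemical distance over the planted compounds,
  mean-rule both-loci genetic distance);
* BIO-ENV best subsets containing ≥ 2 of 3 planted compounds in ≥ 80% of
  100 cohorts at the full study size (40 per sex, 20 compounds, k ≤ 6);
* exact agreement of the Bonferroni thresholds and dyad counts;
* agreement of sampled permutation p-values with exhaustive oracles at
  tiny sizes, and of the BIO-ENV search with brute-force enumeration;
* byte-identical pipeline reruns under a fixed config.

## Numerical conventions and degenerate inputs

* Permutation p-values use the add-one estimator; minimum attainable p is
  1/(n_perm + 1).
* Partial correlations are computed by QR residualization; a covariate
  that explains either variable exactly yields NA with a warning rather
  than a spurious value.
* Constant distance matrices, zero pooled variances, and zero-variance
  heterozygosity vectors are reported as undefined (error or NA with
  warning), never silently imputed.
* Eigenvalue ties and component sign ambiguity are resolved by the
  positive-largest-loading convention.
* All randomness is seed-controlled per call; results record their seed.

## Known limitations

* The max-rule dyadic distance is insensitive by construction; its low
  power under additive allele effects is a property of the statistic, not
  a bug, and the mean rule should accompany it in any real analysis.
* The rectangular entry-permutation null treats dyads as exchangeable
  units; the row-permutation alternative is stricter but has lower
  resolution for small male counts.
* BIO-ENV results are selection-biased and exploratory by nature.
* The generator's one-dimensional allele geometry is a deliberate
  simplification (see above).
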