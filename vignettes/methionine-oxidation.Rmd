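---
title: "Sequence and structure determinants of methionine oxidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence and structure determinants of methionine oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metox)
```

## The scientific problem

Methionine sulphur oxidises to methionine sulfoxide (MetO) under oxidative
stress, but individual methionines differ enormously in susceptibility, and
solvent accessibility alone does not explain the differences. `metox`
implements a chain of analyses that dissect the determinants of this
susceptibility in human proteins: composition-level enrichment, local
sequence environment, sequence-based machine-learning prediction, and --
the central result -- the protective role of the *S-aromatic motif*, a
methionine whose SD sulphur lies within 7 Å of the geometric centre
of an aromatic ring (Phe, Tyr, or either ring of Trp).

## Methionine content and its bootstrap null

`met_content()` is the fraction of residues that are methionine, computed
after dropping the N-terminal initiator (position 1), which reflects
translation initiation rather than composition; `X` residues are excluded
from the denominator. `bootstrap_content_null()` draws repeated samples of
proteins (uniformly, without replacement within a sample) from a background
proteome and records per-sample mean contents; the study-scale design is
10^4 samples of 1646 proteins. `empirical_pvalue()` uses the add-one
estimator `(1 + #{means >= observed})/(1 + n)`, which can never return 0;
when no bootstrap mean reaches the observation the result is flagged as
below the resolution of the null (`< 1/n`).

## The sequence-environment z-score

For each amino acid *i* and offset *j* in −10..−1, +1..+10 around a
methionine, `env_frequencies()` tabulates the relative frequency of *i* at
*j* over a set of sites. Sites with fewer than ten neighbours on either
side are excluded entirely -- windows are never padded -- so every
retained site contributes a residue at every offset. Oxidation-prone sites
are compared against oxidation-resistant methionines *from the same
proteins*, which controls for the general sequence preferences of
methionine itself: `pair_resistant_sites()` picks, for each oxidized site,
one eligible non-oxidized methionine of the same protein.

The comparison statistic is the standardized difference of the two
relative frequencies,

$$z_{ij} = \frac{f^{ox}_{ij} - f^{res}_{ij}}
  {\sqrt{\left(f^{ox}_{ij}(1-f^{ox}_{ij}) +
   f^{res}_{ij}(1-f^{res}_{ij})\right)/n}},$$

where *n* is the number of paired sites. Under the null of identical
environments each z is approximately standard normal; positive values mean
residue *i* is more frequent near oxidation-prone methionines. A 0/0 cell
(residue absent from both environments) is defined as 0. Of the 400 cells,
about `400·2·(1−Φ(b))` are expected outside `[-b, b]` by chance
(≈ 18 for b = 2, ≈ 1 for b = 3); `interval_counts()` reports the observed
exceedances and `aa_aggregate_scores()` the per-residue sums of |z|.

Two design choices deserve emphasis:

* **Pairing is without replacement within a protein.** The z statistic's
  variance normalisation assumes *n* distinct observations on each side.
  If the same resistant methionine may back several oxidized sites, its
  duplicated window inflates the empirical variance of the 400 z values
  well above 1 (we measured ≈ 1.6 on null simulations); drawing distinct
  partners restores calibration (variance ≈ 0.96 pooled over 20 null
  simulations of ≥ 500 pairs each). Oxidized sites left without an
  eligible partner are dropped and counted.
* **Frequency denominators count sites with a canonical residue at the
  offset.** `X` is excluded from numerator and denominator, so columns
  still sum to 1 whenever every site is informative at that offset.

## Sequence-distance features and the random forest

`distance_features()` encodes a methionine's context as 40 integers: for
each amino acid X, the distance in residues to the nearest X towards the
N-terminus (`NT_X`) and towards the C-terminus (`CT_X`), with the protein
length as the default when X is absent in a direction. `train_rf()`
follows the classical protocol: stratified 75/25 train/test split, a
1000-tree random forest with 6 candidate predictors per split (the
truncated square root of 40), repeated 10-fold × 5 cross-validation on the
training part (50 resamplings) scored by AUC with *oxidized* as the
positive class, and a final refit evaluated on the untouched test part.
Out-of-bag error is exposed as a secondary diagnostic. `rfe_select()`
performs backward recursive feature elimination scored by CV AUC and
returns the AUC-versus-size curve; ties in the best size break towards
fewer features.

## S-aromatic motif geometry

`ring_centroids()` computes unweighted centroids of the aromatic ring
atoms: one six-membered ring for Phe/Tyr and, for Trp, both the pyrrole
and the benzene ring. Treating Trp as two rings (with the minimum distance
governing the call) is a conservative superset of either single-ring
convention. `s_aromatic_calls()` measures the Euclidean distance from
every resolved MET SD atom to every centroid, across chains -- inter-chain
contacts are biologically real in oligomers and count for motif status,
but are excluded from `linear_separations()`, where no within-chain
sequence distance exists. The motif call uses the canonical 7 Å
cutoff, the first minimum of the bimodal sulphur-aromatic distance
distribution that `distance_histogram()` exhibits. Methionines whose SD is
not resolved are skipped with a warning rather than silently classified,
and `dedup_chains()` removes sequence-identical chains (homo-oligomer
copies) before any counting.

Author residue numbering in deposited structures rarely equals UniProt
sequence numbering, so benchmark positions must pass through
`map_sequence_to_structure()`, a global alignment (match +1, mismatch −1,
linear gap penalty 2) whose aligned-identical columns define the residue
map; an identity below 0.9 is treated as a wrong chain/protein pairing and
raises an error instead of producing a silently shifted map.

## Solvent accessibility

`shrake_rupley_sasa()` implements the Shrake–Rupley point-sampling method
directly: each heavy atom is covered with a deterministic Fibonacci-spiral
grid (default 960 points) at radius `r + 1.4` Å (water probe), and a
point is accessible when it lies strictly outside every neighbour's
inflated sphere. The strict-inside convention means exactly coincident
spheres do not occlude each other; a 10⁻⁹ relative slack keeps
exact-boundary points accessible despite floating-point rounding. Van der
Waals radii are C 1.70, N 1.55, O 1.52, S 1.80 Å (1.80 for anything
else); hydrogens are excluded. Relative accessibility divides residue SASA
by theoretical Gly-X-Gly maxima (224.0 Å² for methionine); values
slightly above 1 occur for highly exposed conformations. "Exposed" means
relative accessibility *strictly above* the threshold, evaluated at both
5% and 20% so that conclusions can be checked for robustness;
`stratify_by_exposure()` rebuilds the oxidation-by-motif table within the
exposed stratum, the analysis that shows the motif effect is not an
artefact of burial.

At 960 points, per-residue SASA is rigid-transform invariant to better
than 1% and changes by less than 2% relative to a 240-point grid on toy
structures.

## Exact inference

`fisher_exact()` computes the conditional hypergeometric distribution of
the top-left cell from log binomial coefficients. Both sidedness
conventions are always reported, because published p-values rarely state
one: the one-sided tail in the observed direction, and the two-sided
minimum-likelihood sum of all tables no more probable than the observed
one. For small tables the tail is also returned as an exact integer ratio.
On the therapeutic benchmark margins (17, 3 / 2, 13) both conventions give
3 × 10⁻⁵; on the structural proteome counts (39, 97 / 561, 421) the
two-sided value is 4.1 × 10⁻¹⁰ and the one-sided depletion tail
3.0 × 10⁻¹⁰. Note that the minimum-likelihood two-sided p can exceed twice
the one-sided p by a small discreteness slack when p is near 0.5; this is
a property of the convention, not a defect. `binomial_tail()` is the
exact upper-tail binomial sum; on the glutamine-synthetase check
(13 of 15 correct, p = 0.5) it gives 121/32768 ≈ 0.0037.

## The reactivity rule

`predict_reactivity()` is deliberately minimal: motif ⇒ low reactivity,
no motif ⇒ high. Empirical reactivities from kinetics studies are
dichotomised per protein by `median_split_labels()`: values below the
median are low, above are high, and values equal to the median join the
group whose closest assigned member is nearest in value -- if one side of
the median is empty the tied values go there (keeping both groups
populated), and an exact tie goes low. `benchmark_confusion()` scores the
rule with *low reactivity* as the positive class, the convention under
which the packaged 35-methionine therapeutic benchmark yields sensitivity
17/20 and specificity 13/15.

## The synthetic generator

Because the underlying proteomics dataset cannot be redistributed, every
pipeline stage is validated on synthetic data with known ground truth.
`synthetic_config()` defaults encode the study conditions: 1646 proteins,
human-like background frequencies with methionine usage 0.023, mean
protein length 460 (Poisson, floor 25, initiator M forced), a motif
fraction of 0.54 (≈ 600 of 1118 methionines), a baseline oxidation rate of
0.18 for motif-free methionines, and a motif odds ratio of 0.3 -- the
combination reproduces the observed marginal oxidation rate of ≈ 0.12 and
the observed odds ratio ≈ 0.30. The accessibility coefficient defaults to
0 so motif effects can be studied unconfounded; setting `beta_acc > 0`
plants the burial confounder deliberately, which is how the stratified
analysis is shown to de-confound.

`plant_env_bias()` labels a random half of eligible methionines oxidized
and resamples configured flanking offsets with a frequency boost Δ for a
chosen residue (renormalising the rest, never overwriting labelled
methionine positions). `gen_toy_structure()` places Met/Phe scaffolds on a
widely spaced grid with ring centroids at 4.5–6.5 Å (motif) or
8.5–11.5 Å (non-motif) from the SD sulphur, so the 7 Å call
has a guaranteed margin and recovered motif fractions are exact. The toy
structures are geometrically idealised, not physically folded: passing
tests demonstrate the correctness of the measurement machinery, not that
real proteins behave like the generator.

## Problem sizes and runtime choices in the test suite

The suite validates at reduced but statistically adequate scales: null
calibration and planted-signal power use 20 replicates of 200-protein
proteomes (≈ 600 pairs each, comfortably above the n ≥ 500 regime where
the normal approximation is trusted); odds-ratio recovery uses 200
simulations of 1118 methionines; the Fisher implementation is checked
against exhaustive enumeration on hundreds of random tables with totals
≤ 60; geometry is checked against a brute-force all-pairs oracle on 100
random structures and under random rigid transforms; distance features
are compared with a brute-force scan on 1000 random sequences. Forest
tests use smaller forests (100–200 trees) and fewer folds than the
analysis defaults -- the protocol, not the ensemble size, is what the
tests pin down.

## Known limitations

* The Shrake–Rupley implementation is a methodological replacement for
  the POPS program used in the original accessibility analysis; absolute
  SASA values differ from POPS's parameterisation, which is why
  conclusions are drawn from thresholded relative accessibility at two
  thresholds rather than raw areas.
* Sulphur position is taken from the SD atom; no hydrogen or lone-pair
  geometry is modelled, and no interaction energies are computed.
* Whether the original Trp convention used one ring, two rings or the
  9-atom centroid is not documented; the two-ring minimum used here is
  flagged for sensitivity analysis.
* The machine-learning benchmark numbers depend on the external
  proteomics dataset; on synthetic data the protocol is validated
  qualitatively (separable signals learned, no-signal AUC at chance,
  planted features recovered by RFE), not against published AUCs.
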