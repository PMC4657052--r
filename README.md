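# metox

Sequence and structure determinants of methionine oxidation.

Methionine residues oxidise to methionine sulfoxide (MetO) with very
different propensities, and solvent accessibility alone does not explain
which sulphurs are vulnerable. `metox` is an R package for researchers in
structural bioinformatics and protein chemistry (including formulation
scientists worrying about therapeutic-protein shelf life) that implements
the full analysis chain behind one structural answer: methionines whose
SD sulphur sits within 7 Å of an aromatic ring centroid — the
**S-aromatic motif** — are markedly less prone to oxidation.

The package provides:

* **Composition statistics** — methionine content with an initiator-drop
  convention and a bootstrap sampling null (`met_content`,
  `bootstrap_content_null`, `empirical_pvalue`).
* **Sequence-environment z-scores** — for residue *i* at offset *j* in
  ±10 around paired oxidation-prone / oxidation-resistant methionines,

  ```
  z_ij = (f_ij^ox − f_ij^res) / sqrt((f_ij^ox(1−f_ij^ox) + f_ij^res(1−f_ij^res)) / n)
  ```

  standard normal under the null of identical environments
  (`env_frequencies`, `pair_resistant_sites`, `zscore_matrix`,
  `interval_counts`, `aa_aggregate_scores`).
* **Sequence-distance features and random forests** — the 40 NT_X/CT_X
  nearest-residue distances, a 1000-tree forest with repeated
  cross-validation, and recursive feature elimination scored by CV AUC
  (`distance_features`, `assemble_benchmark`, `train_rf`, `rfe_select`).
* **Motif geometry** — aromatic ring centroids (two rings for Trp),
  sulphur-to-centroid distances, the 7 Å motif call, distance
  histograms, chain deduplication, sequence separations
  (`ring_centroids`, `s_aromatic_calls`, `distance_histogram`,
  `dedup_chains`, `linear_separations`).
* **Solvent accessibility** — an internal Shrake–Rupley implementation
  with Gly-X-Gly relative accessibility and exposed/buried stratification
  at 5% and 20% (`shrake_rupley_sasa`, `sasa_records`,
  `stratify_by_exposure`).
* **Exact inference from first principles** — hypergeometric Fisher test
  (both sidedness conventions, exact integer ratios for small tables) and
  exact binomial tails (`fisher_exact`, `binomial_tail`).
* **The reactivity rule classifier** — motif ⇒ low reactivity — with
  median-split labelling and confusion-matrix benchmarking against a
  packaged 35-methionine therapeutic-protein fixture
  (`predict_reactivity`, `median_split_labels`, `benchmark_confusion`,
  `table2_confusion`).
* **A synthetic-data generator** with planted, known effects (composition,
  flanking biases, motif fractions, a logistic oxidation model) so every
  stage is testable without downloads (`synthetic_config`,
  `gen_proteome`, `plant_env_bias`, `gen_toy_structure`,
  `gen_oxidation_labels`).

## Worked example

Score the packaged therapeutic-protein benchmark and classify methionines
in a synthetic structure with a known motif fraction:

```r
library(metox)

cm <- table2_confusion()          # pooled 2x2 of the S-aromatic rule
m  <- confusion_metrics(cm)
sprintf("accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%",
        100 * m$accuracy, 100 * m$sensitivity, 100 * m$specificity)
#> "accuracy 85.7%  sensitivity 85.0%  specificity 86.7%"

r <- fisher_exact(contingency_2x2(cm$tp, cm$fn, cm$fp, cm$tn))
sprintf("one-sided p = %.3g (%s)", r$p_one_sided, r$direction)
#> "one-sided p = 3.02e-05 (enrichment)"

ts    <- gen_toy_structure(synthetic_config(motif_fraction = 0.5),
                           seed = 1, n_met = 6)
calls <- s_aromatic_calls(ts$structure)
cbind(calls$calls[, c("chain", "resno", "nearest_dist", "forms_motif")],
      predicted = predict_reactivity(calls)$predicted)
#>   chain resno nearest_dist forms_motif predicted
#> 1     A     1         6.32        TRUE       low
#> 2     A     3         9.12       FALSE      high
#> 3     A     5         6.30        TRUE       low
#> 4     A     7         6.39        TRUE       low
#> 5     A     9         9.65       FALSE      high
#> 6     A    11        10.81       FALSE      high
```

Of the 35 benchmark methionines, 30 are correctly classified by the bare
geometric rule (accuracy 85.7%), and the enrichment of motifs in the
low-reactivity group has a Fisher exact p of 3 × 10⁻⁵ — the S-aromatic
motif alone is a reliable predictor of in-vitro reactivity. In the toy
structure, every methionine whose nearest ring centroid is within
7 Å is called a motif and predicted low-reactivity.

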