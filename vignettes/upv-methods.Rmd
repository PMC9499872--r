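---
title: "Discordance-based UPV typing: models, parameters and design choices"
author: "TwinUPV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discordance-based UPV typing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the places where the design was genuinely open and a decision had to
be made.

## The problem and the model

Monozygotic co-twins share their genome and, to a large extent, their
environment; the trait differences between them are "unexplained
phenotypic variation" (UPV). The package's working hypothesis is that UPV
is not pure noise but carries reproducible *patterns*: some pairs are
essentially concordant, some show a relative-adiposity pattern (fat mass
up, lean mass modestly down in the heavier co-twin; Type A), and some show
a coordinated overgrowth pattern (fat and lean mass up together; Type B)
that couples to insulin physiology and to an HDAC-responsive
transcriptional program, with reduced expression of the imprinted buffer
gene *NNAT*.

The analysis chain is:

1. **Orientation.** Within each pair the co-twin with the lower BMI is the
   light reference. This is a measurement convention, not a model claim;
   every downstream quantity is conditional on it. Ties are broken by the
   lexicographically smaller individual ID and flagged.
2. **Discordance indices.** `d_t = log x_t(heavy) − log x_t(light)` per
   trait. Log differences make the index scale-free (unit changes cancel
   exactly) and symmetric around zero. Natural log is used for raw traits
   and base 2 for expression, which arrives log2-normalized so its
   discordance is a plain difference; both bases are recorded in the
   output object.
3. **Pair clustering.** Pairs are clustered on the trait-standardized
   discordance matrix through a k-nearest-neighbor graph (Euclidean)
   converted to a shared-nearest-neighbor graph with Jaccard weights, and
   Louvain modularity optimization. The method assumes that UPV patterns
   manifest as local density structure in discordance space; it makes no
   assumption about cluster shape.
4. **Typing.** Types are assigned from cluster centroids only: the
   cluster with minimal mean |d| is Concordant; among the rest, positive
   fat centroid with lean centroid above a threshold `tau_lean` is
   Type B, positive fat with non-positive lean is Type A, in between is
   Intermediate.
5. **Signature.** Within each pair cluster, paired differences
   (heavy − light) per gene are tested with an empirical-Bayes moderated
   t; the Type-B signature is the set of genes significant in Type B and
   in no other cluster.
6. **Population stratification and scores.** Individuals (not pairs) are
   k-means clustered on z-scored signature-gene expression with the
   saturation rule for k; each individual gets a UPV-B median-rank score
   and an HDAC-signature score.
7. **Enrichment.** The heavy-vs-light moderated-t ranking feeds a
   preranked running-sum enrichment; leading-edge genes of significantly
   heavy-enriched HDAC sets define the HDAC signature.
8. **Morph classification.** Mouse body composition (fat, lean) is
   modeled as a Gaussian finite mixture with the wild-type group fit as a
   single fixed reference component; mutant animals are classified light
   / heavy / obese by posterior, and bimodality is judged by BIC against
   the fixed-reference single-component model.

## Tunable parameters

| parameter | default | units / scale | why |
|---|---|---|---|
| `k_neighbors` | 20 (capped at n/3) | pairs | standard SNN neighborhood; cap keeps small cohorts connected but not saturated |
| `resolution` | 0.8 | — | Louvain resolution; slightly below 1 to discourage shredding 40-pair groups |
| `n_null` | 49 | replicates | structure-test resolution 0.02–1; cheap at cohort scale |
| `tau_lean` | ½ · sd of lean discordances | log units | separates "coordinated lean gain" from noise on the cohort's own scale |
| `alpha` | 0.001 | p-value | the specificity filter cutoff used throughout |
| `gene_kmeans_k` | 2 | clusters | signature-vs-background profile split |
| `saturation_threshold` | 0.10 | relative WSS drop | the elbow ("saturation point") rule made explicit |
| `k_max` | 10 | clusters | dispersion curve range |
| `n_boot` | 100 | replicates | Jaccard stability resolution ~0.01 |
| `weight_exponent` | 1 | — | weighted running-sum statistic; 0 gives the classical KS form |
| `n_perm` | 2000 | permutations | permutation-p floor 1/(n+1) ≈ 5e-4, small enough to clear a 0.01 BH cutoff with ~20 sets |
| `padj_cutoff` | 0.01 | BH-adjusted p | enrichment significance for the leading-edge union |
| EM `tol`, `max_iter`, `n_restarts` | 1e-8, 500, 10 | — | relative log-likelihood convergence; restarts from kmeans++ draws |

## What the generator emulates — and what it does not

`simConfig()` defaults encode the package's reference study conditions:
160 MZ pairs (40 per planted pattern: concordant, Type A, Type B,
intermediate), 40 DZ pairs, a 35-trait panel (eight body regions with fat
and lean components, regional and derived totals, weight, height, BMI),
2000 genes with 60 signature genes (30% down-regulated in the heavy
co-twin, housing the NNAT-like gene) and 40 HDAC-responsive genes.

Light co-twin traits are log-normal with sex-specific locations and a
pair-level size factor; the heavy co-twin's primitive region components
are the light co-twin's times `exp(effect + noise)` with fat effect 0.35
and lean effect 0.10 on the log scale (Type A uses −0.10; intermediate is
half-scale; noise s.d. 0.06). The fat-dominant baseline composition
(~37% fat, ~59% lean) is deliberate: it keeps Type-A heavy co-twins
heavier *by BMI* despite their lean-mass reduction, so the orientation
convention and the planted pattern agree. DZ pairs are drawn from the
same generative mixture with effects and noise doubled (`dz_inflation`;
the MZ/DZ variance ratio is a free parameter of the generator, not an
estimate — no published value pins it down).

Expression: null genes are i.i.d. around gene-specific baselines
(log2 noise s.d. 0.3); signature genes shift by ±1.0 log2 units in heavy
Type-B co-twins only. Non-Type-B pairs additionally share a pair-level
background position (±0.5 × effect) along the signature axis, and HDAC
genes ride the same axis. This background is what gives the *population*
its four molecular strata (light-like, two middle states, heavy-like) so
that stratification has something to find; being pair-shared it cancels
exactly in paired differences, leaving within-cluster differential
expression and the specificity filter untouched. Insulin is generated as
`20 + 1.5·BMI + ε` with ε orthogonalized against BMI in-sample and scaled
so the realized within-group R² equals its target exactly (0.5 in Type B,
0.1 elsewhere — the asymmetry the cohort analysis reports).

The generator does **not** emulate: array batch structure or
normalization artifacts, DNA methylation, genotype data, longitudinal
growth, missing-data patterns of real phenotype panels, age/sex effects
on expression, or correlated gene–gene structure beyond the single
signature axis. Passing tests therefore demonstrate that the machinery
recovers planted structure of the assumed form at realistic effect sizes
and sample sizes — not that real cohorts contain such structure, nor that
the method is robust to the technical artifacts real arrays carry.

Problem sizes used by the test-suite and the acceptance script — the
full 160-pair / 2000-gene reference cohort for end-to-end recovery and
null-safety, 60-pair / 400-gene cohorts for per-module checks, 2000
replicates for type-I-error measurements, 20 seeds for mixture recovery —
were chosen as the smallest sizes at which the Monte-Carlo error of each
check is comfortably below its decision margin.

## Numerical choices

* **Moderated t.** Prior df and prior variance by moment matching of
  log-variances against the scaled-F model (digamma/trigamma moments;
  Newton inversion of trigamma). When the observed log-variance spread
  does not exceed chi-square sampling noise the prior df is infinite and
  the prior variance is the pooled (arithmetic-mean) variance. Total df
  is capped at the pooled residual df across genes. With `prior_df = 0`
  the statistic reduces exactly to the ordinary paired t (tested to
  1e-10).
* **Running-sum ES.** Increments `|stat|^w` normalized over set members,
  decrements `1/(N − n_set)`; the signed maximal deviation. An exact tie
  between the positive and negative extremum (generic at weight 0, where
  increments share a denominator) resolves by the sign of the summed
  running profile — the one tie rule that flips under ranking complement
  and so preserves `ES(−stats) = −ES(stats)` exactly. Ranking ties break
  by gene name, stably. When `C(N, n_set) ≤ 500` the null is enumerated
  exhaustively instead of sampled.
* **Cluster-structure null.** The observed Louvain modularity is compared
  with replicates drawn from a single multivariate normal with the
  observed mean and covariance (moment-matched parametric bootstrap).
  Two simpler nulls were rejected: degree-preserving edge rewiring
  ignores the geometric transitivity of kNN graphs (even i.i.d. points
  beat rewired nulls), and independent column permutation destroys the
  correlations that BMI orientation and derived (summed) traits induce in
  *any* cohort, structured or not. The Gaussian null preserves
  covariance while destroying multimodality, which is exactly the
  hypothesis being tested.
* **Saturation rule.** "Visualize the dispersion curve and pick the
  saturation point" is formalized as the smallest k whose relative WSS
  drop to k+1 falls below 10% (configurable).
* **Inflection point** of the sorted PC-association curve is the maximal
  discrete second difference (kneedle-style); numerically zero-variance
  PCs are excluded first, since null-space directions of collinear data
  otherwise dominate the association curve; a flat curve is reported as
  uninformative rather than selecting arbitrarily.
* **EM.** kmeans++ initial centers, log-sum-exp E-step, restart on
  component collapse (vanishing weight or variance), log-likelihood
  trace exposed and asserted non-decreasing. BIC is −2 logL + npar log n
  (smaller is better). Singular single-component covariances are ridged
  by 1e-6 of the trace and flagged.
* **Ties and degeneracies.** BMI ties → lexicographic light co-twin,
  flagged. Odd pair counts in the quantile split → median pair to the
  low half. Constant rows in the heat map → scaled to zeros with a
  warning. Nonpositive trait values → missing cells, with a 20%
  row-missingness drop threshold.

## Design decisions where the ground was open

* **Type assignment** is a formalization of what is otherwise done by
  inspecting a heat map. The rules depend on centroids only (re-labelling
  is idempotent and order-invariant). When two clusters pass the Type-B
  rule — which happens generically when an intermediate, half-scale
  pattern exists, because `tau_lean` scales with the pooled lean spread —
  Type B goes to the cluster with the larger lean centroid and the rest
  become Intermediate: the coordinated-overgrowth type designates a
  single cluster.
* **Signature gene k-means** runs on *absolute* effect profiles. On
  signed profiles the up- and down-regulated arms of a genuine signature
  land in different k-means clusters and a single-cluster selection would
  discard the down-regulated arm (including the NNAT-like gene).
  Clusters scoring within 50% of the best are kept, so a homogeneous
  candidate set is never halved by a forced split.
* **Down-regulated genes in the rank score** are reflected
  (`n + 1 − rank`) so that a high median rank always reads "heavy-like";
  a flag disables the reflection.
* **"Applying the same model" to mutant genotypes** is interpreted as
  holding the wild-type component's mean and covariance fixed and freeing
  only the mixing weights and the other components; a full refit is
  available behind a flag. Covariance classes are limited to
  equal-spherical and free.
* **Insulin adjusted on BMI** is implemented as OLS residuals
  (`adjustOn()`); per-cluster correlation maps report the mean p per gene
  (as stated for the cohort analysis) with the mean rho emitted
  alongside.
* **Expression discordance** uses the stored log2 intensities directly;
  whether to re-log is exposed through the trait-discordance path rather
  than guessed.
* **Age as a DE covariate** is accepted at pair level. MZ co-twins share
  age, so in the paired design it models effect heterogeneity across
  pair ages rather than a within-pair confounder; it matters only for
  user-supplied designs where pairs differ.

## Known limitations

* Type labels are centroid rules; clusters whose fat centroid is
  negative (other than the concordant one) are left Unassigned rather
  than interpreted.
* The embedding (UMAP) is for reporting only; no decision is read off
  it.
* The Gaussian structure null tests "one cluster vs more"; it does not
  calibrate the *number* of clusters.
* Permutation p-values are floored at 1/(n_perm + 1); no multi-level
  refinement for very small p.
* The mixture module covers 1-D and 2-D body-composition data with two
  covariance classes; it is not a general mixture toolbox.
* With restricted-access cohort data out of reach, all quantitative
  guarantees are statements about the generator's planted structure.
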