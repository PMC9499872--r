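# TwinUPV

Typing of unexplained phenotypic variation (UPV) from monozygotic (MZ)
twin cohorts, and the downstream transcriptomic machinery that goes with
it.

Genetically identical co-twins raised in matched environments still differ
substantially in complex traits. `TwinUPV` asks whether that variation is
structured: it quantifies co-twin discordance across a morphometric trait
panel, clusters pairs by their discordance *patterns*, and types the
clusters — a concordant core, a **Type-A** pattern (fat mass up, lean mass
modestly down in the heavier co-twin: relative adiposity) and a **Type-B**
pattern (coordinated fat *and* lean gain: relative overgrowth, the pattern
associated with reduced *NNAT* expression, HDAC-responsive gene programs
and tight insulin–BMI coupling). A Type-B-specific expression signature is
then derived and used to stratify whole populations, score individuals,
and attribute expression variance; a supervised Gaussian-mixture module
classifies body-composition morphs in mouse colonies. A synthetic-cohort
generator with planted ground truth makes every stage verifiable at desk
scale.

## The statistics at the core

* **Discordance index.** For each pair, with the lower-BMI co-twin as the
  light reference, `d_t = log x_t(heavy) − log x_t(light)` per trait `t`
  (expression arrives log2-normalized, so its discordance is a plain
  difference).
* **Pair typing.** Pairs are clustered on z-scored discordances via a
  shared-nearest-neighbor graph with Jaccard edge weights and Louvain
  modularity optimization; observed modularity is referenced against a
  moment-matched Gaussian parametric bootstrap so unstructured cohorts
  report a single stable cluster. Cluster types follow centroid rules on
  mean fat (`m_fat`) and lean (`m_lean`) discordance.
* **Signature derivation.** Per cluster, paired moderated differential
  expression (heavy − light, empirical-Bayes variance shrinkage by moment
  matching on the log-variance scale, age as a covariate); the signature
  is the set of genes with `p < 0.001` in the Type-B cluster and
  `p ≥ 0.001` everywhere else, refined by k-means on absolute effect
  profiles.
* **Stratification and scoring.** Saturation-point k-means (smallest k
  whose relative WSS drop falls under 10%) with bootstrap Jaccard
  stability; the UPV-B score of an individual is the median of its
  direction-aligned cohort ranks over the signature genes.
* **Enrichment.** From-scratch preranked running-sum enrichment
  (weighted Kolmogorov–Smirnov-style statistic, gene-permutation null,
  sign-matched NES, leading-edge extraction); the HDAC signature is the
  leading-edge union over significantly heavy-enriched HDAC sets.
* **Morph classification.** Gaussian finite mixtures fit by EM with
  kmeans++ restarts and BIC selection; mutant animals are classified
  against a *fixed* wild-type reference component (light / heavy / obese
  by posterior).

## Worked example

```r
library(TwinUPV)

cfg    <- simConfig(seed = 1)                      # reference study conditions
cohort <- simulateExpression(cfg, simulateTwinCohort(cfg))
cohort
#> TwinCohort: 400 individuals, 200 pairs ( DZ=40, MZ=160 )
#>   traits: 35 | genes: 2000
#>   planted truth groups present

sets <- simulateGeneSets(cohort, seed = 1)
res  <- runPipeline(pipelineConfig(gene_sets = sets,
                                   out_dir = "upv_out", seed = 1),
                    cohort = cohort)

res$typing$clustering
#> UPVClustering: 160 pairs in 4 clusters
#>   cluster 1: n=40 type=Concordant
#>   cluster 2: n=40 type=TypeA
#>   cluster 3: n=40 type=TypeB
#>   cluster 4: n=40 type=Intermediate
#>   structure p=0.020; stable clusters: 4

res$signature$signature
#> GeneSignature: 100 genes ( 82 up, 18 down ) specific to TypeB at alpha = 0.001

res$stratification
#> StratificationResult: k = 4 over 400 individuals
#>   stability: 1 1 1 1

res$association$group_fits[, c("group", "n", "slope", "r_squared")]
#>          group  n slope r_squared
#> 1   Concordant 80   1.5       0.1
#> 2 Intermediate 80   1.5       0.1
#> 3        TypeA 80   1.5       0.1
#> 4        TypeB 80   1.5       0.5
```

The four pair clusters are exactly the four planted discordance patterns;
the 100-gene signature is the union of the planted Type-B set and the
HDAC-responsive genes (which are Type-B-specific by construction); the
population stratifies into the four planted molecular states; and only the
Type-B group shows the tight insulin–BMI coupling (R² = 0.5 versus 0.1).
Stage outputs (clusters.tsv, signature.tsv, strata.tsv, enrichment.tsv,
hdac_signature.gmt, a hash manifest, …) land in `upv_out/`.

A thin command-line wrapper is available for shell use:

```sh
Rscript inst/scripts/upv-pipeline.R --simulate --seed 1 --out upv_out
```

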