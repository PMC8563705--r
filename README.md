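# omiclust

Multi-omics cancer subtyping by perturbation clustering, randomized SVD and
ensemble integration — with a sampling/propagation path that scales to
cohorts of tens of thousands of patients on a single machine.

## The problem and the method

Given one samples-by-features matrix per omics platform (mRNA, DNA
methylation, miRNA, copy number, ...), the goal is a patient partition that
is supported by every platform, together with the number of subtypes, which
is *not* assumed known. The pipeline:

1. **Reduce** each layer $X \in \mathbb{R}^{n\times m}$ with a randomized
   SVD: Gaussian sketch $Z = XP$, QR orthogonalization with subspace
   iterations, exact SVD of $Y = Q^\top X = U \Sigma V^\top$, scores
   $X' = (X - \bar{x}) V_r$.
2. **Cluster each layer by perturbation stability**: for each candidate
   $k$, repeatedly add Gaussian noise, re-cluster with k-means, and record
   the binary patient-pair connectivity matrix. The $k$ whose unperturbed
   connectivity is closest to the mean perturbed connectivity
   ($\mathrm{stability} = 1 - \operatorname{mean}\lvert C^{orig} -
   \bar{C}^{pert}\rvert$) determines both the cluster count and the
   per-layer partition.
3. **Integrate**: average the per-layer connectivity matrices into one
   similarity matrix $S$, partition it with hierarchical clustering, PAM on
   $1-S$, and a dynamic branch cut of the dendrogram, and keep the candidate
   with the highest mean adjusted Rand index against the per-layer
   partitions.
4. **Scale**: above `max_sampled` patients (default 2,000), only a sampled
   subset of the fully matched patients is clustered; everyone else is
   assigned by per-layer exact k-nearest-neighbour classification in the
   sampled set's component space (k chosen by 5-fold CV over 5–50), with
   class probabilities averaged across layers. Patient-pair matrices are
   only ever allocated for the sampled set.

Evaluation utilities cover Cox proportional-hazards likelihood-ratio
p-values for discovered subtypes, ARI/NMI agreement, and summary statistics
over dataset-by-method p-value tables (a transcription of a published
39-dataset × 9-method benchmark is bundled in
`inst/extdata/cox_pvalues_benchmark.csv`).

## Worked example

```r
library(omiclust)

sim <- simulate_multiomics(n = 300, m = 1000, n_layers = 2, shift = 2, seed = 7)
res <- subtype(sim, subtyping_params(seed = 7))
print(res)
#> subtyping_result: 300 samples -> 3 subtypes (hierarchical ensemble, agreement 1.000)
#>   sampled: 300, propagated: 0
#>   layer layer1: k = 3, stability = 1.0000
#>   layer layer2: k = 3, stability = 1.0000

agreement(res$final_labels, sim$true_labels)
#> [1] 1
```

Three balanced classes, each with its own block of up-regulated features two
background standard deviations high, are planted in both simulated layers;
the pipeline discovers that there are three subtypes (per-layer stability
1.0) and recovers the planted classes exactly (ARI 1). With class-specific
exponential survival:

```r
surv <- simulate_survival(sim$true_labels, rates = c(0.05, 0.1, 0.2), seed = 8)
survival_pvalue(res$final_labels, surv)
#> [1] 1.45e-14
```

i.e. the discovered subtypes separate survival decisively. On the bundled
benchmark table:

```r
tab <- read_pvalue_table(system.file("extdata", "cox_pvalues_benchmark.csv",
                                     package = "omiclust"))
summarize_pvalue_table(tab, alpha = 0.05)$n_significant
#>           SNF         CIMLR          NEMO     moCluster iClusterBayes
#>            15            15            19             9            11
#>    LRACluster          MCCA        IntNMF          SMRT
#>             8            12            14            28
```

Real omics matrices are loaded with `read_omics_csv()` (rows = samples,
columns = features) and aligned with `align_layers()`; `write_result()`
emits a labels CSV and a JSON provenance record.

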