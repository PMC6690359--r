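# gvtsig

Network-weighted prioritization of plasma-proteomics biomarkers for the
graft-versus-tumor (GVT) effect without graft-versus-host disease (GVHD).

After allogeneic hematopoietic cell transplantation, donor lymphocyte
infusion can eliminate relapsed tumor cells (GVT) but often at the price of
GVHD. Separating the two responses in plasma is a prioritization problem:
isotope-labeled (heavy/light) paired proteomics produces per-protein
abundance ratios, and the proteins specific to GVHD-free GVT must be
distilled out of hundreds of upregulated candidates. `gvtsig` implements a
six-step systems-biology pipeline for exactly that, aimed at
transplant-immunology and plasma-proteomics groups who have ratio-level
quantification tables and want a reproducible, parameterized path from
ratios to a disease-specific signature.

## The method

For each labeling experiment:

1. **Fold filter.** Keep proteins with heavy/light ratio *r* > 1.2
   (strict; a ratio of exactly 1.2 fails).
2. **Exclusion.** Remove proteins in GVHD-specific or common-protein gene
   sets (GMT files).
3. **Subnetwork.** Build the candidate-induced protein–protein interaction
   subnetwork from a STRING-style confidence-weighted edge table, keeping
   edges with confidence ≥ 0.7; optionally extend by "outer genes" one hop
   away. Candidates without any database interactions stay in as isolated
   nodes.
4. **Relevance.** Each candidate g gets a normalized connectivity weight
   ĉ(g) ∈ [0, 1] (sum of retained incident edge confidences, scaled by the
   core maximum) and a relevance score

   relevance(g) = r(g) · (1 + α·ĉ(g)),  α ≥ 0 (default 1).

5. **Penalty.** Candidates recurring in k other-disease gene sets are
   down-weighted without being removed:

   final(g) = relevance(g) / (1 + β·k(g)),  β ≥ 0 (default 0.5).

6. **Combination.** Training and validation experiments are united; genes
   seen in both get the geometric mean of their final scores, singletons
   keep their own. No cutoff is applied — sub-1 scores stay in the
   signature, stratified as > 1 / < 1.

The scored network can be rendered as a **GeneTerrain**: a deterministic
force-directed layout in the unit square plus a Gaussian-kernel surface
Σ_g z_g·exp(−‖p−p_g‖²/2σ²) whose peaks are high-scoring clusters. A
single-cell module classifies signature genes by detection fraction across
antigen-stimulated T-cell populations (PRAME-specific, general activation,
CMV-specific, not expressed) and summarizes the overlap.

A bundled generator (`generate_experiments()`, `generate_singlecell()`)
simulates paired experiments with planted signature / GVHD / background /
contaminant proteins, a scale-free interaction network with a dense planted
signature module, and a labeled single-cell matrix — so the whole pipeline
is testable with known ground truth.

## Worked example

```r
library(gvtsig)
cfg <- pipeline_config(out_dir = "run42", sim = sim_config(seed = 42))
res <- run_pipeline(cfg)
head(res$signature, 5)
#>        gene combined_score      provenance final_training final_validation
#> 1 GENE00556       4.592260   training_only       4.592260               NA
#> 2 GENE00514       3.916348            both       3.330875         4.604730
#> 3 GENE00202       3.321863 validation_only             NA         3.321863
#> 4 GENE00345       3.267081            both       2.794217         3.819968
#> 5 GENE00577       3.264204            both       3.675757         2.898730
signature_strata(res$signature)
#>   gt1   lt1   eq1 total
#>   111    82     0   193
res$overlap$total_expressed; res$overlap$percent_expressed
#> [1] 128
#> [1] 66
evaluate_recovery(res$signature, res$bundle$truth)[c("precision", "recall")]
#> $precision
#> [1] 0.95
#> $recall
#> [1] 0.95
```

The signature table ranks genes by combined score with provenance flags;
`signature_strata()` counts the above-1 and below-1 strata; the overlap
summary says how many signature genes are expressed in activated T cells;
`evaluate_recovery()` compares the top of the ranking against the planted
truth (here 95% of the 60 planted genes are recovered). `run42/` holds the
signature TSV, the terrain matrix, the single-cell assignment, and a JSON
manifest from which the run can be replayed byte-identically. Real data
enter the same way through `pipeline_config(simulate = FALSE, inputs =
list(training = ..., validation = ..., ppi = ..., exclusion = ...,
penalty = ...))`.

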