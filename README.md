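# nmfmarker

Disease marker-gene discovery from bulk RNA-seq expression matrices by
non-negative matrix factorization (NMF), for computational biologists
benchmarking ranked gene lists against curated disease reference sets.

## The method

Given a non-negative gene-by-sample matrix *A* (N×M) and two-group
phenotype labels (disease / normal), the package:

1. factorizes *A ≈ WH* by minimizing the generalized Kullback–Leibler
   divergence D(A‖WH) = Σᵢⱼ [Aᵢⱼ log(Aᵢⱼ/(WH)ᵢⱼ) − Aᵢⱼ + (WH)ᵢⱼ] with
   multiplicative updates, where *W* (N×k) holds the metagene basis and
   *H* (k×M) the per-sample metagene activities;
2. selects the rank *k* by consensus clustering over independent seeded
   runs — cophenetic correlation, dispersion, silhouette, explained
   variance per rank (`rank_survey()`);
3. labels the two clusters against the phenotype: the cluster with the
   larger disease fraction becomes the disease cluster g₊ with precision
   *p* (that fraction), and every gene is scored by the
   precision-weighted basis combination

   **scoreᵢ = p · W(i, g₊) + (1 − p) · W(i, g₋)** ,

   ranked descending (`label_clusters()`, `score_genes()`);
4. benchmarks the ranking against a reference gene set via the
   enrichment ratio **ER = (g/n)/(G/N)** (overlap g in a size-n list,
   reference size G, universe N), comparing matched-size NMF and
   DEG-threshold lists across an 8-threshold grid with Welch's t-test
   (`matched_comparison()`).

A synthetic-data generator with planted markers (`generate_dataset()`),
a TPM / log2(TPM+1) / expression-filter preprocessing layer, a
convenience per-gene Welch DE test, and a CLI wrapper round out the
pipeline. See the vignette in `vignettes/nmf-marker-discovery.Rmd` for
the model, diagnostics and design rationale.

## Worked example

Simulate a 2000-gene, 60-sample dataset with 50 planted markers, run a
5-run consensus at rank 2, score genes, and compare against the built-in
DE comparator:

```r
library(nmfmarker)

ds      <- generate_dataset(synthetic_spec(seed = 7))
cons    <- consensus_run(ds$matrix, rank = 2, n_runs = 5, base_seed = 107)
labeling <- label_clusters(assign_clusters(cons$best_run), ds$labels)
scores  <- score_genes(cons$best_run, labeling)
report  <- matched_comparison(scores, generate_de_table(ds),
                              reference = ds$markers)
print(labeling)
print(report)
```

```
Cluster labeling: disease cluster 2 (precision 1.0000), normal cluster 1
 cluster n_disease n_normal n_total frac_disease
       1         0       40      40            0
       2        20        0      20            1
Enrichment comparison (reference G = 50, universe N = 2000)
              threshold   n g_deg ratio_deg g_nmf ratio_nmf
               FDR<0.05 292    46      6.30    50      6.85
   FDR<0.05 & |logFC|>1 108    30     11.11    44     16.30
               FDR<0.01 206    44      8.54    49      9.51
   FDR<0.01 & |logFC|>1 108    30     11.11    44     16.30
 FDR<0.05 & |logFC|>0.5 144    30      8.33    48     13.33
 FDR<0.05 & |logFC|>1.5  55    11      8.00    32     23.27
 FDR<0.01 & |logFC|>0.5 144    30      8.33    48     13.33
 FDR<0.01 & |logFC|>1.5  55    11      8.00    32     23.27
mean enrichment ratio: DEG 8.72 vs NMF 15.27 (Welch t-test p = 0.0159)
```

Reading the output: the consensus fit cleanly separates the 20
disease-program samples into cluster 2 with precision 1, so the gene
score reduces to the disease-metagene weight. At every matched list
size the NMF ranking overlaps the planted 50-marker reference set more
than the DEG list does (e.g. 44 vs 30 markers at n = 108), because the
DEG lists are diluted by strong responders outside the reference set
while several low-fold-change markers are invisible to thresholds —
exactly the regime the precision-weighted score targets.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/nmfmarker.R simulate --genes 2000 --samples 60 --out data/
Rscript inst/cli/nmfmarker.R run-all --seed 42 --out run/
```

For real data, supply `--matrix` (TSV, genes × samples), `--labels`
(two-column TSV), a reference gene list (one symbol per line) and
optionally a DE table from a dedicated tool (`gene`, `logFC`, `adj_p`;
column names remappable).

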