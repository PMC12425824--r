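# motifdev

Single-cell chromatin-state analysis for epithelial lineages: from QC'd
count matrices to transcription-factor motif programs and patient outcome
stratification.

Prostate epithelium harbors an ERG-driven intermediate (IM) cell state
whose regulatory program shows up in single-cell ATAC data as coordinated
accessibility of ETS-family motifs with partner motifs in the same peaks.
`motifdev` is for computational biologists who want a tested, reproducible
reimplementation of that analysis chain: cell-level QC, epithelial lineage
assignment from gene signatures, chromVAR-style motif accessibility
deviations with background-matched peak sets, per-cell-type hypergeometric
motif enrichment with expression and correlation retention filters, the ETS
co-occurrence co-accessibility rank-sum test, and Kaplan–Meier/log-rank
comparison of signature-score quartiles in bulk cohorts. A seeded synthetic
multiome generator with planted ground truth stands in for real accessions,
so every stage is verifiable end to end.

## The core statistic

For a peak-by-cell count matrix `X`, expected counts under uniform
accessibility are `E_ij = r_i c_j / T` (peak totals `r`, cell totals `c`,
grand total `T`). For a peak set `S` (a motif's peaks, or a co-occurrence
partition), the per-cell raw deviation is

    y_j = (Σ_{i∈S} X_ij − Σ_{i∈S} E_ij) / Σ_{i∈S} E_ij

which is bias-corrected against `B` background peak sets matched on GC
content and mean accessibility (k-nearest-neighbour sampling, tie-closed):

    d_j = y_j − mean_b(ỹ_j^(b)),   z_j = d_j / sd_b(ỹ_j^(b))

The co-occurrence test partitions peaks carrying a candidate motif or the
collapsed ETS family into BOTH / CAND_ONLY / ETS_ONLY, computes each set's
per-cell `z` in the IM cells, and runs one-sided ("greater") Wilcoxon
rank-sum tests of BOTH against each exclusive set, BH-corrected across
candidates.

## Worked example

The numbered drivers under `analysis/` run the full chain on the synthetic
multiome (seed 1), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # 2,000 peaks x 200 cells + cohort
Rscript analysis/02_qc.R
Rscript analysis/03_lineage.R
Rscript analysis/04_deviations.R
Rscript analysis/05_motif_enrichment.R
Rscript analysis/06_coaccessibility.R
Rscript analysis/07_survival.R
```

Stage 3 reports lineage recovery against the planted identities:

    epithelial clusters: basal, IM, L1, L2
    assigned 200 cells; 100.0% match the planted identity
    derived 'IM' signature with 10 genes (padj < 0.05, FC > 2)

Stage 6 prints the co-occurrence test inside IM cells. STAT3×ETS peaks are
amplified 2× in IM cells by construction and are recovered in both
comparison directions; NFATC1 co-occurs with ETS but carries no
amplification and is not called:

    co-accessibility in IM cells (FDR across candidates):
      STAT3   both_vs_ets_only   U =   2401  p = 7.56e-18  FDR = 1.51e-17
      STAT3   both_vs_cand_only  U =   2390  p = 1.48e-17  FDR = 2.96e-17
      NFATC1  both_vs_ets_only   U =     98  p = 1         FDR = 1
      NFATC1  both_vs_cand_only  U =    981  p = 0.941     FDR = 0.941

Stage 7 stratifies the simulated cohort (log hazard log(2.5) per signature
SD) into score quartiles within each ERG stratum and compares top versus
bottom by log-rank:

    top vs bottom signature quartile, log-rank within ERG strata:
      ERG negative n =  97  chi-square =  17.20  p = 3.36e-05
      ERG positive n = 103  chi-square =  27.05  p = 1.99e-07

Small p values here mean the planted signature–hazard link is detected; on
a null cohort (`cohort_log_hazard_per_sd = 0`) the same test is calibrated
(type-I error ≈ 5%).

`run_pipeline(default_pipeline_config(seed = 1), "out/")` runs the same
chain as one call and writes a `manifest.json` with file hashes, seeds and
thresholds; reruns are byte-identical.

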