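# ripitome

Simulation-backed analysis pipeline for activation-induced RNA-protein
interactome studies, built around the splicing-factor biology of primary
CD4 T cells: when T cells are activated, the protein interactome of the
U2AF splicing complex reorganizes, and so do the transcripts it binds.
The package implements the four computational stages such a study needs
and ships synthetic-data generators with planted ground truth so every
stage can be validated end to end without any external dataset.

## What it computes

**SILAC isotope-envelope quantification.** For ¹⁴N/¹⁵N metabolic
labeling, the theoretical isotopologue envelope of a peptide with
composition C_c H_h N_n O_o S_s is the convolution of per-atom isotope
abundance vectors, computed in the Fourier domain
(`isotope_distribution()`). An observed mini-spectrum *y(m)* around a
matched light/heavy feature pair is fit as

    min_{A_L, A_H >= 0}  sum_i ( y_i - A_L P_L(m_i) - A_H P_H(m_i) )^2

(`fit_ls_ftc()`), where *P* projects an envelope onto the m/z grid at the
pair's charge. The amplitude ratio R = A_L/A_H quantifies relative
peptide abundance; per protein, log ratios are tested against 0 with a
one-sample t-test and Benjamini–Hochberg correction
(`protein_ratio_stats()`).

**Interactome assembly.** Replicated protein hit tables are filtered
(FDR < 1%, human, non-contaminant; `filter_protein_hits()`), detection is
called by replicate majority (`detection_call()`), and the interactome is
partitioned into core members (CIMs — detection survives RNase A, i.e.
protein-protein contacts) and peripheral members (PIMs — RNase-sensitive,
RNA-scaffolded) with full Venn accounting (`assemble_interactome()`).

**Expression / binding analysis.** Counts convert to FPKM
(`compute_fpkm()`), genes are filtered by a strict-majority
log₂(FPKM) rule (`filter_expressed()`), and differential expression or
binding is called by a self-contained conditional negative-binomial exact
test with median-of-ratios normalization and a pooled method-of-moments
dispersion (`differential_expression()`). Splicing is scored on
inclusion/exclusion feature pairs by a gene-normalized splicing index and
a reciprocity score (`splicing_scores()`), and genes are assigned to the
three response classes (`classify_genes()`).

**Enrichment.** Hypergeometric over-representation of a query list
against a GMT pathway collection over an explicit universe, BH-adjusted
(`hypergeometric_enrichment()`), with bipartite pathway–gene SIF export
(`export_network()`).

## Worked example

```r
library(ripitome)

cfg <- sim_config(seed = 7, n_genes = 500, n_samples_per_group = 3,
                  n_proteins = 8, n_pathways = 10,
                  pathway_size_range = c(10L, 30L), query_size = 60,
                  planted_enriched = 2)
res <- run_pipeline(cfg)

sum(res$de$p_adj < 0.05)          # 105 genes called at FDR 0.05 (100 planted)
head(res$quant$proteins, 2)
#>    protein n_peptides mean_log2        p_adj significant
#> 1 prot0001          7 0.9861356 2.233110e-13        TRUE
#> 2 prot0002          8 1.0722579 5.244195e-15        TRUE
res$interactome
#> Interactome: 8 proteins total
#>   core (RNase-resistant):    2
#>   peripheral (RNase-sensitive): 6
head(res$enrichment[order(res$enrichment$p), ], 2)
#>      pathway  k  K            p        p_adj significant
#> 1 pathway001 11 20 2.199431e-06 2.199431e-05        TRUE
#> 2 pathway002  9 18 5.919021e-05 2.959511e-04        TRUE
```

The differential test recovers essentially all genes planted at
|log₂FC| = 2 while keeping the false-discovery proportion near the
nominal 5%; the SILAC stage recovers each protein's planted ~2-fold
ratio (mean_log2 near 1) with small peptide-level spread; both planted
pathways top the enrichment table. The methods vignette
(`vignettes/pipeline-methods.Rmd`) documents the models, defaults, and
what the simulations do and do not establish.

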