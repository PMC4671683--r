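---
title: "Methods: activation-induced interactome analysis with SILAC envelope fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation-induced interactome analysis with SILAC envelope fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripitome)
```

# Overview

`ripitome` implements the computational core of an activation-induced
RNA-protein interactome study in primary CD4 T cells: when T cells are
activated, the protein complex centered on the splicing factor U2AF2
reorganizes, and both the proteins it touches and the transcripts it binds
change. Four analysis stages capture this:

1. **SILAC isotope-envelope quantification** — relative peptide abundance
   between resting and activated cells from ^14^N/^15^N metabolic labeling,
   by least-squares fitting of theoretical isotope envelopes.
2. **Interactome assembly** — replicated mass-spectrometry hit tables are
   filtered and partitioned into core members (CIMs, RNase-resistant:
   protein-protein contacts) and peripheral members (PIMs, RNase-sensitive:
   held together by the RNA scaffold).
3. **Expression and binding analysis** — RNA-seq / RIP-seq counts to FPKM,
   expression filtering, a conditional negative-binomial exact test for
   differential expression or binding, splicing-index scoring, and the
   three-class gene assignment (DE only, DE + AS, AS only).
4. **Immune-pathway enrichment** — hypergeometric over-representation of
   gene lists in a pathway collection, with Benjamini-Hochberg correction
   and bipartite network export.

Every stage is exercised on synthetic data with planted ground truth, so
the statistical behaviour of the whole pipeline is testable without any
external download.

# Isotope envelopes by Fourier-domain convolution

A peptide's isotopologue envelope is the distribution of the number of
"extra" neutrons over its atoms. For an elemental composition
$\mathrm{C}_{c}\mathrm{H}_{h}\mathrm{N}_{n}\mathrm{O}_{o}\mathrm{S}_{s}$
the envelope is the convolution of one abundance vector per atom. Because
convolution is multiplication in the Fourier domain,
`isotope_distribution()` transforms each element's abundance polynomial
once, raises it elementwise to the atom count, multiplies across elements,
and inverts with a single FFT. The FFT length is padded well beyond the
envelope's mean-plus-12-standard-deviations support so circular wrap-around
cannot corrupt the result, and the returned envelope is truncated at an
upper-tail mass below $10^{-9}$ and renormalized.

Metabolic ^15^N labeling replaces nitrogen's natural abundances
$(0.99636,\,0.00364)$ by $(1-e,\,e)$ at enrichment $e$. The labeling
efficiency of the original experiment is not knowable from the data we
emulate, so $e$ is a free parameter defaulting to $1.0$. At $e = 1$
nitrogen contributes a single line and the envelope is re-based so that
offset 0 is the (all-^15^N) monoisotopic species. The isotope mass and
abundance table is shipped as a fixed constant so envelopes are
bit-reproducible.

The exactness of this route is tested against an independent atom-by-atom
time-domain convolution oracle on compositions up to 200 atoms
(agreement to $10^{-9}$ per offset).

# Least-squares envelope fitting (LS-FTC)

A quantifiable peptide appears twice in a run: a light (^14^N) and a heavy
(^15^N) feature that must share the peptide identity and charge state and
co-elute. The co-elution tolerance is not a published quantity; the default
is 30 s and is configurable. Features with ambiguous identity are excluded
before pairing, and every rejection carries a reason code.

Given a mini-spectrum window $y(m)$ around a pair, `fit_ls_ftc()` solves

$$\min_{A_L, A_H \ge 0}\; \sum_i \left(y_i - A_L P_L(m_i) - A_H
P_H(m_i)\right)^2$$

where $P$ projects an envelope onto the m/z grid: peak $k$ of a
distribution with monoisotopic mass $M$ at charge $z$ lands at
$(M + k\,\Delta_n + z\,m_p)/z$, with $\Delta_n$ the ^13^C-^12^C spacing by
default and a unit-height Gaussian line shape (FWHM 0.02 m/z by default;
centroid mode snaps delta peaks to the grid for exact tests). The
two-variable nonnegative least-squares problem is solved in closed form
with an active-set step. The abundance ratio is $R = A_L / A_H$, and the
orientation onto biological conditions (activated/resting vs
resting/activated) is an explicit argument of the protein-level test,
since either convention appears in published figures.

Manual inspection of fits is replaced by two explicit thresholds: minimum
signal-to-noise ratio (fitted-signal maximum over residual standard
deviation, default 10) and maximum residual fraction (RSS over total
signal energy, default 0.2). A fit is also rejected when the projected
light and heavy envelopes share more than half of the smaller envelope's
grid support ("spectral overlap"), which happens at low labeling
efficiency or very low nitrogen counts.

Per protein, accepted peptide ratios are log-transformed and tested with a
one-sample two-sided t-test against 0 (i.e. ratio 1), BH-adjusted across
proteins; significance is `p_adj < 0.05`. Proteins with fewer than two
finite ratios are "untestable", and proteins whose log-ratios are
numerically constant are "untestable-degenerate" rather than being given
p = 0. Whether the original fitting software also fit the envelope width
is unknown; here the line width is fixed per run.

# Differential expression and binding

FPKM is computed as $c_{gs} / ((\ell_g/10^3)(L_s/10^6))$ with $\ell_g$ the
exon-model length and $L_s$ the sample's total assigned fragments. The
expression filter retains a gene when $\log_2(\mathrm{FPKM})$ exceeds a
threshold in strictly more than half the samples of at least one group.
The printed threshold "FPKM > -2" is only meaningful on the log scale
(linear FPKM is never negative), so the filter is interpreted as
$\log_2(\mathrm{FPKM}) > -2$ for RNA-seq; the RIP-seq "bound transcript"
variant uses $+2$. "More than half" is a strict majority; exact ties drop
the gene.

The differential test is a self-contained conditional negative-binomial
exact test rather than a call into an external package, so that its exact
null distribution can be validated in-repo:

* counts are normalized with **median-of-ratios size factors** and scaled
  to a common pseudo-library. Total-count normalization is biased when a
  fifth of genes shift four-fold (the normalizer absorbs the planted
  signal and shifts every null gene by ~0.29 log2 units); median-of-ratios
  is robust to a minority of changed genes, which is also why the
  standard count-based DE tools use robust normalizations of this family;
* a single dispersion $\phi$ (variance $\mu + \phi\mu^2$) is estimated by
  method of moments pooled over genes and groups, with the group-mean
  squared term debiased by the sampling variance of the mean;
* for each gene the split $(S_A, S_B)$ of the total $S$ between groups is
  tested conditionally on $S$, using the identity that a sum of $n$ iid
  $\mathrm{NB}(\mu, \phi)$ is $\mathrm{NB}(n\mu, \phi/n)$. The two-sided
  p-value sums the probabilities of all splits at most as likely as the
  observed one ($\phi = 0$ degenerates to the exact binomial split).

The test is validated two ways: exact agreement (to $10^{-12}$) with a
brute-force oracle that builds the group-sum distributions by repeated
numeric convolution for totals up to 60, and Monte-Carlo calibration on
null simulations (raw $p < 0.05$ at $0.05 \pm 0.015$, zero expected BH
discoveries).

# Splicing index and gene classes

Splicing changes are scored on microarray-style inclusion/exclusion
feature intensities rather than junction reads. For a feature $f$ of gene
$g$ between condition B (e.g. knockdown) and A (control),

$$SI_f = \log_2 \frac{(I_f / I_g)_B}{(I_f / I_g)_A},$$

so a probeset stronger in the control is negative. The normalization
applied by the original array console is unpublished; gene-level ratio
normalization is the documented stand-in. A reciprocal isoform switch
moves the inclusion and exclusion features oppositely, captured by the
reciprocity score $(SI_{incl} - SI_{excl})/2$; a gene is called
alternatively spliced when the absolute score exceeds 0.2, mirroring the
default threshold of the reciprocal-isoform metric it stands in for. A
stricter variant adding a p-value gate exists in the literature; both
knobs are exposed and neither is privileged. `classify_genes()` then
partitions the universe into DE-only, DE-and-AS, AS-only, and neither.

# Interactome assembly

Hits are kept when the identification FDR is strictly below 1%, the
species is human, and the accession is not on the contaminant list (a
small default list of keratins, trypsin, serum albumin and immunoglobulin
chains ships with the package; real analyses should supply their own).
Detection within one (condition, RNase-state) cell requires presence in at
least $\lceil n/2 \rceil$ of its replicates — the original work states no
replicate rule, so an explicit majority default is used. The whole
interactome is the union of RNase-minus detections across conditions; the
core layer is the union of RNase-plus detections; peripheral members are
the difference. A core-detected accession missing from the whole layer
(possible under dropout) is added back with a warning, because
RNase-resistant detection implies association. PTM records of the four
tracked types are tallied per protein, flagging proteins with three or
more modifications.

# Hypergeometric enrichment

For a query list against a pathway collection over an expressed-gene
universe, the upper-tail hypergeometric probability $P(X \ge k)$ is
computed per pathway and BH-adjusted within the collection. The universe
is the single most result-sensitive free choice — published enrichment
runs rarely state it — so it is a required argument, typically the
`filter_expressed()` output. Only over-representation is tested. Exact
agreement with enumeration over all $\binom{N}{n}$ draws is tested for
$N \le 12$. Significant pathways and their query members are exported as
SIF edges plus a node-attribute table with per-gene directions.

# Synthetic data and what it does (not) show

The generators define the study conditions under which the pipeline is
validated:

* **Counts**: log-normal relative abundances, negative-binomial noise at
  dispersion 0.1, six samples per group (three in the recovery scenario,
  matching the smallest replicated design), expected library size
  $3\times10^5$ over 2000 genes, 20% DE at $|\log_2 FC| = 2$ split evenly
  up/down. Column-sum expectations match the configured library sizes.
* **SILAC spectra**: random tryptic-length peptides (8-20 residues,
  uniform over the 20 standard residues, no digestion model), charge 2-3,
  natural-abundance light channel vs enriched heavy channel, planted
  per-protein log2 ratios $\mathcal N(1, 0.2)$ (or degenerate at 0 for
  null calibration), Gaussian intensity noise of 6 units against a ~300
  unit base peak (SNR near 50). Retention-time jitter stays within half
  the matching tolerance so true pairs always co-elute; an optional decoy
  fraction violates it to exercise rejection.
* **Hit tables**: six whole / four RNase replicates per condition, ~30%
  of members core, condition scope 80% shared / 15% activated-only /
  5% resting-only (emulating the 194/35/10 split of the design being
  modeled), contaminants drawn from the shipped list, non-human and
  high-FDR background hits, per-replicate dropout.
* **Gene sets**: 40 pathways of 20-80 genes over a 2000-gene universe,
  query size 300 (about 15% of the universe, comparable to the
  query-to-universe ratios of the real analyses; small queries make the
  hypergeometric test noticeably conservative through discreteness, and
  the measured null rate of ~0.033-0.04 reflects residual discreteness,
  not miscalibration). Planted pathways contribute half their genes to
  the query.

These simulations establish correctness of the arithmetic and the null
behaviour of the tests. They do **not** model: chromatographic peak
shapes, instrument-specific or multiplicative intensity noise, peptide
misidentification, correlated gene-gene expression, isoform-level read
assignment, batch effects, or overlap between pathways beyond random
sharing. Passing here shows the methods do what they claim under their
own assumptions, not that those assumptions hold for any particular
instrument or library preparation.

# Numerical choices

* Envelope tail truncation at $10^{-9}$ mass, then renormalization; FFT
  padding to a power of two beyond mean $+ 12\sigma + 64$ offsets.
* The two-component NNLS is solved analytically; a design whose projected
  envelopes are numerically collinear (relative determinant below
  $10^{-12}$) raises an error rather than returning an arbitrary split.
* Exact-test two-sided p-values include outcomes with probability within
  a $1 + 10^{-10}$ factor of the observed one, guarding against float
  ties in the "sum of at-most-as-likely outcomes" rule.
* Reported percentages round half-away-from-zero, matching how the
  worked figure numbers (67%, 82%) behave.
* Degenerate inputs are reported, not silently dropped: zero-variance
  proteins are "untestable-degenerate", unmatched features carry reason
  codes, query genes outside the universe are counted.

# Problem sizes

The shipped tests and the acceptance script run, by choice, at desk
scale: 2000-gene count matrices, 100-1800 peptide spectra, 500-600
proteins for null calibration, 250-protein hit tables, and 500-1000
enrichment replicates. These sizes give stable Monte-Carlo estimates
(binomial standard errors under 0.01 on all calibration rates) while a
full run of the test suite plus the acceptance script completes in a few
minutes on one core.

# Known limitations

* The peak-pair matcher assumes at most one light and one heavy feature
  per (peptide, charge); chromatographically split features are rejected
  as duplicates rather than merged.
* The common-dispersion NB test ignores gene-specific dispersion; with
  strong mean-dispersion trends a per-gene shrinkage estimator would be
  needed.
* Envelope fitting assumes the window contains exactly the pair being
  fit; co-eluting contaminant envelopes inflate the residual and are only
  handled by rejection.
* The splicing stand-in scores one inclusion/exclusion feature pair per
  gene; genes with multiple alternative events need one call per event.
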