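---
title: "Methods: genomic convergence for candidate-gene discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic convergence for candidate-gene discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convergene)
```

## The problem and the approach

Single genome-wide association studies of complex autoimmune disease rarely
implicate a gene on their own: association peaks spread over linkage
disequilibrium (LD) blocks containing dozens of genes, and sub-threshold
signals are indistinguishable from noise. *Genomic convergence* strengthens
the inference by requiring independent data types to point at the same gene:

1. **Association**: a composite score over GWAS summary statistics flags
   windows that combine a strong best p-value with a cluster of surrounding
   significant SNPs, and flagged windows are merged into loci.
2. **Position**: loci are mapped to the genes they contain (or, failing
   that, the nearest gene).
3. **Expression**: each locus gene must be differentially expressed between
   cases and controls in at least two independent expression datasets, with
   every probe of the gene changing in the same direction.
4. **Regulation**: associated SNPs in the loci are intersected with a
   cis-eQTL table; the eQTL Z-score sign says whether the allele up- or
   downregulates the gene.
5. **Context**: the surviving genes are placed in a protein-interaction
   network, filtered at a low-confidence score, and clustered.

Candidates that pass the expression filter are then validated by qPCR with
2^-ddCt quantification, two-group tests and ROC statistics.

## The composite window score

For a tiling window of width $w$ (default 20 kb, anchored at position 1,
half-open) holding SNP p-values $p_1 \dots p_m$, with $n_\sigma$ of them
below $\alpha$ (default 0.05):

$$S = \begin{cases} 0 & n_\sigma = 0\\
-\log_{10}\min_i p_i \; + \; \lambda\, n_\sigma & n_\sigma > 0 \end{cases}$$

with weight $\lambda = 1$ by default. The two terms deliberately mirror the
two facets of an LD-clustered association signal: peak strength and local
support. The published locus-scoring tool this emulates does not disclose
its exact statistic, so this package defines its own transparent composite
with the same two ingredients; $\lambda$ is a tunable if one facet should
dominate. Fixed tiling (not sliding) windows keep the SNP-to-window
assignment unique, which makes the score's null behaviour easy to reason
about and the scan order-invariant.

Windows with $S$ at or above a study-chosen threshold merge into a locus
when separated by at most one window width (configurable). There is no
universal threshold: the score scale depends on SNP density and $\alpha$,
so `merge_loci()` requires it explicitly. A practical anchor is the score of
a reference configuration, e.g. `composite_score(1e-4, 5)` = 9.

## Expression convergence

Within each dataset every probe gets a Welch (unequal-variance) two-sided
t-test; Welch is the default because public expression series almost never
have balanced or variance-matched groups. A gene is *significant in a
dataset* when any of its probes has $p < \alpha$. A gene is **called** when

* it is significant in at least `min_datasets` (default 2) datasets,
* all of its probes in those significant datasets share one direction of
  change (probes with an exactly zero mean difference are neutral), and
* it belongs to the reference gene list, i.e. the locus genes -- the
  intersection with the association evidence is the point.

The directional-alignment rule is enforced over *all* probes of the gene in
the significant datasets, not only the significant probes: that is the
strictest reading of "all probes directionally aligned", and it is what the
synthetic generator plants (all probes of a spiked gene shift together).
The gene-level summary p-value is the minimum probe p over the gene's
significant datasets; it is a ranking device, not a calibrated p-value, and
is declared as such in the pipeline metadata. FDR (Benjamini-Hochberg) and
Bonferroni gates are applied over the called genes' summary p-values via
`stats::p.adjust`.

## eQTL direction and extreme tails

`z_to_p()` converts an eQTL Z-score to its two-sided standard-normal tail
with `pnorm(|z|, lower.tail = FALSE)`, which is erfc-based and therefore
accurate where naive `1 - pnorm(z)` returns exactly 0 (any $|z| \gtrsim 8$).
A Z of $-10.92$ maps to $9.2\times10^{-28}$; the sign is read as direction
(negative = the allele downregulates the gene). Below the smallest positive
double (about $5\times10^{-324}$, reached near $|z| = 38.6$) the returned
tail is 0; tests assert positivity and strict monotonicity over the
representable range only.

Hits are ranked by GWAS p first and eQTL p second: an extreme eQTL with
weak genomic support should surface *after* a SNP significant in both
dimensions, but both p-values are reported so that tension stays visible.

## qPCR statistics

`relative_expression()` implements 2^-ddCt: replicates are averaged per
(sample, gene); $\Delta Ct$ subtracts the *arithmetic* mean of the
housekeeping Cts, which on the expression scale is the geometric average of
the housekeeping genes -- the standard multi-reference normalisation;
$\Delta\Delta Ct$ subtracts the control-group mean $\Delta Ct$, making the
control geometric mean exactly 1. The function takes a housekeeping *list*
because practice varies between a single reference gene (GAPDH) and a
geometric pair (ACTB+GAPDH); both are runnable.

Group comparison always reports both a Welch t-test on log2 fold values
(ratios are approximately log-normal) and a Mann-Whitney rank-sum test.
Published qPCR "t-test" statistics in the hundreds are numerically
implausible for a t statistic and are most likely rank-sum U values, so the
package refuses to pick one reading and reports both.

`roc_auc()` uses the rank formulation $AUC = U/(n_1 n_2)$ (ties one half),
the Hanley-McNeil standard error, a truncated normal 95% CI, and a normal
test against 0.5 -- matching the "AUC ± SE, CI95%" presentation style of
standard statistics packages rather than a resampling CI.

## Network stage

Edges are kept when **either** the coexpression or the experimental channel
reaches 0.15 (a low-confidence cutoff chosen to keep modest but real
interactions such as a 0.31 coexpression link); filtering on the combined
score is available as an option because score conventions differ. Scores on
the 0-1000 integer scale are normalised by 1000 at read time, with a
message. The clustering of the upstream web tool is unpublished, so the
package uses a standard spectral relaxation: leading-$k$ eigenvectors of
the symmetric-normalised adjacency, then `stats::kmeans` with 10 restarts
under a fixed seed; eigenvector signs are canonicalised so results are
reproducible. Connecting paths are unweighted BFS with alphabetical
neighbour tie-breaks, again for determinism.

## The synthetic-data generator

The generator replaces external accessions while preserving the statistical
structure each stage assumes; its defaults are the package's study
conditions:

* **GWAS**: one 11 Mb pseudo-chromosome (the width of a typical regional
  search), 10,000 background SNPs with Uniform(0,1) p-values, three planted
  peaks (at 2, 5.5 and 8.5 Mb with $-\log_{10}p$ peak levels 6-8) each
  contributing an LD cluster of 10 co-significant SNPs in a 50 kb span.
  Cluster $-\log_{10}p$ values are the peak level plus Normal(0, 0.5)
  jitter floored at 1.3 -- peak-shaped without simulating genotypes. LD is
  emulated as co-location only; there is no genotype correlation matrix,
  which is adequate because every consumer sees summary statistics only.
* **Expression**: Normal(0,1) probe values, 20 cases vs 20 controls, 500
  genes with 2 probes each; spiked genes shift all their probes' case means
  by $d$ (default $|d| = 1.5$ SD, 20 genes, 2 of 3 datasets affected) with
  one sign across probes and datasets.
* **eQTL**: background Z ~ Normal(0,1) with p equal to the two-sided tail
  by construction; planted target genes are paired with the most
  significant simulated SNPs.
* **qPCR**: housekeeping genes at 18 cycles in both groups, targets at 25;
  case targets shifted by `-ct_shift` cycles (default 1 = one doubling);
  technical replicate noise SD 0.25 cycles (typical qPCR technical
  variance), a per-sample global offset SD 0.5 cycles that the
  normalisation must remove, and a per-sample biological SD of 0.5 cycles
  on targets so group distributions overlap realistically.
* **Annotation and edges**: evenly spaced 20 kb gene bodies matching the
  expression gene universe, and a background interaction table with
  Beta-distributed low scores plus better-connected hubs for spiked genes.
  These two generators exist so the pipeline can run end to end from one
  seed.

What the generator does **not** emulate: genotype-level LD structure,
array normalisation artefacts, probe cross-hybridisation, batch effects,
correlated genes, or permutation-based eQTL p-values. Passing tests
therefore demonstrate correctness of the statistics and the plumbing under
idealised noise, not robustness to real-data pathologies.

All generators are pure functions of `(config, seed)`: the master seed is
split into fixed per-stage streams, so a configuration reproduces
byte-identical tables, and the pipeline is deterministic end to end.

## Numerical and design choices

* Coordinates are 1-based; windows are half-open, gene intervals inclusive
  (NCBI convention); BED input is converted at the reader.
* Top-SNP ties break by smaller p, then position, then SNP id; nearest-gene
  ties alphabetically; path ties alphabetically -- all chosen to make
  outputs order-invariant and reproducible.
* Degenerate probes (zero variance, equal means) get $t = 0, p = 1$ rather
  than NaN.
* The final pipeline ranking -- called, then FDR pass, then eQTL presence,
  then ascending summary p -- is an invented but declared total order; the
  underlying narrative evidence types do not define one.
* Problem sizes in the test-suite calibration runs (e.g. 200 simulated null
  studies of 100 single-probe genes at n = 10 vs 10; 20 recovery runs of
  500 genes at n = 20 vs 20) were chosen as the smallest sizes at which
  binomial simulation error is well below the effects being checked.

## Known limitations

* The composite score is this package's own realisation of the
  peak-plus-support idea; scores are not comparable to the original
  locus-scoring tool's output, and no p-value is attached to a window
  score.
* No meta-analytic p-combination across GWAS is provided -- tables are
  scanned separately and loci intersected by coordinates -- because the
  combination rule of the reference analysis is unstated.
* The convergence summary p (minimum over probes and datasets) is
  anti-conservative as a p-value; FDR/Bonferroni gates on it order genes
  sensibly but should not be read as calibrated error control.
* No colocalisation posterior is computed for eQTL overlaps; overlap plus
  direction is reported, nothing more.
* Ct handling assumes perfect amplification efficiency (a factor of 2 per
  cycle); no standard-curve correction.
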