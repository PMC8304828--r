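#' Simulation configuration for synthetic pipeline inputs
#'
#' Bundles every parameter the synthetic-data generators need into a single
#' validated object. One master `seed` drives all generators through a
#' documented splitting scheme, so a fixed configuration reproduces
#' byte-identical inputs.
#'
#' The defaults describe a single pseudo-chromosome of 11 Mb (the width of a
#' typical regional association search) carrying three planted association
#' peaks, expression studies of 20 cases vs 20 controls across 500 genes with
#' two probes each, and qPCR tables with 0.25-cycle technical noise.
#'
#' @param seed Integer master seed; every generator derives its stream from it.
#' @param chrom Chromosome label used in all coordinate-bearing outputs.
#' @param chrom_length_bp Length of the simulated chromosome in bp.
#' @param n_snps Number of background SNPs with Uniform(0,1) p-values.
#' @param ld_cluster_size Number of co-significant SNPs each planted locus
#'   contributes, emulating an LD cluster around a causal variant.
#' @param locus_span_bp Width of the region a planted locus' SNP cluster
#'   occupies, centred on `center_bp`.
#' @param planted_loci Data frame with columns `center_bp` and `peak`
#'   (peak -log10 p-value of the planted association). `NULL` for a null
#'   genome with no planted signal.
#' @param n_genes Number of genes in the simulated annotation/expression
#'   universe (symbols `G0001`, `G0002`, ...).
#' @param probes_per_gene Microarray probes measuring each gene.
#' @param de_genes Data frame with columns `gene`, `effect_d` (signed shift of
#'   the case-group mean, in SD units) and `n_datasets` (how many expression
#'   datasets carry the effect). `NULL` for a null experiment.
#' @param n_case,n_control Group sizes per expression dataset and per qPCR
#'   cohort.
#' @param eqtl_targets Data frame with columns `gene` and `z`: genes given a
#'   planted cis-eQTL (paired with the most significant simulated SNPs) at the
#'   stated Z-score. `NULL` for background-only eQTL tables.
#' @param ct_shift Cycles subtracted from case-group target Ct (one cycle =
#'   one doubling of expression; positive values mean higher expression in
#'   cases, negative values repression).
#' @param ct_sigma Technical replicate noise SD of Ct values, in cycles.
#' @param ct_bio_sd Per-sample biological SD of target-gene Ct, in cycles.
#' @param ct_replicates Technical replicates per (sample, gene).
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$planted_loci
#' @export
sim_config <- function(seed = 1L,
                       chrom = "chr12",
                       chrom_length_bp = 11e6,
                       n_snps = 10000L,
                       ld_cluster_size = 10L,
                       locus_span_bp = 50000L,
                       planted_loci = tibble(
                         center_bp = c(2e6, 5.5e6, 8.5e6),
                         peak = c(6, 8, 7)
                       ),
                       n_genes = 500L,
                       probes_per_gene = 2L,
                       de_genes = NULL,
                       n_case = 20L,
                       n_control = 20L,
                       eqtl_targets = NULL,
                       ct_shift = 1,
                       ct_sigma = 0.25,
                       ct_bio_sd = 0.5,
                       ct_replicates = 3L) {
  if (length(seed) != 1 || !is.finite(seed)) abort("`seed` must be a single finite integer")
  if (n_snps < 1) abort("`n_snps` must be positive")
  if (chrom_length_bp < 1) abort("`chrom_length_bp` must be positive")
  if (probes_per_gene < 1) abort("`probes_per_gene` must be >= 1")

  planted_loci <- if (is.null(planted_loci)) {
    tibble(center_bp = numeric(), peak = numeric())
  } else {
    as_tibble(planted_loci)
  }
  if (nrow(planted_loci) > 0) {
    check_columns(planted_loci, c("center_bp", "peak"), "`planted_loci`")
    half <- locus_span_bp / 2
    if (any(planted_loci$center_bp - half < 1 |
            planted_loci$center_bp + half > chrom_length_bp)) {
      abort("planted locus span extends beyond the chromosome")
    }
  }

  de_genes <- if (is.null(de_genes)) {
    tibble(gene = character(), effect_d = numeric(), n_datasets = integer())
  } else {
    as_tibble(de_genes)
  }
  if (nrow(de_genes) > 0) check_columns(de_genes, c("gene", "effect_d", "n_datasets"), "`de_genes`")

  eqtl_targets <- if (is.null(eqtl_targets)) {
    tibble(gene = character(), z = numeric())
  } else {
    as_tibble(eqtl_targets)
  }
  if (nrow(eqtl_targets) > 0) check_columns(eqtl_targets, c("gene", "z"), "`eqtl_targets`")

  structure(
    list(
      seed = as.integer(seed), chrom = chrom,
      chrom_length_bp = as.numeric(chrom_length_bp),
      n_snps = as.integer(n_snps),
      ld_cluster_size = as.integer(ld_cluster_size),
      locus_span_bp = as.numeric(locus_span_bp),
      planted_loci = planted_loci,
      n_genes = as.integer(n_genes),
      probes_per_gene = as.integer(probes_per_gene),
      de_genes = de_genes,
      n_case = as.integer(n_case), n_control = as.integer(n_control),
      eqtl_targets = eqtl_targets,
      ct_shift = ct_shift, ct_sigma = ct_sigma, ct_bio_sd = ct_bio_sd,
      ct_replicates = as.integer(ct_replicates)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %s, %.3g bp, %d background SNPs\n",
              x$seed, x$chrom, x$chrom_length_bp, x$n_snps))
  cat(sprintf("  planted loci: %d | DE genes: %d | eQTL targets: %d\n",
              nrow(x$planted_loci), nrow(x$de_genes), nrow(x$eqtl_targets)))
  cat(sprintf("  expression: %d genes x %d probes, %d/%d case/control\n",
              x$n_genes, x$probes_per_gene, x$n_case, x$n_control))
  cat(sprintf("  qPCR: shift %.2g cycles, sigma %.2g, bio sd %.2g, %d replicates\n",
              x$ct_shift, x$ct_sigma, x$ct_bio_sd, x$ct_replicates))
  invisible(x)
}

gene_universe <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))
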