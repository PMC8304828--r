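#' Two-sided p-value of a standard-normal Z-score
#'
#' Converts an eQTL Z-score to its two-sided tail probability,
#' `2 * P(N(0,1) > |z|)`, using R's complementary-error-function based
#' normal tail (`pnorm(lower.tail = FALSE)`), which stays accurate for
#' extreme scores (e.g. |z| > 10, p below 1e-20) where computing `1 - CDF`
#' by subtraction would underflow to 0.
#'
#' @param z Numeric vector of Z-scores.
#' @return Two-sided tail probabilities in (0, 1].
#' @examples
#' z_to_p(-10.92) # ~9.2e-28, the tail of a strong cis-eQTL
#' z_to_p(3.93)   # ~8.5e-05
#' @export
z_to_p <- function(z) {
  if (any(!is.finite(z))) abort("`z` must be finite")
  2 * pnorm(abs(z), lower.tail = FALSE)
}

#' Overlap associated SNPs with a cis-eQTL table
#'
#' Emits one hit per (SNP, gene) pair present both among the significant
#' GWAS SNPs and in the eQTL table, restricted to the supplied gene list
#' (typically genes of called loci). Each hit carries the SNP's GWAS
#' p-value and a direction label read off the Z-score sign: a negative Z
#' means the tested allele downregulates the gene, a positive Z upregulates
#' it.
#'
#' @param sig_snps Data frame of associated SNPs (`snp_id`, `p`); usually
#'   nominally significant SNPs inside called loci.
#' @param eqtl Data frame of eQTL records (`snp_id`, `gene`, `z`, `p_eqtl`).
#' @param genes Character vector of genes of interest.
#' @return A tibble of hits: `snp_id`, `gene`, `z`, `p_eqtl`, `p_gwas`,
#'   `direction_label` (`"upregulates"`, `"downregulates"` or `"neutral"`).
#' @export
eqtl_overlap <- function(sig_snps, eqtl, genes) {
  check_columns(sig_snps, c("snp_id", "p"), "`sig_snps`")
  check_columns(eqtl, c("snp_id", "gene", "z", "p_eqtl"), "`eqtl`")
  eqtl %>%
    as_tibble() %>%
    distinct(.data$snp_id, .data$gene, .keep_all = TRUE) %>%
    filter(.data$gene %in% genes) %>%
    inner_join(
      sig_snps %>% select("snp_id", p_gwas = "p") %>% distinct(),
      by = "snp_id"
    ) %>%
    mutate(direction_label = case_when(
      .data$z < 0 ~ "downregulates",
      .data$z > 0 ~ "upregulates",
      TRUE ~ "neutral"
    )) %>%
    select("snp_id", "gene", "z", "p_eqtl", "p_gwas", "direction_label")
}

#' Rank eQTL hits by genomic, then regulatory significance
#'
#' Orders hits by ascending GWAS p-value, then ascending eQTL p-value, then
#' SNP id. Both p-values are kept side by side so the classic tension -- a
#' SNP with an extremely strong eQTL but weak genomic association ranking
#' below a SNP significant in both -- stays visible in the output.
#'
#' @param hits Output of [eqtl_overlap()].
#' @return `hits` ordered with a `rank` column added.
#' @export
rank_hits <- function(hits) {
  check_columns(hits, c("snp_id", "p_eqtl", "p_gwas"), "`hits`")
  hits %>%
    arrange(.data$p_gwas, .data$p_eqtl, .data$snp_id) %>%
    mutate(rank = row_number())
}
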