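# Row-wise Welch t-test over a probe-by-sample matrix. Returns t, two-sided
# p (Welch-Satterthwaite df) and the sign of (mean case - mean control).
# Degenerate probes (zero variance in both groups, equal means) get t = 0,
# p = 1 rather than NaN.
welch_rows <- function(values, groups) {
  x <- values[, groups == "case", drop = FALSE]
  y <- values[, groups == "control", drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  t[degenerate & m1 == m2] <- 0
  p[degenerate & m1 == m2] <- 1
  list(t = t, p = p, direction = sign(m1 - m2))
}

#' Per-probe two-sample tests within one expression dataset
#'
#' Applies a Welch (unequal-variance) two-sided t-test to every probe,
#' comparing case against control samples, and records the direction of the
#' mean difference. Probes with zero variance and equal means in both groups
#' report `t = 0, p = 1`; missing values are an error naming the probe.
#'
#' @param ds An [expression_dataset()].
#' @return A tibble with one row per probe: `dataset_id`, `probe`, `gene`,
#'   `t`, `p`, `direction` (-1, 0 or +1, the sign of mean case minus mean
#'   control).
#' @examples
#' ds <- sim_expression(sim_config(seed = 1, n_genes = 20), n_datasets = 1)[[1]]
#' probe_tests(ds)
#' @export
probe_tests <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  na_probe <- rownames(ds$values)[!stats::complete.cases(ds$values)]
  if (length(na_probe) > 0) {
    abort(sprintf("missing values in probe(s): %s",
                  paste(head(na_probe, 5), collapse = ", ")))
  }
  res <- welch_rows(ds$values, ds$groups)
  tibble(
    dataset_id = ds$dataset_id,
    probe = rownames(ds$values),
    gene = ds$probe_gene$gene[match(rownames(ds$values), ds$probe_gene$probe)],
    t = unname(res$t),
    p = unname(res$p),
    direction = as.integer(unname(res$direction))
  )
}

#' Gene-level convergence across expression datasets
#'
#' A gene counts as significant in a dataset when at least one of its probes
#' has `p < alpha` there. It is *called* when it is significant in at least
#' `min_datasets` datasets, all its probes in those significant datasets
#' agree in direction (probes with a zero mean difference are neutral), and
#' it belongs to the reference gene list -- typically the genes of the
#' association loci, since intersecting independent evidence types is the
#' point of the convergence step. The gene-level summary p-value is the
#' minimum probe p over the gene's significant datasets.
#'
#' @param results Per-probe test results from [probe_tests()], from two or
#'   more datasets (rows bound together or a list of tibbles).
#' @param reference_genes Non-empty character vector restricting calls (e.g.
#'   genes mapped to called loci).
#' @param min_datasets Minimum number of datasets a called gene must be
#'   significant in.
#' @param alpha Per-probe significance threshold.
#' @return A tibble with one row per gene seen in `results`: `gene`,
#'   `n_datasets_significant`, `aligned`, `in_reference`, `called`, `gene_p`
#'   (NA when the gene is significant nowhere).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 100,
#'   de_genes = data.frame(gene = "G0007", effect_d = 1.5, n_datasets = 2))
#' res <- lapply(sim_expression(cfg, 3), probe_tests)
#' converge_genes(res, reference_genes = sprintf("G%04d", 1:100))
#' @export
converge_genes <- function(results, reference_genes, min_datasets = 2, alpha = 0.05) {
  if (is.list(results) && !is.data.frame(results)) results <- bind_rows(results)
  check_columns(results, c("dataset_id", "probe", "gene", "p", "direction"),
                "`results`")
  if (length(unique(results$dataset_id)) < 2) {
    abort("convergence needs probe results from >= 2 datasets")
  }
  if (missing(reference_genes) || length(reference_genes) == 0) {
    abort("`reference_genes` must be non-empty: convergence intersects expression evidence with a gene list")
  }

  per_ds <- results %>%
    group_by(.data$gene, .data$dataset_id) %>%
    summarise(sig = any(.data$p < alpha), .groups = "drop")

  sig_ds <- per_ds %>% filter(.data$sig)

  # direction over ALL probes of the gene in its significant datasets
  alignment <- results %>%
    semi_join(sig_ds, by = c("gene", "dataset_id")) %>%
    group_by(.data$gene) %>%
    summarise(
      aligned = length(unique(.data$direction[.data$direction != 0])) <= 1,
      gene_p = min(.data$p),
      .groups = "drop"
    )

  per_ds %>%
    group_by(.data$gene) %>%
    summarise(n_datasets_significant = sum(.data$sig), .groups = "drop") %>%
    left_join(alignment, by = "gene") %>%
    mutate(
      aligned = dplyr::coalesce(.data$aligned, TRUE),
      in_reference = .data$gene %in% reference_genes,
      called = .data$n_datasets_significant >= min_datasets &
        .data$aligned & .data$in_reference
    ) %>%
    select("gene", "n_datasets_significant", "aligned", "in_reference",
           "called", "gene_p") %>%
    arrange(.data$gene)
}

#' Multiple-testing gates for convergence calls
#'
#' Applies Benjamini-Hochberg step-up FDR control and the Bonferroni
#' correction over the gene-level p-values of the *called* genes, adding
#' `fdr_pass` and `bonferroni_pass` flags. Bonferroni passing always implies
#' FDR passing. Genes that were not called keep `FALSE` flags.
#'
#' @param calls Output of [converge_genes()].
#' @param alpha Family-wise / FDR level.
#' @return `calls` with `fdr_pass` and `bonferroni_pass` columns added.
#' @export
adjust_convergence <- function(calls, alpha = 0.05) {
  check_columns(calls, c("gene", "called", "gene_p"), "`calls`")
  called <- calls$called & !is.na(calls$gene_p)
  fdr <- bonf <- rep(FALSE, nrow(calls))
  if (any(called)) {
    p <- calls$gene_p[called]
    fdr[called] <- p.adjust(p, method = "BH") <= alpha
    bonf[called] <- p.adjust(p, method = "bonferroni") <= alpha
  }
  calls %>% mutate(fdr_pass = fdr, bonferroni_pass = bonf)
}
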