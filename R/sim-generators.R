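#' Simulate a GWAS summary-statistic table
#'
#' Background SNPs receive independent Uniform(0,1) p-values at uniformly
#' random positions. Each planted locus contributes `ld_cluster_size`
#' additional SNPs inside its span whose -log10 p-values are drawn at the
#' configured peak level plus Normal(0, 0.5) jitter, floored at 1.3
#' (p = 0.05). This emulates an LD cluster of co-significant variants around
#' an association peak without simulating genotypes.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `p`, sorted by
#'   position; `snp_id` is unique.
#' @examples
#' gwas <- sim_gwas(sim_config(seed = 1, n_snps = 1000))
#' head(gwas)
#' @export
sim_gwas <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  loci <- cfg$planted_loci
  if (nrow(loci) > 1) {
    half <- cfg$locus_span_bp / 2
    lo <- loci$center_bp - half
    hi <- loci$center_bp + half
    ord <- order(lo)
    overlap <- which(lo[ord][-1] <= hi[ord][-nrow(loci)])
    if (length(overlap) > 0) {
      i <- ord[overlap[1]]; j <- ord[overlap[1] + 1]
      abort(sprintf(
        "planted loci at %.0f bp and %.0f bp have overlapping spans",
        loci$center_bp[i], loci$center_bp[j]
      ))
    }
  }

  set.seed(split_seed(cfg$seed, 11L))
  pos <- ceiling(runif(cfg$n_snps, 0, cfg$chrom_length_bp))
  p <- runif(cfg$n_snps)

  if (nrow(loci) > 0) {
    half <- cfg$locus_span_bp / 2
    for (i in seq_len(nrow(loci))) {
      lpos <- ceiling(runif(
        cfg$ld_cluster_size,
        loci$center_bp[i] - half, loci$center_bp[i] + half
      ))
      nlp <- pmax(loci$peak[i] + rnorm(cfg$ld_cluster_size, 0, 0.5), 1.3)
      pos <- c(pos, lpos)
      p <- c(p, 10^(-nlp))
    }
  }

  ord <- order(pos)
  tibble(
    snp_id = sprintf("rs%06d", seq_along(pos)),
    chrom = cfg$chrom,
    pos = as.integer(pos[ord]),
    p = p[ord]
  )
}

#' Simulate a gene-annotation interval table
#'
#' Genes `G0001`..`G<n_genes>` are laid out along the chromosome at regular
#' intervals with a fixed 20 kb body, alternating strand. Symbols match the
#' gene universe used by [sim_expression()] and [sim_eqtl()], so loci called
#' on the simulated GWAS map onto the same genes the expression stage tests.
#'
#' @param cfg A [sim_config()].
#' @param gene_length_bp Gene body length in bp.
#' @return A tibble with columns `symbol`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates).
#' @export
sim_annotation <- function(cfg, gene_length_bp = 20000) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  starts <- round(seq_len(n) * cfg$chrom_length_bp / (n + 1))
  ends <- pmin(starts + gene_length_bp - 1, cfg$chrom_length_bp)
  tibble(
    symbol = gene_universe(cfg),
    chrom = cfg$chrom,
    start = as.integer(starts),
    end = as.integer(ends),
    strand = rep_len(c("+", "-"), n)
  )
}

#' Simulate multi-dataset probe-level expression data
#'
#' Each dataset holds a probe-by-sample matrix of Normal(0,1) values, a
#' case/control label per sample and a probe-to-gene map with
#' `probes_per_gene` probes per gene. For every differentially expressed gene
#' in `cfg$de_genes`, all its probes in the first `n_datasets` affected
#' datasets have the case-group mean shifted by `effect_d` -- the same sign
#' across probes and datasets, so planted genes are directionally aligned by
#' construction.
#'
#' @param cfg A [sim_config()].
#' @param n_datasets Number of independent expression datasets to generate.
#' @return A list of `expression_dataset` objects (see [expression_dataset()]).
#' @examples
#' ds <- sim_expression(sim_config(seed = 1, n_genes = 50), n_datasets = 2)
#' ds[[1]]
#' @export
sim_expression <- function(cfg, n_datasets = 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- gene_universe(cfg)
  de <- cfg$de_genes
  if (nrow(de) > 0) {
    unknown <- setdiff(de$gene, genes)
    if (length(unknown) > 0) {
      abort(sprintf(
        "de_genes not in the simulated gene universe: %s",
        paste(head(unknown, 5), collapse = ", ")
      ))
    }
  }

  probe_gene <- tibble(
    probe = sprintf("%s_p%d",
                    rep(genes, each = cfg$probes_per_gene),
                    rep(seq_len(cfg$probes_per_gene), times = cfg$n_genes)),
    gene = rep(genes, each = cfg$probes_per_gene)
  )
  n_samp <- cfg$n_case + cfg$n_control
  groups <- c(rep("case", cfg$n_case), rep("control", cfg$n_control))

  purrr::map(seq_len(n_datasets), function(d) {
    set.seed(split_seed(cfg$seed, 100L + d))
    values <- matrix(
      rnorm(nrow(probe_gene) * n_samp),
      nrow = nrow(probe_gene),
      dimnames = list(probe_gene$probe, sprintf("ds%d_s%02d", d, seq_len(n_samp)))
    )
    if (nrow(de) > 0) {
      affected <- de[de$n_datasets >= d, , drop = FALSE]
      if (nrow(affected) > 0) {
        rows <- probe_gene$gene %in% affected$gene
        shift <- affected$effect_d[match(probe_gene$gene[rows], affected$gene)]
        values[rows, groups == "case"] <-
          values[rows, groups == "case"] + shift
      }
    }
    expression_dataset(sprintf("ds%d", d), values, groups, probe_gene)
  })
}

#' Simulate a cis-eQTL summary table
#'
#' Background rows pair randomly chosen SNPs and genes with Z ~ Normal(0,1).
#' For each configured eQTL target gene, the most significant available SNPs
#' (lowest GWAS p) are paired with that gene at the stated Z-score, emulating
#' a strong cis-eQTL at an association peak. Every row's p-value equals the
#' two-sided standard-normal tail of its Z by construction.
#'
#' @param snps A GWAS table as returned by [sim_gwas()] (columns `snp_id`, `p`).
#' @param genes Character vector of gene symbols to draw background pairs from.
#' @param cfg A [sim_config()]; `cfg$eqtl_targets` defines planted eQTLs.
#' @param n_background Number of background SNP-gene rows.
#' @param snps_per_target Planted SNPs paired with each target gene.
#' @return A tibble with columns `snp_id`, `gene`, `z`, `p_eqtl`, `cis`.
#' @export
sim_eqtl <- function(snps, genes, cfg, n_background = 500L, snps_per_target = 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(snps) == 0 || length(genes) == 0) abort("`snps` and `genes` must be non-empty")
  check_columns(snps, c("snp_id", "p"), "`snps`")

  set.seed(split_seed(cfg$seed, 300L))
  bg <- tibble(
    snp_id = sample(snps$snp_id, n_background, replace = TRUE),
    gene = sample(genes, n_background, replace = TRUE),
    z = rnorm(n_background)
  )

  targets <- cfg$eqtl_targets
  planted <- if (nrow(targets) > 0) {
    top <- snps$snp_id[order(snps$p)]
    purrr::map_dfr(seq_len(nrow(targets)), function(i) {
      take <- top[seq_len(min(snps_per_target, length(top)))]
      tibble(
        snp_id = take,
        gene = targets$gene[i],
        z = targets$z[i] + rnorm(length(take), 0, 0.2)
      )
    })
  } else {
    tibble(snp_id = character(), gene = character(), z = numeric())
  }

  bind_rows(planted, bg) %>%
    distinct(.data$snp_id, .data$gene, .keep_all = TRUE) %>%
    mutate(p_eqtl = z_to_p(.data$z), cis = TRUE) %>%
    arrange(.data$snp_id, .data$gene)
}

#' Simulate a qPCR Ct table
#'
#' Housekeeping genes share one mean Ct (18 cycles) in both groups. Target
#' genes sit at 25 cycles in controls; case samples are shifted by
#' `-ct_shift` cycles (lower Ct means higher expression, one cycle per
#' doubling). Every sample additionally carries a global offset
#' (Normal(0, 0.5) cycles, applied to all its genes) emulating input-amount
#' variation that the housekeeping normalisation must remove, and target
#' genes a per-sample biological deviation of SD `ct_bio_sd`. Technical
#' replicates add Normal(0, `ct_sigma`) noise.
#'
#' @param cfg A [sim_config()].
#' @param targets Character vector of target gene names.
#' @param housekeeping Character vector of housekeeping gene names (non-empty).
#' @return A tibble with columns `sample_id`, `group`, `gene`, `replicate`,
#'   `ct`.
#' @examples
#' ct <- sim_ct(sim_config(seed = 1), targets = "DDX11")
#' head(ct)
#' @export
sim_ct <- function(cfg, targets = "TARGET1", housekeeping = c("GAPDH", "ACTB")) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(housekeeping) == 0) abort("`housekeeping` must be non-empty")

  set.seed(split_seed(cfg$seed, 400L))
  samples <- tibble(
    sample_id = c(sprintf("case%02d", seq_len(cfg$n_case)),
                  sprintf("ctrl%02d", seq_len(cfg$n_control))),
    group = c(rep("case", cfg$n_case), rep("control", cfg$n_control)),
    offset = rnorm(cfg$n_case + cfg$n_control, 0, 0.5)
  )

  grid <- tidyr::expand_grid(
    samples,
    gene = c(targets, housekeeping),
    replicate = seq_len(cfg$ct_replicates)
  )
  is_target <- grid$gene %in% targets
  base <- ifelse(is_target, 25, 18)
  shift <- ifelse(is_target & grid$group == "case", -cfg$ct_shift, 0)

  # biological deviation: one draw per (sample, target gene), shared across
  # replicates
  bio_key <- paste(grid$sample_id, grid$gene)
  uniq <- unique(bio_key[is_target])
  bio_draw <- setNames(rnorm(length(uniq), 0, cfg$ct_bio_sd), uniq)
  bio <- ifelse(is_target, bio_draw[bio_key], 0)

  grid %>%
    mutate(
      ct = base + shift + .data$offset + bio +
        rnorm(nrow(grid), 0, cfg$ct_sigma)
    ) %>%
    select("sample_id", "group", "gene", "replicate", "ct")
}
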