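#' Simulate an interaction-score edge table
#'
#' Draws random undirected gene pairs and assigns each a coexpression and an
#' experimental channel score from distributions concentrated at low
#' confidence (most database edges are weak); the combined score is the
#' maximum of the two. Genes listed in `hub_genes` are additionally wired to
#' a random selection of partners at scores above the usual 0.15 retention
#' threshold, giving the graph the hub-and-spoke look of disease-gene
#' neighbourhoods.
#'
#' @param cfg A [sim_config()].
#' @param genes Character vector of gene symbols to wire.
#' @param n_edges Number of background edges drawn.
#' @param hub_genes Genes guaranteed well-connected edges.
#' @return A tibble `gene_a gene_b coexpression experimental combined`.
#' @export
sim_edges <- function(cfg, genes, n_edges = 400L, hub_genes = character()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(genes) < 2) abort("need >= 2 genes")
  set.seed(split_seed(cfg$seed, 500L))

  a <- sample(genes, n_edges, replace = TRUE)
  b <- sample(genes, n_edges, replace = TRUE)
  keep <- a != b
  bg <- tibble(
    gene_a = pmin(a[keep], b[keep]),
    gene_b = pmax(a[keep], b[keep]),
    coexpression = round(stats::rbeta(sum(keep), 1, 6), 3),
    experimental = round(stats::rbeta(sum(keep), 1, 8), 3)
  )

  hub <- purrr::map_dfr(intersect(hub_genes, genes), function(g) {
    partners <- sample(setdiff(genes, g), min(4, length(genes) - 1))
    tibble(
      gene_a = pmin(g, partners),
      gene_b = pmax(g, partners),
      coexpression = round(runif(length(partners), 0.2, 0.6), 3),
      experimental = round(runif(length(partners), 0.1, 0.5), 3)
    )
  })

  bind_rows(hub, bg) %>%
    distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) %>%
    mutate(combined = pmax(.data$coexpression, .data$experimental)) %>%
    arrange(.data$gene_a, .data$gene_b)
}

#' Write a complete synthetic input bundle
#'
#' Generates every input table the pipeline consumes -- GWAS summary
#' statistics, gene annotation, expression datasets (matrix + sample
#' annotation + probe map each), a cis-eQTL table, a qPCR Ct table and an
#' interaction edge table -- and writes them as TSVs into `dir` using the
#' same dialects the readers expect.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param n_datasets Number of expression datasets.
#' @return Invisibly, a named list of the written file paths.
#' @export
sim_bundle <- function(cfg, dir, n_datasets = 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)

  gwas <- sim_gwas(cfg)
  ann <- sim_annotation(cfg)
  genes <- gene_universe(cfg)
  datasets <- sim_expression(cfg, n_datasets)
  eqtl <- sim_eqtl(gwas, genes, cfg)
  ct <- sim_ct(cfg)
  edges <- sim_edges(cfg, genes, hub_genes = cfg$de_genes$gene)

  readr::write_tsv(gwas, path("gwas.tsv"))
  readr::write_tsv(ann, path("annotation.tsv"))
  readr::write_tsv(eqtl, path("eqtl.tsv"))
  readr::write_tsv(ct %>% rename(sample = "sample_id"), path("ct.tsv"))
  readr::write_tsv(edges, path("edges.tsv"))

  expr_paths <- purrr::map(datasets, function(ds) {
    base <- sprintf("expr_%s", ds$dataset_id)
    readr::write_tsv(
      as_tibble(ds$values, rownames = "probe"),
      path(sprintf("%s_matrix.tsv", base))
    )
    readr::write_tsv(
      tibble(sample = colnames(ds$values), group = ds$groups),
      path(sprintf("%s_samples.tsv", base))
    )
    readr::write_tsv(ds$probe_gene, path(sprintf("%s_probe_map.tsv", base)))
    list(
      matrix = path(sprintf("%s_matrix.tsv", base)),
      samples = path(sprintf("%s_samples.tsv", base)),
      probe_map = path(sprintf("%s_probe_map.tsv", base))
    )
  })

  invisible(list(
    gwas = path("gwas.tsv"), annotation = path("annotation.tsv"),
    eqtl = path("eqtl.tsv"), ct = path("ct.tsv"), edges = path("edges.tsv"),
    expression = expr_paths
  ))
}
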