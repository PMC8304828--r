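#' Pipeline configuration
#'
#' Collects inputs and stage parameters for [run_pipeline()]. Inputs come
#' either from files (paths to the TSV dialects the `read_*` functions
#' accept) or from the synthetic generator (a [sim_config()] in `simulate`),
#' but not both per table: a simulate block fills in every table that has no
#' file path.
#'
#' @param score_threshold Composite-score threshold for calling loci
#'   (required; see [merge_loci()]).
#' @param simulate Optional [sim_config()] used to generate any missing
#'   input.
#' @param gwas,annotation,eqtl,edges Optional file paths.
#' @param expression Optional list of per-dataset path lists, each with
#'   elements `matrix`, `samples`, `probe_map`.
#' @param window_bp,alpha,weight Window scan parameters ([scan_windows()]).
#' @param merge_gap_bp Locus merge gap ([merge_loci()]); default one window.
#' @param gwas_alpha Nominal GWAS threshold selecting SNPs for the eQTL
#'   overlap.
#' @param min_datasets Convergence requirement ([converge_genes()]).
#' @param min_score,channels Network edge filter ([filter_edges()]).
#' @param k Number of network clusters.
#' @param n_datasets Expression datasets to simulate when `simulate` is
#'   given.
#' @param seed Master seed recorded in every output; defaults to the
#'   simulate block's seed when present.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(score_threshold,
                            simulate = NULL,
                            gwas = NULL, annotation = NULL,
                            expression = NULL, eqtl = NULL, edges = NULL,
                            window_bp = 20000, alpha = 0.05, weight = 1,
                            merge_gap_bp = NULL, gwas_alpha = 0.05,
                            min_datasets = 2,
                            min_score = 0.15,
                            channels = c("coexpression", "experimental"),
                            k = 3, n_datasets = 3,
                            seed = NULL) {
  if (missing(score_threshold)) abort("`score_threshold` is required")
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    abort("`simulate` must be a sim_config")
  }
  paths <- list(gwas = gwas, annotation = annotation, eqtl = eqtl, edges = edges)
  if (is.null(simulate)) {
    missing_tbl <- names(paths)[vapply(paths, is.null, logical(1))]
    if (is.null(expression)) missing_tbl <- c(missing_tbl, "expression")
    if (length(missing_tbl) > 0) {
      abort(sprintf(
        "no simulate block and no file path for input(s): %s",
        paste(missing_tbl, collapse = ", ")
      ))
    }
    for (p in c(unlist(paths), unlist(expression))) {
      if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
    }
  }
  structure(
    list(
      simulate = simulate, gwas = gwas, annotation = annotation,
      expression = expression, eqtl = eqtl, edges = edges,
      window_bp = window_bp, alpha = alpha, weight = weight,
      score_threshold = score_threshold, merge_gap_bp = merge_gap_bp,
      gwas_alpha = gwas_alpha, min_datasets = min_datasets,
      min_score = min_score, channels = channels, k = k,
      n_datasets = n_datasets,
      seed = seed %||% (if (!is.null(simulate)) simulate$seed else 1L)
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the genomic-convergence pipeline end to end
#'
#' Sequences the stages: window scan and locus merging on the GWAS table;
#' gene mapping of called loci; per-probe tests and gene-level convergence
#' across the expression datasets (restricted to locus genes) with
#' FDR/Bonferroni gates; eQTL overlap of nominally significant locus SNPs;
#' interaction-network filtering and spectral k-means clustering. The final
#' report ranks locus genes lexicographically on (called, FDR pass, has an
#' eQTL, ascending gene-level p) -- a convergence-evidence ordering declared
#' in the report metadata.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, all intermediates
#'   (windows, loci, probe tests, convergence calls, eQTL hits, clusters),
#'   the report (TSV and JSON) and a run log (versions, seed, parameters)
#'   are written there.
#' @return A list of class `pipeline_result` with elements `report` (the
#'   ranked candidate tibble), `windows`, `loci`, `locus_genes`,
#'   `convergence`, `eqtl_hits`, `clusters` and `params`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 60, n_snps = 2000,
#'   planted_loci = data.frame(center_bp = 5.5e6, peak = 7),
#'   de_genes = data.frame(gene = "G0030", effect_d = 1.5, n_datasets = 2),
#'   eqtl_targets = data.frame(gene = "G0030", z = -6))
#' res <- run_pipeline(pipeline_config(score_threshold = 10, simulate = cfg))
#' head(res$report)
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))

  inputs <- run_stage("load_inputs", {
    sim <- cfg$simulate
    gwas <- if (!is.null(cfg$gwas)) read_gwas(cfg$gwas) else sim_gwas(sim)
    ann <- if (!is.null(cfg$annotation)) read_annotation(cfg$annotation) else sim_annotation(sim)
    datasets <- if (!is.null(cfg$expression)) {
      purrr::imap(cfg$expression, function(p, i) {
        read_expression(p$matrix, p$samples, p$probe_map,
                        dataset_id = sprintf("ds%s", i))
      })
    } else {
      sim_expression(sim, cfg$n_datasets)
    }
    eqtl <- if (!is.null(cfg$eqtl)) read_eqtl(cfg$eqtl) else {
      sim_eqtl(gwas, unique(ann$symbol), sim)
    }
    edges <- if (!is.null(cfg$edges)) read_edges(cfg$edges) else {
      sim_edges(sim, unique(ann$symbol), hub_genes = sim$de_genes$gene)
    }
    list(gwas = gwas, ann = ann, datasets = datasets, eqtl = eqtl, edges = edges)
  })

  windows <- run_stage("gwas_scoring", {
    scan_windows(inputs$gwas, cfg$window_bp, cfg$alpha, cfg$weight)
  })
  loci <- run_stage("gwas_scoring", {
    merge_loci(windows, cfg$score_threshold, cfg$merge_gap_bp)
  })

  locus_genes <- run_stage("locus_genes", {
    if (nrow(loci) == 0) {
      tibble(locus = integer(), gene = character())
    } else {
      purrr::map_dfr(seq_len(nrow(loci)), function(i) {
        g <- genes_in_region(inputs$ann, loci$chrom[i], loci$start[i], loci$end[i])
        if (nrow(g) == 0) {
          # locus falls between gene bodies: take the nearest gene
          g <- nearest_genes(inputs$ann, loci$chrom[i],
                             (loci$start[i] + loci$end[i]) / 2, k = 1)
        }
        tibble(locus = i, gene = g$symbol)
      })
    }
  })

  convergence <- run_stage("expression_convergence", {
    if (nrow(locus_genes) == 0) {
      abort("no locus genes: no called locus overlaps the annotation")
    }
    purrr::map(inputs$datasets, probe_tests) %>%
      converge_genes(reference_genes = unique(locus_genes$gene),
                     min_datasets = cfg$min_datasets, alpha = cfg$alpha) %>%
      adjust_convergence(alpha = cfg$alpha)
  })

  eqtl_hits <- run_stage("eqtl_overlap", {
    sig <- inputs$gwas %>% filter(.data$p < cfg$gwas_alpha)
    in_locus <- vapply(seq_len(nrow(sig)), function(i) {
      any(loci$chrom == sig$chrom[i] &
            loci$start <= sig$pos[i] & loci$end > sig$pos[i])
    }, logical(1))
    eqtl_overlap(sig[in_locus, ], inputs$eqtl, unique(locus_genes$gene)) %>%
      rank_hits()
  })

  clusters <- run_stage("network_analysis", {
    called <- convergence$gene[convergence$called]
    graph <- filter_edges(inputs$edges, cfg$min_score, cfg$channels,
                          seed_genes = called)
    if (length(graph$nodes) == 0) {
      tibble(gene = character(), cluster = integer())
    } else {
      cluster_kmeans(graph, k = min(cfg$k, length(graph$nodes)), seed = cfg$seed)
    }
  })

  report <- run_stage("report", {
    best_eqtl <- eqtl_hits %>%
      group_by(.data$gene) %>%
      slice(1) %>%
      ungroup() %>%
      select("gene", eqtl_snp = "snp_id", eqtl_z = "z",
             eqtl_p = "p_eqtl", eqtl_gwas_p = "p_gwas")
    locus_genes %>%
      distinct(.data$gene, .keep_all = TRUE) %>%
      left_join(convergence, by = "gene") %>%
      left_join(best_eqtl, by = "gene") %>%
      left_join(clusters, by = "gene") %>%
      mutate(
        has_eqtl = !is.na(.data$eqtl_snp),
        called = dplyr::coalesce(.data$called, FALSE),
        fdr_pass = dplyr::coalesce(.data$fdr_pass, FALSE),
        bonferroni_pass = dplyr::coalesce(.data$bonferroni_pass, FALSE)
      ) %>%
      arrange(desc(.data$called), desc(.data$fdr_pass), desc(.data$has_eqtl),
              .data$gene_p, .data$gene) %>%
      mutate(rank = row_number()) %>%
      select("rank", "gene", "locus", "n_datasets_significant", "aligned",
             "called", "gene_p", "fdr_pass", "bonferroni_pass", "has_eqtl",
             "eqtl_snp", "eqtl_z", "eqtl_p", "eqtl_gwas_p", "cluster")
  })

  params <- cfg[setdiff(names(cfg), c("simulate", "gwas", "annotation",
                                      "expression", "eqtl", "edges"))]
  result <- structure(
    list(report = report, windows = windows, loci = loci,
         locus_genes = locus_genes, convergence = convergence,
         eqtl_hits = eqtl_hits, clusters = clusters,
         params = c(params, list(
           ranking = "lexicographic: called desc, fdr_pass desc, has_eqtl desc, gene_p asc",
           gene_p_rule = "minimum probe p over significant datasets",
           clustering = "k-means on spectral embedding of the filtered interaction graph"
         ))),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) {
    run_stage("write_outputs", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_tsv(windows, file.path(out_dir, "windows.tsv"))
      readr::write_tsv(loci, file.path(out_dir, "loci.tsv"))
      readr::write_tsv(locus_genes, file.path(out_dir, "locus_genes.tsv"))
      readr::write_tsv(convergence, file.path(out_dir, "convergence.tsv"))
      readr::write_tsv(eqtl_hits, file.path(out_dir, "eqtl_hits.tsv"))
      readr::write_tsv(clusters, file.path(out_dir, "clusters.tsv"))
      readr::write_tsv(report, file.path(out_dir, "report.tsv"))
      jsonlite::write_json(
        list(params = result$params, report = report),
        file.path(out_dir, "report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      writeLines(c(
        sprintf("convergene %s", as.character(utils::packageVersion("convergene"))),
        sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
        sprintf("seed %d", cfg$seed),
        sprintf("parameters: %s", jsonlite::toJSON(params, auto_unbox = TRUE))
      ), file.path(out_dir, "run_log.txt"))
    })
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d loci, %d locus genes, %d called, %d FDR, %d Bonferroni, %d eQTL hits\n",
    nrow(x$loci), nrow(x$locus_genes), sum(x$report$called),
    sum(x$report$fdr_pass), sum(x$report$bonferroni_pass), nrow(x$eqtl_hits)
  ))
  cat("Top candidates:\n")
  print(head(x$report, 5))
  invisible(x)
}
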