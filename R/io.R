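# TSV readers for the pipeline's input dialects. All return tibbles with the
# canonical column names the analysis functions expect.

#' Read a GWAS summary-statistic table
#'
#' @param path TSV with header `snp_id chrom pos p`.
#' @return Tibble with those columns; p-values validated to lie in (0, 1].
#' @export
read_gwas <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(x, c("snp_id", "chrom", "pos", "p"), "GWAS table")
  check_p_column(x$p)
  x
}

#' Read a gene-annotation table
#'
#' The native format is a TSV `symbol chrom start end strand` with 1-based
#' inclusive coordinates (NCBI convention). With `bed = TRUE` a headerless
#' BED4 file (`chrom start end name`, 0-based half-open) is accepted and
#' converted: start becomes `start + 1`, end stays (half-open end equals the
#' inclusive last base).
#'
#' @param path Annotation file.
#' @param bed Interpret `path` as BED4 instead of the native TSV.
#' @return Tibble `symbol chrom start end strand`.
#' @export
read_annotation <- function(path, bed = FALSE) {
  if (bed) {
    x <- readr::read_tsv(path,
      col_names = c("chrom", "start", "end", "symbol"),
      show_col_types = FALSE
    )
    return(tibble(
      symbol = x$symbol, chrom = x$chrom,
      start = x$start + 1L, end = x$end, strand = "unknown"
    ))
  }
  x <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(x, c("symbol", "chrom", "start", "end"), "annotation table")
  if (!"strand" %in% names(x)) x$strand <- "unknown"
  x
}

#' Read an expression dataset from its three component files
#'
#' @param matrix_path TSV with a `probe` column then one column per sample.
#' @param samples_path TSV `sample group` (groups `case`/`control`).
#' @param probe_map_path TSV `probe gene`.
#' @param dataset_id Identifier for the dataset; defaults to the matrix file
#'   name.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, samples_path, probe_map_path,
                            dataset_id = NULL) {
  mat <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  check_columns(mat, "probe", "expression matrix")
  values <- as.matrix(mat[setdiff(names(mat), "probe")])
  rownames(values) <- mat$probe

  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  check_columns(samples, c("sample", "group"), "sample annotation")
  groups <- samples$group[match(colnames(values), samples$sample)]
  if (anyNA(groups)) abort("sample annotation does not cover all matrix columns")

  probe_map <- readr::read_tsv(probe_map_path, show_col_types = FALSE)
  check_columns(probe_map, c("probe", "gene"), "probe map")

  expression_dataset(
    dataset_id %||% sub("\\.tsv$", "", basename(matrix_path)),
    values, groups, probe_map
  )
}

#' Read a cis-eQTL table
#'
#' @param path TSV `snp_id gene z p cis` (the `p` column is renamed
#'   `p_eqtl`; `cis` optional).
#' @return Tibble `snp_id gene z p_eqtl cis`.
#' @export
read_eqtl <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if ("p" %in% names(x) && !"p_eqtl" %in% names(x)) x <- rename(x, p_eqtl = "p")
  check_columns(x, c("snp_id", "gene", "z", "p_eqtl"), "eQTL table")
  if (!"cis" %in% names(x)) x$cis <- TRUE
  x
}

#' Read a qPCR Ct table
#'
#' @param path TSV `sample group gene replicate ct` (or `sample_id` for the
#'   first column).
#' @return Tibble `sample_id group gene replicate ct`.
#' @export
read_ct <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if ("sample" %in% names(x) && !"sample_id" %in% names(x)) {
    x <- rename(x, sample_id = "sample")
  }
  check_columns(x, c("sample_id", "group", "gene", "ct"), "Ct table")
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  x
}
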