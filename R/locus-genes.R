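#' Genes overlapping a genomic region
#'
#' Returns every gene whose 1-based inclusive interval overlaps the query
#' region by at least one bp, sorted by start coordinate. A chromosome
#' absent from the annotation yields an empty result, not an error, so the
#' function can be mapped over loci from mixed chromosomes.
#'
#' @param ann Annotation data frame with columns `symbol`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param chrom Query chromosome.
#' @param start,end Query interval bounds (1-based inclusive, `end >= start`).
#' @return The matching annotation rows as a tibble, sorted by `start`.
#' @examples
#' ann <- sim_annotation(sim_config(seed = 1, n_genes = 100))
#' genes_in_region(ann, "chr12", 1e6, 2e6)
#' @export
genes_in_region <- function(ann, chrom, start, end) {
  check_columns(ann, c("symbol", "chrom", "start", "end"), "`ann`")
  if (end < start) abort("`end` must be >= `start`")
  ann %>%
    as_tibble() %>%
    filter(.data$chrom == !!chrom, .data$start <= !!end, .data$end >= !!start) %>%
    arrange(.data$start)
}

#' Nearest genes to a genomic position
#'
#' Distance is 0 for positions inside a gene body and otherwise the bp gap to
#' the nearest gene boundary; strand is ignored. Ties are broken by symbol
#' order. At most `min(k, genes on the chromosome)` genes are returned.
#'
#' @param ann Annotation data frame (`symbol`, `chrom`, `start`, `end`).
#' @param chrom Chromosome of the query position.
#' @param pos Query position (1-based bp).
#' @param k Number of genes to return.
#' @return A tibble of the `k` nearest annotation rows with an added
#'   `distance` column, ordered by distance.
#' @export
nearest_genes <- function(ann, chrom, pos, k = 1) {
  check_columns(ann, c("symbol", "chrom", "start", "end"), "`ann`")
  if (k < 1) abort("`k` must be >= 1")
  ann %>%
    as_tibble() %>%
    filter(.data$chrom == !!chrom) %>%
    mutate(distance = pmax(.data$start - pos, pos - .data$end, 0)) %>%
    arrange(.data$distance, .data$symbol) %>%
    head(k)
}
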