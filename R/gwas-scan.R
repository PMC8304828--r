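#' Composite window score for GWAS summary statistics
#'
#' Combines the two facets of a linkage-disequilibrium association signal --
#' the strength of the best association in a window and the number of
#' surrounding significant SNPs -- into one score:
#' `score = -log10(min_p) + weight * n_sig`, defined as 0 when the window
#' holds no significant SNP. The score is strictly increasing in both
#' components.
#'
#' @param min_p Minimum SNP p-value in the window (vectorised).
#' @param n_sig Count of SNPs with p below the significance threshold.
#' @param weight Weight on the significant-SNP count relative to the
#'   -log10 p term.
#' @return Numeric score vector.
#' @examples
#' composite_score(1e-6, 2) # 8
#' @export
composite_score <- function(min_p, n_sig, weight = 1) {
  ifelse(n_sig == 0, 0, -log10(min_p) + weight * n_sig)
}

#' Scan GWAS summary statistics in fixed tiling windows
#'
#' Tiles each chromosome with non-overlapping windows of `window_bp`,
#' anchored at position 1 (windows are half-open `[start, end)`), assigns
#' every SNP to exactly one window, and scores each non-empty window with
#' [composite_score()]. The result is independent of the input row order.
#'
#' @param assocs Data frame of SNP associations with columns `snp_id`,
#'   `chrom`, `pos` (1-based bp), `p`.
#' @param window_bp Window width in bp (default 20 kb).
#' @param alpha Per-SNP significance threshold used for the `n_sig` count.
#' @param weight Passed to [composite_score()].
#' @return A tibble with one row per non-empty window: `chrom`, `start`,
#'   `end`, `n_snps`, `n_sig`, `min_p`, `top_snp`, `top_pos`, `score`,
#'   ordered by chromosome and start. `top_snp` is the SNP achieving `min_p`
#'   (ties broken by lower position, then `snp_id`).
#' @examples
#' gwas <- sim_gwas(sim_config(seed = 1, n_snps = 2000))
#' scan_windows(gwas)
#' @export
scan_windows <- function(assocs, window_bp = 20000, alpha = 0.05, weight = 1) {
  check_columns(assocs, c("snp_id", "chrom", "pos", "p"), "`assocs`")
  if (nrow(assocs) == 0) abort("`assocs` must be non-empty")
  if (window_bp <= 0) abort("`window_bp` must be positive")
  check_p_column(assocs$p)
  if (any(assocs$pos < 1)) abort("positions must be >= 1 (1-based)")

  assocs %>%
    mutate(.win = floor((.data$pos - 1) / window_bp)) %>%
    # deterministic top-SNP tie-break: smallest p, then pos, then snp_id
    arrange(.data$p, .data$pos, .data$snp_id) %>%
    group_by(.data$chrom, .data$.win) %>%
    summarise(
      n_snps = dplyr::n(),
      n_sig = sum(.data$p < alpha),
      min_p = .data$p[1],
      top_snp = .data$snp_id[1],
      top_pos = .data$pos[1],
      .groups = "drop"
    ) %>%
    mutate(
      start = .data$.win * window_bp + 1,
      end = .data$start + window_bp,
      score = composite_score(.data$min_p, .data$n_sig, weight)
    ) %>%
    select("chrom", "start", "end", "n_snps", "n_sig", "min_p",
           "top_snp", "top_pos", "score") %>%
    arrange(.data$chrom, .data$start)
}

#' Merge flagged windows into association loci
#'
#' Windows with `score >= score_threshold` on the same chromosome are merged
#' into one locus when separated by at most `max_gap_bp` (gap measured
#' between the end of one window and the start of the next). Each locus
#' reports its best-scoring member window and its index SNP, the SNP with
#' the globally smallest p-value in the locus.
#'
#' @param windows Output of [scan_windows()].
#' @param score_threshold Minimum composite score for a window to seed or
#'   join a locus. No universal default exists; choose it for the study
#'   (e.g. via the score of a reference configuration such as
#'   `composite_score(1e-4, 5)`).
#' @param max_gap_bp Maximum gap between flagged windows that still merges
#'   them; defaults to one window width.
#' @return A tibble with one row per locus: `chrom`, `start`, `end`,
#'   `n_windows`, `best_score`, `best_window_start`, `index_snp`,
#'   `index_pos`, `min_p`.
#' @examples
#' gwas <- sim_gwas(sim_config(seed = 1))
#' w <- scan_windows(gwas)
#' merge_loci(w, score_threshold = composite_score(1e-4, 5))
#' @export
merge_loci <- function(windows, score_threshold, max_gap_bp = NULL) {
  check_columns(windows, c("chrom", "start", "end", "n_sig", "min_p",
                           "top_snp", "top_pos", "score"), "`windows`")
  if (missing(score_threshold)) abort("`score_threshold` is required")
  if (is.null(max_gap_bp)) {
    max_gap_bp <- if (nrow(windows) > 0) windows$end[1] - windows$start[1] else 0
  }

  flagged <- windows %>%
    filter(.data$score >= score_threshold) %>%
    arrange(.data$chrom, .data$start)
  if (nrow(flagged) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      n_windows = integer(), best_score = numeric(),
      best_window_start = numeric(), index_snp = character(),
      index_pos = numeric(), min_p = numeric()
    ))
  }

  flagged %>%
    group_by(.data$chrom) %>%
    mutate(
      .gap = .data$start - dplyr::lag(.data$end, default = dplyr::first(.data$start)),
      .locus = cumsum(.data$.gap > max_gap_bp)
    ) %>%
    group_by(.data$chrom, .data$.locus) %>%
    summarise(
      n_windows = dplyr::n(),
      best_score = max(.data$score),
      best_window_start = .data$start[which.max(.data$score)],
      index_snp = .data$top_snp[which.min(.data$min_p)],
      index_pos = .data$top_pos[which.min(.data$min_p)],
      # locus bounds and p last: they shadow the member-window columns
      start = min(.data$start),
      end = max(.data$end),
      min_p = min(.data$min_p),
      .groups = "drop"
    ) %>%
    select("chrom", "start", "end", "n_windows", "best_score",
           "best_window_start", "index_snp", "index_pos", "min_p", ".locus") %>%
    select(-".locus") %>%
    arrange(.data$chrom, .data$start)
}

#' Export the most significant SNP of each window
#'
#' Emits one row per window -- its top SNP -- in a four-column layout
#' (`snp_id`, `chrom`, `pos`, `p`) loadable by regional-association plotting
#' tools, sorted by position. This is the thinned representation used when a
#' region holds too many SNPs to plot individually.
#'
#' @param windows Output of [scan_windows()].
#' @param path Optional file path; when given, the table is also written as
#'   TSV.
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `p`.
#' @export
export_top_snps <- function(windows, path = NULL) {
  check_columns(windows, c("chrom", "top_snp", "top_pos", "min_p"), "`windows`")
  if (nrow(windows) == 0) abort("`windows` must be non-empty")
  out <- windows %>%
    mutate(snp_id = .data$top_snp, pos = .data$top_pos, p = .data$min_p) %>%
    select("snp_id", "chrom", "pos", "p") %>%
    arrange(.data$chrom, .data$pos)
  if (!is.null(path)) readr::write_tsv(out, path)
  out
}
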