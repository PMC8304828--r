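# Independent brute-force oracles used across the suite. These deliberately
# use the slowest, most literal formulation of each quantity so they share
# no code path with the package implementation.

# Per-window SNP summary by explicit double loop over tiling windows.
oracle_windows <- function(assocs, window_bp, alpha) {
  out <- list()
  for (ch in sort(unique(assocs$chrom))) {
    sub <- assocs[assocs$chrom == ch, ]
    for (w in sort(unique(floor((sub$pos - 1) / window_bp)))) {
      start <- w * window_bp + 1
      inside <- sub[sub$pos >= start & sub$pos < start + window_bp, ]
      best <- inside[order(inside$p, inside$pos, inside$snp_id), ][1, ]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = start, n_snps = nrow(inside),
        n_sig = sum(inside$p < alpha), min_p = best$p, top_snp = best$snp_id
      )
    }
  }
  do.call(rbind, out)
}

# Interval union of flagged windows by pairwise scanning.
oracle_merge <- function(windows, threshold, max_gap) {
  flagged <- windows[windows$score >= threshold, ]
  flagged <- flagged[order(flagged$chrom, flagged$start), ]
  if (nrow(flagged) == 0) return(data.frame())
  loci <- list()
  cur <- flagged[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(flagged))[-1]) {
    row <- flagged[i, ]
    if (row$chrom == cur$chrom && row$start - cur$end <= max_gap) {
      cur$end <- max(cur$end, row$end)
    } else {
      loci[[length(loci) + 1]] <- cur
      cur <- row[, c("chrom", "start", "end")]
    }
  }
  loci[[length(loci) + 1]] <- cur
  do.call(rbind, loci)
}

# Benjamini-Hochberg step-up rejection set by literal sort-and-scan.
oracle_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i / m * alpha) k <- i
  rejected <- rep(FALSE, m)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  rejected
}

# Mann-Whitney U by explicit pair counting (ties count one half).
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  }
  u
}

# BFS distance between two nodes via igraph.
oracle_distance <- function(edges, from, to) {
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  d <- igraph::distances(g, v = from, to = to)
  as.numeric(d)
}

# Upper-tail standard-normal probability by series (small z) or Lentz
# continued fraction for the Mills ratio (large z); independent of pnorm.
oracle_normal_tail <- function(z) {
  stopifnot(z >= 0)
  if (z < 2) {
    # erf series: Q(z) = 1/2 - phi-scaled series
    term <- z / sqrt(2)
    s <- term
    k <- 0
    repeat {
      k <- k + 1
      term <- -term * (z^2 / 2) * (2 * k - 1) / (k * (2 * k + 1))
      s <- s + term
      if (abs(term) < 1e-18) break
    }
    0.5 - s / sqrt(pi)
  } else {
    # Q(z) = phi(z) * CF, CF = 1/(z + 1/(z + 2/(z + 3/(...))))
    cf <- 0
    for (k in rev(seq_len(200))) cf <- k / (z + cf)
    cf <- 1 / (z + cf)
    exp(-z^2 / 2) / sqrt(2 * pi) * cf
  }
}

# Small convenience: deterministic per-case RNG scope.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}
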