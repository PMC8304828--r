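#' Read and normalise an interaction-score edge table
#'
#' Edge tables exported from interaction databases carry per-channel
#' confidence scores either in [0, 1] or on a 0-1000 integer scale. When any
#' score exceeds 1, every score column is divided by 1000 and a message
#' records the normalisation.
#'
#' @param path TSV file with columns `gene_a`, `gene_b` and one column per
#'   score channel (`coexpression`, `experimental`, `combined`).
#' @return A tibble of edges with scores in [0, 1].
#' @export
read_edges <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(edges, c("gene_a", "gene_b"), "edge table")
  score_cols <- setdiff(names(edges), c("gene_a", "gene_b"))
  if (max(as.matrix(edges[score_cols]), na.rm = TRUE) > 1) {
    inform("scores exceed 1; normalising from the 0-1000 scale")
    edges[score_cols] <- edges[score_cols] / 1000
  }
  edges
}

#' Filter interaction edges by channel scores
#'
#' Keeps an edge when *any* of the named evidence channels reaches
#' `min_score` -- mirroring the convention of retaining gene pairs that are
#' either coexpressed or experimentally validated at a low-confidence
#' threshold of 0.15. The resulting graph's nodes are the endpoints of the
#' retained edges plus any explicitly listed seed genes, which may end up
#' isolated.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` and score
#'   channels in [0, 1].
#' @param min_score Minimum channel score for retention.
#' @param channels Channel columns tested against `min_score` (use
#'   `"combined"` to filter on the combined score instead).
#' @param seed_genes Genes always included as nodes, even if isolated.
#' @return An object of class `gene_graph`: list with `edges` (retained
#'   edges) and `nodes` (sorted character vector).
#' @examples
#' edges <- data.frame(gene_a = "DDX11", gene_b = "MED6",
#'                     coexpression = 0.31, experimental = 0, combined = 0.31)
#' filter_edges(edges)
#' @export
filter_edges <- function(edges, min_score = 0.15,
                         channels = c("coexpression", "experimental"),
                         seed_genes = character()) {
  check_columns(edges, c("gene_a", "gene_b"), "`edges`")
  unknown <- setdiff(channels, names(edges))
  if (length(unknown) > 0) {
    abort(sprintf("unknown channel(s): %s", paste(unknown, collapse = ", ")))
  }
  if (any(edges$gene_a == edges$gene_b)) abort("self-edges are not allowed")
  score_cols <- setdiff(names(edges), c("gene_a", "gene_b"))
  scores <- as.matrix(edges[score_cols])
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    abort("scores must be normalised to [0, 1]; see read_edges()")
  }

  keep_mat <- as.matrix(edges[channels])
  keep <- rowSums(keep_mat >= min_score, na.rm = TRUE) > 0
  kept <- as_tibble(edges[keep, , drop = FALSE])
  structure(
    list(
      edges = kept,
      nodes = sort(unique(c(kept$gene_a, kept$gene_b, seed_genes)))
    ),
    class = "gene_graph"
  )
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("<gene_graph> %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Symmetric adjacency matrix of a gene_graph; edge weight is the maximum
# channel score of the pair.
adjacency_matrix <- function(graph) {
  n <- length(graph$nodes)
  a <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0) {
    score_cols <- setdiff(names(graph$edges), c("gene_a", "gene_b"))
    w <- apply(as.matrix(graph$edges[score_cols]), 1, max, na.rm = TRUE)
    i <- match(graph$edges$gene_a, graph$nodes)
    j <- match(graph$edges$gene_b, graph$nodes)
    a[cbind(i, j)] <- pmax(a[cbind(i, j)], w)
    a[cbind(j, i)] <- a[cbind(i, j)]
  }
  a
}

#' Cluster graph nodes by spectral embedding and k-means
#'
#' Embeds the nodes with the leading `k` eigenvectors of the
#' symmetric-normalised adjacency matrix `D^-1/2 A D^-1/2` (isolated nodes
#' get unit degree so the normalisation is defined) and partitions the
#' embedding with k-means (10 restarts, seeded), so repeated runs with the
#' same seed give identical assignments.
#'
#' @param graph A [filter_edges()] result.
#' @param k Number of clusters (`k <=` node count).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return A tibble with columns `gene` and `cluster` (integer labels 1..k).
#' @export
cluster_kmeans <- function(graph, k = 3, seed = 1, nstart = 10) {
  stopifnot(inherits(graph, "gene_graph"))
  n <- length(graph$nodes)
  if (n == 0) abort("cannot cluster an empty graph")
  if (k > n) abort("`k` exceeds the number of nodes")
  if (k == 1) return(tibble(gene = graph$nodes, cluster = 1L))

  a <- adjacency_matrix(graph)
  d <- rowSums(a)
  d[d == 0] <- 1
  l <- diag(1 / sqrt(d)) %*% a %*% diag(1 / sqrt(d))
  e <- eigen(l, symmetric = TRUE)
  emb <- e$vectors[, seq_len(k), drop = FALSE]
  # fix eigenvector sign so the embedding (and thus k-means) is reproducible
  for (j in seq_len(k)) {
    m <- which.max(abs(emb[, j]))
    if (emb[m, j] < 0) emb[, j] <- -emb[, j]
  }

  set.seed(seed)
  fit <- kmeans(emb, centers = k, nstart = nstart)
  tibble(gene = graph$nodes, cluster = as.integer(fit$cluster))
}

#' Shortest connecting path between two genes
#'
#' Unweighted breadth-first search; among equally short paths the one
#' exploring alphabetically earlier neighbours first is returned, so the
#' result is deterministic. Returns `NULL` when the genes are in different
#' components.
#'
#' @param graph A [filter_edges()] result.
#' @param from,to Gene names present in the graph.
#' @return Character vector of nodes from `from` to `to`, or `NULL` when no
#'   path exists.
#' @export
graph_path <- function(graph, from, to) {
  stopifnot(inherits(graph, "gene_graph"))
  absent <- setdiff(c(from, to), graph$nodes)
  if (length(absent) > 0) {
    abort(sprintf("node(s) not in graph: %s", paste(absent, collapse = ", ")))
  }
  if (from == to) return(from)

  nbr <- split(c(graph$edges$gene_b, graph$edges$gene_a),
               c(graph$edges$gene_a, graph$edges$gene_b))
  nbr <- lapply(nbr, function(x) sort(unique(x)))

  parent <- stats::setNames(rep(NA_character_, length(graph$nodes)), graph$nodes)
  visited <- stats::setNames(rep(FALSE, length(graph$nodes)), graph$nodes)
  visited[from] <- TRUE
  queue <- from
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    for (nx in nbr[[cur]] %||% character()) {
      if (!visited[nx]) {
        visited[nx] <- TRUE
        parent[nx] <- cur
        if (nx == to) {
          path <- to
          while (path[1] != from) path <- c(parent[path[1]], path)
          return(unname(path))
        }
        queue <- c(queue, nx)
      }
    }
  }
  NULL
}
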