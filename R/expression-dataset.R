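#' Construct an expression dataset
#'
#' Lightweight container for one expression study: a probe-by-sample value
#' matrix, case/control labels, and a probe-to-gene map. Every probe must be
#' mapped and each group must hold at least two samples (the minimum for a
#' two-sample test).
#'
#' @param dataset_id Character identifier for the study.
#' @param values Numeric matrix, probes in rows (rownames required), samples
#'   in columns.
#' @param groups Character vector of `"case"`/`"control"` labels, one per
#'   column of `values`.
#' @param probe_gene Data frame with columns `probe` and `gene` covering
#'   every row of `values`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, values, groups, probe_gene) {
  if (!is.matrix(values) || is.null(rownames(values))) {
    abort("`values` must be a matrix with probe rownames")
  }
  if (length(groups) != ncol(values)) {
    abort("`groups` must have one label per sample column")
  }
  bad <- setdiff(unique(groups), c("case", "control"))
  if (length(bad) > 0) abort(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")))
  if (sum(groups == "case") < 2 || sum(groups == "control") < 2) {
    abort("each group needs >= 2 samples")
  }
  probe_gene <- as_tibble(probe_gene)
  check_columns(probe_gene, c("probe", "gene"), "`probe_gene`")
  unmapped <- setdiff(rownames(values), probe_gene$probe)
  if (length(unmapped) > 0) {
    abort(sprintf("unmapped probe(s): %s", paste(head(unmapped, 5), collapse = ", ")))
  }
  structure(
    list(dataset_id = dataset_id, values = values, groups = groups,
         probe_gene = probe_gene),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset %s> %d probes x %d samples (%d case / %d control), %d genes\n",
    x$dataset_id, nrow(x$values), ncol(x$values),
    sum(x$groups == "case"), sum(x$groups == "control"),
    length(unique(x$probe_gene$gene))
  ))
  invisible(x)
}
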