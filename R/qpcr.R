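#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per (sample, gene). Each sample's
#' delta-Ct is its target Ct minus the arithmetic mean of its housekeeping
#' Ts -- averaging Ct cycles corresponds to the geometric average of
#' housekeeping expression, the standard multi-reference normalisation.
#' Delta-delta-Ct subtracts the reference (control) group's mean delta-Ct,
#' and expression is reported in fold units `2^-ddCt`, so the reference
#' group has geometric mean 1 by construction.
#'
#' @param ct Ct table with columns `sample_id`, `group`, `gene`,
#'   `replicate`, `ct`.
#' @param target Target gene name.
#' @param housekeeping Character vector of housekeeping gene names; every
#'   sample must have all of them measured.
#' @param reference_group Group whose mean delta-Ct defines the baseline.
#' @return A tibble with one row per sample: `sample_id`, `group`, `gene`,
#'   `delta_ct`, `value` (2^-ddCt fold units).
#' @examples
#' ct <- sim_ct(sim_config(seed = 1), targets = "DDX11")
#' rel <- relative_expression(ct, "DDX11", c("GAPDH", "ACTB"))
#' head(rel)
#' @export
relative_expression <- function(ct, target, housekeeping,
                                reference_group = "control") {
  check_columns(ct, c("sample_id", "group", "gene", "ct"), "`ct`")
  if (length(housekeeping) == 0) abort("`housekeeping` must be non-empty")
  if (any(ct$ct <= 0)) abort("Ct values must be positive")

  means <- ct %>%
    filter(.data$gene %in% c(target, housekeeping)) %>%
    group_by(.data$sample_id, .data$group, .data$gene) %>%
    summarise(ct = mean(.data$ct), .groups = "drop")

  hk <- means %>%
    filter(.data$gene %in% housekeeping) %>%
    group_by(.data$sample_id) %>%
    summarise(hk_ct = mean(.data$ct), n_hk = dplyr::n(), .groups = "drop")
  incomplete <- hk$sample_id[hk$n_hk < length(housekeeping)]
  tg <- means %>% filter(.data$gene == target)
  incomplete <- union(incomplete, setdiff(tg$sample_id, hk$sample_id))
  if (length(incomplete) > 0) {
    abort(sprintf("sample(s) missing housekeeping measurements: %s",
                  paste(head(sort(incomplete), 5), collapse = ", ")))
  }

  dct <- tg %>%
    inner_join(hk, by = "sample_id") %>%
    mutate(delta_ct = .data$ct - .data$hk_ct)
  ref <- dct %>% filter(.data$group == reference_group)
  if (nrow(ref) == 0) abort(sprintf("no samples in reference group '%s'", reference_group))

  dct %>%
    mutate(value = 2^-(.data$delta_ct - mean(ref$delta_ct))) %>%
    select("sample_id", "group", "gene", "delta_ct", "value") %>%
    arrange(.data$group, .data$sample_id)
}

#' Two-group comparison of relative expression
#'
#' Reports both a Welch two-sided t-test on log2-transformed fold values
#' (expression ratios are log-normal-ish, so the comparison is done on the
#' log scale) and a Wilcoxon rank-sum test. `u` is the Mann-Whitney count of
#' (case, control) pairs where the case value exceeds the control value,
#' ties counting one half.
#'
#' @param values Output of [relative_expression()] (columns `group`,
#'   `value`), or any data frame with those columns.
#' @param log_transform Test log2 values (default) or raw fold values.
#' @return A one-row tibble: `n_case`, `n_control`, `t`, `p_t`, `u`, `p_u`.
#' @export
compare_groups <- function(values, log_transform = TRUE) {
  check_columns(values, c("group", "value"), "`values`")
  x <- values$value[values$group == "case"]
  y <- values$value[values$group == "control"]
  if (length(x) < 2 || length(y) < 2) abort("need >= 2 samples per group")
  if (log_transform) {
    if (any(c(x, y) <= 0)) abort("log transform requires positive values")
    x <- log2(x); y <- log2(y)
  }
  tt <- t.test(x, y)
  wt <- suppressWarnings(wilcox.test(x, y))
  tibble(
    n_case = length(x), n_control = length(y),
    t = unname(tt$statistic), p_t = tt$p.value,
    u = unname(wt$statistic), p_u = wt$p.value
  )
}

#' ROC curve summary for a diagnostic marker
#'
#' The AUC is computed rank-based as the probability that a random case
#' value exceeds a random control value, ties counting one half -- i.e.
#' `U / (n1 * n2)` from the Mann-Whitney pair count. The standard error uses
#' the Hanley-McNeil formula, the 95% CI is the normal approximation
#' `AUC +/- 1.96 SE` truncated to [0, 1], and `p_vs_half` tests the AUC
#' against the uninformative 0.5 by the same normal approximation.
#'
#' @param values Numeric marker values.
#' @param labels Class labels, `"case"`/`"control"` (case = positive class).
#' @return An object of class `roc_result`: a one-row tibble with `auc`,
#'   `se`, `ci_low`, `ci_high`, `p_vs_half`, `n_case`, `n_control`, carrying
#'   the values/labels as attributes for plotting.
#' @examples
#' set.seed(7)
#' r <- roc_auc(c(rnorm(20, 1), rnorm(20)), rep(c("case", "control"), each = 20))
#' glance(r)
#' @export
roc_auc <- function(values, labels) {
  if (length(values) != length(labels)) abort("`values` and `labels` must have equal length")
  x <- values[labels == "case"]
  y <- values[labels == "control"]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both classes must be present")

  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  p <- if (se == 0) 0 else 2 * pnorm(abs(auc - 0.5) / se, lower.tail = FALSE)

  out <- tibble(
    auc = auc, se = se,
    ci_low = max(0, auc - 1.96 * se),
    ci_high = min(1, auc + 1.96 * se),
    p_vs_half = p,
    n_case = n1, n_control = n2
  )
  attr(out, "values") <- values
  attr(out, "labels") <- labels
  class(out) <- c("roc_result", class(out))
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f +/- %.3f, CI95%% = %.2f-%.2f, p = %.3g (%d case / %d control)\n",
              x$auc, x$se, x$ci_low, x$ci_high, x$p_vs_half,
              x$n_case, x$n_control))
  invisible(x)
}

#' @rdname roc_auc
#' @param x A `roc_result`.
#' @param ... Unused.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  out <- x
  attributes(out)[c("values", "labels")] <- NULL
  class(out) <- class(tibble())
  out
}

#' @rdname roc_auc
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  roc_points(attr(x, "values"), attr(x, "labels"))
}

# Full ROC curve coordinates (sensitivity vs 1-specificity) over all
# thresholds; used by tidy()/autoplot().
roc_points <- function(values, labels) {
  thr <- c(Inf, sort(unique(values), decreasing = TRUE), -Inf)
  x <- values[labels == "case"]
  y <- values[labels == "control"]
  tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(x >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(y >= t), numeric(1))
  )
}

#' Normal P-P plot coordinates
#'
#' Standardises the values, sorts them, and pairs the standard-normal
#' cumulative probability at each sorted standardised value (theoretical)
#' with the plotting position `(i - 0.5) / n` (empirical). Both coordinates
#' are monotone increasing in (0, 1); departures from the diagonal indicate
#' non-normality.
#'
#' @param values Numeric vector with positive variance (`n >= 1`; a single
#'   value standardises to 0).
#' @return A tibble with columns `theoretical` and `empirical`.
#' @export
pp_points <- function(values) {
  n <- length(values)
  if (n < 1) abort("need at least one value")
  if (n > 1 && sd(values) == 0) abort("values have zero variance")
  z <- if (n == 1) 0 else (sort(values) - mean(values)) / sd(values)
  tibble(
    theoretical = pnorm(z),
    empirical = (seq_len(n) - 0.5) / n
  )
}
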