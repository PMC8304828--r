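make_ds <- function(values, groups, id = "ds1") {
  pg <- data.frame(probe = rownames(values),
                   gene = sub("_p[0-9]+$", "", rownames(values)))
  expression_dataset(id, values, groups, pg)
}

test_that("degenerate probes give t = 0, p = 1 and neutral direction", {
  v <- rbind(flat_p1 = c(1, 2, 3, 1, 2, 3))
  ds <- make_ds(v, c("case", "case", "case", "control", "control", "control"))
  res <- probe_tests(ds)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$direction, 0L)
})

test_that("per-probe Welch results match stats::t.test to 1e-10", {
  set.seed(21)
  v <- matrix(rnorm(50 * 14), 50,
              dimnames = list(sprintf("g%02d_p1", 1:50), NULL))
  groups <- rep(c("case", "control"), c(6, 8))
  res <- probe_tests(make_ds(v, groups))
  for (i in 1:50) {
    tt <- t.test(v[i, groups == "case"], v[i, groups == "control"])
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res$direction[i],
                 as.integer(sign(mean(v[i, groups == "case"]) -
                                   mean(v[i, groups == "control"]))))
  }
})

test_that("swapping group labels flips direction and preserves p", {
  set.seed(22)
  v <- matrix(rnorm(10 * 12), 10,
              dimnames = list(sprintf("g%02d_p1", 1:10), NULL))
  groups <- rep(c("case", "control"), each = 6)
  flipped <- ifelse(groups == "case", "control", "case")
  a <- probe_tests(make_ds(v, groups))
  b <- probe_tests(make_ds(v, flipped))
  expect_equal(a$p, b$p)
  expect_equal(a$direction, -b$direction)
})

test_that("missing expression values error with the probe name", {
  v <- matrix(rnorm(8), 2, dimnames = list(c("a_p1", "b_p1"), NULL))
  v[2, 1] <- NA
  expect_error(probe_tests(make_ds(v, rep(c("case", "control"), 2))), "b_p1")
})

# hand-built probe results for a 3-dataset toy: gene-by-gene enumeration
toy_results <- function() {
  tibble::tribble(
    ~dataset_id, ~probe, ~gene, ~p, ~direction,
    # gA: significant in ds1+ds2, all directions +1 -> called
    "ds1", "gA_p1", "gA", 0.001, 1L,
    "ds1", "gA_p2", "gA", 0.20,  1L,
    "ds2", "gA_p1", "gA", 0.010, 1L,
    "ds2", "gA_p2", "gA", 0.30,  1L,
    "ds3", "gA_p1", "gA", 0.90, -1L,
    "ds3", "gA_p2", "gA", 0.80,  1L,
    # gB: significant in ds1+ds2 but directions disagree -> aligned = FALSE
    "ds1", "gB_p1", "gB", 0.001,  1L,
    "ds2", "gB_p1", "gB", 0.002, -1L,
    "ds3", "gB_p1", "gB", 0.70,   1L,
    # gC: significant in one dataset only
    "ds1", "gC_p1", "gC", 0.001, 1L,
    "ds2", "gC_p1", "gC", 0.50,  1L,
    "ds3", "gC_p1", "gC", 0.60,  1L
  )
}

test_that("convergence requires multi-dataset significance and alignment", {
  calls <- converge_genes(toy_results(), reference_genes = c("gA", "gB", "gC"))
  gA <- calls[calls$gene == "gA", ]
  expect_true(gA$called)
  expect_equal(gA$n_datasets_significant, 2L)
  expect_equal(gA$gene_p, 0.001) # min probe p over significant datasets
  gB <- calls[calls$gene == "gB", ]
  expect_false(gB$aligned)
  expect_false(gB$called)
  gC <- calls[calls$gene == "gC", ]
  expect_false(gC$called)
  expect_equal(gC$n_datasets_significant, 1L)
})

test_that("alignment is judged over all probes in significant datasets", {
  # gA's ds3 probes disagree, but ds3 is not significant for gA -> still aligned
  calls <- converge_genes(toy_results(), reference_genes = "gA")
  expect_true(calls$aligned[calls$gene == "gA"])
  # move the conflicting direction into significant ds2 -> alignment broken
  res <- toy_results()
  res$direction[res$probe == "gA_p2" & res$dataset_id == "ds2"] <- -1L
  calls2 <- converge_genes(res, reference_genes = "gA")
  expect_false(calls2$aligned[calls2$gene == "gA"])
})

test_that("the reference gene list gates calls and cannot be empty", {
  calls <- converge_genes(toy_results(), reference_genes = "gB")
  expect_false(calls$called[calls$gene == "gA"]) # not in reference
  expect_false(calls$in_reference[calls$gene == "gA"])
  expect_error(converge_genes(toy_results(), reference_genes = character()),
               "reference")
  expect_error(converge_genes(toy_results()[toy_results()$dataset_id == "ds1", ],
                              reference_genes = "gA"), ">= 2 datasets")
})

test_that("FDR and Bonferroni gates match brute-force step-up and dominance", {
  one <- tibble::tibble(gene = "g", n_datasets_significant = 2L,
                        aligned = TRUE, in_reference = TRUE,
                        called = TRUE, gene_p = 0.01)
  adj <- adjust_convergence(one)
  expect_true(adj$fdr_pass)
  expect_true(adj$bonferroni_pass)

  for (s in 1:20) {
    set.seed(300 + s)
    n <- 100
    calls <- tibble::tibble(
      gene = sprintf("g%03d", 1:n),
      n_datasets_significant = 2L, aligned = TRUE, in_reference = TRUE,
      called = TRUE,
      gene_p = runif(n)^sample(1:3, 1)
    )
    adj <- adjust_convergence(calls, alpha = 0.05)
    expect_equal(adj$fdr_pass, oracle_bh(calls$gene_p, 0.05))
    expect_equal(adj$bonferroni_pass, calls$gene_p <= 0.05 / n)
    expect_true(all(adj$fdr_pass[adj$bonferroni_pass])) # Bonferroni subset of BH
  }
})
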