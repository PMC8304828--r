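test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(seed = 42, n_snps = 500, n_genes = 30)
  expect_identical(sim_gwas(cfg), sim_gwas(cfg))
  expect_identical(sim_expression(cfg, 2), sim_expression(cfg, 2))
  gwas <- sim_gwas(cfg)
  genes <- sprintf("G%04d", 1:30)
  expect_identical(sim_eqtl(gwas, genes, cfg), sim_eqtl(gwas, genes, cfg))
  expect_identical(sim_ct(cfg), sim_ct(cfg))
  expect_identical(sim_edges(cfg, genes), sim_edges(cfg, genes))

  cfg2 <- sim_config(seed = 43, n_snps = 500, n_genes = 30)
  expect_false(identical(sim_gwas(cfg), sim_gwas(cfg2)))
})

test_that("background GWAS p-values are uniform when nothing is planted", {
  n_ok <- 0
  for (s in 1:100) {
    g <- sim_gwas(sim_config(seed = s, n_snps = 1000, planted_loci = NULL))
    if (stats::ks.test(g$p, "punif")$p.value > 0.01) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 95)
})

test_that("a planted locus contributes its LD cluster of significant SNPs", {
  cfg <- sim_config(
    seed = 7, n_snps = 1000, ld_cluster_size = 10,
    planted_loci = data.frame(center_bp = 5e6, peak = 6)
  )
  g <- sim_gwas(cfg)
  span <- c(5e6 - cfg$locus_span_bp / 2, 5e6 + cfg$locus_span_bp / 2)
  inside <- g[g$pos >= span[1] & g$pos <= span[2], ]
  expect_gte(sum(inside$p < 0.05), 10)
  expect_true(!is.unsorted(g$pos))
  expect_false(anyDuplicated(g$snp_id) > 0)
})

test_that("overlapping planted loci are rejected, naming the pair", {
  expect_error(
    sim_gwas(sim_config(planted_loci = data.frame(
      center_bp = c(5e6, 5.02e6), peak = c(6, 6)
    ))),
    "5000000 bp and 5020000 bp have overlapping"
  )
})

test_that("null expression data rejects at the nominal rate", {
  cfg <- sim_config(seed = 3, n_genes = 500, probes_per_gene = 2,
                    n_case = 10, n_control = 10)
  ds <- sim_expression(cfg, 1)[[1]]
  res <- probe_tests(ds)
  # 1000 independent null probes: rate within 4 binomial SDs of 0.05
  rate <- mean(res$p < 0.05)
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / 1000))
})

test_that("a planted expression effect shifts case means consistently", {
  hits <- 0
  for (s in 1:50) {
    cfg <- sim_config(
      seed = s, n_genes = 10, probes_per_gene = 2,
      de_genes = data.frame(gene = "G0004", effect_d = 1.5, n_datasets = 2)
    )
    ds <- sim_expression(cfg, 2)
    ok <- all(vapply(ds, function(d) {
      rows <- d$probe_gene$probe[d$probe_gene$gene == "G0004"]
      all(rowMeans(d$values[rows, d$groups == "case", drop = FALSE]) >
            rowMeans(d$values[rows, d$groups == "control", drop = FALSE]))
    }, logical(1)))
    if (ok) hits <- hits + 1
  }
  expect_gte(hits, 48) # >= 95% of 50 seeds
})

test_that("probe universe has the configured shape and unknown DE genes error", {
  cfg <- sim_config(n_genes = 3, probes_per_gene = 1)
  ds <- sim_expression(cfg, 2)
  expect_equal(nrow(ds[[1]]$values), 3)
  expect_equal(nrow(ds[[2]]$values), 3)
  bad <- sim_config(n_genes = 3, de_genes = data.frame(
    gene = "NOPE", effect_d = 1, n_datasets = 1
  ))
  expect_error(sim_expression(bad, 2), "NOPE")
})

test_that("simulated eQTL p-values are normal tails of their Z by construction", {
  cfg <- sim_config(seed = 5, n_snps = 200, n_genes = 20,
                    eqtl_targets = data.frame(gene = "G0002", z = -8))
  eq <- sim_eqtl(sim_gwas(cfg), sprintf("G%04d", 1:20), cfg, n_background = 100)
  expect_equal(eq$p_eqtl, z_to_p(eq$z), tolerance = 1e-12)
  expect_true(any(eq$gene == "G0002" & eq$z < -5))
})

test_that("Ct tables with no shift keep housekeeping and target group-stable", {
  cfg <- sim_config(seed = 9, ct_shift = 0)
  ct <- sim_ct(cfg, targets = "TG", housekeeping = "GAPDH")
  hk <- ct[ct$gene == "GAPDH", ]
  expect_lt(
    abs(mean(hk$ct[hk$group == "case"]) - mean(hk$ct[hk$group == "control"])),
    0.5
  )
  expect_gt(min(ct$ct), 0)
})

test_that("ct_shift of one cycle doubles case-group relative expression", {
  ratios <- vapply(1:50, function(s) {
    ct <- sim_ct(sim_config(seed = s, ct_shift = 1), targets = "TG")
    rel <- relative_expression(ct, "TG", c("GAPDH", "ACTB"))
    mean(rel$value[rel$group == "case"]) / mean(rel$value[rel$group == "control"])
  }, numeric(1))
  expect_gt(mean(ratios), 1.75)
  expect_lt(mean(ratios), 2.3)
})
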