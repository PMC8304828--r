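flat_ct <- function(ct_target = 25, hk = 18, n = 3) {
  tidyr::expand_grid(
    sample_id = sprintf("s%d", 1:(2 * n)),
    gene = c("TG", "GAPDH", "ACTB"),
    replicate = 1:2
  ) |>
    dplyr::mutate(
      group = ifelse(as.integer(sub("s", "", sample_id)) <= n, "case", "control"),
      ct = ifelse(gene == "TG", ct_target, hk)
    )
}

test_that("identical Ct everywhere gives unit relative expression", {
  rel <- relative_expression(flat_ct(), "TG", c("GAPDH", "ACTB"))
  expect_equal(rel$value, rep(1, 6))
  # control geometric mean is 1 by construction
  expect_equal(exp(mean(log(rel$value[rel$group == "control"]))), 1)
})

test_that("ddCt is invariant to per-sample and global Ct offsets", {
  ct <- sim_ct(sim_config(seed = 2), targets = "TG")
  base <- relative_expression(ct, "TG", c("GAPDH", "ACTB"))

  shifted <- ct
  shifted$ct <- shifted$ct + 3 # global offset
  expect_equal(relative_expression(shifted, "TG", c("GAPDH", "ACTB"))$value,
               base$value)

  per_sample <- ct
  bump <- ifelse(per_sample$sample_id == "case01", 2.5, 0)
  per_sample$ct <- per_sample$ct + bump # one sample loaded differently
  expect_equal(relative_expression(per_sample, "TG", c("GAPDH", "ACTB"))$value,
               base$value)
})

test_that("one cycle below the reference mean doubles expression", {
  ct <- flat_ct()
  ct$ct[ct$gene == "TG" & ct$group == "case"] <- 24
  rel <- relative_expression(ct, "TG", c("GAPDH", "ACTB"))
  expect_equal(rel$value[rel$group == "case"], rep(2, 3))
  expect_equal(rel$value[rel$group == "control"], rep(1, 3))
})

test_that("samples missing housekeeping measurements are reported by name", {
  ct <- flat_ct()
  ct <- ct[!(ct$sample_id == "s2" & ct$gene == "GAPDH"), ]
  expect_error(relative_expression(ct, "TG", c("GAPDH", "ACTB")), "s2")
})

test_that("group comparison reports Welch t and the Mann-Whitney pair count", {
  same <- tibble::tibble(group = rep(c("case", "control"), each = 4),
                         value = rep(c(1, 2, 3, 4), 2))
  res <- compare_groups(same)
  expect_equal(res$u, 4 * 4 / 2)
  expect_gt(res$p_u, 0.9)

  sep <- tibble::tibble(group = rep(c("case", "control"), each = 3),
                        value = c(10, 11, 12, 1, 2, 3))
  expect_equal(compare_groups(sep)$u, 9) # all 9 pairs correctly ordered
  inv <- sep |> dplyr::mutate(group = ifelse(group == "case", "control", "case"))
  expect_equal(compare_groups(inv)$u, 0)

  for (s in 1:20) {
    set.seed(400 + s)
    v <- tibble::tibble(
      group = rep(c("case", "control"), each = 20),
      value = 2^round(rnorm(40), 1) # rounded -> ties occur
    )
    res <- compare_groups(v)
    expect_equal(res$u, oracle_u(log2(v$value[v$group == "case"]),
                                 log2(v$value[v$group == "control"])))
  }
  expect_error(compare_groups(tibble::tibble(group = c("case", "case", "control", "control"),
                                             value = c(1, -1, 2, 3))),
               "positive")
})

test_that("AUC equals the pair-count probability with Hanley-McNeil errors", {
  perfect <- roc_auc(c(5, 6, 7, 1, 2, 3), rep(c("case", "control"), each = 3))
  expect_equal(perfect$auc, 1)

  for (s in 1:50) {
    set.seed(500 + s)
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    vals <- c(round(rnorm(n1, 0.5), 1), round(rnorm(n2), 1)) # ties likely
    labs <- rep(c("case", "control"), c(n1, n2))
    r <- roc_auc(vals, labs)
    expect_equal(r$auc, oracle_u(vals[1:n1], vals[-(1:n1)]) / (n1 * n2))
    # label inversion maps auc -> 1 - auc
    flipped <- roc_auc(vals, ifelse(labs == "case", "control", "case"))
    expect_equal(flipped$auc, 1 - r$auc)
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  }
  expect_error(roc_auc(1:3, rep("case", 3)), "both classes")
})

test_that("AUC and its confidence band agree with an independent ROC package", {
  set.seed(510)
  vals <- c(rnorm(25, 0.8), rnorm(30))
  labs <- rep(c("case", "control"), c(25, 30))
  r <- roc_auc(vals, labs)
  pr <- pROC::roc(response = labs, predictor = vals,
                  levels = c("control", "case"), direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("with no planted shift the group test rejects at the nominal rate", {
  rejections <- vapply(1:200, function(s) {
    ct <- sim_ct(sim_config(seed = 5000 + s, ct_shift = 0), targets = "TG")
    rel <- relative_expression(ct, "TG", c("GAPDH", "ACTB"))
    compare_groups(rel)$p_t < 0.05
  }, logical(1))
  # 200 Bernoulli(0.05) trials: allow 4 binomial SDs around 5%
  expect_lt(abs(mean(rejections) - 0.05), 4 * sqrt(0.05 * 0.95 / 200))
})

test_that("a one-cycle shift is detected with high power at n = 20 per group", {
  rejections <- vapply(1:200, function(s) {
    ct <- sim_ct(sim_config(seed = s, ct_shift = 1), targets = "TG")
    rel <- relative_expression(ct, "TG", c("GAPDH", "ACTB"))
    compare_groups(rel)$p_t < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
})

test_that("P-P coordinates are monotone plotting positions against normal CDF", {
  expect_equal(pp_points(7)$empirical, 0.5)
  pts <- pp_points(rnorm(50))
  expect_true(!is.unsorted(pts$theoretical))
  expect_true(!is.unsorted(pts$empirical))
  expect_true(all(pts$theoretical > 0 & pts$theoretical < 1))
  expect_error(pp_points(rep(1, 5)), "zero variance")

  set.seed(520)
  big <- pp_points(rnorm(10000))
  expect_lt(max(abs(big$theoretical - big$empirical)), 0.05)
})
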