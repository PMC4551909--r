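test_that("cohort generation is fully determined by the seed", {
  cfg <- cohort_config(n_genes = 300, seed = 123)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$catalog, b2$catalog)
  expect_identical(b1$variants, b2$variants)
  expect_identical(b1$expr_a, b2$expr_a)
  expect_identical(b1$expr_b, b2$expr_b)
  expect_identical(b1$train_his$members, b2$train_his$members)
  expect_identical(b1$true_labels, b2$true_labels)
})

test_that("bundle components share one gene universe and disjoint gene sets", {
  b <- generate_cohort(cohort_config(n_genes = 300, seed = 2))
  genes <- b$catalog$gene_id
  expect_setequal(rownames(b$expr_a), genes)
  expect_setequal(rownames(b$expr_b), genes)
  expect_true(all(b$variants$gene_id %in% genes))
  expect_setequal(names(b$true_labels), genes)
  expect_length(intersect(b$train_his$members, b$hs_pool$members), 0)
  expect_length(intersect(b$train_his$members, b$eval_his$members), 0)
  expect_length(intersect(b$hs_pool$members, b$eval_hs$members), 0)
  expect_true(all(b$true_labels[b$train_his$members] == "HIS"))
  expect_true(all(b$true_labels[b$hs_pool$members] == "neutral"))
})

test_that("planted depletion lowers NoVaDs in HIS genes", {
  b <- generate_cohort(cohort_config(n_genes = 800, seed = 31))
  panel <- novads_panel(b$variants)
  nv <- setNames(panel$novads, panel$gene_id)
  his <- nv[names(b$true_labels)[b$true_labels == "HIS"]]
  neut <- nv[names(b$true_labels)[b$true_labels == "neutral"]]
  p <- wilcox.test(his, neut, alternative = "less", exact = FALSE)$p.value
  expect_lt(p, 0.01)
})

test_that("a signal-free configuration decouples labels from features", {
  b <- generate_cohort(cohort_config(n_genes = 800, depletion_effect = 1,
                                     coexpr_module_strength = 0,
                                     dnds_shift = 0, f2a_shift = 0,
                                     seed = 19))
  panel <- novads_panel(b$variants)
  nv <- setNames(panel$novads, panel$gene_id)
  his <- nv[names(b$true_labels)[b$true_labels == "HIS"]]
  neut <- nv[names(b$true_labels)[b$true_labels == "neutral"]]
  auc <- roc_auc(his[!is.na(his)], neut[!is.na(neut)])
  expect_lt(abs(auc - 0.5), 0.1)
})

test_that("stronger depletion monotonically improves NoVaDs label recovery", {
  aucs <- vapply(c(0.8, 0.4, 0.2), function(eff) {
    b <- generate_cohort(cohort_config(n_genes = 800,
                                       depletion_effect = eff,
                                       seed = 500))
    panel <- novads_panel(b$variants)
    nv <- setNames(panel$novads, panel$gene_id)
    his <- nv[names(b$true_labels)[b$true_labels == "HIS"]]
    neut <- nv[names(b$true_labels)[b$true_labels == "neutral"]]
    # depletion lowers NoVaDs, so intolerance ranking uses the negative
    roc_auc(-his[!is.na(his)], -neut[!is.na(neut)])
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("the RVIS null simulation is reproducible and CDS-decoupled at source", {
  r1 <- rvis_null(500, seed = 9)
  r2 <- rvis_null(500, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$n_total >=
                    r1$n_common_nonsyn + r1$n_rare_nonsyn +
                    r1$n_common_syn + r1$n_rare_syn))
  # when every gene's common proportion equals the global mean, the
  # regression fits exactly and all residuals vanish
  totals <- 5L * (10:109)
  flat <- data.frame(gene_id = paste0("F", 1:100),
                     n_common_nonsyn = as.integer(round(0.2 * totals)),
                     n_rare_nonsyn = as.integer(round(0.3 * totals)),
                     n_common_syn = 0L, n_rare_syn = 0L,
                     n_total = totals)
  expect_equal(rvis(flat), rep(0, 100), tolerance = 1e-10)
})

test_that("fixture directories round-trip through the plain-text readers", {
  b <- generate_cohort(cohort_config(n_genes = 120, seed = 77))
  dir <- file.path(tempdir(), "ghis_fixture_test")
  files <- write_fixture(b, dir)
  expect_true(all(file.exists(files)))
  back <- read_cohort_fixture(dir)
  expect_equal(back$catalog$gene_id, b$catalog$gene_id)
  expect_equal(back$catalog$cds_length, b$catalog$cds_length)
  expect_equal(back$catalog$dn, b$catalog$dn, tolerance = 1e-9)
  expect_equal(nrow(back$variants), nrow(b$variants))
  expect_equal(back$variants$maf, b$variants$maf, tolerance = 1e-9)
  expect_equal(back$expr_a, b$expr_a, tolerance = 1e-9)
  expect_equal(back$expr_b, b$expr_b, tolerance = 1e-9)
  expect_identical(back$train_his$members, b$train_his$members)
  expect_identical(back$partition$fetal_samples,
                   b$partition$fetal_samples)
  expect_identical(back$true_labels, b$true_labels)
  unlink(dir, recursive = TRUE)
})
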