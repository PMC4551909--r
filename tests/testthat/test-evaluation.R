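test_that("matched random sets draw from the nearest-CDS candidate pools", {
  cat <- make_catalog(c("T1", "U1", "U2", "U3"),
                      cds_length = c(1500, 1490, 1510, 9000))
  target <- gene_set("t", "T1")
  cfg <- matched_set_config(n_sets = 50, candidate_pool_size = 2, seed = 1)
  sets <- matched_random_sets(target, cat, c("U1", "U2", "U3"), cfg)
  drawn <- unlist(lapply(sets, function(s) s$members))
  expect_true(all(drawn %in% c("U1", "U2")))  # 9000 never in the pool
  expect_setequal(unique(drawn), c("U1", "U2"))

  # pool size 1 is a deterministic nearest-CDS substitution
  cfg1 <- matched_set_config(n_sets = 3, candidate_pool_size = 1, seed = 2)
  sets1 <- matched_random_sets(target, cat, c("U1", "U2", "U3"), cfg1)
  expect_true(all(vapply(sets1, function(s) s$members, "") == "U1"))

  # same seed gives identical sets
  setsA <- matched_random_sets(target, cat, c("U1", "U2", "U3"), cfg)
  setsB <- matched_random_sets(target, cat, c("U1", "U2", "U3"), cfg)
  expect_identical(lapply(setsA, `[[`, "members"),
                   lapply(setsB, `[[`, "members"))

  # ortholog restriction limits the candidate universe
  cat$has_mouse_ortholog <- c(TRUE, FALSE, TRUE, TRUE)
  cfg_o <- matched_set_config(n_sets = 30, candidate_pool_size = 3,
                              restrict_to_ortholog_genes = TRUE, seed = 3)
  sets_o <- matched_random_sets(target, cat, c("U1", "U2", "U3"), cfg_o)
  expect_false("U1" %in% unlist(lapply(sets_o, `[[`, "members")))
})

test_that("matched sets reproduce the target's CDS distribution", {
  set.seed(404)
  n_sig <- 0L
  n_trials <- 100L
  for (trial in seq_len(n_trials)) {
    cds <- pmax(90, round(exp(rnorm(400, 7.3, 0.6))))
    cat <- make_catalog(sprintf("G%03d", 1:400), cds)
    target <- gene_set("t", sample(cat$gene_id, 25))
    cfg <- matched_set_config(n_sets = 1, candidate_pool_size = 50,
                              seed = trial)
    ms <- matched_random_sets(target, cat, cat$gene_id, cfg)[[1]]
    p <- wilcox.test(cat$cds_length[match(target$members, cat$gene_id)],
                     cat$cds_length[match(ms$members, cat$gene_id)],
                     exact = FALSE)$p.value
    if (p < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 5L)   # non-significant in >= 95% of trials
})

test_that("MCC at the top fraction matches the direct formula oracle", {
  # construct a genome where the contingency table is known exactly:
  # 40 scored genes, top-25% cutoff -> 10 predicted HIS
  scores <- setNames(seq(40, 1), sprintf("G%02d", 1:40))
  disease <- gene_set("d", c(sprintf("G%02d", 1:5),
                             sprintf("G%02d", 21:25)))  # tp=5, fn=5
  random <- gene_set("r", c(sprintf("G%02d", 6:8),
                            sprintf("G%02d", 31:37)))   # fp=3, tn=7
  got <- mcc_at_top_fraction(scores, disease, random)
  expect_equal(got, mcc_formula_oracle(5, 7, 3, 5), tolerance = 1e-12)

  # complete separation: all disease above, no random above
  d2 <- gene_set("d", sprintf("G%02d", 1:10))
  r2 <- gene_set("r", sprintf("G%02d", 30:39))
  expect_equal(mcc_at_top_fraction(scores, d2, r2),
               mcc_formula_oracle(10, 10, 0, 0), tolerance = 1e-12)

  # swapping equal-size disease/random sets flips the sign
  expect_equal(mcc_at_top_fraction(scores, random, disease),
               -got, tolerance = 1e-12)
})

test_that("identical score multisets give near-zero MCC under the tie rule", {
  # disease and random genes share one score and straddle the top-25%
  # cutoff: 21 genes score above the 8-gene tie block, so 4 of the tied
  # genes enter the top 25.  Over all equally likely 4-subsets the MCC
  # averages 0 (exhaustive enumeration); the deterministic gene-ID
  # tie-break picks one near-even split, bounded by 2/n.
  set.seed(12)
  n <- 8
  scores <- setNames(c(seq(100, 80), rep(50, n), runif(71) * 10),
                     sprintf("G%03d", 1:100))
  disease <- gene_set("d", sprintf("G%03d", c(22, 24, 26, 28)))
  random <- gene_set("r", sprintf("G%03d", c(23, 25, 27, 29)))
  mcc <- mcc_at_top_fraction(scores, disease, random)
  expect_lte(abs(mcc), 2 / n)

  in_disease <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  subsets <- combn(n, 4)
  mccs <- apply(subsets, 2, function(idx) {
    tp <- sum(in_disease[idx]); fp <- 4 - tp
    mcc_formula_oracle(tp, 4 - fp, fp, 4 - tp)
  })
  expect_equal(mean(mccs), 0, tolerance = 1e-12)
})

test_that("ROC AUC equals exhaustive pairwise counting with half-tie credit", {
  expect_equal(roc_auc(c(3, 4), c(1, 2)), 1.0)
  expect_equal(roc_auc(c(1, 1, 1), c(1, 1, 1)), 0.5)
  expect_equal(roc_auc(c(2, 3), c(1, 3)), 0.625)
  expect_equal(roc_auc(c(2, 3), c(1, 3)),
               pairwise_auc_oracle(c(2, 3), c(1, 3)))
  set.seed(88)
  for (i in 1:200) {
    pos <- sample(1:6, sample(1:8, 1), replace = TRUE)
    neg <- sample(1:6, sample(1:8, 1), replace = TRUE)
    expect_equal(roc_auc(pos, neg), pairwise_auc_oracle(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("the best-case expectation reproduces its closed form", {
  bc <- best_case_expectation(0.5, 0.25)
  # rate-level oracle: tp = 0.625, fn = 0.375, fp = 0.25, tn = 0.75
  expect_equal(bc$mcc, mcc_formula_oracle(0.625, 0.75, 0.25, 0.375),
               tolerance = 1e-12)
  expect_equal(round(bc$mcc, 2), 0.38)
  expect_equal(bc$auc, 0.75)

  expect_equal(best_case_expectation(1.0, 0.25)$auc, 1.0)
  expect_equal(best_case_expectation(0.0, 0.25)$mcc, 0.0)
  expect_equal(best_case_expectation(0.0, 0.25)$auc, 0.5)
  # AUC is linear in the causal fraction
  p <- seq(0, 1, by = 0.1)
  aucs <- vapply(p, function(q) best_case_expectation(q, 0.25)$auc,
                 numeric(1))
  expect_equal(aucs, 0.5 + 0.5 * p, tolerance = 1e-12)
})

test_that("gene-set evaluation against matched nulls behaves at its extremes", {
  set.seed(17)
  cds <- pmax(90, round(exp(rnorm(400, 7.3, 0.6))))
  cat <- make_catalog(sprintf("G%03d", 1:400), cds)

  # a pure CDS-rank score carries no signal once length is matched
  cds_score <- setNames(rank(cds, ties.method = "first"), cat$gene_id)
  target <- gene_set("long", cat$gene_id[order(-cds)][seq(2, 60, by = 2)])
  rep1 <- evaluate_gene_set(cds_score, target, cat,
                            matched_set_config(n_sets = 50,
                                               candidate_pool_size = 30,
                                               seed = 4))
  expect_lt(abs(rep1$summary$mean_mcc), 2 * max(rep1$summary$se_mcc, 0.02))

  # a disease set holding the top scores is nearly separable
  score2 <- setNames(seq(400, 1), cat$gene_id)
  top_set <- gene_set("top", cat$gene_id[1:30])
  rep2 <- evaluate_gene_set(score2, top_set, cat,
                            matched_set_config(n_sets = 50, seed = 5))
  expect_gt(rep2$summary$mean_auc, 0.95)

  # comparing a score to itself: identical per-set metric vectors, p = 1
  rep3 <- evaluate_gene_set(list(a = score2, b = score2), top_set, cat,
                            matched_set_config(n_sets = 20, seed = 6))
  expect_true(all(rep3$comparisons$p_value > 0.99))
  expect_true(all(rep3$comparisons$q_value >= rep3$comparisons$p_value))
})

test_that("the percentile showcase counts members cumulatively", {
  scores <- setNames(seq(50, 1), sprintf("G%02d", 1:50))
  top1 <- gene_set("t", "G01")
  counts <- percentile_showcase(scores, top1)
  expect_equal(length(counts), 99L)
  expect_true(all(counts == 1L))          # top gene is in from percentile 1
  expect_true(all(diff(counts) >= 0))

  empty <- gene_set("e", character(0))
  expect_equal(percentile_showcase(scores, empty), rep(0L, 99))

  # all genes in the set: counts equal ceiling(p% * N) by construction
  all_set <- gene_set("all", names(scores))
  expect_equal(percentile_showcase(scores, all_set),
               vapply(1:99, function(p) ceiling(p / 100 * 50), numeric(1)),
               ignore_attr = TRUE)
})

test_that("bias profiles recover planted correlation structure", {
  set.seed(29)
  n <- 2000
  genes <- sprintf("G%04d", 1:n)
  pubmed <- setNames(rnbinom(n, size = 0.5, mu = 20) + 0, genes)
  dnds <- setNames(exp(rnorm(n)), genes)
  nv <- setNames(exp(rnorm(n)), genes)

  bp1 <- bias_profile(pubmed, pubmed, dnds, nv)
  expect_equal(bp1$rho_pubmed, 1.0)

  bp2 <- bias_profile(log(dnds + 1), pubmed, dnds, nv)
  expect_equal(bp2$rho_dnds, 1.0)   # Spearman is monotone-invariant

  indep <- setNames(rnorm(n), genes)
  bp3 <- bias_profile(indep, pubmed, dnds, nv)
  expect_lt(max(abs(c(bp3$rho_pubmed, bp3$rho_dnds, bp3$rho_novads))),
            0.08)
  expect_equal(unname(bp3$n_genes["pubmed"]), n)

  # a zero denominator yields an undefined ratio, not infinity
  g4 <- paste0("Z", 1:4)
  idx4 <- setNames(c(1, 2, 3, 4), g4)
  sym4 <- setNames(c(1, 2, 2, 1), g4)   # rank-symmetric: rho exactly 0
  bp4 <- bias_profile(idx4, idx4, sym4, idx4)
  expect_equal(bp4$rho_dnds, 0)
  expect_true(is.na(bp4$ratio_dnds))

  expect_error(bias_profile(indep[1:2], pubmed[1:2], dnds[1:2], nv[1:2]),
               "at least 3")
})
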