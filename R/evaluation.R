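# Gene-set evaluation against coding-sequence-length matched null sets:
# MCC at a top-quantile cutoff, rank-based ROC AUC, Mann-Whitney score
# comparisons, the best-case closed-form expectation for partially causal
# candidate sets, a percentile showcase, and study-bias diagnostics.

#' Matched-set configuration
#'
#' @param n_sets number of matched random sets to draw (default 100).
#' @param candidate_pool_size for each target gene, substitutes are drawn
#'   from this many genes with the closest CDS length (default 100).
#' @param restrict_to_ortholog_genes when `TRUE`, substitutes are drawn
#'   only from genes flagged as having a one-to-one mouse orthologue.
#' @param seed integer seed for the draws.
#' @return a `matched_set_config` list.
#' @export
matched_set_config <- function(n_sets = 100, candidate_pool_size = 100,
                               restrict_to_ortholog_genes = FALSE,
                               seed = 1L) {
  if (n_sets < 1 || candidate_pool_size < 1) {
    stop("n_sets and candidate_pool_size must be >= 1", call. = FALSE)
  }
  structure(list(n_sets = as.integer(n_sets),
                 candidate_pool_size = as.integer(candidate_pool_size),
                 restrict_to_ortholog_genes = restrict_to_ortholog_genes,
                 seed = as.integer(seed)),
            class = "matched_set_config")
}

#' CDS-length-matched random gene sets
#'
#' Builds null gene sets for a target set by substituting each target gene
#' with a random gene of similar coding-sequence length: the universe is
#' ranked by absolute CDS difference to the target gene (ties broken by
#' gene-ID order), the `candidate_pool_size` nearest genes form the pool,
#' and one is drawn uniformly.  Target genes themselves are excluded from
#' the pools; within one random set draws are without replacement, and the
#' sets are independent of each other.
#'
#' @param target a `gene_set`; every member needs a CDS length in the
#'   catalog.
#' @param catalog a `gene_catalog` supplying CDS lengths.
#' @param universe character vector of candidate gene IDs (typically the
#'   score-covered genes, training genes already removed by the caller).
#' @param config a [matched_set_config()].
#' @return a list of `config$n_sets` `gene_set` objects.
#' @export
matched_random_sets <- function(target, catalog, universe,
                                config = matched_set_config()) {
  cds <- stats::setNames(catalog$cds_length, catalog$gene_id)
  t_genes <- target$members
  if (any(is.na(cds[t_genes]))) {
    stop("every target gene needs a CDS length in the catalog",
         call. = FALSE)
  }
  cand <- setdiff(intersect(universe, catalog$gene_id), t_genes)
  if (config$restrict_to_ortholog_genes) {
    ortho <- catalog$gene_id[!is.na(catalog$has_mouse_ortholog) &
                               catalog$has_mouse_ortholog]
    cand <- intersect(cand, ortho)
  }
  cand <- cand[!is.na(cds[cand])]
  if (length(cand) < length(t_genes)) {
    stop("candidate universe too small for the target set", call. = FALSE)
  }
  # per-target-gene candidate pools, precomputed once
  cand <- cand[order(cand)]
  cand_cds <- cds[cand]
  pools <- lapply(t_genes, function(g) {
    d <- abs(cand_cds - cds[[g]])
    ord <- order(d, cand)  # ties broken by gene-ID order
    cand[ord[seq_len(min(config$candidate_pool_size, length(cand)))]]
  })
  set.seed(config$seed)
  lapply(seq_len(config$n_sets), function(s) {
    drawn <- character(length(t_genes))
    for (j in seq_along(t_genes)) {
      avail <- setdiff(pools[[j]], drawn[seq_len(j - 1L)])
      if (length(avail) == 0L) {
        stop("candidate pool exhausted for target gene '", t_genes[j],
             "'; increase candidate_pool_size", call. = FALSE)
      }
      drawn[j] <- if (length(avail) == 1L) avail else sample(avail, 1L)
    }
    gene_set(sprintf("%s_matched_%d", target$name, s), drawn)
  })
}

# deterministic "predicted HIS" membership: the ceiling(fraction * N)
# genes with the highest scores, ties broken by gene-ID order
.top_genes <- function(scores, fraction) {
  ord <- order(-scores, names(scores))
  n_top <- ceiling(fraction * length(scores))
  names(scores)[ord[seq_len(n_top)]]
}

.mcc_from_counts <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Matthews correlation coefficient at a top-score cutoff
#'
#' Genes in the top `top_fraction` of the genome-wide score (cutoff
#' computed over all scored genes, not just the two sets; ties broken by
#' gene ID) are "predicted HIS", all others "predicted HS".  TP are
#' predicted-HIS disease genes, TN predicted-HS random genes, FP
#' predicted-HIS random genes, FN predicted-HS disease genes; the MCC of
#' that table is returned, with the 0 convention when a marginal is empty.
#'
#' @param scores named numeric vector over the scored genome.
#' @param disease,random `gene_set`s covered by `scores`.
#' @param top_fraction fraction of top-scored genes called predicted HIS
#'   (default 0.25).
#' @return MCC in `[-1, 1]`.
#' @export
mcc_at_top_fraction <- function(scores, disease, random,
                                top_fraction = 0.25) {
  if (length(disease$members) == 0L || length(random$members) == 0L) {
    stop("disease and random sets must be non-empty", call. = FALSE)
  }
  miss <- setdiff(c(disease$members, random$members), names(scores))
  if (length(miss) > 0L) {
    stop("gene(s) not covered by the score: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  top <- .top_genes(scores, top_fraction)
  tp <- sum(disease$members %in% top)
  fn <- length(disease$members) - tp
  fp <- sum(random$members %in% top)
  tn <- length(random$members) - fp
  .mcc_from_counts(tp, tn, fp, fn)
}

#' ROC area under the curve
#'
#' Trapezoidal area under the ROC built from the pooled ranking of
#' positive and negative scores; ties contribute one half.  Equals the
#' probability that a random positive outranks a random negative.
#'
#' @param pos_scores,neg_scores non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  n1 <- length(pos_scores); n2 <- length(neg_scores)
  if (n1 == 0L || n2 == 0L) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  r <- rank(c(pos_scores, neg_scores))  # midranks for ties
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Evaluate one or more scores on a disease gene set
#'
#' For each score column, draws CDS-matched random sets from that score's
#' own covered-gene universe, computes the MCC (top-quantile rule) and AUC
#' of the disease set against each matched set, and reports per-set
#' vectors with means and standard errors.  With several score columns,
#' the per-set metric vectors are compared pairwise with two-sided
#' Mann-Whitney tests and Benjamini-Hochberg q-values.
#'
#' @param scores a named numeric vector, or a named list of named numeric
#'   vectors (one per score).
#' @param disease a `gene_set` (training genes already removed by the
#'   caller).
#' @param catalog a `gene_catalog` with CDS lengths.
#' @param config a [matched_set_config()].
#' @param top_fraction cutoff fraction for the MCC (default 0.25).
#' @return an `evaluation_report`: per-score data frame of `mcc`/`auc`
#'   vectors, summary table (`mean_mcc`, `se_mcc`, `mean_auc`, `se_auc`,
#'   `n_genes_used`) and, for several scores, a `comparisons` data frame
#'   of pairwise p- and q-values.
#' @export
evaluate_gene_set <- function(scores, disease, catalog,
                              config = matched_set_config(),
                              top_fraction = 0.25) {
  if (!is.list(scores)) scores <- list(score = scores)
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("score columns must be named", call. = FALSE)
  }
  per_score <- list()
  summaries <- list()
  for (nm in names(scores)) {
    sc <- scores[[nm]]
    covered <- intersect(disease$members, names(sc))
    if (length(covered) == 0L) {
      stop("score '", nm, "' covers no disease gene", call. = FALSE)
    }
    dset <- gene_set(disease$name, covered)
    sets <- matched_random_sets(dset, catalog, names(sc), config)
    mccs <- vapply(sets, function(s) {
      mcc_at_top_fraction(sc, dset, s, top_fraction)
    }, numeric(1))
    aucs <- vapply(sets, function(s) {
      roc_auc(sc[dset$members], sc[s$members])
    }, numeric(1))
    per_score[[nm]] <- data.frame(set = seq_along(sets),
                                  mcc = mccs, auc = aucs)
    summaries[[nm]] <- data.frame(
      score = nm,
      mean_mcc = mean(mccs), se_mcc = stats::sd(mccs) / sqrt(length(mccs)),
      mean_auc = mean(aucs), se_auc = stats::sd(aucs) / sqrt(length(aucs)),
      n_genes_used = length(covered),
      stringsAsFactors = FALSE
    )
  }
  comparisons <- NULL
  if (length(scores) > 1L) {
    pairs <- utils::combn(names(scores), 2L)
    rows <- list()
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      for (metric in c("mcc", "auc")) {
        va <- per_score[[a]][[metric]]
        vb <- per_score[[b]][[metric]]
        # all-tied pooled values leave the rank statistic undefined
        p <- if (stats::sd(c(va, vb)) == 0) 1
             else stats::wilcox.test(va, vb, alternative = "two.sided",
                                     exact = FALSE)$p.value
        rows[[length(rows) + 1L]] <- data.frame(
          score_a = a, score_b = b, metric = metric, p_value = p,
          stringsAsFactors = FALSE)
      }
    }
    comparisons <- do.call(rbind, rows)
    comparisons$q_value <- stats::p.adjust(comparisons$p_value,
                                           method = "BH")
  }
  structure(list(gene_set = disease$name,
                 per_set = per_score,
                 summary = do.call(rbind, c(summaries,
                                            make.row.names = FALSE)),
                 comparisons = comparisons,
                 top_fraction = top_fraction,
                 config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation of gene set '", x$gene_set, "' against ",
      x$config$n_sets, " CDS-matched random sets\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Best-case MCC/AUC expectation for a partially causal candidate set
#'
#' Closed-form expectation when only a fraction of a candidate gene set is
#' truly causal: causal genes always fall in the predicted-HIS top
#' fraction, while non-causal candidates and matched random genes fall
#' there at the background rate `top_fraction`.  The expected contingency
#' rates are `tp = p_causal + (1 - p_causal) * top_fraction`,
#' `fn = 1 - tp`, `fp = top_fraction`, `tn = 1 - top_fraction`; the MCC is
#' evaluated on these rates and the AUC is
#' `p_causal + (1 - p_causal) / 2`.
#'
#' @param p_causal fraction of candidate genes that are truly causal.
#' @param top_fraction predicted-HIS cutoff fraction.
#' @return list with elements `mcc` and `auc`.
#' @export
best_case_expectation <- function(p_causal, top_fraction = 0.25) {
  if (p_causal < 0 || p_causal > 1 ||
      top_fraction <= 0 || top_fraction > 1) {
    stop("p_causal must lie in [0, 1] and top_fraction in (0, 1]",
         call. = FALSE)
  }
  tp <- p_causal + (1 - p_causal) * top_fraction
  fn <- 1 - tp
  fp <- top_fraction
  tn <- 1 - top_fraction
  list(mcc = .mcc_from_counts(tp, tn, fp, fn),
       auc = p_causal + (1 - p_causal) * 0.5)
}

#' Percentile showcase for a small gene set
#'
#' For p = 1, ..., 99, counts how many member genes fall within the top
#' p% of the scored genes (top sets use the same deterministic ranking as
#' [mcc_at_top_fraction()]).  The result is cumulative, hence monotone
#' non-decreasing.
#'
#' @param scores named numeric vector over the scored genome.
#' @param genes a `gene_set` covered by `scores`.
#' @return integer vector of length 99.
#' @export
percentile_showcase <- function(scores, genes) {
  miss <- setdiff(genes$members, names(scores))
  if (length(miss) > 0L) {
    stop("gene(s) not covered by the score: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  ord <- order(-scores, names(scores))
  ranked <- names(scores)[ord]
  pos <- match(genes$members, ranked)
  n <- length(scores)
  vapply(1:99, function(p) sum(pos <= ceiling(p / 100 * n)), integer(1))
}

#' Study-bias profile of a gene index
#'
#' Spearman correlations (midrank ties, pairwise-complete overlap per
#' pair) of an index with per-gene publication counts, dN/dS and NoVaDs,
#' plus the two absolute ratios |rho(pubmed)/rho(dN/dS)| and
#' |rho(pubmed)/rho(NoVaDs)|.  A large ratio marks an index that tracks
#' how well-studied genes are more strongly than genuine constraint.
#'
#' @param index named numeric vector (the score or network statistic under
#'   scrutiny).
#' @param pubmed,dnds,novads named numeric vectors of the per-gene
#'   covariates.
#' @param name label for the index.
#' @return a `bias_profile` list with the three correlations, the two
#'   ratios (`NA` when a denominator correlation is 0) and per-pair
#'   overlap sizes.
#' @export
bias_profile <- function(index, pubmed, dnds, novads, name = "index") {
  one_cor <- function(covariate) {
    shared <- intersect(names(index), names(covariate))
    x <- index[shared]; y <- covariate[shared]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) {
      stop("need at least 3 overlapping genes per covariate pair",
           call. = FALSE)
    }
    list(rho = stats::cor(x[ok], y[ok], method = "spearman"),
         n = sum(ok))
  }
  cp <- one_cor(pubmed); cd <- one_cor(dnds); cn <- one_cor(novads)
  ratio <- function(num, den) if (den == 0) NA_real_ else abs(num / den)
  structure(list(name = name,
                 rho_pubmed = cp$rho, rho_dnds = cd$rho,
                 rho_novads = cn$rho,
                 ratio_dnds = ratio(cp$rho, cd$rho),
                 ratio_novads = ratio(cp$rho, cn$rho),
                 n_genes = c(pubmed = cp$n, dnds = cd$n, novads = cn$n)),
            class = "bias_profile")
}

#' @export
print.bias_profile <- function(x, ...) {
  cat("bias profile for '", x$name, "':\n", sep = "")
  cat(sprintf("  rho(pubmed) = %.3f  rho(dN/dS) = %.3f  rho(NoVaDs) = %.3f\n",
              x$rho_pubmed, x$rho_dnds, x$rho_novads))
  cat(sprintf("  |rho(pubmed)/rho(dN/dS)| = %s  |rho(pubmed)/rho(NoVaDs)| = %s\n",
              format(x$ratio_dnds, digits = 3),
              format(x$ratio_novads, digits = 3)))
  invisible(x)
}
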