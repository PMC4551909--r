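# The subsampled-SVM ensemble behind the genome-wide haploinsufficiency
# score (GHIS).  Known haploinsufficient (HIS) training genes are paired
# with an equal-size subsample of the much larger haplosufficient (HS)
# pool; a linear SVM is cross-validated on the balanced set, refit on all
# of it, and used to predict a calibrated HIS probability for every gene.
# Randomizations whose cross-validated AUC does not exceed 0.5 are
# dropped, and the per-gene GHIS is the mean predicted probability over
# the kept randomizations.

#' Training configuration for the GHIS ensemble
#'
#' @param n_randomizations number of HS subsampling randomizations
#'   (default 100).
#' @param cv_repeats number of 90/10 cross-validation splits per
#'   randomization (default 30).
#' @param test_fraction held-out fraction per split (default 0.10).
#' @param auc_keep_threshold randomizations are kept iff their
#'   cross-validated AUC is strictly greater than this (default 0.5).
#' @param kernel SVM kernel, `"linear"` (default) or `"radial"`.
#' @param cost SVM cost parameter (default 1).
#' @param cv_mode `"random_split"` (default; `cv_repeats` independent
#'   class-stratified 90/10 splits plus a coverage pass so every training
#'   gene has at least one held-out prediction) or `"kfold"` (strict
#'   stratified 10-fold partitions, `cv_repeats / 10` of them).
#' @param seed integer seed; every randomization derives its own child
#'   stream from `(seed, index)` so the ensemble is reproducible.
#' @return a `training_config` list.
#' @export
training_config <- function(n_randomizations = 100, cv_repeats = 30,
                            test_fraction = 0.10,
                            auc_keep_threshold = 0.5,
                            kernel = c("linear", "radial"), cost = 1,
                            cv_mode = c("random_split", "kfold"),
                            seed = 1L) {
  kernel <- match.arg(kernel)
  cv_mode <- match.arg(cv_mode)
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (n_randomizations < 1) {
    stop("n_randomizations must be >= 1", call. = FALSE)
  }
  if (cost <= 0) stop("cost must be positive", call. = FALSE)
  structure(list(n_randomizations = as.integer(n_randomizations),
                 cv_repeats = as.integer(cv_repeats),
                 test_fraction = test_fraction,
                 auc_keep_threshold = auc_keep_threshold,
                 kernel = kernel, cost = cost, cv_mode = cv_mode,
                 seed = as.integer(seed)),
            class = "training_config")
}

# deterministic child seed for randomization i, kept below 2^31
.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 1299721) %%
               2147483647)
}

.standardization <- function(train_mat) {
  center <- colMeans(train_mat)
  scale <- apply(train_mat, 2L, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  list(center = center, scale = scale)
}

.apply_standardization <- function(mat, std) {
  sweep(sweep(mat, 2L, std$center, "-"), 2L, std$scale, "/")
}

# fit on the (already standardized) training matrix and return predicted
# HIS probabilities for x_new; zero-variance features carry no information
# and are dropped, and with no informative feature at all every gene gets
# the training-set HIS prior (ties by construction)
.fit_predict_prob <- function(x_train, y, x_new, config) {
  keep <- apply(x_train, 2L, stats::sd) > 0
  if (!any(keep)) {
    # the ensemble's training sets are balanced HIS/HS by construction,
    # so the uninformative prediction is one half for every gene
    return(rep(0.5, nrow(x_new)))
  }
  fit <- e1071::svm(x = x_train[, keep, drop = FALSE], y = y,
                    kernel = config$kernel, cost = config$cost,
                    scale = FALSE, probability = TRUE)
  p <- stats::predict(fit, x_new[, keep, drop = FALSE],
                      probability = TRUE)
  unname(attr(p, "probabilities")[, "HIS"])
}

#' Subsample the haplosufficient gene pool
#'
#' Draws a uniform without-replacement subsample of the HS pool, matching
#' the HIS training set size, after checking the pools are disjoint.
#'
#' @param hs_pool a `gene_set` of haplosufficient genes.
#' @param n subsample size.
#' @param his optional `gene_set` of HIS training genes; overlap with the
#'   pool is an error.
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return a `gene_set` named after the pool.
#' @export
subsample_hs <- function(hs_pool, n, his = NULL, seed = NULL) {
  if (!is.null(his)) {
    overlap <- intersect(hs_pool$members, his$members)
    if (length(overlap) > 0L) {
      stop("HIS and HS pools overlap: ",
           paste(utils::head(overlap, 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  if (n > length(hs_pool$members)) {
    stop("cannot draw ", n, " genes from a pool of ",
         length(hs_pool$members), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  gene_set(paste0(hs_pool$name, "_subsample"),
           sample(hs_pool$members, n))
}

.stratified_test_idx <- function(labels, test_fraction) {
  idx <- integer(0)
  for (lv in levels(labels)) {
    cls <- which(labels == lv)
    n_test <- max(1L, round(length(cls) * test_fraction))
    idx <- c(idx, sample(cls, n_test))
  }
  idx
}

#' One randomization's cross-validated AUC
#'
#' Repeatedly splits the balanced HIS/HS training set into class-stratified
#' 90/10 train/test parts, fits the SVM on the training part (features
#' standardized on that part's statistics), and records the held-out
#' predicted HIS probability.  Each gene's held-out predictions are
#' averaged over the repeats in which it was tested; genes never held out
#' receive one dedicated held-out prediction.  A single ROC AUC is computed
#' on the averaged values with HIS as the positive class.
#'
#' @param features a `feature_matrix` or numeric matrix with gene
#'   rownames.
#' @param his `gene_set` of HIS training genes.
#' @param hs_sub `gene_set` of the HS subsample (same size as `his`).
#' @param config a [training_config()].
#' @param seed optional seed; when `NULL` the current RNG state is used.
#' @return a list with `cv_auc` and the per-gene averaged held-out
#'   `predictions`.
#' @export
cross_validate_once <- function(features, his, hs_sub, config,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mat <- if (inherits(features, "feature_matrix")) feature_values(features)
         else features
  genes <- c(his$members, hs_sub$members)
  miss <- setdiff(genes, rownames(mat))
  if (length(miss) > 0L) {
    stop("training genes absent from the feature matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  x <- mat[genes, , drop = FALSE]
  y <- factor(c(rep("HIS", length(his$members)),
                rep("HS", length(hs_sub$members))),
              levels = c("HIS", "HS"))
  n <- length(genes)
  pred_sum <- stats::setNames(rep(0, n), genes)
  pred_n <- stats::setNames(rep(0L, n), genes)

  run_split <- function(test_idx) {
    train_idx <- setdiff(seq_len(n), test_idx)
    if (length(unique(y[train_idx])) < 2L) return(FALSE)
    std <- .standardization(x[train_idx, , drop = FALSE])
    p <- .fit_predict_prob(
      .apply_standardization(x[train_idx, , drop = FALSE], std),
      y[train_idx],
      .apply_standardization(x[test_idx, , drop = FALSE], std),
      config)
    pred_sum[test_idx] <<- pred_sum[test_idx] + p
    pred_n[test_idx] <<- pred_n[test_idx] + 1L
    TRUE
  }

  if (config$cv_mode == "kfold") {
    n_folds <- max(2L, round(1 / config$test_fraction))
    n_rounds <- max(1L, round(config$cv_repeats / n_folds))
    for (round_i in seq_len(n_rounds)) {
      fold <- integer(n)
      for (lv in levels(y)) {
        cls <- which(y == lv)
        fold[cls] <- sample(rep_len(seq_len(n_folds), length(cls)))
      }
      for (k in seq_len(n_folds)) run_split(which(fold == k))
    }
  } else {
    for (rep_i in seq_len(config$cv_repeats)) {
      for (try_i in 1:10) {
        if (run_split(.stratified_test_idx(y, config$test_fraction)))
          break
      }
    }
  }
  uncovered <- which(pred_n == 0L)
  if (length(uncovered) > 0L && length(uncovered) < n) {
    run_split(uncovered)
  }
  avg <- pred_sum / pmax(pred_n, 1L)
  auc <- roc_auc(avg[y == "HIS"], avg[y == "HS"])
  list(cv_auc = auc, predictions = avg)
}

#' Train the genome-wide haploinsufficiency score
#'
#' Runs `n_randomizations` rounds of: subsample the HS pool to the HIS
#' set's size, cross-validate a linear SVM on the balanced set, refit on
#' all of it (features standardized to the balanced set's mean/variance,
#' applied identically genome-wide) and predict a calibrated HIS
#' probability for every gene in the feature universe.  The final GHIS is
#' the per-gene mean over the randomizations whose cross-validated AUC
#' strictly exceeds the keep threshold.
#'
#' @param features a `feature_matrix` or numeric matrix with gene rownames
#'   covering the training genes and the genome-wide targets.
#' @param his `gene_set` of HIS training genes.
#' @param hs_pool `gene_set` of haplosufficient genes (disjoint from
#'   `his`).
#' @param config a [training_config()].
#' @return a `ghis_result`: list with `scores` (named per-gene GHIS in
#'   [0, 1]), `records` (per-randomization `index`, `cv_auc`, `kept`),
#'   `genomewide` (genes x randomizations prediction matrix), `n_kept`
#'   and `config`.
#' @export
train_ghis <- function(features, his, hs_pool, config = training_config()) {
  mat <- if (inherits(features, "feature_matrix")) feature_values(features)
         else features
  overlap <- intersect(his$members, hs_pool$members)
  if (length(overlap) > 0L) {
    stop("HIS and HS pools overlap: ",
         paste(utils::head(overlap, 5L), collapse = ", "), call. = FALSE)
  }
  n_his <- length(his$members)
  genomewide <- matrix(NA_real_, nrow = nrow(mat),
                       ncol = config$n_randomizations,
                       dimnames = list(rownames(mat), NULL))
  cv_auc <- numeric(config$n_randomizations)
  for (i in seq_len(config$n_randomizations)) {
    set.seed(.child_seed(config$seed, i))
    hs_sub <- subsample_hs(hs_pool, n_his, his = his)
    cv <- cross_validate_once(mat, his, hs_sub, config)
    cv_auc[i] <- cv$cv_auc
    train_genes <- c(his$members, hs_sub$members)
    x_train <- mat[train_genes, , drop = FALSE]
    y <- factor(c(rep("HIS", n_his), rep("HS", n_his)),
                levels = c("HIS", "HS"))
    std <- .standardization(x_train)
    genomewide[, i] <- .fit_predict_prob(
      .apply_standardization(x_train, std), y,
      .apply_standardization(mat, std), config)
  }
  kept <- cv_auc > config$auc_keep_threshold
  if (!any(kept)) {
    stop("no randomization exceeded the AUC keep threshold (",
         config$auc_keep_threshold,
         "); the features may carry no signal, or try another seed",
         call. = FALSE)
  }
  scores <- rowMeans(genomewide[, kept, drop = FALSE])
  structure(list(
    scores = scores,
    records = data.frame(index = seq_len(config$n_randomizations),
                         cv_auc = cv_auc, kept = kept),
    genomewide = genomewide,
    n_kept = sum(kept),
    config = config
  ), class = "ghis_result")
}

#' @export
print.ghis_result <- function(x, ...) {
  cat("ghis_result:", length(x$scores), "genes;",
      x$n_kept, "of", nrow(x$records),
      "randomizations kept (mean CV AUC",
      sprintf("%.3f", mean(x$records$cv_auc)), ")\n")
  invisible(x)
}

#' Spearman stability between two score runs
#'
#' @param result_a,result_b `ghis_result` objects or named score vectors
#'   over the same gene universe.
#' @return Spearman correlation over the shared genes.
#' @export
score_stability <- function(result_a, result_b) {
  a <- if (inherits(result_a, "ghis_result")) result_a$scores else result_a
  b <- if (inherits(result_b, "ghis_result")) result_b$scores else result_b
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) {
    stop("need at least 3 shared genes", call. = FALSE)
  }
  stats::cor(a[shared], b[shared], method = "spearman")
}
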