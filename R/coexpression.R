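# Thresholded co-expression networks and proximity to a seed set of known
# haploinsufficient genes.
#
# Genes expressed below 1 RPKM in more than 95% of samples are removed,
# pairwise (optionally weighted) Pearson correlations are computed, and
# links with signed r >= 0.3 are kept.  A gene's proximity to the seed set
# is the sum of its 20 strongest link weights to seed members.

#' Co-expression network configuration
#'
#' @param correlation_threshold minimum signed Pearson correlation for a
#'   link to be kept (default 0.3; negative correlations are excluded).
#' @param top_k number of strongest seed links summed into the proximity
#'   (default 20).
#' @param low_expression_rpkm expression level below which a sample counts
#'   as "not expressed" (default 1).
#' @param low_expression_fraction a gene is removed when strictly more than
#'   this fraction of samples is below `low_expression_rpkm`
#'   (default 0.95).
#' @return a `network_config` list.
#' @export
network_config <- function(correlation_threshold = 0.3, top_k = 20,
                           low_expression_rpkm = 1,
                           low_expression_fraction = 0.95) {
  if (!(correlation_threshold > 0 && correlation_threshold <= 1)) {
    stop("correlation_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  structure(list(correlation_threshold = correlation_threshold,
                 top_k = as.integer(top_k),
                 low_expression_rpkm = low_expression_rpkm,
                 low_expression_fraction = low_expression_fraction),
            class = "network_config")
}

#' Remove genes with negligible expression
#'
#' Drops genes whose expression is below `low_expression_rpkm` in strictly
#' more than `low_expression_fraction` of the samples.
#'
#' @param matrix genes-by-samples numeric matrix.
#' @param config a [network_config()].
#' @return the filtered matrix.
#' @export
filter_low_expression <- function(matrix, config = network_config()) {
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) {
    stop("expression matrix is empty", call. = FALSE)
  }
  frac_low <- rowMeans(matrix < config$low_expression_rpkm)
  keep <- frac_low <= config$low_expression_fraction
  if (!any(keep)) {
    stop("all genes removed by the low-expression filter", call. = FALSE)
  }
  matrix[keep, , drop = FALSE]
}

#' Weighted Pearson correlation
#'
#' Pearson correlation with per-sample weights: means, variances and the
#' covariance are all weighted.  Uniform weights reduce exactly to the
#' plain Pearson correlation.
#'
#' @param x,y numeric sample vectors of equal length (>= 3).
#' @param w positive sample weights; default uniform.
#' @return correlation in `[-1, 1]`, or `NA` if either vector has zero
#'   weighted variance.
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  if (length(x) != length(y) || length(x) != length(w)) {
    stop("x, y and w must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  cxy <- sum(w * (x - mx) * (y - my))
  max(-1, min(1, cxy / sqrt(vx * vy)))
}

# full weighted correlation matrix; genes in rows
.weighted_cor_matrix <- function(matrix, w) {
  w <- w / sum(w)
  mu <- as.vector(matrix %*% w)
  xc <- matrix - mu
  xw <- sweep(xc, 2L, sqrt(w), "*")
  cov <- tcrossprod(xw)
  sd <- sqrt(diag(cov))
  r <- cov / outer(sd, sd)
  r <- pmin(pmax(r, -1), 1)
  r[sd == 0, ] <- NA_real_
  r[, sd == 0] <- NA_real_
  r
}

#' Build a thresholded co-expression network
#'
#' Computes all pairwise (weighted) Pearson correlations between genes and
#' keeps links with signed correlation at or above the threshold.  Genes
#' with zero expression variance yield no links; the number of skipped
#' undefined correlations is recorded in attribute `n_undefined`.
#'
#' @param matrix genes-by-samples numeric matrix (already filtered with
#'   [filter_low_expression()]).
#' @param config a [network_config()].
#' @param sample_weights optional positive per-sample weights (default
#'   uniform, i.e. plain Pearson).
#' @return an `edge_list` of unique undirected links.
#' @export
build_network <- function(matrix, config = network_config(),
                          sample_weights = NULL) {
  if (nrow(matrix) < 2L) {
    out <- edge_list(character(0), character(0), numeric(0))
    attr(out, "n_undefined") <- 0L
    return(out)
  }
  if (is.null(sample_weights)) sample_weights <- rep(1, ncol(matrix))
  if (length(sample_weights) != ncol(matrix) || any(sample_weights <= 0)) {
    stop("sample_weights must be positive and one per sample",
         call. = FALSE)
  }
  r <- .weighted_cor_matrix(matrix, sample_weights)
  ut <- upper.tri(r)
  n_undef <- sum(is.na(r[ut]))
  hit <- which(ut & !is.na(r) & r >= config$correlation_threshold,
               arr.ind = TRUE)
  genes <- rownames(matrix)
  out <- edge_list(genes[hit[, 1L]], genes[hit[, 2L]],
                   r[hit])
  attr(out, "n_undefined") <- n_undef
  out
}

#' Proximity of each gene to a seed set in a co-expression network
#'
#' For every gene appearing in the edge list, its link weights to seed-set
#' members are sorted in decreasing order and the strongest `top_k` (or all,
#' if fewer) are summed.  Seed genes' links to other seed members count;
#' self-links do not exist by construction.  Genes with no seed links get
#' proximity 0.
#'
#' @param edges an `edge_list`.
#' @param seed a `gene_set` of known haploinsufficient genes.
#' @param config a [network_config()].
#' @return a data frame `gene_id`, `proximity`, `n_his_links` covering all
#'   genes incident to at least one edge.
#' @export
proximity_to_his <- function(edges, seed, config = network_config()) {
  if (length(seed$members) == 0L) {
    stop("seed gene set is empty", call. = FALSE)
  }
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  a_seed <- edges$gene_a %in% seed$members
  b_seed <- edges$gene_b %in% seed$members
  # a link contributes to a gene when its *other* endpoint is a seed member
  long_gene <- c(edges$gene_a[b_seed], edges$gene_b[a_seed])
  long_wt <- c(edges$weight[b_seed], edges$weight[a_seed])
  k <- config$top_k
  prox <- rep(0, length(genes))
  nlinks <- rep(0L, length(genes))
  if (length(long_gene) > 0L) {
    f <- factor(long_gene, levels = genes)
    sums <- tapply(long_wt, f, function(w) {
      sum(sort(w, decreasing = TRUE)[seq_len(min(k, length(w)))])
    })
    cnts <- tapply(long_wt, f, length)
    hit <- !is.na(sums)
    prox[hit] <- sums[hit]
    nlinks[hit] <- as.integer(cnts[hit])
  }
  data.frame(gene_id = genes, proximity = prox, n_his_links = nlinks,
             stringsAsFactors = FALSE)
}
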