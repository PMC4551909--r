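# The five-feature matrix behind the haploinsufficiency score: proximity
# to known-HIS genes in two co-expression networks, NoVaDs, dN/dS and the
# fetal-to-adult (F2A) expression ratio.  Missing values are imputed with
# fixed rules: 0 for network proximities (absence from a network means no
# measured co-expression), the median for NoVaDs and dN/dS, the mean for
# F2A; every imputed cell is flagged and the constants are recorded.

#' dN/dS evolutionary-constraint ratio
#'
#' Ratio of non-synonymous to synonymous substitution rates against a
#' one-to-one orthologue.  A rate of exactly 0 is replaced by 0.001 before
#' division so the ratio stays finite and positive.  `NA` inputs propagate
#' (the gene's constraint is unknown, imputed downstream).
#'
#' @param dn,ds non-negative numeric vectors.
#' @return numeric vector of ratios.
#' @export
dnds_ratio <- function(dn, ds) {
  if (any(dn < 0, na.rm = TRUE) || any(ds < 0, na.rm = TRUE)) {
    stop("dn and ds must be non-negative", call. = FALSE)
  }
  dn <- ifelse(!is.na(dn) & dn == 0, 0.001, dn)
  ds <- ifelse(!is.na(ds) & ds == 0, 0.001, ds)
  dn / ds
}

#' Fetal/adult tissue partition
#'
#' @param fetal_samples,adult_samples disjoint non-empty character vectors
#'   of sample identifiers.
#' @return a `tissue_partition` list.
#' @export
tissue_partition <- function(fetal_samples, adult_samples) {
  fetal_samples <- as.character(fetal_samples)
  adult_samples <- as.character(adult_samples)
  if (length(fetal_samples) == 0L || length(adult_samples) == 0L) {
    stop("both tissue groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(fetal_samples, adult_samples)) > 0L) {
    stop("fetal and adult sample lists must be disjoint", call. = FALSE)
  }
  structure(list(fetal_samples = fetal_samples,
                 adult_samples = adult_samples),
            class = "tissue_partition")
}

#' Fetal-to-adult expression ratio (F2A)
#'
#' Median expression across the fetal samples divided by the median across
#' the adult samples, per gene.  Genes whose adult median is 0 get `NA`
#' (mean-imputed downstream) rather than infinity.
#'
#' @param matrix genes-by-samples expression matrix.
#' @param partition a [tissue_partition()]; all its samples must be columns
#'   of `matrix`.
#' @return named numeric vector over the matrix's genes.
#' @export
f2a_ratio <- function(matrix, partition) {
  miss <- setdiff(c(partition$fetal_samples, partition$adult_samples),
                  colnames(matrix))
  if (length(miss) > 0L) {
    stop("partition samples absent from the matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  med_f <- apply(matrix[, partition$fetal_samples, drop = FALSE], 1L,
                 stats::median)
  med_a <- apply(matrix[, partition$adult_samples, drop = FALSE], 1L,
                 stats::median)
  out <- ifelse(med_a == 0, NA_real_, med_f / med_a)
  names(out) <- rownames(matrix)
  out
}

.feature_lookup <- function(universe, ids, values) {
  out <- rep(NA_real_, length(universe))
  idx <- match(universe, ids)
  hit <- !is.na(idx)
  out[hit] <- values[idx[hit]]
  out
}

#' Assemble the five-feature matrix
#'
#' Joins the feature sources over the catalog's gene universe and applies
#' the imputation rules: missing co-expression proximities become 0,
#' missing NoVaDs and dN/dS become the median over genes where the feature
#' is observed, missing F2A becomes the mean.  Imputation statistics are
#' computed over the full catalog universe before imputation and recorded
#' in the `imputation` attribute; the `imputed` attribute is a per-cell
#' logical mask.
#'
#' @param catalog a `gene_catalog` (defines the gene universe and supplies
#'   dN and dS).
#' @param prox_a,prox_b proximity tables from [proximity_to_his()] for the
#'   two co-expression networks.
#' @param intolerance a data frame with columns `gene_id` and `novads`
#'   (e.g. from [novads_panel()]).
#' @param f2a named numeric vector from [f2a_ratio()].
#' @return a `feature_matrix` data frame: `gene_id`, `coexpr_prox_a`,
#'   `coexpr_prox_b`, `novads`, `dnds`, `f2a`, with attributes `imputed`
#'   (logical matrix) and `imputation` (named list of constants).
#' @export
assemble_features <- function(catalog, prox_a, prox_b, intolerance, f2a) {
  universe <- catalog$gene_id
  raw <- data.frame(
    gene_id = universe,
    coexpr_prox_a = .feature_lookup(universe, prox_a$gene_id,
                                    prox_a$proximity),
    coexpr_prox_b = .feature_lookup(universe, prox_b$gene_id,
                                    prox_b$proximity),
    novads = .feature_lookup(universe, intolerance$gene_id,
                             intolerance$novads),
    dnds = dnds_ratio(catalog$dn, catalog$ds),
    f2a = .feature_lookup(universe, names(f2a), unname(f2a)),
    stringsAsFactors = FALSE
  )
  feats <- c("coexpr_prox_a", "coexpr_prox_b", "novads", "dnds", "f2a")
  all_missing <- feats[vapply(feats,
                              function(f) all(is.na(raw[[f]])), logical(1))]
  if (length(all_missing) > 0L) {
    stop("feature(s) missing for every gene: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  constants <- list(
    coexpr_prox_a = 0,
    coexpr_prox_b = 0,
    novads = stats::median(raw$novads, na.rm = TRUE),
    dnds = stats::median(raw$dnds, na.rm = TRUE),
    f2a = mean(raw$f2a, na.rm = TRUE)
  )
  imputed <- is.na(as.matrix(raw[, feats]))
  rownames(imputed) <- universe
  out <- raw
  for (f in feats) {
    out[[f]][is.na(out[[f]])] <- constants[[f]]
  }
  attr(out, "imputed") <- imputed
  attr(out, "imputation") <- constants
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Extract the numeric feature columns of a feature matrix
#' @param features a `feature_matrix`.
#' @return numeric matrix with gene rownames.
#' @export
feature_values <- function(features) {
  m <- as.matrix(features[, c("coexpr_prox_a", "coexpr_prox_b",
                              "novads", "dnds", "f2a")])
  rownames(m) <- features$gene_id
  m
}
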