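# Variant classification and per-gene intolerance scores.
#
# Variants are dichotomized at a minor-allele-frequency cutoff (default
# 0.1%): MAF <= cutoff is "rare", MAF > cutoff is "common".  Functional
# classes follow the annotation vocabulary of the exome-server call sets.
# NoVaDs (non-synonymous variation depletion score) is the ratio of common
# to rare non-synonymous variant counts in a gene: purifying selection
# against functional variation keeps such variants rare, so depleted
# (intolerant) genes have low NoVaDs.  The reference RVIS is the
# studentized residual from regressing the common non-synonymous count on
# the total variant count.

.NONSYN_LABELS <- c("missense", "missense-near-splice",
                    "splice-3", "splice-5",
                    "stop-gained", "stop-gained-near-splice",
                    "stop-lost", "stop-lost-near-splice")
.SYN_LABELS <- c("coding-synonymous", "coding-synonymous-near-splice")

#' Variant classification configuration
#'
#' @param common_maf_cutoff MAF above which a variant is "common" (a
#'   fraction; the boundary value itself classifies as rare).
#' @param nonsyn_labels annotation labels treated as non-synonymous.
#' @param syn_labels annotation labels treated as synonymous.
#' @return a `variant_class_config` list.
#' @export
variant_class_config <- function(common_maf_cutoff = 0.001,
                                 nonsyn_labels = .NONSYN_LABELS,
                                 syn_labels = .SYN_LABELS) {
  if (!(common_maf_cutoff > 0 && common_maf_cutoff < 0.5)) {
    stop("common_maf_cutoff must lie in (0, 0.5)", call. = FALSE)
  }
  if (length(intersect(nonsyn_labels, syn_labels)) > 0L) {
    stop("nonsyn_labels and syn_labels must be disjoint", call. = FALSE)
  }
  structure(list(common_maf_cutoff = common_maf_cutoff,
                 nonsyn_labels = nonsyn_labels,
                 syn_labels = syn_labels),
            class = "variant_class_config")
}

#' Classify variants into frequency-by-function classes
#'
#' @param annotation character vector of annotation labels.
#' @param maf numeric vector of minor allele frequencies.
#' @param config a [variant_class_config()].
#' @return character vector over `{common_nonsyn, rare_nonsyn, common_syn,
#'   rare_syn, other}`.
#' @export
classify_variant <- function(annotation, maf,
                             config = variant_class_config()) {
  common <- maf > config$common_maf_cutoff
  out <- rep("other", length(annotation))
  ns <- annotation %in% config$nonsyn_labels
  sy <- annotation %in% config$syn_labels
  out[ns & common] <- "common_nonsyn"
  out[ns & !common] <- "rare_nonsyn"
  out[sy & common] <- "common_syn"
  out[sy & !common] <- "rare_syn"
  out
}

#' Count variant classes per gene
#'
#' Aggregates a QC-passed variant table into per-gene class counts.
#' `n_total` counts every variant in the gene regardless of class, so
#' intronic/UTR records contribute to the total used by the RVIS
#' regression.
#'
#' @param table a `variant_table`.
#' @param config a [variant_class_config()].
#' @return a data frame with one row per gene present in the table:
#'   `gene_id`, `n_common_nonsyn`, `n_rare_nonsyn`, `n_common_syn`,
#'   `n_rare_syn`, `n_total`.
#' @export
count_by_gene <- function(table, config = variant_class_config()) {
  if (nrow(table) == 0L) {
    out <- data.frame(gene_id = character(0), n_common_nonsyn = integer(0),
                      n_rare_nonsyn = integer(0), n_common_syn = integer(0),
                      n_rare_syn = integer(0), n_total = integer(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  cls <- classify_variant(table$annotation, table$maf, config)
  genes <- sort(unique(table$gene_id))
  f <- factor(table$gene_id, levels = genes)
  count_class <- function(label) {
    as.integer(tapply(cls == label, f, sum, default = 0L))
  }
  data.frame(
    gene_id = genes,
    n_common_nonsyn = count_class("common_nonsyn"),
    n_rare_nonsyn = count_class("rare_nonsyn"),
    n_common_syn = count_class("common_syn"),
    n_rare_syn = count_class("rare_syn"),
    n_total = as.integer(tabulate(f, nbins = length(genes))),
    stringsAsFactors = FALSE
  )
}

#' Non-synonymous variation depletion score (NoVaDs)
#'
#' The ratio of common to rare non-synonymous variant counts per gene.
#' Genes with no rare non-synonymous variants get `NA` (the ratio is
#' undefined there; median imputation applies downstream at feature
#' assembly), not infinity.
#'
#' @param counts a per-gene count table from [count_by_gene()].
#' @return numeric vector aligned with `counts` rows.
#' @export
novads <- function(counts) {
  ifelse(counts$n_rare_nonsyn == 0, NA_real_,
         counts$n_common_nonsyn / counts$n_rare_nonsyn)
}

#' Residual variation intolerance score (RVIS)
#'
#' Ordinary least squares of the common non-synonymous variant count on the
#' total variant count (with intercept), returning internally studentized
#' residuals.  Genes with no variants (`n_total == 0`) get `NA`.
#'
#' @param counts a per-gene count table from [count_by_gene()].
#' @return numeric vector aligned with `counts` rows.
#' @export
rvis <- function(counts) {
  use <- counts$n_total > 0
  if (sum(use) < 3L) {
    stop("rvis needs at least 3 genes with n_total > 0", call. = FALSE)
  }
  x <- counts$n_total[use]
  y <- counts$n_common_nonsyn[use]
  if (stats::var(x) == 0) {
    stop("rvis: total variant counts have zero variance; ",
         "the regression is degenerate", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  out <- rep(NA_real_, nrow(counts))
  sigma <- stats::sigma(fit)
  # an (all but) exact fit has no residual variance to studentize against
  out[use] <- if (sigma <= 1e-10 * (1 + max(abs(y)))) 0
              else stats::rstandard(fit)
  out
}

.novads_column_name <- function(cutoff) {
  pct <- cutoff * 100
  paste0("novads_", format(pct, scientific = FALSE, trim = TRUE), "pct")
}

#' Per-gene intolerance score panel
#'
#' Counts variant classes per gene at the primary MAF cutoff and computes
#' NoVaDs, the reference RVIS, and optional NoVaDs variants at alternative
#' common-variant cutoffs (classification is redone per cutoff; e.g. 0.01
#' yields a `novads_1pct` column).
#'
#' @param table a `variant_table`.
#' @param cutoffs numeric vector of additional common-variant MAF cutoffs
#'   (fractions in (0, 0.5)); may be empty.
#' @param config a [variant_class_config()] giving the primary cutoff and
#'   label sets.
#' @return a data frame with per-gene counts, `novads`, one
#'   `novads_<pct>pct` column per extra cutoff, and `rvis`.
#' @export
novads_panel <- function(table, cutoffs = numeric(0),
                         config = variant_class_config()) {
  cutoffs <- as.numeric(cutoffs)
  if (anyDuplicated(cutoffs)) {
    stop("duplicate cutoffs are not allowed", call. = FALSE)
  }
  if (length(cutoffs) > 0L && any(cutoffs <= 0 | cutoffs >= 0.5)) {
    stop("cutoffs must lie in (0, 0.5)", call. = FALSE)
  }
  counts <- count_by_gene(table, config)
  out <- counts
  out$novads <- novads(counts)
  for (cut in cutoffs) {
    cfg <- variant_class_config(common_maf_cutoff = cut,
                                nonsyn_labels = config$nonsyn_labels,
                                syn_labels = config$syn_labels)
    cnt <- count_by_gene(table, cfg)
    stopifnot(identical(cnt$gene_id, counts$gene_id))
    out[[.novads_column_name(cut)]] <- novads(cnt)
  }
  out$rvis <- if (nrow(counts) >= 3L && sum(counts$n_total > 0) >= 3L &&
                  stats::var(counts$n_total[counts$n_total > 0]) > 0) {
    rvis(counts)
  } else rep(NA_real_, nrow(counts))
  out
}
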