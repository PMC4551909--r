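# Self-contained synthetic cohorts with the statistical structure the
# scoring method assumes: coding-sequence lengths are log-normal, variant
# counts are Poisson in proportion to CDS, haploinsufficient (HIS) genes
# are depleted of common non-synonymous variation, co-expressed with each
# other through a shared latent factor, under stronger evolutionary
# constraint (lower dN/dS) and relatively more fetally expressed.  Also
# provides the CDS-bias null simulation for the RVIS, in which each gene's
# common non-synonymous proportion is drawn independently of CDS.

#' Synthetic cohort configuration
#'
#' Effect directions are fixed by construction: HIS genes get a *lower*
#' common-variant rate (factor `depletion_effect` < 1), lower dN/dS
#' (log-scale shift `-dnds_shift`), higher fetal expression (log-scale
#' shift `+f2a_shift`) and mutual co-expression of strength
#' `coexpr_module_strength`.  Setting `depletion_effect = 1` and the other
#' effects to 0 yields a signal-free null cohort.
#'
#' @param n_genes number of genes (default 2000).
#' @param frac_his fraction of genes that are truly HIS (default 0.05).
#' @param n_samples_expr samples in the second (RNA-seq-like) expression
#'   matrix (default 60); the first (atlas-like) matrix always has 4 fetal
#'   plus 31 adult samples.
#' @param variants_per_kb expected QC-pass variants per kilobase of CDS
#'   (default 20, giving a few dozen variants for a typical gene — the
#'   scale of a several-thousand-exome call set).
#' @param cds_lognormal_params `c(mu, sigma)` of the log CDS length
#'   (default `c(7.3, 0.6)`, median about 1.5 kb).
#' @param p_common baseline probability that a variant is common
#'   (default 0.3).
#' @param depletion_effect multiplier (< 1) on the common probability for
#'   non-synonymous variants in HIS genes (default 0.4).
#' @param coexpr_module_strength latent-factor loading shared by HIS genes
#'   on the log-expression scale (default 0.6).
#' @param dnds_shift,f2a_shift log-scale effect sizes for HIS genes
#'   (defaults 0.7).
#' @param seed integer seed; the bundle is fully determined by it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_genes = 2000, frac_his = 0.05,
                          n_samples_expr = 60, variants_per_kb = 20,
                          cds_lognormal_params = c(7.3, 0.6),
                          p_common = 0.3, depletion_effect = 0.4,
                          coexpr_module_strength = 0.6,
                          dnds_shift = 0.7, f2a_shift = 0.7, seed = 1L) {
  if (!(frac_his > 0 && frac_his < 1)) {
    stop("frac_his must lie in (0, 1)", call. = FALSE)
  }
  if (round(n_genes * frac_his) < 2) {
    stop("configuration yields fewer than 2 HIS genes", call. = FALSE)
  }
  if (depletion_effect <= 0 || depletion_effect > 1) {
    stop("depletion_effect must lie in (0, 1]", call. = FALSE)
  }
  if (coexpr_module_strength < 0 || coexpr_module_strength >= 1) {
    stop("coexpr_module_strength must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), frac_his = frac_his,
                 n_samples_expr = as.integer(n_samples_expr),
                 variants_per_kb = variants_per_kb,
                 cds_lognormal_params = cds_lognormal_params,
                 p_common = p_common,
                 depletion_effect = depletion_effect,
                 coexpr_module_strength = coexpr_module_strength,
                 dnds_shift = dnds_shift, f2a_shift = f2a_shift,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

.NONSYN_PROBS <- c(0.70, 0.05, 0.05, 0.05, 0.08, 0.03, 0.02, 0.02)
.SYN_PROBS <- c(0.9, 0.1)

.sim_expression <- function(n_genes, samples, is_his, rho, f2a_shift,
                            fetal_samples = character(0)) {
  n_s <- length(samples)
  f <- stats::rnorm(n_s)                     # shared latent factor
  eps <- matrix(stats::rnorm(n_genes * n_s), nrow = n_genes)
  z <- eps
  if (rho > 0 && any(is_his)) {
    z[is_his, ] <- sqrt(rho) * matrix(f, nrow = sum(is_his), ncol = n_s,
                                      byrow = TRUE) +
      sqrt(1 - rho) * eps[is_his, , drop = FALSE]
  }
  base <- stats::rnorm(n_genes, mean = 1.5, sd = 1)
  low <- stats::runif(n_genes) < 0.05        # exercises the RPKM<1 filter
  base[low] <- -4
  logx <- base + z
  if (length(fetal_samples) > 0L && f2a_shift != 0) {
    fet <- samples %in% fetal_samples
    logx[is_his, fet] <- logx[is_his, fet] + f2a_shift
  }
  m <- exp(logx)
  dimnames(m) <- list(NULL, samples)
  m
}

#' Generate a synthetic cohort bundle
#'
#' Produces, from one seed, a gene catalog, a QC-passed variant table, two
#' expression matrices (an atlas-like one with a fetal/adult tissue
#' partition and an RNA-seq-like one), the true per-gene labels, and the
#' training/evaluation gene sets: a training HIS set (60% of the true HIS
#' genes), a disjoint haplosufficient pool drawn from the neutral genes,
#' and held-out HIS/HS evaluation sets.
#'
#' @param config a [cohort_config()].
#' @return a `cohort_bundle` list with elements `catalog`, `variants`,
#'   `expr_a`, `expr_b`, `partition`, `true_labels`, `train_his`,
#'   `hs_pool`, `eval_his`, `eval_hs` and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("G%0*d", nchar(as.character(n)), seq_len(n))
  n_his <- round(n * config$frac_his)
  is_his <- seq_len(n) %in% sample.int(n, n_his)
  labels <- ifelse(is_his, "HIS", "neutral")

  # --- catalog -----------------------------------------------------------
  mu <- config$cds_lognormal_params[1L]
  sigma <- config$cds_lognormal_params[2L]
  cds <- pmax(90, round(exp(stats::rnorm(n, mu, sigma))))
  ds <- exp(stats::rnorm(n, log(0.05), 0.4))
  w <- exp(stats::rnorm(n, log(0.25) - config$dnds_shift * is_his, 0.5))
  dn <- ds * w
  dn[stats::runif(n) < 0.02] <- 0            # exercises the 0.001 rule
  miss <- stats::runif(n) < 0.03             # genes with unknown dN/dS
  dn[miss] <- NA_real_
  ds[miss] <- NA_real_
  catalog <- data.frame(
    gene_id = genes, cds_length = cds, dn = dn, ds = ds,
    pubmed_count = stats::rnbinom(n, size = 0.5, mu = 20),
    has_mouse_ortholog = stats::runif(n) < 0.7,
    stringsAsFactors = FALSE
  )
  class(catalog) <- c("gene_catalog", "data.frame")

  # --- variants ----------------------------------------------------------
  n_var <- stats::rpois(n, cds / 1000 * config$variants_per_kb)
  gene_of <- rep(genes, n_var)
  his_of <- rep(is_his, n_var)
  n_tot <- length(gene_of)
  cls <- sample(c("nonsyn", "syn", "other"), n_tot, replace = TRUE,
                prob = c(0.5, 0.25, 0.25))
  p_com <- rep(config$p_common, n_tot)
  p_com[cls == "nonsyn" & his_of] <-
    config$p_common * config$depletion_effect
  common <- stats::runif(n_tot) < p_com
  maf <- ifelse(common,
                10^stats::runif(n_tot, log10(0.0015), log10(0.5)),
                10^stats::runif(n_tot, log10(1e-05), log10(0.001)))
  ann <- character(n_tot)
  ann[cls == "nonsyn"] <- sample(.NONSYN_LABELS, sum(cls == "nonsyn"),
                                 replace = TRUE, prob = .NONSYN_PROBS)
  ann[cls == "syn"] <- sample(.SYN_LABELS, sum(cls == "syn"),
                              replace = TRUE, prob = .SYN_PROBS)
  ann[cls == "other"] <- sample(c("intron", "utr-3", "utr-5"),
                                sum(cls == "other"), replace = TRUE,
                                prob = c(0.8, 0.1, 0.1))
  variants <- data.frame(gene_id = gene_of, annotation = ann, maf = maf,
                         qc_pass = TRUE, stringsAsFactors = FALSE)
  class(variants) <- c("variant_table", "data.frame")

  # --- expression --------------------------------------------------------
  fetal <- paste0("fetal_", 1:4)
  adult <- paste0("adult_", 1:31)
  expr_a <- .sim_expression(n, c(fetal, adult), is_his,
                            config$coexpr_module_strength,
                            config$f2a_shift, fetal_samples = fetal)
  rownames(expr_a) <- genes
  expr_b <- .sim_expression(n, paste0("s_", seq_len(config$n_samples_expr)),
                            is_his, config$coexpr_module_strength, 0)
  rownames(expr_b) <- genes
  partition <- tissue_partition(fetal, adult)

  # --- training / evaluation gene sets -----------------------------------
  his_genes <- genes[is_his]
  neutral <- genes[!is_his]
  n_train <- max(2L, round(0.6 * n_his))
  train_his <- sort(sample(his_genes, n_train))
  eval_his <- sort(setdiff(his_genes, train_his))
  pool_size <- min(4L * n_his, floor(length(neutral) / 2))
  hs_pool <- sort(sample(neutral, pool_size))
  eval_hs <- sort(sample(setdiff(neutral, hs_pool),
                         min(2L * max(length(eval_his), 1L),
                             length(neutral) - pool_size)))

  structure(list(
    catalog = catalog, variants = variants,
    expr_a = expr_a, expr_b = expr_b, partition = partition,
    true_labels = stats::setNames(labels, genes),
    train_his = gene_set("train_his", train_his),
    hs_pool = gene_set("hs_pool", hs_pool),
    eval_his = gene_set("eval_his", eval_his),
    eval_hs = gene_set("eval_hs", eval_hs),
    config = config
  ), class = "cohort_bundle")
}

#' Build the five-feature matrix from a cohort bundle
#'
#' Runs the full upstream chain on a bundle: per-gene variant counts and
#' NoVaDs, low-expression filtering and network construction for both
#' expression matrices, proximity to the training HIS genes, the F2A
#' ratio, and feature assembly with the standard imputation rules.
#'
#' @param bundle a `cohort_bundle`.
#' @param net_config a [network_config()].
#' @return a `feature_matrix` over the bundle's gene universe.
#' @export
cohort_features <- function(bundle, net_config = network_config()) {
  panel <- novads_panel(bundle$variants)
  prox <- lapply(list(bundle$expr_a, bundle$expr_b), function(m) {
    net <- build_network(filter_low_expression(m, net_config), net_config)
    proximity_to_his(net, bundle$train_his, net_config)
  })
  f2a <- f2a_ratio(bundle$expr_a, bundle$partition)
  assemble_features(bundle$catalog, prox[[1L]], prox[[2L]], panel, f2a)
}

#' CDS-bias null simulation for the RVIS
#'
#' Simulates per-gene variant counts with *no* true relationship between
#' CDS length and intolerance: total variants are Poisson in proportion to
#' CDS, and each gene's common non-synonymous proportion is drawn from a
#' Beta distribution and permuted across genes.  Because the count
#' variance still grows with the total, the absolute studentized residual
#' (RVIS) inherits a CDS dependence, while the ratio-based NoVaDs does
#' not.
#'
#' @param n_genes number of genes (>= 100).
#' @param cds optional CDS length vector; by default drawn log-normally
#'   with `cds_lognormal_params`.
#' @param cds_lognormal_params `c(mu, sigma)` of log CDS (default
#'   `c(7.3, 0.6)`).
#' @param variants_per_kb expected variants per kilobase (default 20).
#' @param seed integer seed.
#' @return a data frame of per-gene class counts (as [count_by_gene()])
#'   plus a `cds_length` column.
#' @export
rvis_null <- function(n_genes, cds = NULL,
                      cds_lognormal_params = c(7.3, 0.6),
                      variants_per_kb = 20, seed = 1L) {
  if (n_genes < 100) stop("n_genes must be >= 100", call. = FALSE)
  set.seed(seed)
  if (is.null(cds)) {
    cds <- pmax(90, round(exp(stats::rnorm(n_genes,
                                           cds_lognormal_params[1L],
                                           cds_lognormal_params[2L]))))
  }
  stopifnot(length(cds) == n_genes)
  total <- stats::rpois(n_genes, cds / 1000 * variants_per_kb)
  n_nonsyn <- stats::rbinom(n_genes, total, 0.5)
  n_syn <- stats::rbinom(n_genes, total - n_nonsyn, 0.5)
  p <- sample(stats::rbeta(n_genes, 4, 8))   # permuted: independent of CDS
  n_common_ns <- stats::rbinom(n_genes, n_nonsyn, p)
  n_common_sy <- stats::rbinom(n_genes, n_syn, 0.3)
  data.frame(
    gene_id = sprintf("N%0*d", nchar(as.character(n_genes)),
                      seq_len(n_genes)),
    n_common_nonsyn = n_common_ns,
    n_rare_nonsyn = n_nonsyn - n_common_ns,
    n_common_syn = n_common_sy,
    n_rare_syn = n_syn - n_common_sy,
    n_total = total,
    cds_length = cds,
    stringsAsFactors = FALSE
  )
}

#' Write a cohort bundle as a plain-text fixture directory
#'
#' Emits every reader's format so the whole pipeline can be run from
#' files: the catalog, the variant table (with a `qc` column), both
#' expression matrices, the four gene-set lists, the tissue partition and
#' the true labels.
#'
#' @param bundle a `cohort_bundle`.
#' @param directory output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_fixture <- function(bundle, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  p <- function(f) file.path(directory, f)
  write_gene_catalog(bundle$catalog, p("catalog.tsv"))
  vdf <- data.frame(gene_id = bundle$variants$gene_id,
                    annotation = bundle$variants$annotation,
                    maf = bundle$variants$maf,
                    qc = "PASS", stringsAsFactors = FALSE)
  .write_tsv(vdf, p("variants.tsv"))
  write_expression_matrix(bundle$expr_a, p("expr_a.tsv"))
  write_expression_matrix(bundle$expr_b, p("expr_b.tsv"))
  for (s in c("train_his", "hs_pool", "eval_his", "eval_hs")) {
    write_gene_set(bundle[[s]], p(paste0(s, ".txt")))
  }
  part <- data.frame(
    sample_id = c(bundle$partition$fetal_samples,
                  bundle$partition$adult_samples),
    group = c(rep("fetal", length(bundle$partition$fetal_samples)),
              rep("adult", length(bundle$partition$adult_samples))),
    stringsAsFactors = FALSE
  )
  .write_tsv(part, p("partition.tsv"))
  lab <- data.frame(gene_id = names(bundle$true_labels),
                    label = unname(bundle$true_labels),
                    stringsAsFactors = FALSE)
  .write_tsv(lab, p("labels.tsv"))
  files <- c(catalog = p("catalog.tsv"), variants = p("variants.tsv"),
             expr_a = p("expr_a.tsv"), expr_b = p("expr_b.tsv"),
             train_his = p("train_his.txt"), hs_pool = p("hs_pool.txt"),
             eval_his = p("eval_his.txt"), eval_hs = p("eval_hs.txt"),
             partition = p("partition.tsv"), labels = p("labels.tsv"))
  invisible(files)
}

#' Read a cohort fixture directory back into bundle components
#'
#' @param directory a directory written by [write_fixture()].
#' @return a list with the same data components as a `cohort_bundle`
#'   (without the generating `config`).
#' @export
read_cohort_fixture <- function(directory) {
  p <- function(f) file.path(directory, f)
  part <- .read_tsv(p("partition.tsv"))
  lab <- .read_tsv(p("labels.tsv"))
  list(
    catalog = read_gene_catalog(p("catalog.tsv")),
    variants = read_variant_table(p("variants.tsv"), format = "tsv"),
    expr_a = read_expression_matrix(p("expr_a.tsv")),
    expr_b = read_expression_matrix(p("expr_b.tsv")),
    partition = tissue_partition(part$sample_id[part$group == "fetal"],
                                 part$sample_id[part$group == "adult"]),
    true_labels = stats::setNames(lab$label, lab$gene_id),
    train_his = read_gene_set(p("train_his.txt")),
    hs_pool = read_gene_set(p("hs_pool.txt")),
    eval_his = read_gene_set(p("eval_his.txt")),
    eval_hs = read_gene_set(p("eval_hs.txt"))
  )
}
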