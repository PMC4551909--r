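# Shared in-code fixtures; everything is generated at test time.

write_tmp_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a small in-memory variant table (already QC-passed)
make_variant_table <- function(gene_id, annotation, maf) {
  df <- data.frame(gene_id = gene_id, annotation = annotation, maf = maf,
                   qc_pass = rep(TRUE, length(gene_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

make_catalog <- function(gene_id, cds_length,
                         dn = rep(NA_real_, length(gene_id)),
                         ds = rep(NA_real_, length(gene_id)),
                         pubmed_count = rep(NA_real_, length(gene_id)),
                         has_mouse_ortholog = rep(TRUE, length(gene_id))) {
  df <- data.frame(gene_id = gene_id, cds_length = cds_length, dn = dn,
                   ds = ds, pubmed_count = pubmed_count,
                   has_mouse_ortholog = has_mouse_ortholog,
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_catalog", "data.frame")
  df
}

# exhaustive pairwise AUC oracle: P(pos > neg) + 0.5 P(pos == neg)
pairwise_auc_oracle <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# direct evaluation of the printed MCC formula
mcc_formula_oracle <- function(tp, tn, fp, fn) {
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

# brute-force internally studentized residuals via the hat matrix
studentized_residual_oracle <- function(x, y) {
  X <- cbind(1, x)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  e <- y - H %*% y
  s2 <- sum(e^2) / (length(y) - 2)
  as.vector(e / sqrt(s2 * (1 - diag(H))))
}
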