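# Readers/writers and the shared data model.  All tabular formats are
# tab-separated with a mandatory header; "." and the empty string denote
# missing values.  Gene identifiers are opaque strings.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = c(".", ""),
                    check.names = FALSE, quote = "", comment.char = "")
}

.write_tsv <- function(df, path) {
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) col else as.character(col)
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}

# numeric coercion that errors (naming the column) if a non-missing cell
# fails to parse; percent strings are rejected everywhere
.parse_numeric <- function(x, column) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L) {
    stop("column '", column, "': cannot parse value '", x[bad[1L]],
         "' as a number (row ", bad[1L],
         "); fractions are required, percent strings are rejected",
         call. = FALSE)
  }
  out
}

.parse_logical <- function(x, column) {
  if (is.logical(x)) return(x)
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L) {
    stop("column '", column, "': cannot parse '", x[bad[1L]],
         "' as a logical", call. = FALSE)
  }
  out
}

#' Read a gene catalog
#'
#' Reads the per-gene static attribute table: coding-sequence length of the
#' longest transcript (nucleotides), dN and dS substitution rates against a
#' one-to-one primate orthologue, publication count, and a flag for having a
#' one-to-one mouse orthologue.  Every column except the gene identifier may
#' be missing for individual genes; missingness is kept as `NA`, never
#' silently filled.
#'
#' @param path path to a tab-separated file with a header row.
#' @param schema named list mapping canonical field names (`gene_id`,
#'   `cds_length`, `dn`, `ds`, `pubmed_count`, `has_mouse_ortholog`) to the
#'   column names used in the file.  Fields other than `gene_id` whose
#'   column is absent are filled with `NA`.
#' @return a `gene_catalog` data frame with the canonical columns.
#' @export
read_gene_catalog <- function(path, schema = list()) {
  defaults <- list(gene_id = "gene_id", cds_length = "cds_length",
                   dn = "dn", ds = "ds", pubmed_count = "pubmed_count",
                   has_mouse_ortholog = "has_mouse_ortholog")
  schema <- utils::modifyList(defaults, as.list(schema))
  raw <- .read_tsv(path)
  if (!schema$gene_id %in% names(raw)) {
    stop("gene catalog is missing the required gene-ID column '",
         schema$gene_id, "'", call. = FALSE)
  }
  gene_id <- as.character(raw[[schema$gene_id]])
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene ID(s) in catalog: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  grab_num <- function(field) {
    col <- schema[[field]]
    if (col %in% names(raw)) .parse_numeric(raw[[col]], col)
    else rep(NA_real_, length(gene_id))
  }
  out <- data.frame(
    gene_id = gene_id,
    cds_length = grab_num("cds_length"),
    dn = grab_num("dn"),
    ds = grab_num("ds"),
    pubmed_count = grab_num("pubmed_count"),
    stringsAsFactors = FALSE
  )
  out$has_mouse_ortholog <-
    if (schema$has_mouse_ortholog %in% names(raw)) {
      .parse_logical(raw[[schema$has_mouse_ortholog]],
                     schema$has_mouse_ortholog)
    } else rep(NA, length(gene_id))
  if (any(!is.na(out$cds_length) & out$cds_length < 1)) {
    stop("cds_length must be >= 1 for every gene where it is present",
         call. = FALSE)
  }
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' Write a gene catalog
#' @param catalog a `gene_catalog` data frame.
#' @param path output path.
#' @export
write_gene_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  df$has_mouse_ortholog <- as.character(df$has_mouse_ortholog)
  .write_tsv(df, path)
}

#' Construct a gene set
#'
#' A named set of gene identifiers.  Duplicate members are collapsed; the
#' number removed is recorded in the `provenance` attribute.
#'
#' @param name label for the set.
#' @param members character vector of gene identifiers.
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, members) {
  members <- as.character(members)
  n_dup <- sum(duplicated(members))
  members <- unique(members)
  out <- list(name = name, members = members)
  prov <- character(0)
  if (n_dup > 0L) prov <- sprintf("collapsed %d duplicate member(s)", n_dup)
  attr(out, "provenance") <- prov
  class(out) <- "gene_set"
  out
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

#' Remove genes from a gene set
#'
#' Set difference that preserves the set's name and records what was removed
#' in the provenance attribute (used, e.g., to strip training genes from a
#' disease test set before evaluation).
#'
#' @param set a `gene_set`.
#' @param remove a `gene_set` or character vector of identifiers to remove.
#' @param note optional provenance note.
#' @return the reduced `gene_set`.
#' @export
gene_set_difference <- function(set, remove, note = NULL) {
  rm_ids <- if (inherits(remove, "gene_set")) remove$members
            else as.character(remove)
  kept <- setdiff(set$members, rm_ids)
  out <- gene_set(set$name, kept)
  msg <- sprintf("removed %d gene(s)%s",
                 length(set$members) - length(kept),
                 if (is.null(note)) "" else paste0(" (", note, ")"))
  attr(out, "provenance") <- c(attr(set, "provenance"), msg)
  out
}

#' Read a gene set from a one-ID-per-line file
#' @param path path to the file; blank lines and `#` comments are ignored.
#' @param name set label; defaults to the file name without extension.
#' @return a `gene_set`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(name, lines)
}

#' Write a gene set
#' @param set a `gene_set`.
#' @param path output path.
#' @export
write_gene_set <- function(set, path) {
  writeLines(set$members, path)
  invisible(path)
}

.fold_maf <- function(maf) ifelse(!is.na(maf) & maf > 0.5, 1 - maf, maf)

#' Read a per-variant table
#'
#' Parses variant records (gene assignment, functional annotation label,
#' minor allele frequency) from either an annotated TSV or a VCF whose INFO
#' field carries gene and annotation tags.  Only records passing QC are
#' retained.  Allele frequencies above 0.5 are folded to the minor allele so
#' that the stored MAF is always in [0, 0.5]; annotation labels are kept
#' verbatim.
#'
#' @param path path to the input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param schema for TSV input, a named list with entries `gene_id`,
#'   `annotation`, `maf` and optionally `qc` naming the file's columns; a
#'   `qc` column holds `PASS`/`TRUE`/`1` for passing records and is assumed
#'   all-pass when absent.  For VCF input, entries `gene_field` and
#'   `annotation_field` name the INFO keys, and `af_field` (default `"AF"`)
#'   the allele-frequency key; when the AF key is absent the frequency is
#'   computed as `AC`/`AN`.
#' @return a `variant_table` data frame with columns `gene_id`,
#'   `annotation`, `maf` and `qc_pass` (all `TRUE` after filtering).  The
#'   number of records dropped by QC is stored in attribute `n_qc_fail`.
#' @export
read_variant_table <- function(path, format = c("tsv", "vcf"),
                               schema = list()) {
  format <- match.arg(format)
  if (format == "tsv") .read_variant_tsv(path, schema)
  else .read_variant_vcf(path, schema)
}

.read_variant_tsv <- function(path, schema) {
  defaults <- list(gene_id = "gene_id", annotation = "annotation",
                   maf = "maf", qc = "qc")
  schema <- utils::modifyList(defaults, as.list(schema))
  raw <- .read_tsv(path)
  for (field in c("gene_id", "annotation", "maf")) {
    if (!schema[[field]] %in% names(raw)) {
      stop("variant table is missing required column '", schema[[field]],
           "'", call. = FALSE)
    }
  }
  maf <- .parse_numeric(raw[[schema$maf]], schema$maf)
  if (any(!is.na(maf) & (maf < 0 | maf > 1))) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  qc_pass <- if (schema$qc %in% names(raw)) {
    qc_raw <- toupper(trimws(as.character(raw[[schema$qc]])))
    qc_raw %in% c("PASS", "TRUE", "T", "1")
  } else rep(TRUE, nrow(raw))
  out <- data.frame(
    gene_id = as.character(raw[[schema$gene_id]]),
    annotation = as.character(raw[[schema$annotation]]),
    maf = .fold_maf(maf),
    stringsAsFactors = FALSE
  )
  n_fail <- sum(!qc_pass)
  out <- out[qc_pass, , drop = FALSE]
  rownames(out) <- NULL
  out$qc_pass <- rep(TRUE, nrow(out))
  attr(out, "n_qc_fail") <- n_fail
  class(out) <- c("variant_table", "data.frame")
  out
}

.read_variant_vcf <- function(path, schema) {
  defaults <- list(gene_field = "GENE", annotation_field = "ANN",
                   af_field = "AF")
  schema <- utils::modifyList(defaults, as.list(schema))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  filt <- fix[, "FILTER"]
  qc_pass <- is.na(filt) | filt %in% c("PASS", ".")
  gene <- vcfR::extract.info(vcf, element = schema$gene_field)
  ann <- vcfR::extract.info(vcf, element = schema$annotation_field)
  af <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = schema$af_field)))
  if (all(is.na(af))) {
    ac <- suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, element = "AC")))
    an <- suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, element = "AN")))
    af <- ac / an
  }
  bad <- which(qc_pass & is.na(af))
  if (length(bad) > 0L) {
    stop("cannot determine an allele frequency for VCF record ", bad[1L],
         " (no ", schema$af_field, " and no usable AC/AN)", call. = FALSE)
  }
  out <- data.frame(
    gene_id = as.character(gene),
    annotation = as.character(ann),
    maf = .fold_maf(af),
    stringsAsFactors = FALSE
  )
  n_fail <- sum(!qc_pass)
  out <- out[qc_pass, , drop = FALSE]
  rownames(out) <- NULL
  out$qc_pass <- rep(TRUE, nrow(out))
  attr(out, "n_qc_fail") <- n_fail
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Construct an undirected weighted edge list
#'
#' Edges are stored once, with `gene_a < gene_b` under lexicographic
#' ordering.  Self-edges are rejected; duplicate pairs are collapsed if
#' their weights agree and rejected otherwise.
#'
#' @param gene_a,gene_b character vectors of endpoint identifiers.
#' @param weight numeric edge weights.
#' @return an `edge_list` data frame with columns `gene_a`, `gene_b`,
#'   `weight`.
#' @export
edge_list <- function(gene_a, gene_b, weight) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  weight <- as.numeric(weight)
  if (any(gene_a == gene_b)) {
    bad <- gene_a[gene_a == gene_b][1L]
    stop("self-edge not allowed (gene '", bad, "')", call. = FALSE)
  }
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    w_range <- tapply(weight, key, function(w) diff(range(w)))
    if (any(w_range > 1e-12)) {
      bad <- names(w_range)[which(w_range > 1e-12)[1L]]
      stop("conflicting weights for duplicated edge ",
           gsub("\r", " -- ", bad), call. = FALSE)
    }
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]; weight <- weight[keep]
  }
  ord <- order(a, b)
  out <- data.frame(gene_a = a[ord], gene_b = b[ord],
                    weight = weight[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Read an edge list from a three-column TSV
#' @param path path to a TSV with columns `gene_a`, `gene_b`, `weight`.
#' @return an `edge_list`.
#' @export
read_edge_list <- function(path) {
  raw <- .read_tsv(path)
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(raw))) {
    stop("edge list must have columns gene_a, gene_b, weight",
         call. = FALSE)
  }
  edge_list(raw$gene_a, raw$gene_b, .parse_numeric(raw$weight, "weight"))
}

#' Write an edge list
#' @param edges an `edge_list`.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  .write_tsv(as.data.frame(edges), path)
}

#' Read an expression matrix
#'
#' Reads a genes-by-samples table of non-negative RPKM-like values.  The
#' first column holds gene identifiers; remaining column names are sample
#' identifiers.
#'
#' @param path path to the TSV.
#' @return a numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  raw <- .read_tsv(path)
  genes <- as.character(raw[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene ID(s) in expression matrix", call. = FALSE)
  }
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  rownames(m) <- genes
  m
}

#' Write an expression matrix
#' @param matrix numeric genes-by-samples matrix with dimnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Re-map gene identifiers through a two-column mapping table
#'
#' Applies a join from one identifier namespace to another.  Rows whose
#' identifier has no mapping are dropped, with the count reported in a
#' message and stored in attribute `n_unmapped`.
#'
#' @param x a data frame with a `gene_id` column, or a `gene_set`.
#' @param mapping a two-column data frame (`from`, `to`) or a path to a TSV
#'   with those columns.
#' @return the re-identified object.
#' @export
apply_gene_mapping <- function(x, mapping) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- .read_tsv(mapping)
  }
  if (!all(c("from", "to") %in% names(mapping))) {
    stop("mapping table must have columns 'from' and 'to'", call. = FALSE)
  }
  map <- stats::setNames(as.character(mapping$to),
                         as.character(mapping$from))
  if (inherits(x, "gene_set")) {
    hit <- x$members %in% names(map)
    n_un <- sum(!hit)
    out <- gene_set(x$name, unname(map[x$members[hit]]))
    attr(out, "n_unmapped") <- n_un
    if (n_un > 0L) message("apply_gene_mapping: dropped ", n_un,
                           " unmappable gene(s)")
    return(out)
  }
  hit <- x$gene_id %in% names(map)
  n_un <- sum(!hit)
  out <- x[hit, , drop = FALSE]
  out$gene_id <- unname(map[out$gene_id])
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_un
  if (n_un > 0L) message("apply_gene_mapping: dropped ", n_un,
                         " unmappable gene(s)")
  out
}
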