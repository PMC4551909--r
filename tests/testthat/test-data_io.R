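test_that("gene catalog parsing enforces uniqueness and records missingness", {
  path <- write_tmp_lines(c(
    "gene_id\tcds_length\tdn\tds",
    "G1\t1500\t0.01\t0.1",
    "G2\t900\t.\t0.2",
    "G3\t3000\t0.02\t0.05"
  ))
  cat <- read_gene_catalog(path)
  expect_s3_class(cat, "gene_catalog")
  expect_equal(nrow(cat), 3L)
  expect_equal(cat$cds_length, c(1500, 900, 3000))
  expect_true(is.na(cat$dn[2]))          # "." cell stays missing
  expect_false(anyNA(cat$dn[-2]))
  # columns absent from the file are all-missing, never invented
  expect_true(all(is.na(cat$pubmed_count)))

  dup <- write_tmp_lines(c("gene_id\tcds_length", "G1\t100", "G1\t200"))
  expect_error(read_gene_catalog(dup), "G1")
  nocol <- write_tmp_lines(c("id\tcds_length", "G1\t100"))
  expect_error(read_gene_catalog(nocol), "gene_id")
})

test_that("gene sets collapse duplicates and record set differences", {
  gs <- gene_set("test", c("A", "B", "B", "C"))
  expect_setequal(gs$members, c("A", "B", "C"))
  reduced <- gene_set_difference(gs, c("B", "Z"), note = "training genes")
  expect_setequal(reduced$members, c("A", "C"))
  expect_equal(reduced$name, "test")
  expect_match(paste(attr(reduced, "provenance"), collapse = " "),
               "training genes")
})

test_that("variant TSV reading filters on QC and rejects malformed MAFs", {
  path <- write_tmp_lines(c(
    "gene_id\tannotation\tmaf\tqc",
    "G1\tmissense\t0.002\tPASS",
    "G1\tintron\t0.1\tPASS",
    "G2\tmissense\t0.0005\tPASS",
    "G2\tcoding-synonymous\t0.3\tPASS",
    "G3\tmissense\t0.01\tPASS",
    "G3\tmissense\t0.2\tFAIL",
    "G3\tsplice-3\t0.4\tFAIL"
  ))
  vt <- read_variant_table(path, format = "tsv")
  expect_equal(nrow(vt), 5L)
  expect_equal(attr(vt, "n_qc_fail"), 2L)
  expect_true(all(vt$qc_pass))

  pct <- write_tmp_lines(c("gene_id\tannotation\tmaf",
                           "G1\tmissense\t0.2%"))
  expect_error(read_variant_table(pct, format = "tsv"), "percent")
})

test_that("allele frequencies above 0.5 are folded to the minor allele", {
  path <- write_tmp_lines(c("gene_id\tannotation\tmaf",
                            "G1\tmissense\t0.8",
                            "G1\tmissense\t0.4"))
  vt <- read_variant_table(path, format = "tsv")
  expect_equal(vt$maf, c(0.2, 0.4), tolerance = 1e-12)
  expect_true(all(vt$maf <= 0.5))
})

test_that("VCF reading honours FILTER and computes MAF from AC/AN", {
  vcf <- write_tmp_lines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="gene">',
    '##INFO=<ID=ANN,Number=1,Type=String,Description="annotation">',
    '##INFO=<ID=AC,Number=1,Type=Integer,Description="allele count">',
    '##INFO=<ID=AN,Number=1,Type=Integer,Description="allele number">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\t.\tA\tG\t50\tPASS\tGENE=G1;ANN=missense;AC=1;AN=1000",
    "1\t200\t.\tC\tT\t50\tLowQual\tGENE=G1;ANN=missense;AC=5;AN=1000",
    "1\t300\t.\tG\tA\t50\tPASS\tGENE=G2;ANN=coding-synonymous;AC=900;AN=1000"
  ), ext = ".vcf")
  vt <- read_variant_table(vcf, format = "vcf")
  expect_equal(nrow(vt), 2L)              # LowQual record dropped
  expect_equal(attr(vt, "n_qc_fail"), 1L)
  expect_equal(vt$maf[vt$gene_id == "G1"], 0.001)   # AC/AN arithmetic
  expect_equal(vt$maf[vt$gene_id == "G2"], 0.1)     # folded from 0.9
})

test_that("edge lists are canonically undirected and reject bad input", {
  e <- edge_list(c("A", "B"), c("B", "A"), c(0.5, 0.5))
  expect_equal(nrow(e), 1L)
  expect_equal(e$gene_a, "A")
  expect_equal(e$gene_b, "B")

  expect_error(edge_list("A", "A", 0.9), "self-edge")
  expect_error(edge_list(c("A", "B"), c("B", "A"), c(0.5, 0.6)),
               "conflicting")

  path <- tempfile(fileext = ".tsv")
  big <- edge_list(c("g3", "g1", "g2"), c("g1", "g2", "g3"),
                   c(-0.4, 0.31, 0.9))
  write_edge_list(big, path)
  expect_equal(read_edge_list(path), big, ignore_attr = TRUE)
})

test_that("expression matrices round-trip through TSV", {
  m <- matrix(c(0, 1.5, 2.25, 10, 0.5, 3), nrow = 3,
              dimnames = list(c("G1", "G2", "G3"), c("s1", "s2")))
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  expect_equal(read_expression_matrix(path), m)
})

test_that("gene-ID mapping joins drop unmappable genes with a count", {
  map <- data.frame(from = c("A", "B"), to = c("ENSG1", "ENSG2"))
  df <- data.frame(gene_id = c("A", "B", "C"), value = 1:3)
  suppressMessages(out <- apply_gene_mapping(df, map))
  expect_equal(out$gene_id, c("ENSG1", "ENSG2"))
  expect_equal(attr(out, "n_unmapped"), 1L)
  gs <- gene_set("s", c("A", "C", "D"))
  suppressMessages(out2 <- apply_gene_mapping(gs, map))
  expect_equal(out2$members, "ENSG1")
  expect_equal(attr(out2, "n_unmapped"), 2L)
})
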