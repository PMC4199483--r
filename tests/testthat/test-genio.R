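toy_genotypes <- function() {
  dos <- matrix(c(0, 1, 2,
                  2, NA, 0), nrow = 3,
                dimnames = list(c("A1", "A2", "A3"), c("rs1", "rs2")))
  genotype_matrix(c("A1", "A2", "A3"), c("rs1", "rs2"),
                  tibble::tibble(snp_id = c("rs1", "rs2"),
                                 chrom = "chr1", pos = c(150, 900)), dos)
}

test_that("VCF round-trip preserves dosages, coordinates and missingness", {
  g <- toy_genotypes()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, path)
  lines <- readLines(path)
  expect_true(any(grepl("^#CHROM", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_true(grepl("\t0/1\t", paste0("\t", strsplit(body[1], "\t")[[1]][11], "\t")))
  back <- read_genotypes(path)
  expect_identical(back$samples, g$samples)
  expect_identical(back$snp_ids, g$snp_ids)
  expect_identical(unname(back$dosages), unname(g$dosages))
  expect_equal(back$coords$pos, g$coords$pos)
})

test_that("GT strings map to dosages per the format definition", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3", "S4"), collapse = "\t"),
    paste(c("chr1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1|1", "./."), collapse = "\t"),
    paste(c("chr1", "200", "v2", "A", "G,T", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "0/0"), collapse = "\t")
  ), path)
  expect_warning(g <- read_genotypes(path), "1 multi-allelic")
  expect_identical(g$snp_ids, "v1")
  expect_identical(unname(g$dosages[, 1]), c(0, 1, 2, NA))
})

test_that("dosage tables read back and reject non-numeric cells by position", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\trs1\trs2", "A\t0\t2", "B\t1\tNA", "C\t2\t1"), path)
  g <- read_genotypes(path, format = "dosage")
  expect_identical(unname(g$dosages[, "rs2"]), c(2, NA, 1))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\trs1\trs2", "A\t0\t2", "B\toops\t1"), bad)
  expect_error(read_genotypes(bad, format = "dosage"), "row 2.*rs1")
})

test_that("closest-gene assignment honours containment, ties and dropping", {
  genes <- tibble::tibble(chrom = "chr1", start = c(100, 0, 200),
                          end = c(200, 100, 300),
                          name = c("inner", "A", "B"))
  # containment: 1-based P in (start, end]
  snps <- tibble::tibble(snp_id = c("in1", "edge_lo", "edge_hi"),
                         chrom = "chr1", pos = c(150, 100, 200))
  gm <- assign_snps_to_genes(snps, genes[1, ])
  expect_identical(gm$assignment$gene, c("inner", "inner", "inner"))
  expect_identical(gm$assignment$distance, c(0, 0, 0))  # book-ended gap is 0

  # equidistant between A [0,100) and B [200,300): distance 50 each ->
  # leftmost start wins (oracle: exhaustive distance over all intervals)
  tie <- tibble::tibble(snp_id = "t", chrom = "chr1", pos = 150)
  gm2 <- assign_snps_to_genes(tie, genes[2:3, ])
  d_all <- c(A = 150 - 100, B = 200 - 150)
  expect_identical(unname(d_all["A"]), unname(gm2$assignment$distance))
  expect_identical(unname(d_all["A"]), unname(d_all["B"]))
  expect_identical(gm2$assignment$gene, "A")

  # permuting gene order does not change the assignment
  gm3 <- assign_snps_to_genes(tie, genes[3:2, ])
  expect_identical(gm3$assignment$gene, "A")

  # name tie-break for identical intervals
  twin <- tibble::tibble(chrom = "chr1", start = c(0, 0), end = c(100, 100),
                         name = c("zeta", "alpha"))
  expect_identical(assign_snps_to_genes(tie, twin)$assignment$gene, "alpha")

  # SNPs on a gene-less chromosome are dropped and counted
  far <- tibble::tibble(snp_id = c("x1", "x2"), chrom = "chrX", pos = c(5, 6))
  gm4 <- assign_snps_to_genes(dplyr::bind_rows(tie, far), genes)
  expect_identical(gm4$dropped_no_gene_chrom, c("x1", "x2"))
  expect_identical(nrow(gm4$assignment), 1L)

  # no SNPs -> empty assignment; no genes -> error
  empty <- assign_snps_to_genes(snps[0, ], genes)
  expect_identical(nrow(empty$assignment), 0L)
  expect_error(assign_snps_to_genes(snps, genes[0, ]), "empty gene set")

  # max_distance cap
  gm5 <- assign_snps_to_genes(tie, genes[2:3, ], max_distance = 10)
  expect_identical(gm5$dropped_beyond_max_distance, "t")
})

test_that("assignment is a total function with exhaustive-distance agreement", {
  withr::with_seed(31, {
    genes <- tibble::tibble(chrom = "chr2",
                            start = sort(sample.int(10000, 8)) * 10,
                            name = sprintf("g%02d", 1:8))
    genes$end <- genes$start + 500
    snps <- tibble::tibble(snp_id = sprintf("s%03d", 1:100), chrom = "chr2",
                           pos = sample.int(110000, 100))
  })
  gm <- assign_snps_to_genes(snps, genes)
  expect_identical(nrow(gm$assignment), 100L)
  # oracle: brute-force distance over every interval
  for (i in sample.int(100, 15)) {
    p <- snps$pos[snps$snp_id == gm$assignment$snp_id[i]]
    d <- pmax(genes$start - p, p - genes$end, 0)
    expect_equal(gm$assignment$distance[i], min(d))
    best <- genes$name[d == min(d)]
    expect_true(gm$assignment$gene[i] %in% best)
  }
})

test_that("gene blocks preserve genomic order and mean-impute missing dosages", {
  g <- toy_genotypes()
  genes <- tibble::tibble(chrom = "chr1", start = c(0, 800),
                          end = c(400, 1000), name = c("gA", "gB"))
  gm <- assign_snps_to_genes(g$coords, genes)
  blocks <- make_gene_blocks(g, gm)
  expect_setequal(names(blocks), c("gA", "gB"))
  expect_identical(blocks$gA$snp_ids, "rs1")
  # rs2 has dosages (2, NA, 0): missing becomes the observed mean 1
  expect_equal(unname(blocks$gB$dosages[, "rs2"]), c(2, 1, 0))
})

test_that("rule tables round-trip through TSV including the threshold header", {
  rules <- tibble::tibble(
    genes = list("F7", c("F5", "ABO")),
    phenotypes = list(c("fvii", "chol"), "vwf"),
    cca_log10_p = c(-12.5, -300.2),
    cca_p = pleiocca:::linear_p(c(-12.5, -300.2)),
    fisher_log10_p = c(-10.1, -250.0),
    marginals = list(c(fvii = -11.2, chol = -0.7), c(vwf = -200.5)),
    significant = c(TRUE, TRUE))
  attr(rules, "log10_threshold") <- -7.25
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rules(rules, path)
  expect_identical(readLines(path, n = 1L), "# log10_threshold=-7.25")
  # two phenotypes joined "fvii;chol"
  expect_true(any(grepl("fvii;chol", readLines(path))))
  back <- read_rules(path)
  expect_identical(back$genes, rules$genes)
  expect_identical(back$phenotypes, rules$phenotypes)
  expect_equal(back$cca_log10_p, rules$cca_log10_p)
  expect_equal(back$marginals, rules$marginals)
  expect_identical(attr(back, "log10_threshold"), -7.25)
  # empty rule list -> header-only file (comment + column header)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_rules(rules[0, ], p2, log10_threshold = -1)
  expect_identical(nrow(read_rules(p2)), 0L)
})

test_that("synthetic datasets round-trip through the on-disk formats", {
  ds <- planted_dataset(n = 60, seed = 8)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  g <- read_genotypes(file.path(dir, "genotypes.vcf"))
  expect_identical(g$samples, ds$genotypes$samples)
  expect_equal(unname(g$dosages), unname(ds$genotypes$dosages))
  genes <- read_bed(file.path(dir, "genes.bed"))
  expect_identical(genes$name, ds$gene_coords$name)
  expect_identical(genes$start, as.integer(ds$gene_coords$start))
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(as.data.frame(ph), as.data.frame(ds$phenotypes), tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth[[1]]$gene, "gene03")
})
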