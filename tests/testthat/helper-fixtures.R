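# Shared fixture builders. Everything is generated in code at test time.

# small cohort with one planted (1-gene, 2-phenotype) rule; used by the
# search-mode tests
planted_dataset <- function(n = 500, seed = 42) {
  spec <- synth_spec(
    n_samples = n,
    genes = synth_gene_table(6, 5),
    n_phenotypes = 8,
    target_ld = 0.3,
    maf_range = c(0.15, 0.45),
    effects = tibble::tibble(
      gene = "gene03", snp_index = 2L,
      phenotype_idx = list(c(3L, 6L)), beta = 0.4),
    missing_rate = 0.014,
    seed = seed)
  synth_generate(spec)
}

planted_truth <- list(gene = "gene03", phenotypes = c("pheno_03", "pheno_06"))

# null Gaussian design pair for CCA-level tests
null_xy <- function(n, q, p, seed) {
  withr::with_seed(seed, list(
    x = matrix(rnorm(n * q), n, q),
    y = matrix(rnorm(n * p), n, p)))
}

# random standardised dosage-like block with some collinearity
random_block <- function(n, q, seed, ld = 0.4) {
  withr::with_seed(seed, {
    shared <- rnorm(n)
    x <- sqrt(ld) * matrix(shared, n, q) + sqrt(1 - ld) * matrix(rnorm(n * q), n, q)
    gene_block("g", x, snp_ids = paste0("s", seq_len(q)))
  })
}

expect_sorted_desc <- function(x) expect_true(all(diff(x) <= 1e-12))
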