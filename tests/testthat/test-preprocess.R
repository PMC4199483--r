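make_pheno <- function(m) {
  dplyr::bind_cols(tibble::tibble(sample = sprintf("S%02d", seq_len(nrow(m)))),
                   tibble::as_tibble(as.data.frame(m)))
}

test_that("kNN imputation: identity, hand-checked fixture, non-destruction", {
  m <- withr::with_seed(1, matrix(rnorm(40), 10, 4,
                                  dimnames = list(NULL, paste0("p", 1:4))))
  tbl <- make_pheno(m)
  expect_identical(impute_knn(tbl), tbl)   # nothing missing -> unchanged

  # 7-sample fixture: sample 1 is missing p2; its five nearest neighbours by
  # p1 (samples 2..6, distances 1..5 after standardisation) carry p2 values
  # 1..5; sample 7 is far away with an extreme p2 value
  fx <- make_pheno(cbind(p1 = c(0, 1, 2, 3, 4, 5, 50),
                         p2 = c(NA, 1, 2, 3, 4, 5, 1000)))
  imp <- impute_knn(fx, impute_config(k = 5))
  expect_equal(imp$p2[1], 3.0)
  expect_identical(imp$p1, fx$p1)          # observed cells untouched
  expect_identical(imp$p2[-1], fx$p2[-1])
})

test_that("kNN imputation rejects pathological tables", {
  bad1 <- make_pheno(cbind(p1 = c(NA, NA, NA, NA, NA, NA),
                           p2 = c(1, 2, 3, 4, 5, 6)))
  expect_error(impute_knn(bad1), "all-missing")
  bad2 <- make_pheno(cbind(p1 = c(NA, 1, 2, 3, 4, 5),
                           p2 = c(NA, 2, 3, 4, 5, 6)))
  expect_error(impute_knn(bad2), "no observed")
  few <- make_pheno(cbind(p1 = c(NA, 1, 2, NA, NA, NA),
                          p2 = 1:6))
  expect_error(impute_knn(few, impute_config(k = 5)), "fewer than k")
})

test_that("normalization: closed form, idempotence, constant-column error", {
  tbl <- make_pheno(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
  z <- normalize_phenotypes(tbl)
  expect_equal(z$a, c(-1, 0, 1))
  expect_equal(colMeans(pleiocca:::pheno_matrix(z)), c(a = 0, b = 0),
               tolerance = 1e-12)
  expect_equal(apply(pleiocca:::pheno_matrix(z), 2, sd), c(a = 1, b = 1),
               tolerance = 1e-12)
  z2 <- normalize_phenotypes(z)
  expect_equal(as.data.frame(z2), as.data.frame(z), tolerance = 1e-12)
  cn <- make_pheno(cbind(a = c(1, 2, 3), flat = c(4, 4, 4)))
  expect_error(normalize_phenotypes(cn), "flat")
})

test_that("exact HWE test matches a direct enumeration oracle", {
  # oracle: full conditional distribution of heterozygote counts via choose()
  oracle_hwe <- function(naa, nab, nbb) {
    n <- naa + nab + nbb
    na <- 2 * naa + nab
    nm <- min(na, 2 * n - na)
    hets <- seq(nm %% 2, nm, by = 2)
    pr <- vapply(hets, function(h) {
      choose(n, (nm - h) / 2) * choose(n - (nm - h) / 2, h) * 2^h /
        choose(2 * n, nm)
    }, numeric(1))
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(nab, hets)] * (1 + 1e-9)])
  }
  # equilibrium counts: p close to 1
  expect_gt(hwe_exact_p(25, 50, 25), 0.99)
  cases <- list(c(25, 50, 25), c(60, 30, 10), c(40, 10, 50), c(5, 0, 5),
                c(98, 1, 1), c(0, 50, 0))
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 oracle_hwe(cs[1], cs[2], cs[3]), tolerance = 1e-9)
  }
  expect_equal(hwe_exact_p(10, 0, 0), 1)   # monomorphic
})

test_that("QC removes low-call-rate samples, monomorphic and HWE-failing SNPs", {
  withr::with_seed(3, {
    n <- 60
    dos <- cbind(
      good = rbinom(n, 2, 0.3),
      mono = rep(0, n),
      hwe_bad = rep(c(0, 2), n / 2)       # no hets at 50% frequency
    )
  })
  dos[1, ] <- c(NA, NA, NA)               # sample 1: 0% call rate
  g <- genotype_matrix(sprintf("S%02d", 1:60), colnames(dos),
                       tibble::tibble(snp_id = colnames(dos), chrom = "chr1",
                                      pos = c(100, 200, 300)), dos)
  res <- qc_filter(g, qc_config())
  expect_false("S01" %in% res$genotypes$samples)
  expect_identical(res$genotypes$snp_ids, "good")
  expect_setequal(res$report$reason[res$report$type == "snp"], c("maf", "hwe"))
  expect_true("S01" %in% res$report$id[res$report$reason == "call_rate"])
  # boundary: call rate exactly at the threshold is retained
  dos2 <- matrix(rbinom(200, 2, 0.4), 20, 10)
  dos2[2, 1:2] <- NA                       # 80% call rate < 90% -> removed
  g2 <- genotype_matrix(paste0("T", 1:20), paste0("s", 1:10),
                        tibble::tibble(snp_id = paste0("s", 1:10),
                                       chrom = "chr1", pos = 1:10 * 100), dos2)
  res2 <- qc_filter(g2)
  expect_false("T2" %in% res2$genotypes$samples)
})

test_that("r2 pruning: duplicates dropped, boundary strict, exhaustive oracle", {
  b <- random_block(200, 4, seed = 11)
  dup <- gene_block("g", cbind(b$dosages, b$dosages[, 1]),
                    snp_ids = c(b$snp_ids, "s1_copy"))
  pruned <- prune_r2(dup, prune_config(r2_max = 0.64))
  expect_false("s1_copy" %in% pruned$snp_ids)
  expect_true("s1" %in% pruned$snp_ids)    # earlier SNP of the pair is kept

  # boundary semantics: a pair at exactly the cutoff is retained (strict >)
  pair <- random_block(300, 2, seed = 12, ld = 0.5)
  r2_obs <- cor(pair$dosages)[1, 2]^2
  expect_identical(ncol(prune_r2(pair, prune_config(r2_max = r2_obs))$dosages), 2L)
  expect_identical(ncol(prune_r2(pair, prune_config(r2_max = r2_obs - 1e-9))$dosages), 1L)

  # survivors satisfy the all-pairs bound (independent exhaustive check)
  for (s in 1:10) {
    blk <- random_block(150, 6, seed = 100 + s, ld = 0.7)
    out <- prune_r2(blk, prune_config())
    if (ncol(out$dosages) > 1) {
      r2 <- cor(out$dosages)^2
      expect_lte(max(r2[upper.tri(r2)]), 0.64)
    }
    # idempotence
    out2 <- prune_r2(out, prune_config())
    expect_identical(out2$snp_ids, out$snp_ids)
  }
})

test_that("VIF pruning: orthogonal passthrough, collinear removal, oracle bound", {
  # exactly orthogonal columns -> all VIF 1, nothing dropped
  orth <- gene_block("g", unclass(poly(1:100, 4)),
                     snp_ids = paste0("s", 1:4))
  expect_equal(unname(block_vif(orth$dosages)), rep(1, 4), tolerance = 1e-8)
  expect_identical(ncol(prune_vif(orth)$dosages), 4L)

  # a column that is the sum of two others plus tiny noise has huge VIF
  withr::with_seed(21, {
    x <- matrix(rnorm(300), 100, 3)
    x <- cbind(x, x[, 1] + x[, 2] + rnorm(100, sd = 0.01))
  })
  blk <- gene_block("g", x, snp_ids = paste0("s", 1:4))
  lm_r2 <- summary(lm(x[, 4] ~ x[, 1:3]))$r.squared
  expect_gt(1 / (1 - lm_r2), 2)            # oracle: direct least squares
  out <- prune_vif(blk, prune_config(vif_max = 2))
  expect_false("s4" %in% out$snp_ids)

  # postcondition via independent least-squares oracle, plus idempotence
  for (s in 1:10) {
    blk <- random_block(120, 6, seed = 900 + s, ld = 0.85)
    out <- prune_vif(blk, prune_config())
    xs <- out$dosages
    if (ncol(xs) > 1) {
      for (j in seq_len(ncol(xs))) {
        r2 <- summary(lm(xs[, j] ~ xs[, -j]))$r.squared
        expect_lte(1 / (1 - r2), 2 + 1e-6)
      }
    }
    expect_identical(prune_vif(out, prune_config())$snp_ids, out$snp_ids)
  }
})

test_that("config constructors validate their domains", {
  expect_error(qc_config(sample_call_rate_min = 1.2), "\\(0, 1\\)")
  expect_error(prune_config(r2_max = 0), "r2_max")
  expect_error(prune_config(vif_max = 0.5), "vif_max")
  expect_error(impute_config(k = 0), "positive")
})
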