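#' Genotype quality-control configuration
#'
#' Defaults follow standard array QC practice: samples with a genotype call
#' rate below 90% are removed first, then SNPs out of Hardy-Weinberg
#' equilibrium at p < 1e-7 (exact conditional test by default) or with minor
#' allele frequency below 1%.
#'
#' @param sample_call_rate_min Minimum per-sample call rate, in (0, 1).
#' @param hwe_p_min HWE p-value floor, in (0, 1).
#' @param maf_min Minimum minor allele frequency, in (0, 1).
#' @param hwe_test `"exact"` (two-sided exact conditional test) or
#'   `"chisq"` (1-df chi-square, no continuity correction).
#' @return A `qc_config` list.
#' @export
qc_config <- function(sample_call_rate_min = 0.90, hwe_p_min = 1e-7,
                      maf_min = 0.01, hwe_test = c("exact", "chisq")) {
  hwe_test <- match.arg(hwe_test)
  for (v in c(sample_call_rate_min, hwe_p_min, maf_min)) {
    if (!is_prob(v)) abort("qc_config thresholds must lie in (0, 1)")
  }
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 hwe_p_min = hwe_p_min, maf_min = maf_min,
                 hwe_test = hwe_test),
            class = "qc_config")
}

#' LD pruning configuration
#'
#' Two-stage pruning: pairwise squared correlation of dosages (composite LD)
#' with a strict `>` cutoff, then iterative variance-inflation-factor
#' removal. Defaults: `r2_max = 0.64`, `vif_max = 2`.
#'
#' @param r2_max Maximum retained pairwise r-squared, in (0, 1].
#' @param vif_max Maximum retained VIF, >= 1.
#' @return A `prune_config` list.
#' @export
prune_config <- function(r2_max = 0.64, vif_max = 2.0) {
  if (!(length(r2_max) == 1 && r2_max > 0 && r2_max <= 1)) {
    abort("r2_max must lie in (0, 1]")
  }
  if (!(length(vif_max) == 1 && vif_max >= 1)) abort("vif_max must be >= 1")
  structure(list(r2_max = r2_max, vif_max = vif_max), class = "prune_config")
}

#' Phenotype imputation configuration
#'
#' @param k Number of nearest neighbours (default 5).
#' @return An `impute_config` list.
#' @export
impute_config <- function(k = 5L) {
  if (!is_count(k)) abort("k must be a positive integer")
  structure(list(k = as.integer(k)), class = "impute_config")
}

#' k-nearest-neighbour phenotype imputation
#'
#' Each missing cell (i, j) is replaced by the mean of phenotype j over the
#' k samples nearest to sample i. Distances are root-mean-square Euclidean
#' over the phenotypes observed in both samples, computed on provisionally
#' column-standardised values (so no phenotype dominates by scale) and
#' ignoring column j itself. Observed cells are returned unchanged.
#'
#' @param phenotypes Tibble: `sample` ID column plus numeric phenotype
#'   columns, NA for missing.
#' @param cfg An [impute_config()].
#' @return The phenotype tibble with missing cells filled.
#' @export
impute_knn <- function(phenotypes, cfg = impute_config()) {
  m <- pheno_matrix(phenotypes)
  n <- nrow(m); p <- ncol(m)
  if (cfg$k >= n) abort("k must be smaller than the number of samples")
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0)) {
    abort(paste0("all-missing phenotype column(s): ",
                 paste(colnames(m)[n_obs == 0], collapse = ", ")))
  }
  if (any(n_obs < cfg$k)) {
    abort(paste0("phenotype column(s) with fewer than k observed values: ",
                 paste(colnames(m)[n_obs < cfg$k], collapse = ", ")))
  }
  if (any(rowSums(!is.na(m)) == 0)) {
    abort("sample(s) with no observed phenotype")
  }
  if (!anyNA(m)) return(phenotypes)
  mu <- colMeans(m, na.rm = TRUE)
  sg <- apply(m, 2, sd, na.rm = TRUE)
  sg[sg == 0 | is.na(sg)] <- 1
  z <- sweep(sweep(m, 2, mu), 2, sg, "/")
  out <- m
  for (i in which(rowSums(is.na(m)) > 0)) {
    for (j in which(is.na(m[i, ]))) {
      donors <- which(!is.na(m[, j]))
      shared <- !is.na(z[rep(i, length(donors)), -j, drop = FALSE]) &
        !is.na(z[donors, -j, drop = FALSE])
      diffs <- (z[rep(i, length(donors)), -j, drop = FALSE] -
                  z[donors, -j, drop = FALSE])^2
      diffs[!shared] <- NA
      n_shared <- rowSums(shared)
      d <- sqrt(rowSums(diffs, na.rm = TRUE) / n_shared)
      d[n_shared == 0] <- Inf
      usable <- which(is.finite(d))
      if (length(usable) == 0L) {
        abort(sprintf(
          "cannot impute sample %d, phenotype '%s': no donor shares an observed phenotype",
          i, colnames(m)[j]))
      }
      k_use <- min(cfg$k, length(usable))
      nn <- usable[order(d[usable])][seq_len(k_use)]
      out[i, j] <- mean(m[donors[nn], j])
    }
  }
  res <- phenotypes
  res[, -1] <- as_tibble(as.data.frame(out))
  res
}

#' Standardise phenotypes to mean zero, unit standard deviation
#'
#' Run after imputation: missing values are not allowed. Sample (n-1)
#' standard deviation is used.
#'
#' @param phenotypes Complete phenotype tibble (`sample` + numeric columns).
#' @return The tibble with each phenotype column standardised.
#' @export
normalize_phenotypes <- function(phenotypes) {
  m <- pheno_matrix(phenotypes)
  if (anyNA(m)) abort("missing values present; run impute_knn() first")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant phenotype column(s): ",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  z <- scale(m)
  res <- phenotypes
  res[, -1] <- as_tibble(as.data.frame(z))
  res
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: given the minor-allele count, sums the
#' probabilities of all heterozygote counts no more probable than the one
#' observed (Wigginton-style enumeration). A chi-square variant is available
#' through [qc_config()].
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major homozygote, heterozygote,
#'   minor homozygote; any consistent labelling works).
#' @return The exact two-sided p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  n_minor <- min(n_a, n_b)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- lfactorial(n) - lfactorial((n_minor - hets) / 2) -
    lfactorial(hets) - lfactorial((2 * n - n_minor - hets) / 2) +
    hets * log(2) + lfactorial(n_minor) + lfactorial(2 * n - n_minor) -
    lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

hwe_chisq_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  p <- (2 * n_aa + n_ab) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(e == 0)) return(1)
  x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' Removes low-call-rate samples first, then SNPs failing the HWE test or
#' the MAF floor, reporting every removal with its reason.
#'
#' @param genotypes A [genotype_matrix()].
#' @param cfg A [qc_config()].
#' @return List with the filtered `genotypes` and a `report` tibble
#'   (`type`, `id`, `reason`, `value`).
#' @export
qc_filter <- function(genotypes, cfg = qc_config()) {
  g <- genotypes
  report <- list()
  call_rate <- rowMeans(!is.na(g$dosages))
  bad_samples <- call_rate < cfg$sample_call_rate_min
  if (any(bad_samples)) {
    report[[length(report) + 1L]] <- tibble(
      type = "sample", id = g$samples[bad_samples],
      reason = "call_rate", value = call_rate[bad_samples])
  }
  if (all(bad_samples)) abort("all samples removed by call-rate filter")
  dos <- g$dosages[!bad_samples, , drop = FALSE]
  hwe_fun <- if (cfg$hwe_test == "exact") hwe_exact_p else hwe_chisq_p
  stats_per_snp <- apply(dos, 2, function(x) {
    x <- x[!is.na(x)]
    counts <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    f <- if (length(x) > 0) sum(x) / (2 * length(x)) else NA_real_
    c(maf = min(f, 1 - f), hwe = hwe_fun(counts[1], counts[2], counts[3]))
  })
  maf <- stats_per_snp["maf", ]
  hwe <- stats_per_snp["hwe", ]
  bad_maf <- is.na(maf) | maf < cfg$maf_min
  bad_hwe <- !bad_maf & hwe < cfg$hwe_p_min
  if (any(bad_hwe)) {
    report[[length(report) + 1L]] <- tibble(
      type = "snp", id = g$snp_ids[bad_hwe], reason = "hwe",
      value = hwe[bad_hwe])
  }
  if (any(bad_maf)) {
    report[[length(report) + 1L]] <- tibble(
      type = "snp", id = g$snp_ids[bad_maf], reason = "maf",
      value = maf[bad_maf])
  }
  keep <- !(bad_maf | bad_hwe)
  filtered <- genotype_matrix(
    samples = g$samples[!bad_samples],
    snp_ids = g$snp_ids[keep],
    coords = g$coords[keep, , drop = FALSE],
    dosages = dos[, keep, drop = FALSE])
  report <- if (length(report) > 0) bind_rows(report) else {
    tibble(type = character(0), id = character(0),
           reason = character(0), value = numeric(0))
  }
  list(genotypes = filtered, report = report)
}

#' Pairwise r-squared LD pruning of a gene block
#'
#' Greedy scan in genomic order: a SNP is dropped when its squared Pearson
#' correlation of dosages with any already-retained SNP strictly exceeds
#' `r2_max`; the earlier SNP of a correlated pair is kept.
#'
#' @param block A [gene_block()] (complete dosages).
#' @param cfg A [prune_config()].
#' @return The pruned `gene_block`.
#' @export
prune_r2 <- function(block, cfg = prune_config()) {
  x <- block$dosages
  q <- ncol(x)
  if (q == 1L) return(block)
  keep <- 1L
  for (j in 2:q) {
    r2 <- suppressWarnings(cor(x[, j], x[, keep, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    if (all(r2 <= cfg$r2_max)) keep <- c(keep, j)
  }
  subset_block(block, keep)
}

#' Variance-inflation-factor pruning of a gene block
#'
#' Iteratively computes `VIF_j = 1 / (1 - R2_j)`, where `R2_j` comes from
#' regressing SNP j's dosage on all other retained SNPs in the block, and
#' drops the arg-max SNP (ties break to the later genomic position) while
#' any VIF exceeds `vif_max`. Single-SNP blocks have VIF 1 by definition.
#' Run after [prune_r2()].
#'
#' @inheritParams prune_r2
#' @return The pruned `gene_block`, with all VIF at or below `vif_max`.
#' @export
prune_vif <- function(block, cfg = prune_config()) {
  keep <- seq_len(ncol(block$dosages))
  while (length(keep) > 1L) {
    v <- block_vif(block$dosages[, keep, drop = FALSE])
    if (max(v) <= cfg$vif_max) break
    worst <- max(which(v == max(v)))   # tie -> later genomic position
    keep <- keep[-worst]
  }
  subset_block(block, keep)
}

#' Variance inflation factors of a dosage block
#'
#' @param x Numeric matrix (complete). Returns 1 for a single column.
#' @return Numeric vector of VIFs, one per column (Inf for exactly
#'   collinear columns).
#' @export
block_vif <- function(x) {
  x <- as.matrix(x)
  q <- ncol(x)
  if (q == 1L) return(1)
  r <- suppressWarnings(cor(x))
  v <- tryCatch(diag(solve(r)), error = function(e) NULL)
  if (!is.null(v) && all(is.finite(v))) return(pmax(v, 1))
  # near-singular correlation matrix: fall back to per-column least squares
  vapply(seq_len(q), function(j) {
    fit <- lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else max(1 / (1 - r2), 1)
  }, numeric(1))
}

subset_block <- function(block, keep) {
  gene_block(block$gene,
             dosages = block$dosages[, keep, drop = FALSE],
             snp_ids = block$snp_ids[keep],
             chrom = block$chrom, start = block$start, end = block$end)
}
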