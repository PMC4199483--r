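#' Specification of a synthetic genotype/phenotype dataset
#'
#' Describes a cohort-like dataset: gene-centred SNP blocks with tunable
#' within-gene LD (a single equicorrelated latent Gaussian per gene,
#' thresholded at MAF-derived quantiles), phenotypes with a given
#' correlation matrix, planted gene-to-phenotype effects, and
#' missing-completely-at-random entries. Defaults mirror a cohort-scale
#' phenotype panel: 1.4% missing phenotype values, MAFs drawn uniformly from
#' (0.05, 0.5), no genotype missingness.
#'
#' @param n_samples Number of samples.
#' @param genes Tibble with columns `name`, `chrom`, `start`, `end`
#'   (BED convention), `n_snps` (1-50 typical).
#' @param n_phenotypes Number of phenotype columns.
#' @param target_ld Target within-gene pairwise squared dosage correlation,
#'   in [0, 1).
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param phenotype_correlation Positive-semidefinite correlation matrix
#'   (`n_phenotypes` square, unit diagonal); default identity.
#' @param effects Tibble of planted effects: `gene`, `snp_index` (causal SNP
#'   within the gene), `phenotype_idx` (list-column of affected phenotype
#'   indices), `beta` (effect in phenotypic SD per allele). Default none.
#' @param missing_rate Fraction of phenotype cells set missing, in [0, 1).
#' @param genotype_missing_rate Fraction of dosage cells set missing.
#' @param seed Integer seed; the same spec and seed give bit-identical data.
#' @return A validated `synth_spec`.
#' @export
synth_spec <- function(n_samples, genes, n_phenotypes,
                       target_ld = 0.3, maf_range = c(0.05, 0.5),
                       phenotype_correlation = NULL, effects = NULL,
                       missing_rate = 0.014, genotype_missing_rate = 0,
                       seed = 1L) {
  if (!is_count(n_samples, min = 2)) abort("n_samples must be an integer >= 2")
  genes <- as_tibble(genes)
  need <- c("name", "chrom", "start", "end", "n_snps")
  if (!all(need %in% names(genes))) {
    abort(paste0("genes needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(genes$name)) abort("duplicate gene names")
  if (any(genes$n_snps < 1)) abort("each gene needs >= 1 SNP")
  if (!(target_ld >= 0 && target_ld < 1)) abort("target_ld must lie in [0, 1)")
  if (!(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
        maf_range[1] <= maf_range[2])) {
    abort("maf_range must be an interval within (0, 0.5]")
  }
  if (is.null(phenotype_correlation)) {
    phenotype_correlation <- diag(n_phenotypes)
  }
  phenotype_correlation <- as.matrix(phenotype_correlation)
  if (!isTRUE(all.equal(dim(phenotype_correlation),
                        c(n_phenotypes, n_phenotypes)))) {
    abort("phenotype_correlation must be n_phenotypes x n_phenotypes")
  }
  if (max(abs(phenotype_correlation - t(phenotype_correlation))) > 1e-8 ||
      max(abs(diag(phenotype_correlation) - 1)) > 1e-8) {
    abort("phenotype_correlation must be symmetric with unit diagonal")
  }
  ev <- eigen(phenotype_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("phenotype_correlation is not positive semi-definite")
  if (is.null(effects)) {
    effects <- tibble(gene = character(0), snp_index = integer(0),
                      phenotype_idx = list(), beta = numeric(0))
  }
  effects <- as_tibble(effects)
  if (nrow(effects) > 0) {
    bad_gene <- setdiff(effects$gene, genes$name)
    if (length(bad_gene) > 0) {
      abort(paste0("effect references absent gene(s): ",
                   paste(bad_gene, collapse = ", ")))
    }
    for (i in seq_len(nrow(effects))) {
      qg <- genes$n_snps[genes$name == effects$gene[i]]
      if (effects$snp_index[i] < 1 || effects$snp_index[i] > qg) {
        abort(sprintf("effect %d references SNP index %d outside gene '%s' (%d SNPs)",
                      i, effects$snp_index[i], effects$gene[i], qg))
      }
      idx <- effects$phenotype_idx[[i]]
      if (any(idx < 1 | idx > n_phenotypes)) {
        abort(sprintf("effect %d references a phenotype outside 1..%d",
                      i, n_phenotypes))
      }
    }
  }
  if (!(missing_rate >= 0 && missing_rate < 1)) {
    abort("missing_rate must lie in [0, 1)")
  }
  structure(
    list(n_samples = as.integer(n_samples), genes = genes,
         n_phenotypes = as.integer(n_phenotypes), target_ld = target_ld,
         maf_range = maf_range, phenotype_correlation = phenotype_correlation,
         effects = effects, missing_rate = missing_rate,
         genotype_missing_rate = genotype_missing_rate,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# Latent equicorrelation rho for a gene: thresholding a Gaussian attenuates
# correlation (tetrachoric -> phi), so rho is solved such that the mean
# pairwise squared allele-indicator correlation over the gene's actual MAFs
# equals target_ld. The shared-factor integral is evaluated on a fixed
# Gaussian grid, vectorised over all SNP pairs.
latent_rho_for_ld <- function(target_ld, mafs) {
  q <- length(mafs)
  if (target_ld <= 0 || q < 2) return(0)
  z <- seq(-8, 8, length.out = 401)
  w <- dnorm(z) * (z[2] - z[1])
  qn <- qnorm(mafs)
  mean_r2 <- function(rho) {
    a <- outer(qn, sqrt(rho) * z, "-") / sqrt(1 - rho)
    b <- sweep(pnorm(a), 2, sqrt(w), "*")
    p11 <- tcrossprod(b)
    phi <- (p11 - outer(mafs, mafs)) /
      sqrt(outer(mafs * (1 - mafs), mafs * (1 - mafs)))
    mean(phi[upper.tri(phi)]^2)
  }
  if (mean_r2(0.999999) < target_ld) return(0.999999)
  uniroot(function(rho) mean_r2(rho) - target_ld,
          lower = 1e-9, upper = 0.999999, tol = 1e-9)$root
}

#' Generate a synthetic dataset
#'
#' Dosages are drawn per SNP as the sum of two haplotype allele indicators;
#' within a gene, alleles on the same haplotype share an equicorrelated
#' latent Gaussian factor whose correlation is calibrated (at the gene's
#' mean MAF) so that pairwise dosage r-squared matches `target_ld`.
#' Phenotypes are correlated Gaussian noise (unit SD, the spec's correlation
#' matrix) plus the planted additive genetic effects; missing entries are
#' then masked completely at random.
#'
#' @param spec A [synth_spec()].
#' @return A `synth_dataset`: `genotypes` (a [genotype_matrix()]),
#'   `phenotypes` tibble, `gene_coords` tibble, `truth` (verbatim copy of
#'   `spec$effects`), and the `spec` itself.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, synth_generate_impl(spec))
}

synth_generate_impl <- function(spec) {
  n <- spec$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  dos_list <- list(); coord_list <- list()
  for (gi in seq_len(nrow(spec$genes))) {
    g <- spec$genes[gi, ]
    q <- g$n_snps
    mafs <- runif(q, spec$maf_range[1], spec$maf_range[2])
    rho <- latent_rho_for_ld(spec$target_ld, mafs)
    hap <- function() {
      shared <- rnorm(n)
      z <- sqrt(rho) * shared +
        sqrt(1 - rho) * matrix(rnorm(n * q), n, q)
      sweep(z, 2, qnorm(mafs), "<") * 1
    }
    dos <- hap() + hap()
    ids <- sprintf("%s_snp%02d", g$name, seq_len(q))
    colnames(dos) <- ids
    pos <- unique(round(seq(g$start + 1, g$end, length.out = q)))
    while (length(pos) < q) pos <- sort(unique(c(pos, max(pos) + 1)))
    dos_list[[gi]] <- dos
    coord_list[[gi]] <- tibble(snp_id = ids, chrom = g$chrom, pos = pos)
  }
  dosages <- do.call(cbind, dos_list)
  coords <- bind_rows(coord_list)
  p <- spec$n_phenotypes
  noise <- matrix(rnorm(n * p), n, p) %*% chol(near_psd(spec$phenotype_correlation))
  y <- noise
  if (nrow(spec$effects) > 0) {
    for (i in seq_len(nrow(spec$effects))) {
      eff <- spec$effects[i, ]
      snp_col <- sprintf("%s_snp%02d", eff$gene, eff$snp_index)
      for (j in eff$phenotype_idx[[1]]) {
        y[, j] <- y[, j] + eff$beta * dosages[, snp_col]
      }
    }
  }
  colnames(y) <- sprintf("pheno_%02d", seq_len(p))
  if (spec$missing_rate > 0) {
    y[runif(n * p) < spec$missing_rate] <- NA
  }
  if (spec$genotype_missing_rate > 0) {
    dosages[runif(length(dosages)) < spec$genotype_missing_rate] <- NA
  }
  genotypes <- genotype_matrix(samples, colnames(dosages), coords, dosages)
  phenotypes <- dplyr::bind_cols(tibble(sample = samples),
                                 as_tibble(as.data.frame(y)))
  structure(
    list(genotypes = genotypes, phenotypes = phenotypes,
         gene_coords = spec$genes[, c("name", "chrom", "start", "end")],
         truth = spec$effects, spec = spec),
    class = "synth_dataset"
  )
}

# clip tiny negative eigenvalues so chol() accepts PSD-but-degenerate inputs
near_psd <- function(s) {
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) > 1e-10) return(s)
  v <- pmax(e$values, 1e-10)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "<synth_dataset> %d samples, %d SNPs in %d genes, %d phenotypes, %d planted effect(s)\n",
    length(x$genotypes$samples), length(x$genotypes$snp_ids),
    nrow(x$gene_coords), ncol(x$phenotypes) - 1L, nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the exact formats the pipeline consumes: `genotypes.vcf`,
#' `genes.bed` (0-based half-open), `phenotypes.tsv` (NA for missing), and
#' `truth.json` recording the planted effects.
#'
#' @param dataset A `synth_dataset` from [synth_generate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(dataset$genotypes, file.path(dir, "genotypes.vcf"))
  write_bed(dataset$gene_coords, file.path(dir, "genes.bed"))
  write_phenotypes(dataset$phenotypes, file.path(dir, "phenotypes.tsv"))
  truth <- dataset$truth
  truth_list <- if (nrow(truth) == 0) list() else {
    lapply(seq_len(nrow(truth)), function(i) {
      list(gene = truth$gene[i], snp_index = truth$snp_index[i],
           phenotype_idx = truth$phenotype_idx[[i]], beta = truth$beta[i])
    })
  }
  jsonlite::write_json(truth_list, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Evenly spaced synthetic gene table
#'
#' Convenience builder: `n_genes` genes on one chromosome, each spanning
#' 10 kb with a 100 kb spacing, holding `n_snps` SNPs apiece.
#'
#' @param n_genes Number of genes.
#' @param n_snps Integer vector (recycled) of SNPs per gene.
#' @param chrom Chromosome label.
#' @return Tibble suitable for [synth_spec()]'s `genes` argument.
#' @export
synth_gene_table <- function(n_genes, n_snps = 5L, chrom = "chr1") {
  starts <- (seq_len(n_genes) - 1L) * 100000L
  tibble(name = sprintf("gene%02d", seq_len(n_genes)), chrom = chrom,
         start = starts, end = starts + 10000L,
         n_snps = as.integer(rep_len(n_snps, n_genes)))
}
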