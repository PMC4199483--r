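#' Gene-centred SNP block
#'
#' Bundles one gene's dosage submatrix with its coordinates. Dosages are kept
#' on the raw 0/1/2 additive scale (mean-imputed if missing); standardisation
#' happens inside the CCA routines, which are scale-invariant.
#'
#' @param gene Gene name.
#' @param dosages Numeric matrix, samples x SNPs, no missing values.
#' @param snp_ids Character vector of SNP identifiers, one per column.
#' @param chrom,start,end Gene coordinates (BED convention: 0-based,
#'   half-open) carried along for reporting.
#' @return An object of class `gene_block`.
#' @export
gene_block <- function(gene, dosages, snp_ids = colnames(dosages),
                       chrom = NA_character_, start = NA_real_, end = NA_real_) {
  dosages <- as.matrix(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0(gene, "_snp", seq_len(ncol(dosages)))
  if (ncol(dosages) < 1L) abort("a gene block needs at least one SNP")
  if (length(snp_ids) != ncol(dosages)) {
    abort("snp_ids length must match the number of dosage columns")
  }
  if (anyNA(dosages)) abort("gene block dosages must be complete; impute first")
  colnames(dosages) <- snp_ids
  structure(
    list(gene = gene, dosages = dosages, snp_ids = snp_ids,
         chrom = chrom, start = start, end = end),
    class = "gene_block"
  )
}

#' @export
print.gene_block <- function(x, ...) {
  cat(sprintf("<gene_block> %s: %d samples x %d SNPs\n",
              x$gene, nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Canonical correlations between two matrices
#'
#' Computes the `min(p, q)` canonical correlations between the column spaces
#' of `x` (n x q) and `y` (n x p) via QR decomposition of each centred matrix
#' followed by an SVD of the cross-product of the orthonormal bases. This
#' avoids explicitly inverting covariance matrices and is numerically stable
#' for the modest block sizes produced by LD pruning.
#'
#' @param x,y Numeric matrices with the same number of rows and no missing
#'   values. Columns must be linearly independent (prune first).
#' @return Numeric vector of canonical correlations, sorted non-increasing,
#'   clipped to `[0, 1]`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2)
#' y <- matrix(rnorm(60), 20, 3)
#' canonical_correlations(x, y)
#' @export
canonical_correlations <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) abort("x and y must have the same number of rows")
  if (anyNA(x) || anyNA(y)) {
    abort("missing values in CCA input; imputation must run upstream")
  }
  n <- nrow(x); q <- ncol(x); p <- ncol(y)
  if (n <= p + q + 1) {
    abort(sprintf(
      "too few samples for CCA: need n > p + q + 1 (n = %d, p = %d, q = %d)",
      n, p, q))
  }
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  qrx <- qr(xc)
  qry <- qr(yc)
  if (qrx$rank < q || qry$rank < p) {
    abort("rank-deficient input: columns are collinear; apply LD/VIF pruning first")
  }
  d <- svd(crossprod(qr.Q(qrx)[, seq_len(q), drop = FALSE],
                     qr.Q(qry)[, seq_len(p), drop = FALSE]),
           nu = 0, nv = 0)$d
  sort(pmin(pmax(d, 0), 1), decreasing = TRUE)[seq_len(min(p, q))]
}

#' Wilks' Lambda / Rao's F test of all canonical correlations
#'
#' Tests the joint null that every canonical correlation between a q-variable
#' set and a p-variable set is zero. Wilks' Lambda is
#' \eqn{\Lambda = \prod_j (1 - r_j^2)} over the `min(p, q)` canonical
#' correlations; Rao's approximation transforms it to an F statistic with
#' `df1 = p * q` and `df2 = w * t - p * q / 2 + 1` degrees of freedom, where
#' `w = n - (p + q + 3) / 2` and
#' `t = sqrt((p^2 q^2 - 4) / (p^2 + q^2 - 5))` (with `t = 1` when
#' `p^2 + q^2 - 5 <= 0`, which covers the 1x1 and 1x2 cases). The p-value is
#' carried on the log10 scale throughout so that associations far below the
#' double-precision floor remain representable.
#'
#' @param r Canonical correlations, e.g. from [canonical_correlations()].
#' @param n,p,q Sample size and the two set sizes.
#' @return A `cca_result` object: canonical correlations, Wilks' Lambda, the
#'   Rao exponent `t`, `f_stat`, `df1`, `df2`, and `log10_p`.
#' @export
wilks_rao_test <- function(r, n, p, q) {
  c_comp <- min(p, q)
  if (length(r) != c_comp) {
    abort(sprintf("expected %d canonical correlations, got %d", c_comp, length(r)))
  }
  r <- pmin(pmax(r, 0), 1 - 1e-12)
  lambda <- prod(1 - r^2)
  t_exp <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- n - (p + q + 3) / 2
  df1 <- p * q
  df2 <- w * t_exp - p * q / 2 + 1
  if (df2 <= 0) {
    abort(sprintf(
      "non-positive denominator degrees of freedom (df2 = %.2f): subset sizes too large for n = %d",
      df2, n))
  }
  lam_t <- lambda^(1 / t_exp)
  f_stat <- (1 - lam_t) / lam_t * df2 / df1
  log10_p <- if (lambda == 0) -Inf else log10_pf_upper(f_stat, df1, df2)
  structure(
    list(r = r, c = c_comp, wilks_lambda = lambda, t = t_exp,
         df1 = df1, df2 = df2, f_stat = f_stat, log10_p = log10_p,
         n = n, p = p, q = q),
    class = "cca_result"
  )
}

#' CCA association test between two matrices
#'
#' Convenience composition of [canonical_correlations()] and
#' [wilks_rao_test()].
#'
#' @inheritParams canonical_correlations
#' @return A `cca_result`.
#' @export
cca_test <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  r <- canonical_correlations(x, y)
  wilks_rao_test(r, n = nrow(x), p = ncol(y), q = ncol(x))
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> n = %d, q = %d SNPs, p = %d phenotypes\n",
              x$n, x$q, x$p))
  cat(sprintf("  canonical r: %s\n", paste(signif(x$r, 4), collapse = ", ")))
  cat(sprintf("  Wilks' Lambda = %.6g, Rao F(%g, %.1f) = %.4g\n",
              x$wilks_lambda, x$df1, x$df2, x$f_stat))
  cat(sprintf("  log10 p = %.4g  (p = %.4g)\n", x$log10_p, linear_p(x$log10_p)))
  invisible(x)
}

#' Gene-block vs phenotype-set association
#'
#' Runs the Wilks/Rao CCA test between one gene's pruned dosage block and a
#' chosen subset of phenotype columns. Results can be memoised through an
#' environment `cache` keyed by gene and subset, which the genetic-algorithm
#' search exploits heavily.
#'
#' @param block A [gene_block()].
#' @param phenotypes Data frame whose first column is the sample ID and whose
#'   remaining columns are complete numeric phenotypes (post-imputation).
#' @param subset Character vector of phenotype column names to test.
#' @param cache Optional environment used to memoise results.
#' @return A `cca_result` with `gene` and `phenotypes` fields attached.
#' @export
gene_phenotype_association <- function(block, phenotypes, subset,
                                       cache = NULL) {
  if (length(subset) == 0L) abort("phenotype subset must be non-empty")
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(block$gene, paste(sort(subset), collapse = ";"), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  y <- pheno_matrix(phenotypes, subset)
  if (anyNA(y)) abort("phenotype subset contains missing values; impute first")
  res <- cca_test(block$dosages, y)
  res$gene <- block$gene
  res$phenotypes <- subset
  if (!is.null(cache)) cache[[key]] <- res
  res
}

# sample-ID-first phenotype tibble -> numeric matrix (optionally a column subset)
pheno_matrix <- function(phenotypes, subset = NULL) {
  stopifnot(is.data.frame(phenotypes), ncol(phenotypes) >= 2L)
  vals <- phenotypes[, -1, drop = FALSE]
  if (!is.null(subset)) {
    missing_cols <- setdiff(subset, names(vals))
    if (length(missing_cols) > 0) {
      abort(paste0("unknown phenotype column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    vals <- vals[, subset, drop = FALSE]
  }
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("all phenotype columns after the sample ID must be numeric")
  }
  m <- as.matrix(vals)
  rownames(m) <- as.character(phenotypes[[1]])
  m
}
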