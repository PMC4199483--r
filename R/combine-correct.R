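#' Fisher's combined probability test
#'
#' Combines k p-values into one via \eqn{X^2 = -2 \sum_i \ln p_i}, referred to
#' a chi-square distribution with 2k degrees of freedom. Inputs may be given
#' on the linear scale (`p`) or, for extreme values, on the log10 scale
#' (`log10_p`); exactly one of the two must be supplied. The combined p-value
#' is computed in log space and never underflows.
#'
#' An optional Brown-style adjustment for positively correlated inputs scales
#' the chi-square mean/variance using the phenotype correlation matrix
#' (Kost–McDermott polynomial approximation of the covariance of
#' \eqn{-2\ln p} terms). The plain Fisher combination is the default and is
#' what the pipeline reports.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param log10_p Numeric vector of log10 p-values (non-positive; may be very
#'   negative).
#' @param correlation Optional correlation matrix of the combined variables
#'   (k x k); triggers the Brown-style adjustment.
#' @return A `combined_result`: `statistic`, `df`, `log10_p`.
#' @examples
#' fisher_combine(c(0.05, 0.05))
#' @export
fisher_combine <- function(p = NULL, log10_p = NULL, correlation = NULL) {
  if (is.null(p) == is.null(log10_p)) {
    abort("supply exactly one of `p` or `log10_p`")
  }
  if (!is.null(p)) {
    if (length(p) == 0L) abort("need at least one p-value")
    if (any(p <= 0)) {
      abort("p-values must be > 0; pass extreme values via `log10_p`")
    }
    if (any(p > 1)) abort("p-values must be <= 1")
    log10_p <- log10(p)
  }
  if (length(log10_p) == 0L) abort("need at least one p-value")
  if (any(log10_p > 0)) abort("log10 p-values must be <= 0")
  k <- length(log10_p)
  stat <- -2 * LOG10 * sum(log10_p)
  df <- 2 * k
  if (is.null(correlation)) {
    out_log10_p <- log10_pchisq_upper(stat, df)
  } else {
    correlation <- as.matrix(correlation)
    if (!isTRUE(all.equal(dim(correlation), c(k, k)))) {
      abort("correlation must be k x k for k p-values")
    }
    rho <- correlation[upper.tri(correlation)]
    cov_terms <- 3.263 * rho + 0.710 * rho^2 + 0.027 * rho^3
    mean_x2 <- 2 * k
    var_x2 <- 4 * k + 2 * sum(cov_terms)
    scale_c <- var_x2 / (2 * mean_x2)
    df_adj <- 2 * mean_x2^2 / var_x2
    out_log10_p <- log10_pchisq_upper(stat / scale_c, df_adj)
    df <- df_adj
  }
  structure(list(statistic = stat, df = df, log10_p = out_log10_p),
            class = "combined_result")
}

#' @export
print.combined_result <- function(x, ...) {
  cat(sprintf("<combined_result> X2 = %.4g on %g df, log10 p = %.4g\n",
              x$statistic, x$df, x$log10_p))
  invisible(x)
}

#' Size of a subset search space
#'
#' Counts \eqn{\sum_{k=k_{min}}^{k_{max}} \binom{n}{k}}, the number of
#' candidate item subsets a bounded search could propose, both exactly (via
#' arbitrary-precision integer arithmetic) and as a log-sum-exp over
#' log-gamma terms. The two routes are cross-checked internally; the exact
#' route supplies the reported `log10_count` and decimal digit string.
#'
#' @param n_items Universe size (number of genes or phenotypes).
#' @param k_min,k_max Inclusive subset-size bounds.
#' @return A `search_space`: `n_items`, `k_min`, `k_max`, `log10_count`,
#'   `count` (exact decimal string), `log10_count_lse`.
#' @examples
#' subset_count(82, 2, 24)   # the phenotype-rule space
#' @export
subset_count <- function(n_items, k_min, k_max) {
  if (!is_count(n_items)) abort("n_items must be a positive integer")
  if (!is_count(k_min) || !is_count(k_max) ||
      k_min > k_max || k_max > n_items) {
    abort("need 1 <= k_min <= k_max <= n_items")
  }
  # exact: C(n, k+1) = C(n, k) * (n - k) / (k + 1)
  cur <- big_from_int(1)            # C(n, 0)
  total <- NULL
  for (k in seq_len(k_max)) {
    cur <- big_div_small(big_mul_small(cur, n_items - k + 1), k)
    if (k >= k_min) {
      total <- if (is.null(total)) cur else big_add(total, cur)
    }
  }
  log10_exact <- big_log10(total)
  # log-sum-exp over lchoose terms
  lg <- lchoose(n_items, k_min:k_max) / LOG10
  m <- max(lg)
  log10_lse <- m + log10(sum(10^(lg - m)))
  if (abs(log10_exact - log10_lse) > 1e-6) {
    abort("internal error: exact and log-sum-exp subset counts disagree")
  }
  structure(
    list(n_items = n_items, k_min = k_min, k_max = k_max,
         log10_count = log10_exact, count = big_to_string(total),
         log10_count_lse = log10_lse),
    class = "search_space"
  )
}

#' A single-item (unit) search space
#'
#' The degenerate space used when one side of a rule is not searched, e.g.
#' the gene side of the per-gene phenotype search, where the multiplicity is
#' just the number of genes scanned.
#'
#' @param n_items Number of fixed alternatives (default 1).
#' @return A `search_space` with `log10_count = log10(n_items)`.
#' @export
unit_space <- function(n_items = 1L) {
  if (!is_count(n_items)) abort("n_items must be a positive integer")
  structure(
    list(n_items = n_items, k_min = 1L, k_max = 1L,
         log10_count = log10(n_items),
         count = format(n_items, scientific = FALSE),
         log10_count_lse = log10(n_items)),
    class = "search_space"
  )
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("<search_space> sum C(%d, %d..%d) = %s (log10 = %.4f)\n",
              x$n_items, x$k_min, x$k_max,
              format_count(x$count), x$log10_count))
  invisible(x)
}

format_count <- function(s) {
  if (nchar(s) <= 15) s else {
    sprintf("%s.%se%d", substr(s, 1, 1), substr(s, 2, 4), nchar(s) - 1L)
  }
}

#' Search-space-aware Bonferroni threshold
#'
#' Divides the family-wise error rate by the product of the gene-side and
#' phenotype-side search-space sizes, on the log10 scale:
#' `log10(alpha) - log10 |gene space| - log10 |phenotype space|`. A rule is
#' flagged significant when its CCA `log10_p` does not exceed this threshold.
#' This is deliberately conservative: it corrects for every rule the search
#' could in principle have proposed, not just those it evaluated.
#'
#' @param alpha Family-wise error rate in (0, 1). Default 0.05.
#' @param gene_space,phenotype_space `search_space` objects (see
#'   [subset_count()], [unit_space()]); default unit spaces.
#' @return The log10-scale significance threshold (a negative number).
#' @examples
#' bonferroni_threshold(0.05, unit_space(3648), unit_space(82))
#' @export
bonferroni_threshold <- function(alpha = 0.05, gene_space = unit_space(),
                                 phenotype_space = unit_space()) {
  if (!is_prob(alpha)) abort("alpha must lie in (0, 1)")
  stopifnot(inherits(gene_space, "search_space"),
            inherits(phenotype_space, "search_space"))
  log10(alpha) - gene_space$log10_count - phenotype_space$log10_count
}
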