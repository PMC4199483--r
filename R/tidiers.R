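#' Tidy a CCA test result
#'
#' One row per canonical component.
#'
#' @param x A `cca_result`.
#' @param ... Unused.
#' @return Tibble with `component`, `correlation`.
#' @method tidy cca_result
#' @export
tidy.cca_result <- function(x, ...) {
  tibble(component = seq_along(x$r), correlation = x$r)
}

#' One-row summary of a CCA test result
#'
#' @param x A `cca_result`.
#' @param ... Unused.
#' @return Tibble with dimensions, Wilks' Lambda, Rao's F, degrees of
#'   freedom, `log10_p`, and the floored linear-scale `p_value`.
#' @method glance cca_result
#' @export
glance.cca_result <- function(x, ...) {
  tibble(n = x$n, p = x$p, q = x$q, wilks_lambda = x$wilks_lambda,
         f_stat = x$f_stat, df1 = x$df1, df2 = x$df2,
         log10_p = x$log10_p, p_value = linear_p(x$log10_p))
}

#' Tidy a combined p-value result
#'
#' @param x A `combined_result`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `log10_p`, `p_value`.
#' @method tidy combined_result
#' @export
tidy.combined_result <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, log10_p = x$log10_p,
         p_value = linear_p(x$log10_p))
}

#' Canonical-correlation bar chart
#'
#' @param object A `cca_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cca_result
#' @export
autoplot.cca_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(component), correlation)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Canonical component", y = "Canonical correlation") +
    ggplot2::theme_minimal()
}

#' Association-rule significance plot
#'
#' Dot plot of rules by association strength (-log10 p), with the
#' search-space Bonferroni threshold as a reference line.
#'
#' @param rules A rule tibble from one of the `run_*` stages.
#' @param top Show at most this many top rules.
#' @return A ggplot.
#' @export
plot_rules <- function(rules, top = 30L) {
  df <- head(rules, top)
  lab <- paste(map_chr(df$genes, paste, collapse = ";"),
               map_chr(df$phenotypes, paste, collapse = ";"), sep = " ~ ")
  df2 <- tibble(rule = factor(lab, levels = rev(lab)),
                neglog10 = -df$cca_log10_p,
                significant = df$significant)
  thr <- attr(rules, "log10_threshold")
  p <- ggplot2::ggplot(df2, ggplot2::aes(neglog10, rule,
                                         colour = significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL,
                  colour = "Significant") +
    ggplot2::theme_minimal()
  if (!is.null(thr) && is.finite(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = -thr, linetype = "dashed")
  }
  p
}
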