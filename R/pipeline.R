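#' Preprocess a dataset into analysis-ready form
#'
#' Runs the full preparation chain: genotype QC (call rate, HWE, MAF),
#' sample alignment between genotypes and phenotypes, kNN phenotype
#' imputation, standardisation, closest-gene SNP assignment, and two-stage
#' LD pruning (pairwise r-squared, then VIF) per gene block. After this every
#' block's dosage matrix has full column rank, so CCA is well-posed.
#'
#' @param genotypes A [genotype_matrix()].
#' @param genes Gene interval tibble (`chrom`, `start`, `end`, `name`; BED
#'   convention).
#' @param phenotypes Phenotype tibble (`sample` + numeric columns, NA
#'   allowed).
#' @param qc,prune,impute Configuration objects ([qc_config()],
#'   [prune_config()], [impute_config()]).
#' @param max_distance Optional cap on SNP-to-gene distance (default none).
#' @return A `pleio_data` list: `blocks` (pruned [gene_block()]s),
#'   `phenotypes` (imputed, standardised), `gene_map`, `qc_report`,
#'   `prune_info`.
#' @export
preprocess_data <- function(genotypes, genes, phenotypes,
                            qc = qc_config(), prune = prune_config(),
                            impute = impute_config(), max_distance = Inf) {
  qcres <- qc_filter(genotypes, qc)
  g <- qcres$genotypes
  if (length(g$snp_ids) == 0L) abort("no SNPs left after QC")
  shared <- intersect(g$samples, phenotypes[[1]])
  if (length(shared) == 0L) abort("no samples shared between genotypes and phenotypes")
  g <- genotype_matrix(shared, g$snp_ids, g$coords,
                       g$dosages[match(shared, g$samples), , drop = FALSE])
  ph <- phenotypes[match(shared, phenotypes[[1]]), , drop = FALSE]
  ph <- normalize_phenotypes(impute_knn(ph, impute))
  gmap <- assign_snps_to_genes(g$coords, genes, max_distance = max_distance)
  if (nrow(gmap$assignment) == 0L) abort("no SNPs assigned to any gene")
  blocks <- make_gene_blocks(g, gmap)
  info <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b0 <- blocks[[i]]
    b1 <- prune_r2(b0, prune)
    b2 <- prune_vif(b1, prune)
    blocks[[i]] <- b2
    info[[i]] <- tibble(gene = b0$gene, n_snps = ncol(b0$dosages),
                        n_after_r2 = ncol(b1$dosages),
                        n_after_vif = ncol(b2$dosages))
  }
  structure(
    list(blocks = blocks, phenotypes = ph, gene_map = gmap,
         qc_report = qcres$report, prune_info = bind_rows(info)),
    class = "pleio_data"
  )
}

#' @export
print.pleio_data <- function(x, ...) {
  cat(sprintf("<pleio_data> %d gene blocks, %d samples, %d phenotypes\n",
              length(x$blocks), nrow(x$phenotypes), ncol(x$phenotypes) - 1L))
  invisible(x)
}

phenotype_names <- function(data) names(data$phenotypes)[-1]

# all single-gene / single-phenotype log10 p-values (genes x phenotypes)
marginal_matrix <- function(data, cache = NULL) {
  phs <- phenotype_names(data)
  out <- matrix(NA_real_, length(data$blocks), length(phs),
                dimnames = list(names(data$blocks), phs))
  for (gname in names(data$blocks)) {
    for (ph in phs) {
      out[gname, ph] <- gene_phenotype_association(
        data$blocks[[gname]], data$phenotypes, ph, cache = cache)$log10_p
    }
  }
  out
}

# concatenate pruned blocks for a gene set and re-apply VIF pruning jointly,
# so that pooled multi-gene CCA stays well-posed
pooled_block <- function(data, genes, prune = prune_config()) {
  mats <- lapply(genes, function(g) data$blocks[[g]]$dosages)
  joint <- gene_block(paste(genes, collapse = "+"), do.call(cbind, mats))
  prune_vif(joint, prune)
}

rule_table <- function(genes_list, phen_list, cca_log10_p, marginals,
                       fisher_log10_p, log10_threshold) {
  cca_log10_p <- unname(unlist(cca_log10_p))
  out <- tibble(
    genes = unname(genes_list), phenotypes = unname(phen_list),
    cca_log10_p = cca_log10_p, cca_p = linear_p(cca_log10_p),
    fisher_log10_p = unname(unlist(fisher_log10_p)),
    marginals = unname(marginals),
    significant = cca_log10_p <= log10_threshold
  )
  out <- out[order(out$cca_log10_p), , drop = FALSE]
  attr(out, "log10_threshold") <- log10_threshold
  class(out) <- c("rule_table", class(out))
  out
}

#' @export
print.rule_table <- function(x, ...) {
  cat(sprintf("<rule_table> %d rules, log10 threshold %.4g, %d significant\n",
              nrow(x), attr(x, "log10_threshold"), sum(x$significant)))
  NextMethod()
}

#' Stage 1: every gene against every single phenotype
#'
#' Plain gene-centred CCA of each pruned block against each phenotype, with
#' a Bonferroni threshold over the genes x phenotypes grid.
#'
#' @param data A `pleio_data` from [preprocess_data()].
#' @param alpha Family-wise error rate.
#' @return A rule [tibble][tibble::tibble] sorted by `cca_log10_p`
#'   (list-columns `genes`, `phenotypes`, `marginals`; attribute
#'   `log10_threshold`).
#' @export
run_1g1p <- function(data, alpha = 0.05) {
  if (length(data$blocks) == 0L) abort("no gene blocks after preprocessing")
  phs <- phenotype_names(data)
  thr <- bonferroni_threshold(alpha, unit_space(length(data$blocks)),
                              unit_space(length(phs)))
  marg <- marginal_matrix(data)
  grid <- expand.grid(gene = rownames(marg), phenotype = colnames(marg),
                      stringsAsFactors = FALSE)
  lp <- marg[cbind(grid$gene, grid$phenotype)]
  rule_table(
    genes_list = map(grid$gene, identity),
    phen_list = map(grid$phenotype, identity),
    cca_log10_p = lp,
    marginals = map2(grid$phenotype, lp, function(ph, v) setNames(v, ph)),
    fisher_log10_p = lp,          # single test: Fisher of one p is itself
    log10_threshold = thr
  )
}

default_ga_1gNp <- function(n_phenotypes, seed = NULL) {
  ga_config(population_size = 100L, elitism = 20L, zero_to_one_ratio = 50,
            mutation_rate = NULL, k_max = as.integer(min(24L, n_phenotypes)),
            seed = seed)
}

default_ga_Ng1p <- function(n_genes, seed = NULL) {
  ga_config(population_size = 600L, elitism = 35L, zero_to_one_ratio = 700,
            mutation_rate = NULL, k_max = as.integer(min(29L, n_genes)),
            seed = seed)
}

default_ga_NgNp <- function(n_genes, n_phenotypes, seed = NULL) {
  list(
    genes = ga_config(population_size = 1000L, elitism = 100L,
                      zero_to_one_ratio = 700, k_max = as.integer(min(22L, n_genes)),
                      seed = seed),
    phenotypes = ga_config(population_size = 1000L, elitism = 100L,
                           zero_to_one_ratio = 50,
                           k_max = as.integer(min(9L, n_phenotypes)), seed = seed)
  )
}

#' Stage 2: per-gene phenotype-set search
#'
#' For each gene, a binary GA selects the phenotype subset maximising the
#' CCA association with the gene's SNP block. Each reported rule is
#' annotated with the per-phenotype marginal p-values and their Fisher
#' combination; the Bonferroni threshold covers the gene count times the
#' phenotype-subset search space (subsets of size 2 up to `k_max`).
#'
#' @param data A `pleio_data`.
#' @param ga A [ga_config()]; defaults to the phenotype-search preset
#'   (population 100, elitism 20, zero-to-one ratio 50, `k_max` 24).
#' @param alpha Family-wise error rate.
#' @param seed Integer; per-gene GA seeds are derived from it.
#' @return Rule tibble, one row per gene, sorted by `cca_log10_p`.
#' @export
run_1gNp <- function(data, ga = NULL, alpha = 0.05, seed = 1L) {
  phs <- phenotype_names(data)
  if (is.null(ga)) ga <- default_ga_1gNp(length(phs))
  cache <- new.env(parent = emptyenv())
  marg <- marginal_matrix(data, cache = cache)
  k_max <- min(ga$k_max, length(phs))
  thr <- bonferroni_threshold(
    alpha, unit_space(length(data$blocks)),
    subset_count(length(phs), min(2L, k_max), k_max))
  res <- imap(data$blocks, function(block, gname) {
    fit <- function(subset) {
      res <- tryCatch(
        gene_phenotype_association(block, data$phenotypes, subset,
                                   cache = cache),
        error = function(e) NULL)
      if (is.null(res)) -Inf else -res$log10_p
    }
    ga_i <- ga
    ga_i$seed <- (ga$seed %||% seed) + match(gname, names(data$blocks))
    top <- evolve_single(phs, ga_i, fit)
    list(gene = gname, phenotypes = top$items[[1]], fitness = top$fitness[1])
  })
  marginals <- map(res, function(r) setNames(marg[r$gene, r$phenotypes],
                                             r$phenotypes))
  rule_table(
    genes_list = map(res, function(r) r$gene),
    phen_list = map(res, "phenotypes"),
    cca_log10_p = -map_dbl(res, "fitness"),
    marginals = marginals,
    fisher_log10_p = map_dbl(marginals, function(m) {
      fisher_combine(log10_p = m)$log10_p
    }),
    log10_threshold = thr
  )
}

#' Stage 3: per-phenotype gene-set search
#'
#' For each phenotype, a binary GA selects the gene subset whose pooled SNPs
#' (concatenated pruned blocks, re-pruned jointly by VIF) maximise the CCA
#' association with that phenotype. Rules carry per-gene marginal p-values
#' and their Fisher combination; the threshold covers the phenotype count
#' times the gene-subset space (subsets of size 1 up to `k_max`).
#'
#' @inheritParams run_1gNp
#' @param ga Defaults to the gene-search preset (population 600, elitism 35,
#'   zero-to-one ratio 700, `k_max` 29).
#' @param prune [prune_config()] used for the joint re-pruning.
#' @return Rule tibble, one row per phenotype.
#' @export
run_Ng1p <- function(data, ga = NULL, alpha = 0.05, prune = prune_config(),
                     seed = 1L) {
  gene_names <- names(data$blocks)
  if (length(gene_names) == 0L) abort("no gene blocks after preprocessing")
  if (is.null(ga)) ga <- default_ga_Ng1p(length(gene_names))
  cache <- new.env(parent = emptyenv())
  marg <- marginal_matrix(data, cache = cache)
  phs <- phenotype_names(data)
  k_max <- min(ga$k_max, length(gene_names))
  thr <- bonferroni_threshold(
    alpha, subset_count(length(gene_names), 1L, k_max),
    unit_space(length(phs)))
  res <- imap(setNames(phs, phs), function(ph, nm) {
    fit <- function(genes) {
      val <- tryCatch({
        pooled <- pooled_block(data, genes, prune)
        -gene_phenotype_association(pooled, data$phenotypes, ph)$log10_p
      }, error = function(e) -Inf)
      val
    }
    ga_i <- ga
    ga_i$seed <- (ga$seed %||% seed) + match(ph, phs)
    top <- evolve_single(gene_names, ga_i, fit)
    list(phenotype = ph, genes = top$items[[1]], fitness = top$fitness[1])
  })
  marginals <- map(res, function(r) setNames(marg[r$genes, r$phenotype],
                                             r$genes))
  rule_table(
    genes_list = map(res, "genes"),
    phen_list = map(res, "phenotype"),
    cca_log10_p = -map_dbl(res, "fitness"),
    marginals = marginals,
    fisher_log10_p = map_dbl(marginals, function(m) {
      fisher_combine(log10_p = m)$log10_p
    }),
    log10_threshold = thr
  )
}

#' Stage 4: joint gene-set / phenotype-set search
#'
#' Two cooperating GA populations, one over gene subsets and one over
#' phenotype subsets, evolved in parallel with the joint CCA association as
#' fitness (pooled, jointly re-pruned SNPs of the selected genes against the
#' selected phenotypes). All evaluated rules are deduplicated and ranked;
#' the threshold covers both subset spaces (sizes 2 up to each side's
#' `k_max`, defaults 22 genes and 9 phenotypes).
#'
#' @inheritParams run_Ng1p
#' @param ga Optional list with `genes` and `phenotypes` [ga_config()]s.
#' @param max_rules Keep at most this many top rules (default 100).
#' @return Rule tibble ranked by `cca_log10_p`.
#' @export
run_NgNp <- function(data, ga = NULL, alpha = 0.05, prune = prune_config(),
                     max_rules = 100L, seed = 1L) {
  gene_names <- names(data$blocks)
  phs <- phenotype_names(data)
  if (length(gene_names) == 0L) abort("no gene blocks after preprocessing")
  if (is.null(ga)) ga <- default_ga_NgNp(length(gene_names), length(phs))
  if (is.null(ga$genes$seed)) ga$genes$seed <- seed
  cache <- new.env(parent = emptyenv())
  marg <- marginal_matrix(data, cache = cache)
  fit <- function(genes, phenos) {
    tryCatch({
      pooled <- pooled_block(data, genes, prune)
      -gene_phenotype_association(pooled, data$phenotypes, phenos)$log10_p
    }, error = function(e) -Inf)
  }
  gk <- min(ga$genes$k_max, length(gene_names))
  pk <- min(ga$phenotypes$k_max, length(phs))
  thr <- bonferroni_threshold(
    alpha,
    subset_count(length(gene_names), min(2L, gk), gk),
    subset_count(length(phs), min(2L, pk), pk))
  rules <- evolve_dual(gene_names, phs, ga$genes, ga$phenotypes, fit)
  rules <- head(rules, max_rules)
  marginals <- map2(rules$genes, rules$phenotypes, function(gs, ps) {
    vapply(gs, function(g) {
      gene_phenotype_association(data$blocks[[g]], data$phenotypes, ps,
                                 cache = cache)$log10_p
    }, numeric(1))
  })
  rule_table(
    genes_list = rules$genes,
    phen_list = rules$phenotypes,
    cca_log10_p = -rules$fitness,
    marginals = marginals,
    fisher_log10_p = map_dbl(marginals, function(m) {
      fisher_combine(log10_p = m)$log10_p
    }),
    log10_threshold = thr
  )
}

#' Run the pipeline end-to-end from files
#'
#' Reads genotypes (VCF or dosage TSV), gene intervals (BED) and phenotypes
#' (TSV), preprocesses, dispatches one of the four analysis modes, and
#' writes `rules.tsv`, `qc_report.tsv` and a JSON run manifest to the output
#' directory.
#'
#' @param config Path to a YAML config, or an equivalent named list. Keys:
#'   `mode` (one of `1g1p`, `1gNp`, `Ng1p`, `NgNp`), `genotypes`, `genes`,
#'   `phenotypes` (paths), optional `preprocess` (`qc`, `prune`, `impute`
#'   blocks), `correction` (`alpha`, `k_max_genes`, `k_max_phenotypes`),
#'   `ga` (any [ga_config()] field), `out`.
#' @param seed Integer seed for the stochastic search stages.
#' @param out Output directory (overrides the config's `out`).
#' @return The rule tibble, invisibly.
#' @export
run_pipeline <- function(config, seed = 1L, out = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  mode <- match.arg(cfg$mode, c("1g1p", "1gNp", "Ng1p", "NgNp"))
  out <- out %||% cfg$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  genotypes <- read_genotypes(cfg$genotypes)
  genes <- read_bed(cfg$genes)
  phenotypes <- read_phenotypes(cfg$phenotypes)
  pp <- cfg$preprocess %||% list()
  qc <- do.call(qc_config, pp$qc %||% list())
  prune <- do.call(prune_config, pp$prune %||% list())
  impute <- do.call(impute_config, pp$impute %||% list())
  data <- preprocess_data(genotypes, genes, phenotypes, qc, prune, impute,
                          max_distance = pp$max_distance %||% Inf)
  alpha <- cfg$correction$alpha %||% 0.05
  ga_over <- cfg$ga %||% list()
  mk_ga <- function(defaults) {
    do.call(ga_config, modifyList(defaults[names(defaults) != "class"],
                                  ga_over))
  }
  rules <- switch(
    mode,
    "1g1p" = run_1g1p(data, alpha = alpha),
    "1gNp" = run_1gNp(data, ga = mk_ga(unclass(
      default_ga_1gNp(ncol(data$phenotypes) - 1L))), alpha = alpha,
      seed = seed),
    "Ng1p" = run_Ng1p(data, ga = mk_ga(unclass(
      default_ga_Ng1p(length(data$blocks)))), alpha = alpha, prune = prune,
      seed = seed),
    "NgNp" = {
      defaults <- default_ga_NgNp(length(data$blocks),
                                  ncol(data$phenotypes) - 1L)
      run_NgNp(data, ga = list(genes = mk_ga(unclass(defaults$genes)),
                               phenotypes = mk_ga(unclass(defaults$phenotypes))),
               alpha = alpha, prune = prune, seed = seed)
    })
  write_rules(rules, file.path(out, "rules.tsv"))
  readr::write_tsv(data$qc_report, file.path(out, "qc_report.tsv"))
  manifest <- list(
    mode = mode, seed = seed, alpha = alpha,
    n_samples = nrow(data$phenotypes),
    n_genes = length(data$blocks),
    n_phenotypes = ncol(data$phenotypes) - 1L,
    log10_threshold = attr(rules, "log10_threshold"),
    n_rules = nrow(rules), n_significant = sum(rules$significant),
    multi_gene_pooling = "concatenate pruned blocks, joint VIF re-pruning"
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rules)
}
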