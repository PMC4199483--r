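#' Genetic-algorithm configuration
#'
#' Binary-encoded GA for subset selection: each chromosome is a bit vector
#' over the candidate universe; a set bit includes the item. Initial bits
#' (and re-drawn mutated bits) are 1 with probability
#' `1 / (1 + zero_to_one_ratio)`, so the ratio controls sparsity. Parent
#' selection is rank-weighted roulette, crossover is single-point, and the
#' top `elitism` individuals survive unchanged, which makes the best fitness
#' non-decreasing across generations. Chromosomes with no set bits, or more
#' than `k_max` set bits, receive worst fitness rather than being repaired.
#'
#' The field-scale presets used by the four analysis modes are: population
#' 100 / elitism 20 / ratio 50 for the per-gene phenotype search; population
#' 600 / elitism 35 / ratio 700 for the per-phenotype gene search; and
#' population 1000 / elitism 100 for the two-population search. Mutation
#' defaults to 1 / chromosome length.
#'
#' @param population_size Number of chromosomes.
#' @param mutation_rate Per-bit mutation probability; `NULL` means
#'   1 / universe size.
#' @param elitism Individuals copied unchanged into the next generation.
#' @param zero_to_one_ratio Expected zeros per one at initialisation and
#'   mutation (>= 1).
#' @param generations Maximum generations.
#' @param stagnation Stop early after this many generations without
#'   improvement of the best fitness.
#' @param k_max Maximum number of selected items per chromosome.
#' @param crossover Apply single-point crossover (disable for degenerate
#'   dynamics testing).
#' @param seed Integer seed; runs are deterministic given config + seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 100L, mutation_rate = NULL,
                      elitism = 20L, zero_to_one_ratio = 50,
                      generations = 100L, stagnation = 20L,
                      k_max = Inf, crossover = TRUE, seed = NULL) {
  if (!is_count(population_size, 2)) abort("population_size must be >= 2")
  if (!is.null(mutation_rate) &&
      !(length(mutation_rate) == 1 && mutation_rate >= 0 && mutation_rate < 1)) {
    abort("mutation_rate must lie in [0, 1)")
  }
  if (!is_count(elitism, 0) || elitism > population_size) {
    abort("elitism must be a count not exceeding population_size")
  }
  if (!(zero_to_one_ratio >= 1)) abort("zero_to_one_ratio must be >= 1")
  if (!is_count(generations)) abort("generations must be a positive integer")
  structure(
    list(population_size = as.integer(population_size),
         mutation_rate = mutation_rate, elitism = as.integer(elitism),
         zero_to_one_ratio = zero_to_one_ratio,
         generations = as.integer(generations),
         stagnation = as.integer(stagnation), k_max = k_max,
         crossover = isTRUE(crossover), seed = seed),
    class = "ga_config"
  )
}

# evaluate a population matrix against a memoising fitness wrapper
eval_population <- function(bits, universe, k_max, fit_env, fitness) {
  apply(bits, 1, function(b) {
    s <- sum(b)
    if (s == 0 || s > k_max) return(-Inf)
    key <- paste(which(b == 1L), collapse = ",")
    hit <- fit_env[[key]]
    if (!is.null(hit)) return(hit)
    val <- fitness(universe[b == 1L])
    if (!is.finite(val)) val <- -Inf
    fit_env[[key]] <- val
    val
  })
}

ga_breed <- function(bits, fit, cfg, p_one) {
  np <- cfg$population_size
  len <- ncol(bits)
  ord <- order(fit, decreasing = TRUE)
  bits <- bits[ord, , drop = FALSE]
  fit <- fit[ord]
  elite <- bits[seq_len(cfg$elitism), , drop = FALSE]
  n_child <- np - cfg$elitism
  # rank-weighted roulette: weight proportional to reversed rank
  w <- rev(seq_len(np)) / sum(seq_len(np))
  pa <- sample.int(np, n_child, replace = TRUE, prob = w)
  pb <- sample.int(np, n_child, replace = TRUE, prob = w)
  children <- matrix(0L, n_child, len)
  for (i in seq_len(n_child)) {
    if (cfg$crossover && len > 1L) {
      cut <- sample.int(len - 1L, 1L)
      children[i, ] <- c(bits[pa[i], seq_len(cut)],
                         bits[pb[i], (cut + 1L):len])
    } else {
      children[i, ] <- bits[pa[i], ]
    }
  }
  mu <- cfg$mutation_rate %||% (1 / len)
  flip <- matrix(runif(n_child * len) < mu, n_child, len)
  if (any(flip)) {
    children[flip] <- as.integer(runif(sum(flip)) < p_one)
  }
  rbind(elite, children)
}

init_population <- function(np, len, p_one) {
  bits <- matrix(as.integer(runif(np * len) < p_one), np, len)
  # guarantee at least one non-empty chromosome so generation 0 has a best
  empty <- rowSums(bits) == 0
  if (all(empty)) bits[1, sample.int(len, 1L)] <- 1L
  bits
}

#' Single-population GA subset search
#'
#' Evolves subsets of `universe` to maximise `fitness` (the association
#' value, as -log10 p, of the subset against a fixed other side). Fitness
#' evaluations are memoised across the run.
#'
#' @param universe Character vector of candidate items (phenotype or gene
#'   names).
#' @param cfg A [ga_config()].
#' @param fitness Function taking a non-empty character subset and returning
#'   a finite fitness (larger is better) or `-Inf` for inadmissible subsets.
#' @return A `ga_result`: tibble of the final population, deduplicated and
#'   ranked by fitness, with list-column `items`; attributes `trace`
#'   (per-generation best fitness) and `n_evaluations`.
#' @export
evolve_single <- function(universe, cfg = ga_config(), fitness) {
  if (length(universe) == 0L) abort("empty universe")
  run <- function() evolve_single_impl(universe, cfg, fitness)
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

evolve_single_impl <- function(universe, cfg, fitness) {
  len <- length(universe)
  p_one <- 1 / (1 + cfg$zero_to_one_ratio)
  fit_env <- new.env(parent = emptyenv())
  bits <- init_population(cfg$population_size, len, p_one)
  fit <- eval_population(bits, universe, cfg$k_max, fit_env, fitness)
  trace <- max(fit)
  stagnant <- 0L
  for (gen in seq_len(cfg$generations - 1L)) {
    bits <- ga_breed(bits, fit, cfg, p_one)
    fit <- eval_population(bits, universe, cfg$k_max, fit_env, fitness)
    best <- max(fit)
    stagnant <- if (best > tail(trace, 1) + 1e-12) 0L else stagnant + 1L
    trace <- c(trace, max(best, tail(trace, 1)))
    if (stagnant >= cfg$stagnation) break
  }
  ord <- order(fit, decreasing = TRUE)
  bits <- bits[ord, , drop = FALSE]
  fit <- fit[ord]
  keys <- apply(bits, 1, paste, collapse = "")
  keep <- !duplicated(keys)
  out <- tibble(
    items = map(seq_len(sum(keep)), function(i) {
      universe[bits[which(keep)[i], ] == 1L]
    }),
    fitness = fit[keep]
  )
  structure(out, class = c("ga_result", class(out)),
            trace = trace, n_evaluations = length(ls(fit_env)))
}

#' Two-population cooperative GA for joint gene/phenotype rules
#'
#' Runs one population over gene subsets and one over phenotype subsets in
#' parallel. An individual's fitness is the joint CCA association of its
#' subset paired with the best individual of the other population from the
#' previous generation (generation 0 pairs with a random individual). All
#' evaluated (gene-set, phenotype-set) rules are collected, deduplicated and
#' ranked.
#'
#' @param gene_universe,phenotype_universe Candidate item names.
#' @param cfg_genes,cfg_phenotypes [ga_config()] for each population; the
#'   run length and seed are taken from `cfg_genes`.
#' @param fitness Function `(genes, phenotypes) -> fitness` (larger is
#'   better; `-Inf` for inadmissible rules).
#' @param pairing `"best"` (classic cooperative coevolution) or `"random"`
#'   (pair with a random member of the other population each generation).
#' @return A `ga_rules` tibble: list-columns `genes`, `phenotypes`, plus
#'   `fitness`, ranked decreasing; attribute `trace`.
#' @export
evolve_dual <- function(gene_universe, phenotype_universe,
                        cfg_genes = ga_config(population_size = 1000L,
                                              elitism = 100L),
                        cfg_phenotypes = cfg_genes,
                        fitness, pairing = c("best", "random")) {
  pairing <- match.arg(pairing)
  if (length(gene_universe) == 0L || length(phenotype_universe) == 0L) {
    abort("empty universe")
  }
  run <- function() {
    evolve_dual_impl(gene_universe, phenotype_universe, cfg_genes,
                     cfg_phenotypes, fitness, pairing)
  }
  if (is.null(cfg_genes$seed)) run() else withr::with_seed(cfg_genes$seed, run())
}

evolve_dual_impl <- function(gu, pu, cfg_g, cfg_p, fitness, pairing) {
  lg <- length(gu); lp <- length(pu)
  pg_one <- 1 / (1 + cfg_g$zero_to_one_ratio)
  pp_one <- 1 / (1 + cfg_p$zero_to_one_ratio)
  bits_g <- init_population(cfg_g$population_size, lg, pg_one)
  bits_p <- init_population(cfg_p$population_size, lp, pp_one)
  rules <- new.env(parent = emptyenv())
  pair_fitness <- function(genes, phenos) {
    if (length(genes) == 0 || length(genes) > cfg_g$k_max ||
        length(phenos) == 0 || length(phenos) > cfg_p$k_max) return(-Inf)
    key <- paste(paste(sort(genes), collapse = ","),
                 paste(sort(phenos), collapse = ","), sep = "|")
    hit <- rules[[key]]
    if (!is.null(hit)) return(hit$fitness)
    val <- fitness(genes, phenos)
    if (!is.finite(val)) val <- -Inf
    rules[[key]] <- list(genes = sort(genes), phenotypes = sort(phenos),
                         fitness = val)
    val
  }
  subset_of <- function(bits, i, universe) universe[bits[i, ] == 1L]
  # a partner must itself be an admissible subset (1..k_max bits), otherwise
  # every pairing would be penalised and the search would receive no signal
  admissible_row <- function(bits, k_max) {
    sizes <- rowSums(bits)
    ok <- which(sizes >= 1 & sizes <= k_max)
    if (length(ok) > 0) return(if (length(ok) == 1) ok else sample(ok, 1L))
    ne <- which(sizes > 0)
    if (length(ne) > 0) return(if (length(ne) == 1) ne else sample(ne, 1L))
    NA_integer_
  }
  pick_partner <- function(bits, universe, best_subset, k_max) {
    if (pairing == "best" && !is.null(best_subset)) return(best_subset)
    i <- admissible_row(bits, k_max)
    if (is.na(i)) universe[sample.int(length(universe), 1L)] else
      subset_of(bits, i, universe)
  }
  best_g <- NULL; best_p <- NULL
  trace <- numeric(0)
  stagnant <- 0L
  for (gen in seq_len(cfg_g$generations)) {
    partner_p <- pick_partner(bits_p, pu, best_p, cfg_p$k_max)
    fit_g <- vapply(seq_len(nrow(bits_g)), function(i) {
      pair_fitness(subset_of(bits_g, i, gu), partner_p)
    }, numeric(1))
    partner_g <- pick_partner(bits_g, gu, best_g, cfg_g$k_max)
    fit_p <- vapply(seq_len(nrow(bits_p)), function(i) {
      pair_fitness(partner_g, subset_of(bits_p, i, pu))
    }, numeric(1))
    # keep the previous best when a whole generation is inadmissible
    if (any(is.finite(fit_g))) best_g <- subset_of(bits_g, which.max(fit_g), gu)
    if (any(is.finite(fit_p))) best_p <- subset_of(bits_p, which.max(fit_p), pu)
    gen_best <- max(max(fit_g), max(fit_p))
    prev <- if (length(trace) > 0) tail(trace, 1) else -Inf
    stagnant <- if (gen_best > prev + 1e-12) 0L else stagnant + 1L
    trace <- c(trace, max(gen_best, prev))
    if (stagnant >= cfg_g$stagnation) break
    if (gen < cfg_g$generations) {
      bits_g <- ga_breed(bits_g, fit_g, cfg_g, pg_one)
      bits_p <- ga_breed(bits_p, fit_p, cfg_p, pp_one)
    }
  }
  all_rules <- lapply(ls(rules), function(k) rules[[k]])
  out <- tibble(
    genes = map(all_rules, "genes"),
    phenotypes = map(all_rules, "phenotypes"),
    fitness = map_dbl(all_rules, "fitness")
  )
  out <- out[is.finite(out$fitness), , drop = FALSE]
  out <- out[order(out$fitness, decreasing = TRUE), , drop = FALSE]
  structure(out, class = c("ga_rules", class(out)), trace = trace)
}

#' Merge repeated GA runs
#'
#' Runs a GA search `n_restarts` times with different seeds and merges the
#' per-start rankings, deduplicating identical (gene-set, phenotype-set) or
#' item-set rules and re-ranking by fitness.
#'
#' @param run_fn Function of one argument (the seed) returning a `ga_result`
#'   or `ga_rules` tibble.
#' @param seeds Integer vector of seeds, one per restart.
#' @return The merged, deduplicated, fitness-ranked tibble.
#' @export
multi_start <- function(run_fn, seeds) {
  if (length(seeds) < 1L) abort("need at least one seed")
  runs <- map(seeds, run_fn)
  merged <- bind_rows(lapply(runs, as_tibble))
  key <- if ("items" %in% names(merged)) {
    map_chr(merged$items, function(s) paste(sort(s), collapse = ","))
  } else {
    paste(map_chr(merged$genes, function(s) paste(sort(s), collapse = ",")),
          map_chr(merged$phenotypes, function(s) paste(sort(s), collapse = ",")),
          sep = "|")
  }
  merged <- merged[!duplicated(key), , drop = FALSE]
  merged[order(merged$fitness, decreasing = TRUE), , drop = FALSE]
}

#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  trace <- attr(object, "trace")
  df <- tibble(generation = seq_along(trace), best_fitness = trace)
  ggplot2::ggplot(df, ggplot2::aes(generation, best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Generation", y = "Best fitness (-log10 p)",
                  title = "GA convergence") +
    ggplot2::theme_minimal()
}
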