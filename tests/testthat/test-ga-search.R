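# deterministic toy fitness landscapes let the GA be checked against
# exhaustive enumeration without any stochastic data

subset_score <- function(target, weights = NULL) {
  # peak at `target`; each wrong inclusion/exclusion costs 1 (or its weight)
  function(subset) {
    u <- union(subset, target)
    miss <- setdiff(target, subset)
    extra <- setdiff(subset, target)
    10 - length(miss) * 2 - length(extra)
  }
}

exhaustive_best <- function(universe, fitness, k_max = length(universe)) {
  best <- NULL; best_fit <- -Inf
  for (k in seq_len(k_max)) {
    for (idx in utils::combn(length(universe), k, simplify = FALSE)) {
      f <- fitness(universe[idx])
      if (f > best_fit) { best_fit <- f; best <- universe[idx] }
    }
  }
  list(subset = best, fitness = best_fit)
}

test_that("single-population GA finds the exhaustive optimum on a small universe", {
  universe <- c("A", "B", "C")
  fit <- subset_score(c("A", "B"))
  oracle <- exhaustive_best(universe, fit)
  expect_setequal(oracle$subset, c("A", "B"))
  res <- evolve_single(universe, ga_config(population_size = 20L, elitism = 4L,
                                           zero_to_one_ratio = 2,
                                           generations = 30L, seed = 1L), fit)
  expect_setequal(res$items[[1]], oracle$subset)
  expect_equal(res$fitness[1], oracle$fitness)
})

test_that("GA matches exhaustive optimum in >= 90% of seeded runs (12 items)", {
  universe <- LETTERS[1:12]
  fit <- subset_score(c("C", "G", "K"))
  oracle <- exhaustive_best(universe, fit, k_max = 6)
  wins <- 0L
  for (s in 1:20) {
    res <- evolve_single(universe,
                         ga_config(population_size = 40L, elitism = 8L,
                                   zero_to_one_ratio = 3, generations = 60L,
                                   stagnation = 25L, seed = s), fit)
    if (setequal(res$items[[1]], oracle$subset)) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("degenerate dynamics leave the population invariant", {
  universe <- letters[1:6]
  fit <- subset_score(c("a", "b"))
  cfg <- ga_config(population_size = 10L, mutation_rate = 0,
                   elitism = 10L, crossover = FALSE, zero_to_one_ratio = 2,
                   generations = 15L, stagnation = 50L, seed = 3L)
  res <- evolve_single(universe, cfg, fit)
  # with full elitism, no mutation and no crossover, generation 0's best is
  # never displaced and the trace is flat
  trace <- attr(res, "trace")
  expect_true(all(abs(diff(trace)) < 1e-12))
  # the final population equals the initial one (same seed, one generation)
  cfg1 <- cfg; cfg1$generations <- 1L
  res1 <- evolve_single(universe, cfg1, fit)
  expect_identical(res$items, res1$items)
  expect_identical(res$fitness, res1$fitness)
})

test_that("GA runs are deterministic given config + seed and track elitism", {
  universe <- LETTERS[1:8]
  fit <- subset_score(c("B", "E"))
  cfg <- ga_config(population_size = 24L, elitism = 6L, zero_to_one_ratio = 3,
                   generations = 25L, seed = 11L)
  r1 <- evolve_single(universe, cfg, fit)
  r2 <- evolve_single(universe, cfg, fit)
  expect_identical(r1$items, r2$items)
  expect_identical(r1$fitness, r2$fitness)
  # elitism makes the best fitness non-decreasing
  expect_sorted_desc(-attr(r1, "trace"))
  expect_sorted_desc(r1$fitness)
})

test_that("zero-bit and over-k_max chromosomes are penalised, not repaired", {
  universe <- LETTERS[1:6]
  fit <- function(subset) length(subset)       # favours big subsets
  res <- evolve_single(universe,
                       ga_config(population_size = 30L, elitism = 5L,
                                 zero_to_one_ratio = 1, generations = 40L,
                                 k_max = 2L, seed = 5L), fit)
  expect_lte(length(res$items[[1]]), 2L)
  expect_equal(res$fitness[1], 2)
  ok <- which(is.finite(res$fitness))
  sizes <- vapply(res$items[ok], length, integer(1))
  expect_true(all(sizes >= 1L & sizes <= 2L))
})

test_that("two-population GA recovers a planted joint rule", {
  genes <- sprintf("g%d", 1:6)
  phenos <- sprintf("p%d", 1:8)
  fit <- function(gs, ps) {
    subset_score(c("g2"))(gs) + subset_score(c("p3", "p5"))(ps)
  }
  # exhaustive oracle over all (<= 2-gene, <= 3-phenotype) rules
  best_fit <- -Inf; best <- NULL
  for (kg in 1:2) for (gidx in utils::combn(6, kg, simplify = FALSE)) {
    for (kp in 1:3) for (pidx in utils::combn(8, kp, simplify = FALSE)) {
      f <- fit(genes[gidx], phenos[pidx])
      if (f > best_fit) { best_fit <- f; best <- list(genes[gidx], phenos[pidx]) }
    }
  }
  cfg <- ga_config(population_size = 40L, elitism = 8L, zero_to_one_ratio = 2,
                   generations = 40L, stagnation = 15L, seed = 7L)
  rules <- evolve_dual(genes, phenos, cfg, cfg, fit)
  expect_setequal(rules$genes[[1]], best[[1]])
  expect_setequal(rules$phenotypes[[1]], best[[2]])
  expect_equal(rules$fitness[1], best_fit)
  # determinism
  rules2 <- evolve_dual(genes, phenos, cfg, cfg, fit)
  expect_identical(rules$genes, rules2$genes)
  expect_identical(rules$fitness, rules2$fitness)
})

test_that("multi_start merges and deduplicates rules across restarts", {
  universe <- letters[1:5]
  fit <- subset_score(c("a", "c"))
  run <- function(seed) {
    evolve_single(universe, ga_config(population_size = 12L, elitism = 3L,
                                      zero_to_one_ratio = 2,
                                      generations = 15L, seed = seed), fit)
  }
  merged <- multi_start(run, seeds = c(1L, 2L, 3L))
  keys <- vapply(merged$items, function(s) paste(sort(s), collapse = ","),
                 character(1))
  expect_false(any(duplicated(keys)))
  expect_sorted_desc(merged$fitness)
  single <- multi_start(run, seeds = 1L)
  direct <- run(1L)
  expect_identical(single$fitness, direct$fitness)
  sum_parts <- nrow(run(1L)) + nrow(run(2L)) + nrow(run(3L))
  expect_lte(nrow(merged), sum_parts)
  expect_error(multi_start(run, seeds = integer(0)), "at least one")
})

test_that("GA config presets match the documented field-scale parameters", {
  cfg <- pleiocca:::default_ga_1gNp(82)
  expect_identical(cfg$population_size, 100L)
  expect_identical(cfg$elitism, 20L)
  expect_identical(cfg$zero_to_one_ratio, 50)
  expect_identical(cfg$k_max, 24L)
  expect_null(cfg$mutation_rate)     # resolves to 1/universe at run time
  cfgN <- pleiocca:::default_ga_Ng1p(3648)
  expect_identical(cfgN$population_size, 600L)
  expect_identical(cfgN$elitism, 35L)
  expect_identical(cfgN$zero_to_one_ratio, 700)
  expect_identical(cfgN$k_max, 29L)
  cfgD <- pleiocca:::default_ga_NgNp(3648, 82)
  expect_identical(cfgD$genes$population_size, 1000L)
  expect_identical(cfgD$genes$elitism, 100L)
  expect_identical(cfgD$genes$k_max, 22L)
  expect_identical(cfgD$phenotypes$k_max, 9L)
})
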