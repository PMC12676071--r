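test_that("landscape frequencies and cM/Mb rates follow from event counts", {
  map <- tiny_map(chroms = "1R", lengths_mb = 800, n = 10)
  events <- data.frame(chromosome = rep("1R", 10),
                       position_rel = rep(0.25, 10))
  ls <- build_landscape(events, n_gametes = 100, map)
  w <- ls[ls$window == 2, ]
  expect_equal(w$n_events, 10L)
  expect_equal(w$frequency, 0.1)
  expect_equal(w$window_mb, 80)
  expect_equal(w$rate_cm_per_mb, 0.125)
  expect_equal(sum(ls$n_events), 10L)

  empty <- build_landscape(events[0, ], 100, map)
  expect_true(all(empty$n_events == 0L))
  expect_true(all(empty$rate_cm_per_mb == 0))
  expect_error(build_landscape(events, 0, map), "positive")
})

test_that("the genome-wide rate equals mean crossovers per gamete over genome size", {
  b <- simulate_cohort(sim_config(n_individuals = 20, seed = 41))
  r <- analyze_cohort(b)
  ls <- build_landscape(r$events, nrow(r$nuclei), r$map)
  genome_mb <- sum(attr(r$map, "chrom_lengths")) / 1e6
  expect_equal(attr(ls, "genome_rate_cm_per_mb"),
               mean(r$summary$per_nucleus$n_co) * 100 / genome_mb)
  # identical to summing window frequencies
  expect_equal(attr(ls, "genome_rate_cm_per_mb"),
               sum(ls$frequency) * 100 / genome_mb)
})

test_that("uniform crossover placement gives an approximately flat landscape", {
  b <- simulate_cohort(sim_config(n_individuals = 80, seed = 31,
                                  recomb_profile = "uniform"))
  r <- analyze_cohort(b)
  cnt <- table(factor(round(r$events$position_rel * 10), levels = 1:9))
  expect_gt(chisq.test(as.integer(cnt))$p.value, 0.01)
})

test_that("landscape comparison: identity, anti-symmetry, and grid checks", {
  map <- tiny_map(chroms = "1R", lengths_mb = 800, n = 10)
  events <- data.frame(chromosome = "1R",
                       position_rel = rep(seq(0.1, 0.9, by = 0.1),
                                          times = c(1:5, 4:1)))
  a <- build_landscape(events, 50, map)
  cmp <- compare_landscapes(a, a)
  expect_equal(cmp$pearson_r, 1)
  expect_true(all(cmp$windows$p_adj == 1))

  # reversing a monotone profile anti-correlates
  mono <- data.frame(chromosome = "1R",
                     position_rel = rep(seq(0.1, 0.9, by = 0.1), times = 1:9))
  rev_mono <- data.frame(chromosome = "1R",
                         position_rel = rep(seq(0.1, 0.9, by = 0.1), times = 9:1))
  expect_lt(compare_landscapes(build_landscape(mono, 50, map),
                               build_landscape(rev_mono, 50, map))$pearson_r, 0)

  map2 <- tiny_map(chroms = c("1R", "2R"), lengths_mb = c(800, 700), n = 5)
  b2 <- build_landscape(mono, 50, map2)
  expect_error(compare_landscapes(a, b2), "different")
})

test_that("BH adjustment preserves the raw p-value ordering", {
  b1 <- simulate_cohort(sim_config(n_individuals = 30, seed = 43))
  b2 <- simulate_cohort(sim_config(n_individuals = 30, seed = 44), map = b1$map)
  r1 <- analyze_cohort(b1); r2 <- analyze_cohort(b2)
  cmp <- compare_landscapes(build_landscape(r1$events, nrow(r1$nuclei), r1$map),
                            build_landscape(r2$events, nrow(r2$nuclei), r2$map))
  w <- cmp$windows
  expect_true(all(w$p_adj >= w$chisq_p - 1e-12))
  ord <- order(w$chisq_p)
  expect_true(all(diff(w$p_adj[ord]) >= -1e-12))
})

test_that("group effects run one-way ANOVA with Tukey contrasts", {
  traits <- data.frame(individual_id = as.character(1:6),
                       subpopulation = "diversity_panel",
                       treatment = rep(c("control", "nutrient_deficiency"), each = 3),
                       cc_per_chromatid = c(1, 2, 3, 1, 2, 3))
  ge <- group_effects(traits, "cc_per_chromatid")
  expect_equal(ge$contrasts$estimate, 0)
  expect_equal(ge$contrasts$p_adj, 1)

  # hand-computed one-way ANOVA on a small two-group example
  y <- c(2, 3, 4, 6, 7, 8); g <- rep(c("a", "b"), each = 3)
  traits2 <- data.frame(individual_id = as.character(1:6),
                        subpopulation = g, treatment = "control",
                        cc_per_chromatid = y)
  ssb <- 3 * (mean(y[1:3]) - mean(y))^2 + 3 * (mean(y[4:6]) - mean(y))^2
  ssw <- sum((y[1:3] - mean(y[1:3]))^2) + sum((y[4:6] - mean(y[4:6]))^2)
  f_manual <- (ssb / 1) / (ssw / 4)
  ge2 <- group_effects(traits2, "cc_per_chromatid", factors = "subpopulation")
  expect_equal(ge2$anova$f, f_manual)
  expect_equal(abs(ge2$contrasts$estimate), 4)

  # undersized groups are skipped with a warning
  traits3 <- traits2
  traits3$subpopulation[6] <- "c"
  expect_warning(group_effects(traits3, "cc_per_chromatid",
                               factors = "subpopulation"), "skipped")
})

test_that("allele stacking orders by frequency and detects additive effects", {
  set.seed(8)
  n <- 400; M <- 6
  A <- vapply(seq_len(M), function(m) as.integer(runif(n) < 0.8 - 0.1 * m),
              integer(n))
  rownames(A) <- sprintf("ind%03d", seq_len(n))
  colnames(A) <- sprintf("al%d", seq_len(M))
  traits <- data.frame(individual_id = rownames(A),
                       subpopulation = "diversity_panel", treatment = "control",
                       cc_per_chromatid = 2 + 0.05 * rowSums(A) + rnorm(n, 0, 0.1))
  st <- allele_stacking(traits, A)
  expect_identical(st$stack$allele, colnames(A))   # already frequency-ordered
  expect_gt(st$spearman_rho, 0)
  expect_lt(st$spearman_p, 0.01)
  expect_true(all(diff(st$stack$n) <= 0))          # nested subsets shrink

  # no effect: correlation is near zero
  traits$cc_per_chromatid <- 2 + rnorm(n, 0, 0.1)
  st0 <- allele_stacking(traits, A)
  expect_lt(abs(st0$spearman_rho), 0.2)

  # one allele, two carrier groups: stacked mean is the carrier-group mean
  A1 <- A[, 1, drop = FALSE]
  st1 <- allele_stacking(traits, A1)
  expect_equal(st1$stack$mean_trait,
               mean(traits$cc_per_chromatid[A1[, 1] == 1]))
})
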