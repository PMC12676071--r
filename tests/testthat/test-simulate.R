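test_that("the simulator is deterministic given its seed", {
  cfg <- sim_config(n_individuals = 4, seed = 99)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$gametes$calls, b2$gametes$calls)
  expect_identical(b1$diploid$calls, b2$diploid$calls)
  expect_identical(b1$map$position_bp, b2$map$position_bp)
  expect_identical(b1$truth, b2$truth)
  b3 <- simulate_cohort(sim_config(n_individuals = 4, seed = 100))
  expect_false(identical(b1$gametes$calls, b3$gametes$calls))
})

test_that("without interference crossover counts are Poisson with mean lambda", {
  set.seed(314)
  co <- gametecross:::batch_crossovers(1e4, 2.2, 1, identity)
  n <- lengths(co)
  se <- sqrt(var(n) / length(n))
  expect_lt(abs(mean(n) - 2.2), 3 * se)
  expect_lt(abs(var(n) / mean(n) - 1), 0.1)
})

test_that("interference preserves the mean but shrinks count dispersion", {
  set.seed(271)
  co <- gametecross:::batch_crossovers(1e4, 2.2, 5, identity)
  n <- lengths(co)
  expect_lt(abs(mean(n) - 2.2), 3 * sqrt(var(n) / length(n)))
  expect_lt(var(n) / mean(n), 0.8)
})

test_that("error and missingness are realised at their nominal rates", {
  cfg <- sim_config(n_individuals = 20, seed = 55)
  b <- simulate_cohort(cfg)
  M <- nrow(b$map) * cfg$nuclei_per_individual
  err <- vapply(b$truth, function(tr) length(tr$error_idx), numeric(1))
  mis <- vapply(b$truth, function(tr) length(tr$missing_idx), numeric(1))
  n_tot <- 20 * M
  expect_lt(abs(sum(err) / n_tot - 0.01), 4 * sqrt(0.01 * 0.99 / n_tot))
  expect_lt(abs(sum(mis) / n_tot - 0.05), 4 * sqrt(0.05 * 0.95 / n_tot))
  # realised missingness in the emitted calls (errors can hide under masks)
  expect_lt(abs(mean(is.na(b$gametes$calls)) - 0.05), 0.005)
})

test_that("the treatment effect reduces true crossover rates by delta", {
  b <- simulate_cohort(sim_config(n_individuals = 300, seed = 66))
  tc <- true_crossover_counts(b)
  tc$treatment <- b$meta$treatment[match(tc$individual_id, b$meta$individual_id)]
  ratio <- mean(tc$n_co_true[tc$treatment == "nutrient_deficiency"]) /
           mean(tc$n_co_true[tc$treatment == "control"])
  expect_lt(abs(ratio - 0.92), 0.02)

  b0 <- simulate_cohort(sim_config(n_individuals = 300, nd_effect_delta = 0,
                                   seed = 67))
  tc0 <- true_crossover_counts(b0)
  tc0$treatment <- b0$meta$treatment[match(tc0$individual_id, b0$meta$individual_id)]
  ratio0 <- mean(tc0$n_co_true[tc0$treatment == "nutrient_deficiency"]) /
            mean(tc0$n_co_true[tc0$treatment == "control"])
  expect_lt(abs(ratio0 - 1), 0.02)
})

test_that("cohort bundles have the reference shape and window geometry", {
  cfg <- sim_config(seed = 1)
  expect_identical(cfg$n_individuals, 584L)
  b <- simulate_cohort(sim_config(n_individuals = 8, seed = 2))
  expect_identical(nrow(b$nuclei), 48L)
  expect_identical(dim(b$gametes$calls), c(48L, nrow(b$map)))
  expect_identical(dim(b$diploid$calls), c(8L, nrow(b$map)))
  # 10% windows of the default chromosomes span 73-96 Mb
  win_mb <- cfg$chrom_lengths_mb * 0.1
  expect_true(all(win_mb >= 73 & win_mb <= 96))
})

test_that("obligate crossover mode leaves no chromatid without a crossover", {
  b <- simulate_cohort(sim_config(n_individuals = 4, obligate_co = TRUE,
                                  lambda_cc = 1, seed = 3))
  n_co <- unlist(lapply(b$truth, function(tr)
    lapply(tr$nuclei, function(nu) lengths(lapply(nu, `[[`, "crossovers")))))
  expect_true(all(n_co >= 1))
})

test_that("written cohorts read back identically", {
  b <- simulate_cohort(sim_config(n_individuals = 4, seed = 23))
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  b2 <- read_cohort(dir)
  expect_identical(b2$gametes$calls, b$gametes$calls)
  expect_identical(b2$diploid$calls, b$diploid$calls)
  expect_equal(b2$map$position_bp, b$map$position_bp)
  expect_identical(b2$map$marker_id, b$map$marker_id)
  expect_identical(b2$meta, b$meta)
  expect_identical(b2$nuclei$nucleus_id, b$nuclei$nucleus_id)
})

test_that("detectable-event censoring matches hand-worked cases", {
  # one individual, one chromosome, constructed truth: crossovers at 0.31
  # and 0.33 fall inside window 3 -> censored double; the one at 0.55 splits
  # window 5's markers 2 vs 2 -> tied window, event resolved across it
  map <- tiny_map(chroms = "1R", lengths_mb = 100, n = 40)
  truth <- list(ind1 = list(
    het = rep(TRUE, 40), hapA = rep(1L, 40),
    nuclei = list(list(`1R` = list(start = 1, crossovers = c(0.31, 0.33, 0.55))),
                  list(`1R` = list(start = 1, crossovers = numeric(0)))),
    error_idx = integer(0), missing_idx = integer(0), lambda = 2.2))
  bundle <- list(map = map, truth = truth)
  ev <- detectable_events(bundle)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$nucleus_id, "ind1_n1")
  expect_equal(ev$position_rel, 0.55)
  expect_identical(ev$resolution, 1L)
})
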