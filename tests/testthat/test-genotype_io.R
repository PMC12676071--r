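test_that("genotype tables parse, validate tokens, and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,m1,m2,m3", "s1,A,B,NA", "s2,B,NA,A"), path)
  g <- read_genotype_table(path, "haploid")
  expect_identical(dim(g$calls), c(2L, 3L))
  expect_identical(sum(is.na(g$calls)), 2L)
  expect_identical(g$calls["s1", "m1"], 1L)
  expect_identical(g$calls["s2", "m1"], -1L)

  out <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(g, out)
  expect_identical(read_genotype_table(out, "haploid")$calls, g$calls)
  expect_identical(readLines(out), readLines(path))

  # tab-delimited dialect is auto-detected
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tm1\tm2\tm3", "s1\tA\tB\tNA", "s2\tB\tNA\tA"), tsv)
  expect_identical(read_genotype_table(tsv, "haploid")$calls, g$calls)
})

test_that("haploid files reject heterozygous calls; diploids accept them", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,m1,m2", "s1,A,AB"), path)
  expect_error(read_genotype_table(path, "haploid"), "heterozygous")
  d <- read_genotype_table(path, "diploid")
  expect_identical(d$calls[1, "m2"], 0L)
})

test_that("duplicated ids and unknown tokens are caught", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,m1,m2", "s1,A,B", "s1,B,A"), path)
  expect_error(read_genotype_table(path, "haploid"), "duplicated sample")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,m1,m2", "s1,A,X"), path2)
  expect_warning(g <- read_genotype_table(path2, "haploid"), "unknown genotype token")
  expect_true(is.na(g$calls[1, "m2"]))
})

test_that("marker map validates coordinates and sorts by position", {
  mk <- data.frame(marker_id = c("b", "a"), chromosome = "1R",
                   position_bp = c(900, 100))
  mm <- marker_map(mk, c(`1R` = 1000))
  expect_identical(mm$marker_id, c("a", "b"))
  expect_equal(mm$rel_position, c(0.1, 0.9))
  expect_error(marker_map(mk, c(`2R` = 1000)), "no declared length")
  expect_error(marker_map(data.frame(marker_id = "a", chromosome = "1R",
                                     position_bp = 2000), c(`1R` = 1000)),
               "exceeds")
})

test_that("informative markers are the heterozygous subset in map order", {
  map <- tiny_map(n = 4)
  # diploid calls: het, hom, het, missing
  calls <- matrix(c(0L, 1L, 0L, NA), 1,
                  dimnames = list("ind1", map$marker_id))
  dip <- gametecross:::new_genotype_matrix(calls, "diploid")
  expect_identical(informative_markers(dip, "ind1", map),
                   map$marker_id[c(1, 3)])
  expect_error(informative_markers(dip, "nope", map), "absent")

  hom <- gametecross:::new_genotype_matrix(
    matrix(1L, 1, 4, dimnames = list("ind1", map$marker_id)), "diploid")
  expect_warning(res <- informative_markers(hom, "ind1", map),
                 "no heterozygous")
  expect_length(res, 0)
})

qc_fixture <- function(call_rates, n_markers = 20) {
  map <- tiny_map(n = n_markers)
  nuc <- sprintf("ind1_n%d", seq_along(call_rates))
  calls <- matrix(1L, length(call_rates), n_markers,
                  dimnames = list(nuc, map$marker_id))
  for (i in seq_along(call_rates)) {
    n_miss <- round((1 - call_rates[i]) * n_markers)
    if (n_miss > 0) calls[i, seq_len(n_miss)] <- NA
  }
  dip <- gametecross:::new_genotype_matrix(
    matrix(0L, 1, n_markers, dimnames = list("ind1", map$marker_id)), "diploid")
  list(g = gametecross:::new_genotype_matrix(calls, "haploid"),
       nm = data.frame(nucleus_id = nuc, individual_id = "ind1"),
       dip = dip, map = map)
}

test_that("QC drops low-call-rate nuclei but keeps the individual", {
  fx <- qc_fixture(c(0.05, rep(0.95, 5)))
  qc <- qc_filter(fx$g, fx$nm, fx$dip, fx$map)
  expect_length(qc$sets, 1)
  expect_length(qc$sets[["ind1"]]$nuclei_ids, 5)
  expect_identical(qc$report$reason, "call_rate_below_min")
})

test_that("QC drops individuals left with fewer than three nuclei", {
  fx <- qc_fixture(c(0.05, 0.05, 0.05, 0.05, 0.95, 0.95))
  qc <- qc_filter(fx$g, fx$nm, fx$dip, fx$map)
  expect_length(qc$sets, 0)
  expect_true("fewer_than_three_nuclei" %in% qc$report$reason)
})

test_that("QC thresholds are strict: boundary cases are retained", {
  # call rate exactly 0.10 passes
  fx <- qc_fixture(c(0.10, 0.95, 0.95))
  qc <- qc_filter(fx$g, fx$nm, fx$dip, fx$map)
  expect_length(qc$sets[["ind1"]]$nuclei_ids, 3)
  # missing fraction exactly 0.50 passes
  fx2 <- qc_fixture(rep(0.5, 4))
  qc2 <- qc_filter(fx2$g, fx2$nm, fx2$dip, fx2$map)
  expect_length(qc2$sets, 1)
  # just above 0.50 fails
  fx3 <- qc_fixture(rep(0.45, 4))
  qc3 <- qc_filter(fx3$g, fx3$nm, fx3$dip, fx3$map)
  expect_length(qc3$sets, 0)
  expect_true("missing_fraction_above_max" %in% qc3$report$reason)
})

test_that("QC is idempotent and warns on empty input", {
  fx <- qc_fixture(c(0.05, rep(0.95, 5)))
  qc1 <- qc_filter(fx$g, fx$nm, fx$dip, fx$map)
  keep <- qc1$sets[["ind1"]]$nuclei_ids
  g2 <- gametecross:::new_genotype_matrix(fx$g$calls[keep, , drop = FALSE],
                                          "haploid")
  nm2 <- fx$nm[fx$nm$nucleus_id %in% keep, ]
  qc2 <- qc_filter(g2, nm2, fx$dip, fx$map)
  expect_identical(qc2$sets[["ind1"]]$calls, qc1$sets[["ind1"]]$calls)
  expect_identical(nrow(qc2$report), 0L)

  empty <- gametecross:::new_genotype_matrix(
    matrix(integer(0), 0, 20, dimnames = list(NULL, fx$map$marker_id)), "haploid")
  expect_warning(qc_filter(empty, fx$nm[0, ], fx$dip, fx$map), "empty")
})

test_that("simulated QC dropout matches the analytic survival rate", {
  # a failed nucleus has > 90% missing data, so its call rate falls below
  # 10% and QC removes it; an individual survives iff >= 3 of 6 nuclei are
  # intact. With a 38% failure rate the survival probability is
  # P(Binom(6, 0.62) >= 3) -- computed here analytically, ~84%.
  q <- 0.38
  p_surv <- 1 - pbinom(2, 6, 1 - q)
  expect_equal(p_surv, 0.847, tolerance = 0.01)
  cfg <- sim_config(n_individuals = 700, bad_nucleus_rate = q, seed = 404)
  b <- simulate_cohort(cfg)
  qc <- qc_filter(b$gametes, b$nuclei, b$diploid, b$map)
  expected <- 700 * p_surv
  tol <- 3 * sqrt(700 * p_surv * (1 - p_surv))
  expect_lt(abs(length(qc$sets) - expected), tol)
})

test_that("heterozygous marker count follows the binomial expectation", {
  cfg <- sim_config(n_individuals = 1, heterozygosity = 0.4, seed = 11)
  b <- simulate_cohort(cfg)
  n_inf <- sum(b$diploid$calls[1, ] == 0L)
  M <- ncol(b$diploid$calls)
  expect_lt(abs(n_inf - 0.4 * M), 3 * sqrt(M * 0.4 * 0.6))
})
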