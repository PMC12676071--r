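#' Configuration for the meiosis simulator
#'
#' Defines the data-generating process the analysis assumes: two parental
#' haplotypes per individual, crossovers placed along each transmitted
#' chromatid by a stationary gamma renewal process (shape `interference_nu`;
#' `nu = 1` reduces to a Poisson process, larger values give crossover
#' interference), gametes observed as array-style genotype calls with
#' symmetric allele-flip errors and missing data.
#'
#' Defaults emulate a rye-like study: 7 chromosomes of 730-960 Mb (so 10%
#' windows span 73-96 Mb), ~200 informative SNPs per chromosome, 6 nuclei
#' per individual, a mean of 2.2 crossovers per chromatid with interference,
#' 5% missing calls, 1% genotyping error, and a nutrient-deficiency
#' treatment reducing the crossover rate by 8%. Crossover positional
#' intensity is distal-skewed by default (`recomb_profile = "distal"`),
#' reflecting the strongly telomeric recombination of large cereal
#' chromosomes; `"uniform"` gives a flat landscape.
#'
#' @param n_individuals number of diploid individuals in a cohort.
#' @param nuclei_per_individual gametes genotyped per individual.
#' @param chrom_lengths_mb named per-chromosome physical lengths (Mb).
#' @param n_markers_per_chrom markers assayed per chromosome.
#' @param heterozygosity probability a marker is heterozygous in an
#'   individual (only heterozygous markers are informative).
#' @param lambda_cc expected crossovers per chromatid per chromosome.
#' @param interference_nu gamma-renewal shape (>= 1 recommended).
#' @param obligate_co if `TRUE`, chromatids are redrawn until they carry at
#'   least one crossover.
#' @param nd_effect_delta multiplicative reduction of `lambda_cc` under the
#'   `nutrient_deficiency` treatment.
#' @param subpop_effect multiplicative increase of `lambda_cc` in the
#'   `population_variety` subpopulation (0 = no baseline difference).
#' @param missing_rate,error_rate per-call missingness and allele-flip
#'   probabilities.
#' @param bad_nucleus_rate probability that a nucleus fails amplification
#'   (its missingness is raised above 90%, so QC removes it).
#' @param recomb_profile `"distal"` or `"uniform"` crossover positional
#'   intensity along the chromosome.
#' @param group_sizes optional named integer vector of cohort cell sizes with
#'   names `subpopulation.treatment` (defaults to an even split of
#'   `n_individuals` over the four cells).
#' @param seed integer seed; all randomness derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 584,
                       nuclei_per_individual = 6,
                       chrom_lengths_mb = c(`1R` = 730, `2R` = 960, `3R` = 940,
                                            `4R` = 900, `5R` = 880, `6R` = 850,
                                            `7R` = 780),
                       n_markers_per_chrom = 400,
                       heterozygosity = 0.5,
                       lambda_cc = 2.2,
                       interference_nu = 5,
                       obligate_co = FALSE,
                       nd_effect_delta = 0.08,
                       subpop_effect = 0,
                       missing_rate = 0.05,
                       error_rate = 0.01,
                       bad_nucleus_rate = 0,
                       recomb_profile = c("distal", "uniform"),
                       group_sizes = NULL,
                       seed = 1L) {
  recomb_profile <- match.arg(recomb_profile)
  stopifnot(lambda_cc > 0, interference_nu > 0,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            bad_nucleus_rate >= 0, bad_nucleus_rate <= 1,
            nd_effect_delta >= 0, nd_effect_delta < 1,
            heterozygosity > 0, heterozygosity <= 1,
            nuclei_per_individual >= 3)
  if (is.null(names(chrom_lengths_mb)))
    names(chrom_lengths_mb) <- paste0("chr", seq_along(chrom_lengths_mb))
  if (is.null(group_sizes)) {
    cells <- c("diversity_panel.control", "diversity_panel.nutrient_deficiency",
               "population_variety.control", "population_variety.nutrient_deficiency")
    base <- n_individuals %/% 4L
    group_sizes <- stats::setNames(rep(base, 4L), cells)
    extra <- n_individuals - 4L * base
    if (extra > 0) group_sizes[seq_len(extra)] <- group_sizes[seq_len(extra)] + 1L
  }
  structure(list(n_individuals = as.integer(sum(group_sizes)),
                 nuclei_per_individual = as.integer(nuclei_per_individual),
                 chrom_lengths_mb = chrom_lengths_mb,
                 n_chromosomes = length(chrom_lengths_mb),
                 n_markers_per_chrom = as.integer(n_markers_per_chrom),
                 heterozygosity = heterozygosity,
                 lambda_cc = lambda_cc,
                 interference_nu = interference_nu,
                 obligate_co = isTRUE(obligate_co),
                 nd_effect_delta = nd_effect_delta,
                 subpop_effect = subpop_effect,
                 missing_rate = missing_rate,
                 error_rate = error_rate,
                 bad_nucleus_rate = bad_nucleus_rate,
                 recomb_profile = recomb_profile,
                 group_sizes = group_sizes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Quantile function of the crossover positional intensity. The distal profile
# f(x) = 0.4 + 1.8*(2x-1)^2 concentrates crossovers towards the chromosome
# ends (terminal/pericentromeric intensity ratio 5.5), the broad-scale shape
# typical of large cereal chromosomes.
profile_quantile <- function(profile) {
  if (profile == "uniform") return(identity)
  x <- seq(0, 1, length.out = 4097)
  f <- 0.4 + 1.8 * (2 * x - 1)^2
  cdf <- cumsum((f[-1] + f[-length(f)]) / 2) * diff(x)[1]
  cdf <- c(0, cdf / cdf[length(cdf)])
  stats::approxfun(cdf, x, rule = 2)
}

# Stationary gamma renewal process on [0, 1]: interarrivals Gamma(shape = nu,
# rate = lambda * nu), burn-in from -10/lambda so the first event on [0, 1]
# follows the equilibrium distribution. Returns sorted event positions.
renewal_positions <- function(lambda, nu, burn = 10 / lambda) {
  k <- max(8L, ceiling((burn + 1) * lambda + 6 * sqrt((burn + 1) * lambda / nu)))
  pos <- cumsum(stats::rgamma(k, shape = nu, rate = lambda * nu)) - burn
  while (pos[length(pos)] < 1) {
    pos <- c(pos, pos[length(pos)] +
               cumsum(stats::rgamma(k, shape = nu, rate = lambda * nu)))
  }
  pos[pos > 0 & pos < 1]
}

# Crossover positions of one chromatid in physical relative coordinates.
chromatid_crossovers <- function(lambda, nu, qfun, obligate = FALSE) {
  for (i in seq_len(if (obligate) 1000L else 1L)) {
    u <- renewal_positions(lambda, nu)
    if (!obligate || length(u) >= 1L) return(sort(qfun(u)))
  }
  stop("could not realise an obligate crossover after 1000 attempts; lambda too small")
}

# Draw crossover positions for `nc` chromatids at once: one batched gamma
# draw, per-chromatid cumulative sums via offset subtraction, burn-in for
# stationarity as in renewal_positions(). Returns sorted position vectors.
batch_crossovers <- function(nc, lambda, nu, qfun, obligate = FALSE) {
  burn <- 10 / lambda
  k <- max(8L, ceiling((burn + 1) * lambda + 8 * sqrt((burn + 1) * lambda / nu) + 4))
  cs <- cumsum(stats::rgamma(k * nc, shape = nu, rate = lambda * nu))
  off <- c(0, cs[k * seq_len(nc - 1L)])
  P <- matrix(cs, k, nc) - matrix(off, k, nc, byrow = TRUE) - burn
  out <- vector("list", nc)
  for (j in seq_len(nc)) {
    p <- P[, j]
    if (p[k] < 1)   # tail not covered by the batch; extend this chromatid
      p <- c(p, p[k] + cumsum(stats::rgamma(k, shape = nu, rate = lambda * nu)))
    co <- qfun(p[p > 0 & p < 1])
    if (obligate && !length(co))
      co <- chromatid_crossovers(lambda, nu, qfun, obligate = TRUE)
    out[[j]] <- sort(co)
  }
  out
}

# Simulate one individual: parental haplotypes, gamete mosaics, noisy calls.
# map_rel: list per chromosome of relative marker positions.
simulate_individual_calls <- function(cfg, lambda, map_rel, qfun) {
  M <- sum(lengths(map_rel))
  n <- cfg$nuclei_per_individual
  chroms <- names(map_rel)
  het <- stats::runif(M) < cfg$heterozygosity
  hapA <- 1 - 2 * (stats::runif(M) < 0.5)
  offsets <- c(0L, cumsum(lengths(map_rel)))

  nc <- n * length(chroms)
  co_all <- batch_crossovers(nc, lambda, cfg$interference_nu, qfun, cfg$obligate_co)
  start_all <- 1 - 2 * (stats::runif(nc) < 0.5)

  calls <- matrix(NA_real_, n, M)
  truth_nuclei <- vector("list", n)
  cidx <- 0L
  for (i in seq_len(n)) {
    orig <- numeric(M)
    per_chrom <- vector("list", length(chroms))
    names(per_chrom) <- chroms
    for (ci in seq_along(chroms)) {
      cidx <- cidx + 1L
      co <- co_all[[cidx]]
      start <- start_all[cidx]
      j <- (offsets[ci] + 1L):offsets[ci + 1L]
      orig[j] <- start * (1 - 2 * (findInterval(map_rel[[ci]], co) %% 2L))
      per_chrom[[ci]] <- list(start = start, crossovers = co)
    }
    # call = hapA allele where origin A (or marker homozygous), else complement
    orig[!het] <- 1
    calls[i, ] <- hapA * orig
    truth_nuclei[[i]] <- per_chrom
  }

  err_idx <- which(stats::runif(n * M) < cfg$error_rate)
  if (length(err_idx)) calls[err_idx] <- -calls[err_idx]
  mrate <- rep(cfg$missing_rate, n)
  bad <- stats::runif(n) < cfg$bad_nucleus_rate
  if (any(bad)) mrate[bad] <- stats::runif(sum(bad), 0.92, 0.995)
  miss_idx <- which(stats::runif(n * M) < rep(mrate, times = M))
  if (length(miss_idx)) calls[miss_idx] <- NA_real_

  list(calls = calls,
       diploid = ifelse(het, 0, hapA),
       truth = list(het = het, hapA = hapA, nuclei = truth_nuclei,
                    error_idx = err_idx, missing_idx = miss_idx,
                    lambda = lambda))
}

#' Simulate the gametes of a single individual
#'
#' Convenience wrapper around the cohort generator for one individual: draws
#' a marker map (unless supplied), simulates meiosis for each nucleus, and
#' returns calls plus complete ground truth.
#'
#' @param cfg a [sim_config()].
#' @param map optional [marker_map()]; drawn from `cfg` when `NULL`.
#' @param individual_id id used in the output.
#' @param lambda crossover rate for this individual (defaults to
#'   `cfg$lambda_cc`).
#' @return list with `gametes` (haploid `genotype_matrix`), `diploid`
#'   (1-row diploid `genotype_matrix`), `map`, and `truth` (parental
#'   haplotypes, per-nucleus crossover positions and start haplotypes, and
#'   the injected error/missingness indices).
#' @export
simulate_meiosis <- function(cfg, map = NULL, individual_id = "ind001",
                             lambda = cfg$lambda_cc) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (is.null(map)) map <- simulate_marker_map(cfg)
  map_rel <- split(map$rel_position, map$chromosome)[unique(map$chromosome)]
  qfun <- profile_quantile(cfg$recomb_profile)
  sim <- simulate_individual_calls(cfg, lambda, map_rel, qfun)
  nuc_ids <- sprintf("%s_n%d", individual_id, seq_len(cfg$nuclei_per_individual))
  dimnames(sim$calls) <- list(nuc_ids, map$marker_id)
  storage.mode(sim$calls) <- "integer"
  diploid <- matrix(as.integer(sim$diploid), 1L,
                    dimnames = list(individual_id, map$marker_id))
  list(gametes = new_genotype_matrix(sim$calls, "haploid"),
       diploid = new_genotype_matrix(diploid, "diploid"),
       map = map, truth = stats::setNames(list(sim$truth), individual_id))
}

# Draw the shared marker map: positions uniform along each chromosome.
simulate_marker_map <- function(cfg) {
  chroms <- names(cfg$chrom_lengths_mb)
  lens_bp <- cfg$chrom_lengths_mb * 1e6
  mk <- do.call(rbind, lapply(chroms, function(chr) {
    pos <- sort(sample.int(lens_bp[[chr]], cfg$n_markers_per_chrom))
    data.frame(marker_id = sprintf("%s_%05d", chr, seq_along(pos)),
               chromosome = chr, position_bp = pos)
  }))
  marker_map(mk, lens_bp)
}

#' Simulate a full study cohort
#'
#' Generates the complete input bundle of the analysis: a shared marker map,
#' diploid genotypes, gamete calls for every nucleus, and sample metadata for
#' two subpopulations crossed with two treatments. Individuals under
#' `nutrient_deficiency` use a crossover rate of
#' `lambda_cc * (1 - nd_effect_delta)`; individuals of the
#' `population_variety` subpopulation use `lambda_cc * (1 + subpop_effect)`.
#'
#' @param cfg a [sim_config()].
#' @param map optional [marker_map()] to reuse (e.g. to simulate several
#'   cohorts genotyped on the same array); drawn from `cfg` when `NULL`.
#' @return list with `gametes` (haploid `genotype_matrix`, all nuclei x all
#'   markers), `diploid` (diploid `genotype_matrix`), `nuclei`
#'   (nucleus/individual table), `map`, `meta`, `truth` (per-individual
#'   ground truth) and `cfg`.
#' @export
simulate_cohort <- function(cfg, map = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (is.null(map)) map <- simulate_marker_map(cfg)
  map_rel <- split(map$rel_position, map$chromosome)[names(cfg$chrom_lengths_mb)]
  qfun <- profile_quantile(cfg$recomb_profile)

  cells <- strsplit(names(cfg$group_sizes), ".", fixed = TRUE)
  meta <- data.frame(
    individual_id = sprintf("ind%04d", seq_len(cfg$n_individuals)),
    subpopulation = rep(vapply(cells, `[`, "", 1L), cfg$group_sizes),
    treatment = rep(vapply(cells, `[`, "", 2L), cfg$group_sizes))

  n <- cfg$nuclei_per_individual
  M <- nrow(map)
  calls <- matrix(NA_real_, cfg$n_individuals * n, M)
  diploid <- matrix(NA_real_, cfg$n_individuals, M,
                    dimnames = list(meta$individual_id, map$marker_id))
  truth <- vector("list", cfg$n_individuals)
  names(truth) <- meta$individual_id
  for (k in seq_len(cfg$n_individuals)) {
    lambda <- cfg$lambda_cc *
      (1 + cfg$subpop_effect * (meta$subpopulation[k] == "population_variety")) *
      (1 - cfg$nd_effect_delta * (meta$treatment[k] == "nutrient_deficiency"))
    sim <- simulate_individual_calls(cfg, lambda, map_rel, qfun)
    calls[(k - 1L) * n + seq_len(n), ] <- sim$calls
    diploid[k, ] <- sim$diploid
    truth[[k]] <- sim$truth
  }
  nuclei <- data.frame(
    nucleus_id = sprintf("%s_n%d", rep(meta$individual_id, each = n),
                         rep(seq_len(n), cfg$n_individuals)),
    individual_id = rep(meta$individual_id, each = n))
  dimnames(calls) <- list(nuclei$nucleus_id, map$marker_id)
  storage.mode(calls) <- "integer"
  storage.mode(diploid) <- "integer"
  list(gametes = new_genotype_matrix(calls, "haploid"),
       diploid = new_genotype_matrix(diploid, "diploid"),
       nuclei = nuclei, map = map, meta = meta, truth = truth, cfg = cfg)
}

#' Detectable crossovers implied by the simulated truth
#'
#' Censors the simulator's true crossover positions by the detection rules of
#' the window-based caller, working directly from ground truth (parental
#' haplotype origin at each informative marker position) without touching
#' genotype calls, phasing or the calling code path: window labels are the
#' majority of true origins among the window's informative markers (tie or
#' empty = missing), label changes between consecutive informative windows
#' are events, and events whose flanking midpoints are separated by more
#' than the gap bound are discarded. Double crossovers inside one window and
#' crossovers beyond the outermost informative window midpoints are thereby
#' censored, exactly as in the real analysis.
#'
#' @param bundle a cohort from [simulate_cohort()] (or the list returned by
#'   [simulate_meiosis()]).
#' @param cfg a [crossover_config()].
#' @return data.frame of detectable events: `individual_id`, `nucleus_id`,
#'   `chromosome`, `left_window`, `right_window`, `position_rel`,
#'   `resolution`.
#' @export
detectable_events <- function(bundle, cfg = crossover_config()) {
  map <- bundle$map
  chroms <- unique(map$chromosome)
  rel_by_chrom <- split(map$rel_position, map$chromosome)[chroms]
  idx_by_chrom <- split(seq_len(nrow(map)), map$chromosome)[chroms]
  nw <- cfg$n_windows
  wf <- cfg$window_fraction
  max_gap_w <- as.integer(round(cfg$max_gap_rel / wf))
  out <- list()
  for (ind in names(bundle$truth)) {
    tr <- bundle$truth[[ind]]
    for (ci in seq_along(chroms)) {
      j <- idx_by_chrom[[ci]]
      p <- rel_by_chrom[[ci]][tr$het[j]]
      win <- pmin(floor(p / wf), nw - 1) + 1L
      for (ni in seq_along(tr$nuclei)) {
        nu <- tr$nuclei[[ni]][[chroms[ci]]]
        o <- nu$start * (1 - 2 * (findInterval(p, nu$crossovers) %% 2))
        lab <- rep(NA_real_, nw)
        for (wdx in unique(win)) {
          s <- sum(o[win == wdx])
          if (s != 0) lab[wdx] <- sign(s)
        }
        inf <- which(!is.na(lab))
        if (length(inf) < 2L) next
        chg <- which(diff(lab[inf]) != 0)
        if (!length(chg)) next
        left <- inf[chg]; right <- inf[chg + 1L]
        d <- right - left
        keep <- if (cfg$gap_inclusive) d <= max_gap_w else d < max_gap_w
        if (!any(keep)) next
        left <- left[keep]; right <- right[keep]
        out[[length(out) + 1L]] <- data.frame(
          individual_id = ind,
          nucleus_id = sprintf("%s_n%d", ind, ni),
          chromosome = chroms[ci],
          left_window = left - 1L, right_window = right - 1L,
          position_rel = wf * (left + right - 1) / 2,
          resolution = right - left - 1L)
      }
    }
  }
  if (!length(out))
    return(data.frame(individual_id = character(0), nucleus_id = character(0),
                      chromosome = character(0), left_window = integer(0),
                      right_window = integer(0), position_rel = numeric(0),
                      resolution = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' True crossover counts per nucleus
#'
#' @param bundle a cohort from [simulate_cohort()].
#' @return data.frame `individual_id`, `nucleus_id`, `n_co_true`.
#' @export
true_crossover_counts <- function(bundle) {
  rows <- lapply(names(bundle$truth), function(ind) {
    tr <- bundle$truth[[ind]]
    data.frame(individual_id = ind,
               nucleus_id = sprintf("%s_n%d", ind, seq_along(tr$nuclei)),
               n_co_true = vapply(tr$nuclei, function(nu)
                 sum(lengths(lapply(nu, `[[`, "crossovers"))), numeric(1)))
  })
  do.call(rbind, rows)
}

#' Write a simulated cohort bundle as delimited text files
#'
#' Emits exactly the formats the IO layer reads: `gametes.csv`,
#' `diploid.csv` (samples x markers), `map.csv`, `chrom_lengths.csv`,
#' `nuclei.csv`, `meta.csv`, plus `truth_crossovers.csv` (true crossover
#' positions) and `config.csv` as a reproducibility record.
#'
#' @param bundle from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotype_table(bundle$gametes, file.path(dir, "gametes.csv"))
  write_genotype_table(bundle$diploid, file.path(dir, "diploid.csv"))
  data.table::fwrite(bundle$map[, c("marker_id", "chromosome", "position_bp")],
                     file.path(dir, "map.csv"))
  lens <- attr(bundle$map, "chrom_lengths")
  data.table::fwrite(data.frame(chromosome = names(lens), length_bp = unname(lens)),
                     file.path(dir, "chrom_lengths.csv"))
  data.table::fwrite(bundle$nuclei, file.path(dir, "nuclei.csv"))
  data.table::fwrite(bundle$meta, file.path(dir, "meta.csv"))
  if (!is.null(bundle$truth)) {
    tc <- do.call(rbind, lapply(names(bundle$truth), function(ind) {
      tr <- bundle$truth[[ind]]
      do.call(rbind, lapply(seq_along(tr$nuclei), function(ni) {
        nu <- tr$nuclei[[ni]]
        co <- unlist(lapply(nu, `[[`, "crossovers"), use.names = FALSE)
        if (!length(co)) return(NULL)
        data.frame(individual_id = ind,
                   nucleus_id = sprintf("%s_n%d", ind, ni),
                   chromosome = rep(names(nu), lengths(lapply(nu, `[[`, "crossovers"))),
                   position_rel = co)
      }))
    }))
    if (!is.null(tc)) data.table::fwrite(tc, file.path(dir, "truth_crossovers.csv"))
  }
  cfg <- bundle$cfg
  flat <- vapply(cfg, function(v) paste(v, collapse = ";"), character(1))
  data.table::fwrite(data.frame(param = names(flat), value = unname(flat)),
                     file.path(dir, "config.csv"))
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir directory of delimited files.
#' @return list with `gametes`, `diploid`, `nuclei`, `map`, `meta` (truth is
#'   not reloaded).
#' @export
read_cohort <- function(dir) {
  list(gametes = read_genotype_table(file.path(dir, "gametes.csv"), "haploid"),
       diploid = read_genotype_table(file.path(dir, "diploid.csv"), "diploid"),
       nuclei = as.data.frame(data.table::fread(file.path(dir, "nuclei.csv"),
                                                colClasses = "character")),
       map = read_marker_map(file.path(dir, "map.csv"),
                             file.path(dir, "chrom_lengths.csv")),
       meta = read_metadata(file.path(dir, "meta.csv")))
}
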