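#' Build a broad-scale recombination landscape
#'
#' Aggregates crossover events into the relative chromosomal windows of the
#' caller and converts per-window crossover frequency to cM/Mb: each event in
#' a sampled chromatid contributes `100 / n_gametes` cM, so the window rate
#' is `frequency * 100 / window_Mb`. An event is assigned to the window
#' containing its relative position (positions on a window boundary go to
#' the right window).
#'
#' @param events data.frame of events with `chromosome`, `position_rel`.
#' @param n_gametes number of gametes the events were called in.
#' @param map a [marker_map()].
#' @param cfg a [crossover_config()].
#' @return a `landscape` data.frame: `chromosome`, `window` (0-based),
#'   `n_events`, `frequency`, `window_mb`, `rate_cm_per_mb`; attributes
#'   `n_gametes` and `genome_rate_cm_per_mb` (genome-wide average rate).
#' @export
build_landscape <- function(events, n_gametes, map, cfg = crossover_config()) {
  if (n_gametes <= 0) stop("n_gametes must be positive")
  lens <- attr(map, "chrom_lengths")
  chroms <- names(lens)
  nw <- cfg$n_windows
  grid <- expand.grid(window = 0:(nw - 1L), chromosome = chroms,
                      stringsAsFactors = FALSE)[, c("chromosome", "window")]
  n_events <- integer(nrow(grid))
  if (nrow(events)) {
    # event positions sit exactly on window boundaries (midpoint geometry);
    # nudge before flooring so e.g. 0.3/0.1 cannot truncate to 2
    win <- pmin(floor(events$position_rel / cfg$window_fraction + 1e-9), nw - 1L)
    tab <- table(factor(paste(events$chromosome, win),
                        levels = paste(grid$chromosome, grid$window)))
    n_events <- as.integer(tab)
  }
  grid$n_events <- n_events
  grid$frequency <- n_events / n_gametes
  grid$window_mb <- lens[grid$chromosome] / 1e6 * cfg$window_fraction
  grid$rate_cm_per_mb <- grid$frequency * 100 / grid$window_mb
  rownames(grid) <- NULL
  attr(grid, "n_gametes") <- n_gametes
  attr(grid, "genome_rate_cm_per_mb") <-
    sum(n_events) / n_gametes * 100 / (sum(lens) / 1e6)
  class(grid) <- c("landscape", "data.frame")
  grid
}

#' Compare two recombination landscapes
#'
#' Pearson correlation of per-window crossover frequencies, plus a per-window
#' chi-square test of event counts against gamete totals (events vs
#' non-events by condition, 2x2) with Benjamini-Hochberg adjustment across
#' windows.
#'
#' @param a,b `landscape` objects on identical (chromosome, window) grids.
#' @return list with `pearson_r`, `cor_p`, and `windows` (per-window
#'   `chisq_p` and `p_adj`).
#' @export
compare_landscapes <- function(a, b) {
  if (!identical(a$chromosome, b$chromosome) || !identical(a$window, b$window))
    stop("landscapes are on different (chromosome, window) grids")
  ct <- suppressWarnings(stats::cor.test(a$frequency, b$frequency))
  na <- attr(a, "n_gametes"); nb <- attr(b, "n_gametes")
  p <- vapply(seq_len(nrow(a)), function(i) {
    xa <- a$n_events[i]; xb <- b$n_events[i]
    if (xa + xb == 0L) return(1)
    tab <- rbind(c(xa, na - xa), c(xb, nb - xb))
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }, numeric(1))
  windows <- data.frame(chromosome = a$chromosome, window = a$window,
                        n_events_a = a$n_events, n_events_b = b$n_events,
                        chisq_p = p, p_adj = stats::p.adjust(p, "BH"))
  list(pearson_r = unname(ct$estimate), cor_p = ct$p.value, windows = windows)
}

#' Group comparison of a crossover trait (ANOVA + Tukey's HSD)
#'
#' One-way ANOVA of the trait over the grouping cells (by default the four
#' subpopulation x treatment combinations) followed by all pairwise Tukey
#' HSD contrasts; estimates are differences of group means.
#'
#' @param traits trait table from [build_trait_table()].
#' @param trait column name (e.g. `"cc_per_chromatid"`).
#' @param factors metadata column(s) whose interaction defines the groups.
#' @return list with `anova` (data.frame with F and p), `contrasts`
#'   (data.frame: `contrast`, `estimate`, `lwr`, `upr`, `p_adj`),
#'   `group_means`.
#' @export
group_effects <- function(traits, trait = "cc_per_chromatid",
                          factors = c("subpopulation", "treatment")) {
  stopifnot(trait %in% names(traits), all(factors %in% names(traits)))
  y <- traits[[trait]]
  cell <- interaction(traits[factors], drop = TRUE, sep = ":")
  keep <- !is.na(y) & !is.na(cell)
  y <- y[keep]; cell <- droplevels(cell[keep])
  sizes <- table(cell)
  if (any(sizes < 2L)) {
    warning("group(s) with < 2 records skipped: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
    ok <- cell %in% names(sizes)[sizes >= 2L]
    y <- y[ok]; cell <- droplevels(cell[ok])
  }
  if (nlevels(cell) < 2L) stop("need at least two groups with >= 2 records")
  fit <- stats::aov(y ~ cell)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$cell
  contrasts <- data.frame(contrast = rownames(tk),
                          estimate = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL)
  list(anova = data.frame(f = an$`F value`[1L], p = an$`Pr(>F)`[1L],
                          df_between = an$Df[1L], df_within = an$Df[2L]),
       contrasts = contrasts,
       group_means = tapply(y, cell, mean))
}

#' Additive stacking of beneficial alleles
#'
#' Orders allele indicators by decreasing allele frequency, forms nested
#' subsets of individuals carrying the first `m` beneficial alleles, and
#' reports the mean trait per subset together with Spearman's rank
#' correlation between the number of beneficial alleles an individual
#' carries and its trait value.
#'
#' @param traits trait table from [build_trait_table()].
#' @param alleles 0/1 matrix (individuals x alleles, rownames =
#'   individual ids): 1 if the individual carries the beneficial allele.
#' @param trait trait column name.
#' @return list with `stack` (data.frame `m`, `allele`, `n`, `mean_trait`;
#'   `NA` mean when no individual carries all first `m` alleles),
#'   `spearman_rho`, `spearman_p`.
#' @export
allele_stacking <- function(traits, alleles, trait = "cc_per_chromatid") {
  stopifnot(trait %in% names(traits), !is.null(rownames(alleles)))
  ids <- intersect(traits$individual_id, rownames(alleles))
  if (!length(ids)) stop("no overlap between trait table and allele matrix")
  y <- traits[[trait]][match(ids, traits$individual_id)]
  A <- alleles[ids, , drop = FALSE]
  A <- A[, order(colMeans(A), decreasing = TRUE), drop = FALSE]
  stack <- do.call(rbind, lapply(seq_len(ncol(A)), function(m) {
    sel <- rowSums(A[, seq_len(m), drop = FALSE]) == m
    data.frame(m = m, allele = colnames(A)[m], n = sum(sel),
               mean_trait = if (any(sel)) mean(y[sel], na.rm = TRUE) else NA_real_)
  }))
  ct <- suppressWarnings(stats::cor.test(rowSums(A), y, method = "spearman",
                                         exact = FALSE))
  list(stack = stack, spearman_rho = unname(ct$estimate), spearman_p = ct$p.value)
}
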