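# Shared fixtures and independent oracles used across test files.

# tiny marker map: n evenly spread markers per chromosome
tiny_map <- function(chroms = "1R", lengths_mb = 100, n = 10) {
  lens <- stats::setNames(lengths_mb * 1e6, chroms)
  mk <- do.call(rbind, lapply(chroms, function(chr) {
    pos <- round(seq(0.05, 0.95, length.out = n) * lens[[chr]])
    data.frame(marker_id = sprintf("%s_m%02d", chr, seq_len(n)),
               chromosome = chr, position_bp = pos)
  }))
  marker_map(mk, lens)
}

# gamete_set built directly from a +1/-1/NA call matrix
make_gset <- function(calls, individual_id = "ind1", map = NULL) {
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("%s_n%d", individual_id, seq_len(nrow(calls)))
  structure(list(individual_id = individual_id,
                 nuclei_ids = rownames(calls),
                 marker_ids = colnames(calls),
                 calls = calls,
                 qc = data.frame(nucleus_id = rownames(calls),
                                 call_rate = rowMeans(!is.na(calls)))),
            class = "gamete_set")
}

# canonical event key for exact set comparisons
event_key <- function(e) {
  paste(e$individual_id, e$nucleus_id, e$chromosome,
        round(e$position_rel, 6), e$resolution)
}

# aggregate fraction of markers phased consistently with simulated truth,
# scoring each chromosome under its best global flip
phasing_accuracy <- function(bundle, link_window = 2L) {
  qc <- qc_filter(bundle$gametes, bundle$nuclei, bundle$diploid, bundle$map)
  num <- 0; den <- 0
  for (ind in names(qc$sets)) {
    pp <- phase_individual(qc$sets[[ind]], bundle$map, link_window = link_window)
    tr <- bundle$truth[[ind]]
    for (chr in names(pp$chromosomes)) {
      ch <- pp$chromosomes[[chr]]
      a <- mean(ch$hapA == tr$hapA[match(ch$marker_id, bundle$map$marker_id)])
      num <- num + max(a, 1 - a) * length(ch$hapA)
      den <- den + length(ch$hapA)
    }
  }
  num / den
}

# (individual, chromosome) pairs where the gamete data do not identify the
# phase: a residual block split, a stitched link, or a phased haplotype not
# equal to the truth up to one global flip. Used to condition the
# exact-oracle comparison on identifiable phase.
phase_exclusions <- function(bundle) {
  qc <- qc_filter(bundle$gametes, bundle$nuclei, bundle$diploid, bundle$map)
  exk <- character(0); tot <- 0L
  for (ind in names(qc$sets)) {
    pp <- phase_individual(qc$sets[[ind]], bundle$map)
    tr <- bundle$truth[[ind]]
    for (chr in names(pp$chromosomes)) {
      tot <- tot + 1L
      ch <- pp$chromosomes[[chr]]
      a <- mean(ch$hapA == tr$hapA[match(ch$marker_id, bundle$map$marker_id)])
      if ((a > 0 && a < 1) || ch$block[length(ch$block)] > 1L || ch$n_stitched > 0L)
        exk <- c(exk, paste(ind, chr))
    }
  }
  list(keys = exk, total = tot)
}

# Monte-Carlo two-locus oracle for intrachromosomal shuffling: probability
# that two loci drawn uniformly from the genome land on the same chromosome
# with different haplotype origins, reading origins off window labels.
mc_shuffling <- function(labels_by_chrom, nucleus, rel_lengths, n_pairs = 1e6) {
  chroms <- names(labels_by_chrom)
  L <- rel_lengths[chroms]
  c1 <- sample.int(length(L), n_pairs, replace = TRUE, prob = L)
  c2 <- sample.int(length(L), n_pairs, replace = TRUE, prob = L)
  w1 <- pmin(floor(stats::runif(n_pairs) * 10), 9) + 1L
  w2 <- pmin(floor(stats::runif(n_pairs) * 10), 9) + 1L
  lab <- vapply(chroms, function(chr) labels_by_chrom[[chr]][nucleus, ], numeric(10))
  l1 <- lab[cbind(w1, c1)]
  l2 <- lab[cbind(w2, c2)]
  mean(c1 == c2 & !is.na(l1) & !is.na(l2) & l1 != l2)
}

# brute-force maximum-agreement phasing of one chromosome: maximises the
# number of satisfied pairwise votes over all 2^(m-1) orientation chains
brute_force_orientation <- function(calls) {
  m <- ncol(calls)
  m1 <- colSums(calls[, -1L, drop = FALSE] * calls[, -m, drop = FALSE],
                na.rm = TRUE)
  best <- NULL; best_score <- -Inf
  for (mask in 0:(2^(m - 1) - 1)) {
    rel <- 1 - 2 * as.integer(intToBits(mask)[seq_len(m - 1)])
    score <- sum(rel * m1)
    if (score > best_score) {
      best_score <- score
      best <- cumprod(c(1, rel))
    }
  }
  list(orientation = best, score = best_score)
}
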