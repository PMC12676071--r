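#' Run the full per-individual analysis
#'
#' Phases the parent from its gametes, labels haplotype origins, aggregates
#' them into relative windows, and calls crossovers on every chromosome.
#'
#' @param gset a `gamete_set` from [qc_filter()].
#' @param map a [marker_map()].
#' @param cfg a [crossover_config()].
#' @param link_window phasing link window (see [phase_individual()]).
#' @return list with `events` (data.frame incl. `chromosome`),
#'   `labels_by_chrom` (window-label matrices), `ics` (per-nucleus
#'   shuffling), `phase` (per-chromosome data.frame of `n_blocks` and
#'   `unresolved_links`).
#' @export
analyze_individual <- function(gset, map, cfg = crossover_config(),
                               link_window = 2L) {
  parent <- phase_individual(gset, map, link_window = link_window)
  origins <- label_origins(gset, parent, min_block_span = cfg$window_fraction)
  labels <- lapply(origins, aggregate_windows, cfg = cfg)
  nuc <- character(0); lft <- integer(0); rgt <- integer(0); chrv <- character(0)
  for (chr in names(labels)) {
    core <- call_crossovers_core(labels[[chr]], cfg)
    if (length(core$left)) {
      nuc <- c(nuc, core$nucleus_id)
      lft <- c(lft, core$left); rgt <- c(rgt, core$right)
      chrv <- c(chrv, rep(chr, length(core$left)))
    }
  }
  events <- data.frame(nucleus_id = nuc, left_window = lft - 1L,
                       right_window = rgt - 1L,
                       position_rel = cfg$window_fraction * (lft + rgt - 1) / 2,
                       resolution = rgt - lft - 1L, chromosome = chrv)
  phase <- data.frame(
    chromosome = names(parent$chromosomes),
    n_blocks = vapply(parent$chromosomes, function(ch) max(ch$block), integer(1)),
    unresolved_links = vapply(parent$chromosomes,
                              function(ch) length(ch$unresolved), integer(1)),
    n_stitched = vapply(parent$chromosomes, function(ch) ch$n_stitched,
                        integer(1)),
    row.names = NULL)
  rel_lengths <- chrom_rel_lengths(map)
  list(events = events, labels_by_chrom = labels,
       ics = ics_per_nucleus(labels, rel_lengths), phase = phase)
}

#' Run the full cohort analysis
#'
#' Applies QC, then runs phasing, window aggregation, crossover calling and
#' trait computation for every retained individual, and assembles the
#' cohort-level tables.
#'
#' @param bundle input bundle with `gametes`, `diploid`, `nuclei`, `map`,
#'   `meta` — either from [simulate_cohort()] or assembled from files via
#'   [read_cohort()].
#' @param cfg a [crossover_config()].
#' @param link_window phasing link window.
#' @param min_call_rate,max_missing QC thresholds (see [qc_filter()]).
#' @return list with `traits` (per-individual trait table), `events` (all
#'   called crossovers), `summary` (from [crossover_summary()]), `nuclei`
#'   (retained nuclei), `qc_report`, `phase` (per individual x chromosome
#'   phasing diagnostics), `map`, `cfg`, `n_chromosomes`.
#' @export
analyze_cohort <- function(bundle, cfg = crossover_config(), link_window = 2L,
                           min_call_rate = 0.10, max_missing = 0.50) {
  qc <- qc_filter(bundle$gametes, bundle$nuclei, bundle$diploid, bundle$map,
                  min_call_rate = min_call_rate, max_missing = max_missing)
  n_chrom <- length(unique(bundle$map$chromosome))
  rel_lengths <- chrom_rel_lengths(bundle$map)
  inds <- names(qc$sets)
  ev_i <- ev_n <- ev_c <- vector("list", length(inds))
  ev_l <- ev_r <- vector("list", length(inds))
  ph_i <- ph_c <- ph_b <- ph_u <- ph_s <- vector("list", length(inds))
  ics_l <- vector("list", length(inds))
  names(ics_l) <- inds
  for (k in seq_along(inds)) {
    gset <- qc$sets[[k]]
    parent <- phase_individual(gset, bundle$map, link_window = link_window)
    origins <- label_origins(gset, parent, min_block_span = cfg$window_fraction)
    labels <- lapply(origins, aggregate_windows, cfg = cfg)
    nuc <- character(0); lft <- integer(0); rgt <- integer(0); chrv <- character(0)
    for (chr in names(labels)) {
      core <- call_crossovers_core(labels[[chr]], cfg)
      if (length(core$left)) {
        nuc <- c(nuc, core$nucleus_id)
        lft <- c(lft, core$left); rgt <- c(rgt, core$right)
        chrv <- c(chrv, rep(chr, length(core$left)))
      }
    }
    ev_i[[k]] <- rep(inds[k], length(lft))
    ev_n[[k]] <- nuc; ev_c[[k]] <- chrv; ev_l[[k]] <- lft; ev_r[[k]] <- rgt
    ics_l[[k]] <- ics_per_nucleus(labels, rel_lengths)
    ph_i[[k]] <- rep(inds[k], length(parent$chromosomes))
    ph_c[[k]] <- names(parent$chromosomes)
    ph_b[[k]] <- vapply(parent$chromosomes, function(ch) ch$block[length(ch$block)],
                        integer(1), USE.NAMES = FALSE)
    ph_u[[k]] <- vapply(parent$chromosomes, function(ch) length(ch$unresolved),
                        integer(1), USE.NAMES = FALSE)
    ph_s[[k]] <- vapply(parent$chromosomes, function(ch) ch$n_stitched,
                        integer(1), USE.NAMES = FALSE)
  }
  lft <- unlist(ev_l); rgt <- unlist(ev_r)
  events <- data.frame(individual_id = unlist(ev_i) %||% character(0),
                       nucleus_id = unlist(ev_n) %||% character(0),
                       chromosome = unlist(ev_c) %||% character(0),
                       left_window = (lft %||% integer(0)) - 1L,
                       right_window = (rgt %||% integer(0)) - 1L,
                       position_rel = cfg$window_fraction *
                         ((lft %||% integer(0)) + (rgt %||% integer(0)) - 1) / 2,
                       resolution = (rgt %||% integer(0)) - (lft %||% integer(0)) - 1L)
  nuclei <- data.frame(
    nucleus_id = unlist(lapply(qc$sets, `[[`, "nuclei_ids"),
                        use.names = FALSE) %||% character(0),
    individual_id = rep(inds, vapply(qc$sets, function(s) length(s$nuclei_ids),
                                     integer(1))) %||% character(0))
  phase <- data.frame(individual_id = unlist(ph_i) %||% character(0),
                      chromosome = unlist(ph_c) %||% character(0),
                      n_blocks = unlist(ph_b) %||% integer(0),
                      unresolved_links = unlist(ph_u) %||% integer(0),
                      n_stitched = unlist(ph_s) %||% integer(0))
  summ <- crossover_summary(events, nuclei, n_chrom)
  icd_l <- pooled_icd(events)
  traits <- build_trait_table(summ$per_individual, icd_l, ics_l, bundle$meta)
  list(traits = traits, events = events, summary = summ, nuclei = nuclei,
       qc_report = qc$report, phase = phase, map = bundle$map, cfg = cfg,
       n_chromosomes = n_chrom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pooled inter-crossover distances per individual, over all nuclei/chromosomes
pooled_icd <- function(events) {
  if (!nrow(events)) return(list())
  key <- paste(events$individual_id, events$nucleus_id, events$chromosome)
  ord <- order(key, events$position_rel)
  key <- key[ord]; pos <- events$position_rel[ord]
  ind <- events$individual_id[ord]
  same <- key[-1L] == key[-length(key)]
  split(pos[-1L][same] - pos[-length(pos)][same], ind[-1L][same])
}
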