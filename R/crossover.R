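#' Crossover-calling configuration
#'
#' @param window_fraction width of the nonoverlapping aggregation windows as a
#'   fraction of chromosome length (default 0.10; its reciprocal must be an
#'   integer).
#' @param max_gap_rel maximum separation (relative chromosome length) between
#'   the midpoints of the two informative windows flanking a haplotype switch
#'   for the event to be counted (default 0.30; must be >= 2 windows).
#' @param gap_inclusive if `TRUE` (default) a separation exactly equal to
#'   `max_gap_rel` is admitted; if `FALSE` the bound is strict.
#' @return a `crossover_config` list.
#' @export
crossover_config <- function(window_fraction = 0.10, max_gap_rel = 0.30,
                             gap_inclusive = TRUE) {
  n_windows <- 1 / window_fraction
  if (abs(n_windows - round(n_windows)) > 1e-9)
    stop("1 / window_fraction must be an integer")
  if (max_gap_rel < 2 * window_fraction - 1e-9)
    stop("max_gap_rel must be at least two window widths")
  structure(list(window_fraction = window_fraction,
                 n_windows = as.integer(round(n_windows)),
                 max_gap_rel = max_gap_rel,
                 gap_inclusive = isTRUE(gap_inclusive)),
            class = "crossover_config")
}

#' Aggregate haplotype origins into relative chromosomal windows
#'
#' Divides a chromosome into `1/window_fraction` equal windows of relative
#' length and assigns each window the most common haplotype origin among its
#' markers (majority vote). A window with no called markers, or with a tied
#' vote, is missing. Windows are half-open `[i*w, (i+1)*w)` with the last
#' window closed at 1.
#'
#' @param origins matrix (nuclei x markers) of origins +1/-1/NA, as returned
#'   per chromosome by [label_origins()].
#' @param rel_position relative marker positions in `[0, 1]` (taken from the
#'   matrix attribute if absent).
#' @param cfg a [crossover_config()].
#' @return matrix (nuclei x windows) with entries +1 (A), -1 (B), NA; windows
#'   are columns `1..n_windows` (window i covers `[(i-1)*w, i*w)`).
#' @export
aggregate_windows <- function(origins, rel_position = attr(origins, "rel_position"),
                              cfg = crossover_config()) {
  if (is.null(rel_position) || length(rel_position) != ncol(origins))
    stop("rel_position must match the marker columns")
  if (any(rel_position < 0 | rel_position > 1))
    stop("relative marker positions must lie in [0, 1]")
  nw <- cfg$n_windows
  w <- pmin(floor(rel_position / cfg$window_fraction), nw - 1) + 1L
  Z <- origins
  Z[is.na(Z)] <- 0
  ind <- matrix(0, length(w), nw)
  ind[cbind(seq_along(w), w)] <- 1
  S <- Z %*% ind
  lab <- sign(S)
  lab[lab == 0] <- NA_real_
  dimnames(lab) <- list(rownames(origins), NULL)
  lab
}

#' Call crossovers from window-level haplotype labels
#'
#' Scans the informative (non-missing) windows of each gamete left to right;
#' every change of haplotype label between consecutive informative windows is
#' a candidate crossover. A candidate is kept only if the two flanking window
#' midpoints are separated by at most `max_gap_rel` of relative chromosome
#' length (at defaults: up to two intervening missing windows), so switches
#' observed across large uninformative gaps are not counted. The crossover
#' position is the midpoint between the two flanking window midpoints, and
#' the resolution is the number of intervening missing windows (0 = adjacent
#' informative windows).
#'
#' @param labels matrix (nuclei x windows) from [aggregate_windows()], or a
#'   single label vector.
#' @param cfg a [crossover_config()].
#' @return data.frame with columns `nucleus_id`, `left_window`,
#'   `right_window` (0-based indices), `position_rel`, `resolution`. Gametes
#'   with < 2 informative windows contribute no rows and are listed in the
#'   `uninformative` attribute.
#' @export
call_crossovers <- function(labels, cfg = crossover_config()) {
  core <- call_crossovers_core(labels, cfg)
  wf <- cfg$window_fraction
  out <- data.frame(nucleus_id = core$nucleus_id,
                    left_window = core$left - 1L, right_window = core$right - 1L,
                    position_rel = wf * (core$left + core$right - 1) / 2,
                    resolution = core$right - core$left - 1L)
  attr(out, "uninformative") <- core$uninformative
  out
}

# vector-accumulating scan used by call_crossovers() and the cohort pipeline
call_crossovers_core <- function(labels, cfg) {
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1L)
  max_gap_w <- as.integer(round(cfg$max_gap_rel / cfg$window_fraction))
  acc_n <- character(0); acc_l <- integer(0); acc_r <- integer(0)
  uninformative <- character(0)
  rn <- rownames(labels)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(labels)))
  for (i in seq_len(nrow(labels))) {
    l <- labels[i, ]
    inf <- which(!is.na(l))
    if (length(inf) < 2L) {
      uninformative <- c(uninformative, rn[i])
      next
    }
    chg <- which(diff(l[inf]) != 0)
    if (!length(chg)) next
    left <- inf[chg]
    right <- inf[chg + 1L]
    d <- right - left                       # midpoint separation in windows
    keep <- if (cfg$gap_inclusive) d <= max_gap_w else d < max_gap_w
    if (!any(keep)) next
    left <- left[keep]; right <- right[keep]
    acc_n <- c(acc_n, rep(rn[i], length(left)))
    acc_l <- c(acc_l, left); acc_r <- c(acc_r, right)
  }
  list(nucleus_id = acc_n, left = acc_l, right = acc_r,
       uninformative = uninformative)
}

#' Summarise called crossovers per nucleus and per individual
#'
#' @param events data.frame of events with columns `individual_id`,
#'   `nucleus_id`, `chromosome` (as assembled by [analyze_cohort()]).
#' @param nuclei data.frame with columns `nucleus_id`, `individual_id` listing
#'   every retained nucleus (so gametes with zero events are counted).
#' @param n_chromosomes number of chromosomes in the genome.
#' @return list with `per_nucleus` (nucleus_id, individual_id, n_co,
#'   cc_per_chromatid), `per_individual` (individual_id, n_nuclei, mean counts)
#'   and `resolution` (fraction of events at each resolution, plus the
#'   fraction resolved with at most one missing window between flanks).
#' @export
crossover_summary <- function(events, nuclei, n_chromosomes) {
  n_co <- integer(nrow(nuclei))
  names(n_co) <- nuclei$nucleus_id
  if (nrow(events)) {
    tab <- table(events$nucleus_id)
    n_co[names(tab)] <- as.integer(tab)
  }
  per_nucleus <- data.frame(nucleus_id = nuclei$nucleus_id,
                            individual_id = nuclei$individual_id,
                            n_co = unname(n_co),
                            cc_per_chromatid = unname(n_co) / n_chromosomes)
  agg <- stats::aggregate(cbind(n_co, cc_per_chromatid) ~ individual_id,
                          per_nucleus, mean)
  n_nuc <- stats::aggregate(nucleus_id ~ individual_id, per_nucleus, length)
  per_individual <- merge(n_nuc, agg, by = "individual_id", sort = TRUE)
  names(per_individual)[2] <- "n_nuclei"
  resolution <- if (nrow(events)) {
    h <- table(factor(events$resolution, levels = 0:max(events$resolution)))
    list(histogram = h / sum(h), frac_le_1 = mean(events$resolution <= 1))
  } else list(histogram = table(integer(0)), frac_le_1 = NA_real_)
  list(per_nucleus = per_nucleus, per_individual = per_individual,
       resolution = resolution)
}
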