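#' Inter-crossover distances (crossover interference distance, ICD)
#'
#' For every chromatid (nucleus x chromosome) carrying two or more
#' crossovers, the distances between successive crossover positions in
#' relative chromosome length. Crossover interference makes these distances
#' larger than expected under independent placement.
#'
#' @param events data.frame of crossover events with columns `nucleus_id`,
#'   `chromosome`, `position_rel`.
#' @return numeric vector of distances (one per successive pair), with
#'   attribute `chromatid` giving the `nucleus_id:chromosome` of each.
#' @export
icd_distances <- function(events) {
  if (!nrow(events)) return(structure(numeric(0), chromatid = character(0)))
  key <- paste(events$nucleus_id, events$chromosome, sep = ":")
  ord <- order(key, events$position_rel)
  key <- key[ord]; pos <- events$position_rel[ord]
  same <- key[-1L] == key[-length(key)]
  structure(pos[-1L][same] - pos[-length(pos)][same],
            chromatid = key[-1L][same])
}

#' Intrachromosomal genetic shuffling of one gamete (r-bar intra)
#'
#' The probability that two loci drawn uniformly at random from the genome
#' lie on the same chromosome and were uncoupled in the meiosis that produced
#' the gamete:
#' \deqn{\bar r_{intra} = \sum_{k=1}^{n} 2 p_k (1 - p_k) L_k^2}
#' where \eqn{p_k} is the proportion of the gamete's alleles on chromosome
#' \eqn{k} inherited from one parental haplotype and \eqn{L_k} the length of
#' chromosome \eqn{k} as a fraction of total genome length. It is maximal
#' (\eqn{\sum_k L_k^2 / 2}) when every chromosome is an even haplotype mix
#' and zero when each chromosome is inherited intact.
#'
#' @param p per-chromosome proportion of alleles from haplotype A; `NA`
#'   entries (chromosomes without informative windows) are excluded.
#' @param L per-chromosome relative lengths (summing to 1 over the genome).
#' @return the shuffling value, a number in `[0, sum(L^2)/2]`.
#' @export
r_bar_intra <- function(p, L) {
  stopifnot(length(p) == length(L))
  ok <- !is.na(p)
  sum(2 * p[ok] * (1 - p[ok]) * L[ok]^2)
}

#' Per-nucleus shuffling from window labels
#'
#' Computes \eqn{p_k} as the fraction of informative windows labelled
#' haplotype A on chromosome \eqn{k} and applies [r_bar_intra()].
#'
#' @param labels_by_chrom named list (per chromosome) of window-label
#'   matrices (nuclei x windows) from [aggregate_windows()].
#' @param rel_lengths named per-chromosome relative lengths.
#' @return numeric vector, one shuffling value per nucleus.
#' @export
ics_per_nucleus <- function(labels_by_chrom, rel_lengths) {
  chroms <- names(labels_by_chrom)
  stopifnot(all(chroms %in% names(rel_lengths)))
  n <- nrow(labels_by_chrom[[1L]])
  P <- vapply(chroms, function(chr) {
    lab <- labels_by_chrom[[chr]]
    rowMeans(lab == 1, na.rm = TRUE)   # NaN if no informative window
  }, numeric(n))
  if (is.null(dim(P))) P <- matrix(P, nrow = n)
  P[is.nan(P)] <- NA_real_
  L <- rel_lengths[chroms]
  apply(P, 1L, r_bar_intra, L = L)
}

#' Assemble the per-individual crossover trait table
#'
#' One record per retained individual, combining crossover count per
#' chromatid (CC), mean inter-crossover distance (ICD; `NA` when no chromatid
#' carries two crossovers), mean intrachromosomal shuffling (ICS) and group
#' metadata. ICD pools all inter-crossover distances of an individual's
#' nuclei before averaging; ICS and CC are nucleus means.
#'
#' @param per_individual per-individual summary from [crossover_summary()].
#' @param icd_by_individual named list of pooled ICD distance vectors.
#' @param ics_by_individual named list of per-nucleus ICS vectors.
#' @param meta data.frame with `individual_id`, `subpopulation`, `treatment`.
#' @return data.frame ordered by `individual_id` with columns
#'   `individual_id`, `subpopulation`, `treatment`, `n_nuclei`,
#'   `cc_per_chromatid`, `icd_mean`, `ics_mean`.
#' @export
build_trait_table <- function(per_individual, icd_by_individual,
                              ics_by_individual, meta) {
  ids <- sort(per_individual$individual_id)
  per_individual <- per_individual[match(ids, per_individual$individual_id), ]
  icd <- vapply(ids, function(i) {
    d <- icd_by_individual[[i]]
    if (is.null(d) || !length(d)) NA_real_ else mean(d)
  }, numeric(1))
  ics <- vapply(ids, function(i) mean(ics_by_individual[[i]], na.rm = TRUE),
                numeric(1))
  mrow <- match(ids, meta$individual_id)
  if (anyNA(mrow))
    warning("no metadata for individual(s): ",
            paste(ids[is.na(mrow)], collapse = ", "))
  data.frame(individual_id = ids,
             subpopulation = meta$subpopulation[mrow],
             treatment = meta$treatment[mrow],
             n_nuclei = per_individual$n_nuclei,
             cc_per_chromatid = per_individual$cc_per_chromatid,
             icd_mean = unname(icd),
             ics_mean = unname(ics),
             row.names = NULL)
}
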