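#' Phase the two parental haplotypes of an individual from its gametes
#'
#' Haploid gametes of a diploid individual carry mosaics of its two parental
#' haplotypes. Because crossovers are rare relative to marker spacing,
#' adjacent heterozygous markers are usually inherited together, so the
#' relative phase of consecutive markers can be decided by majority voting:
#' over all gametes called at both markers of a pair, `cis` votes (equal
#' alleles) against `trans` votes (opposite alleles). The chain of pairwise
#' orientations, anchored by setting haplotype A to allele A at the first
#' marker of each block, defines the two complementary haplotypes.
#'
#' Zero-margin links (tied or empty votes) are never guessed: they split the
#' chromosome into independent phase blocks, each re-anchored. With
#' `link_window = 2`, next-nearest marker pairs also vote (weight 1), which
#' adds robustness to isolated genotyping errors.
#'
#' @param gset a `gamete_set` from [qc_filter()] (>= 3 nuclei).
#' @param map a [marker_map()] covering the set's markers.
#' @param link_window 1 (consecutive pairs only) or 2 (also next-nearest,
#'   weight 1; the default, robust to isolated genotyping errors).
#' @param stitch if `TRUE` (default), attempt to re-join phase blocks broken
#'   at zero-margin links by a window-scale majority vote (see Details);
#'   genuinely tied votes stay split.
#' @param stitch_markers flanking markers per side used for stitching votes.
#' @return A `phased_parent`: per chromosome a list with `marker_id`,
#'   `rel_position`, `hapA` (+1 = allele A, -1 = allele B; hapB is the
#'   complement), `block` (phase-block index), `margin` (absolute vote margin
#'   per adjacent link; stitched links carry the window-scale vote),
#'   `unresolved` (indices of links still splitting blocks) and `n_stitched`.
#'   Chromosomes with < 2 informative markers are skipped with a warning.
#' @export
phase_individual <- function(gset, map, link_window = 2L, stitch = TRUE,
                             stitch_markers = 10L) {
  stopifnot(inherits(gset, "gamete_set"))
  if (nrow(gset$calls) < 3L)
    stop("phasing requires at least 3 gametes (individual '",
         gset$individual_id, "' has ", nrow(gset$calls), ")")
  if (!link_window %in% c(1L, 2L)) stop("link_window must be 1 or 2")
  idx <- match(gset$marker_ids, map$marker_id)
  if (anyNA(idx)) stop("gamete set contains markers absent from the map")
  chrom <- map$chromosome[idx]
  rel <- map$rel_position[idx]

  chroms <- list()
  for (chr in unique(chrom)) {
    sel <- which(chrom == chr)
    m <- length(sel)
    if (m < 2L) {
      warning("chromosome ", chr, " of individual '", gset$individual_id,
              "' has < 2 informative markers; skipped")
      next
    }
    X <- gset$calls[, sel, drop = FALSE]
    storage.mode(X) <- "double"
    # vote margins: sum over gametes of call_i * call_j (+1 cis, -1 trans)
    m1 <- colSums(X[, -1L, drop = FALSE] * X[, -m, drop = FALSE], na.rm = TRUE)
    m2 <- if (link_window == 2L && m >= 3L)
      colSums(X[, -(1:2), drop = FALSE] * X[, -((m - 1):m), drop = FALSE],
              na.rm = TRUE) else numeric(0)

    # relative orientation of each link: r[j] = sign of the combined score
    # s_j = m1[j] + r[j-1] * m2[j-1] (the m2 vote orients marker j+1 against
    # marker j-1, so it enters through the previous link's orientation; it is
    # not carried across an unresolved link).
    if (link_window == 2L && m >= 3L) {
      s <- m1
      rprev <- (s[1L] > 0) - (s[1L] < 0)   # rprev = 0 drops the m2 carry
      r <- numeric(m - 1L)
      r[1L] <- rprev
      for (j in 2:(m - 1L)) {
        sj <- m1[j] + rprev * m2[j - 1L]
        rprev <- (sj > 0) - (sj < 0)
        r[j] <- rprev
        s[j] <- sj
      }
      margin <- abs(s)
    } else {
      r <- sign(m1)
      margin <- abs(m1)
    }
    unresolved <- which(r == 0)
    block <- cumsum(c(1L, r == 0))
    raw <- cumprod(c(1, ifelse(r == 0, 1, r)))
    anchor <- raw[match(block, block)]   # raw value at each block's first marker
    o <- as.integer(raw / anchor)

    # stitch adjacent phase blocks by a window-scale majority: per gamete,
    # the consensus haplotype over up to `stitch_markers` flanking markers on
    # each side of the broken link; the summed vote orients the right block.
    # A zero vote (e.g. a genuine half-vs-half recombination tie) is never
    # guessed and leaves the blocks split.
    n_stitched <- 0L
    if (stitch && length(unresolved)) {
      Z <- X
      Z[is.na(Z)] <- 0
      for (u in unresolved) {
        bl <- block[u]; br <- block[u + 1L]
        li <- which(block == bl)
        li <- li[max(1L, length(li) - stitch_markers + 1L):length(li)]
        ri <- which(block == br)
        ri <- ri[seq_len(min(stitch_markers, length(ri)))]
        ls <- Z[, li, drop = FALSE] %*% o[li]
        rs <- Z[, ri, drop = FALSE] %*% o[ri]
        vote <- sum(sign(ls) * sign(rs))
        if (vote != 0) {
          if (vote < 0) o[block == br] <- -o[block == br]
          block[block == br] <- bl
          margin[u] <- abs(vote)
          n_stitched <- n_stitched + 1L
        }
      }
      block <- match(block, unique(block))
      unresolved <- which(diff(block) != 0)
    }
    chroms[[chr]] <- list(marker_id = gset$marker_ids[sel], rel_position = rel[sel],
                          hapA = o, block = block, margin = margin,
                          unresolved = unresolved, n_stitched = n_stitched)
  }
  if (!length(chroms))
    warning("individual '", gset$individual_id, "' could not be phased on any chromosome")
  structure(list(individual_id = gset$individual_id, chromosomes = chroms,
                 link_window = link_window),
            class = "phased_parent")
}

#' @export
print.phased_parent <- function(x, ...) {
  nb <- vapply(x$chromosomes, function(ch) max(ch$block), integer(1))
  cat(sprintf("phased_parent '%s': %d chromosomes, %d phase block(s) total\n",
              x$individual_id, length(x$chromosomes), sum(nb)))
  invisible(x)
}

#' Label each gamete call with its haplotype of origin
#'
#' Maps every non-missing gamete call to the parental haplotype it matches:
#' origin A if the call equals the phased haplotype-A allele, otherwise B.
#' Markers in phase blocks spanning less than one aggregation window
#' (`min_block_span` of relative chromosome length) are set to missing, so
#' unanchored fragments cannot inject spurious haplotype switches.
#'
#' @param gset the `gamete_set` that was phased.
#' @param parent the matching `phased_parent`.
#' @param min_block_span minimum relative span for a phase block to be kept
#'   (default 0.10, one aggregation window).
#' @return named list (per chromosome) of origin matrices
#'   (nuclei x markers; +1 = haplotype A, -1 = haplotype B, NA = missing or
#'   unphased), each with attribute `rel_position`.
#' @export
label_origins <- function(gset, parent, min_block_span = 0.10) {
  stopifnot(inherits(gset, "gamete_set"), inherits(parent, "phased_parent"))
  if (!identical(gset$individual_id, parent$individual_id))
    stop("gamete set and phased parent belong to different individuals")
  out <- list()
  for (chr in names(parent$chromosomes)) {
    ph <- parent$chromosomes[[chr]]
    j <- match(ph$marker_id, gset$marker_ids)
    if (anyNA(j)) stop("phased markers absent from gamete set on chromosome ", chr)
    calls <- gset$calls[, j, drop = FALSE]
    storage.mode(calls) <- "double"
    origins <- calls * matrix(ph$hapA, nrow(calls), length(j), byrow = TRUE)
    if (ph$block[length(ph$block)] > 1L) {
      # drop phase blocks too short to span one window
      spans <- tapply(ph$rel_position, ph$block, function(p) max(p) - min(p))
      short <- as.integer(names(spans)[spans < min_block_span])
      if (length(short) && any(ph$block %in% short))
        origins[, ph$block %in% short] <- NA_real_
    }
    colnames(origins) <- ph$marker_id
    attr(origins, "rel_position") <- ph$rel_position
    out[[chr]] <- origins
  }
  out
}
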