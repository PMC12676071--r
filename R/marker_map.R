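#' Build a validated marker map
#'
#' A marker map holds the physical coordinates of every SNP marker together
#' with the length of its chromosome, and derives the relative position
#' (position / chromosome length) used by all window-based computations.
#'
#' @param markers data.frame with columns `marker_id`, `chromosome`,
#'   `position_bp` (1-based integer coordinates).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   names must cover every chromosome present in `markers`.
#' @return A `marker_map`: a data.frame sorted by (chromosome, position_bp)
#'   with columns `marker_id`, `chromosome`, `position_bp`, `chrom_length_bp`,
#'   `rel_position`, and attribute `chrom_lengths`.
#' @export
marker_map <- function(markers, chrom_lengths) {
  stopifnot(is.data.frame(markers),
            all(c("marker_id", "chromosome", "position_bp") %in% names(markers)))
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  markers <- as.data.frame(markers)[, c("marker_id", "chromosome", "position_bp")]
  markers$marker_id <- as.character(markers$marker_id)
  markers$chromosome <- as.character(markers$chromosome)
  markers$position_bp <- as.numeric(markers$position_bp)
  if (anyDuplicated(markers$marker_id))
    stop("duplicated marker ids in marker map")
  missing_chr <- setdiff(unique(markers$chromosome), names(chrom_lengths))
  if (length(missing_chr))
    stop("no declared length for chromosome(s): ", paste(missing_chr, collapse = ", "))
  if (any(markers$position_bp < 1))
    stop("marker positions must be >= 1 (1-based bp)")
  ord <- order(markers$chromosome, markers$position_bp)
  markers <- markers[ord, , drop = FALSE]
  markers$chrom_length_bp <- unname(chrom_lengths[markers$chromosome])
  markers$rel_position <- markers$position_bp / markers$chrom_length_bp
  if (any(markers$rel_position > 1))
    stop("marker position exceeds declared chromosome length")
  dup_pos <- stats::ave(markers$position_bp, markers$chromosome,
                        FUN = function(p) duplicated(p))
  if (any(dup_pos > 0))
    stop("duplicate marker positions within a chromosome")
  rownames(markers) <- NULL
  attr(markers, "chrom_lengths") <- chrom_lengths
  class(markers) <- c("marker_map", "data.frame")
  markers
}

#' Read a marker map from delimited text
#'
#' @param path delimited file with columns marker_id, chromosome, position_bp.
#' @param lengths_path two-column delimited file (chromosome, length_bp).
#' @return a [marker_map()].
#' @export
read_marker_map <- function(path, lengths_path) {
  mk <- as.data.frame(data.table::fread(path))
  ln <- as.data.frame(data.table::fread(lengths_path))
  lens <- stats::setNames(as.numeric(ln[[2]]), as.character(ln[[1]]))
  marker_map(mk, lens)
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("marker_map: %d markers on %d chromosomes\n",
              nrow(x), length(unique(x$chromosome))))
  NextMethod()
}

# relative chromosome lengths L_k = chrom_length / genome_length
chrom_rel_lengths <- function(map) {
  lens <- attr(map, "chrom_lengths")
  lens / sum(lens)
}
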