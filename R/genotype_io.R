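# Internal genotype coding: calls are stored as integer matrices with
# +1 = allele A, -1 = allele B, 0 = heterozygous (diploid only), NA = missing.
# The character alphabet only exists at the file boundary.

.default_alphabet <- c(A = "A", B = "B", het = "AB", missing = "NA")

encode_calls <- function(chr, alphabet = .default_alphabet, ploidy = "haploid") {
  out <- matrix(NA_integer_, nrow(chr), ncol(chr), dimnames = dimnames(chr))
  out[chr == alphabet[["A"]]] <- 1L
  out[chr == alphabet[["B"]]] <- -1L
  het <- chr == alphabet[["het"]]
  if (any(het, na.rm = TRUE)) {
    if (ploidy == "haploid")
      stop("heterozygous call '", alphabet[["het"]], "' in haploid genotype data")
    out[which(het)] <- 0L
  }
  known <- is.na(chr) | chr == alphabet[["missing"]] | chr == "" |
    chr == alphabet[["A"]] | chr == alphabet[["B"]] | het
  if (!all(known)) {
    bad <- unique(chr[!known])
    warning("unknown genotype token(s) set to missing: ",
            paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

decode_calls <- function(calls, alphabet = .default_alphabet) {
  out <- matrix(alphabet[["missing"]], nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  out[which(calls == 1L)] <- alphabet[["A"]]
  out[which(calls == -1L)] <- alphabet[["B"]]
  out[which(calls == 0L)] <- alphabet[["het"]]
  out
}

new_genotype_matrix <- function(calls, ploidy) {
  structure(list(calls = calls, ploidy = ploidy,
                 sample_ids = rownames(calls), marker_ids = colnames(calls)),
            class = "genotype_matrix")
}

#' Read a genotype matrix from delimited text
#'
#' Expects samples in rows and markers in columns: the first column holds the
#' sample id, the header row holds marker ids. The delimiter (comma or tab) is
#' auto-detected from the header unless `sep` is given.
#'
#' @param path file path.
#' @param ploidy `"haploid"` (gamete calls; heterozygous tokens are an error)
#'   or `"diploid"` (sporophyte calls; heterozygous allowed).
#' @param alphabet named character vector with entries `A`, `B`, `het`,
#'   `missing` giving the tokens used in the file.
#' @param sep field separator; `NULL` to auto-detect.
#' @return A `genotype_matrix`: calls coded +1 (A), -1 (B), 0 (heterozygous,
#'   diploid only), `NA` (missing), with sample and marker ids as dimnames.
#' @export
read_genotype_table <- function(path, ploidy = c("haploid", "diploid"),
                                alphabet = .default_alphabet, sep = NULL) {
  ploidy <- match.arg(ploidy)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  dt <- data.table::fread(path, sep = sep, header = TRUE, colClasses = "character",
                          na.strings = character(0))
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) stop("duplicated sample ids in ", path)
  mk <- names(dt)[-1L]
  if (anyDuplicated(mk)) stop("duplicated marker ids in ", path)
  chr <- as.matrix(dt[, -1L, with = FALSE])
  dimnames(chr) <- list(ids, mk)
  new_genotype_matrix(encode_calls(chr, alphabet, ploidy), ploidy)
}

#' Write a genotype matrix as delimited text
#'
#' Inverse of [read_genotype_table()]; a write/read round trip reproduces the
#' matrix exactly.
#'
#' @param x a `genotype_matrix`.
#' @param path output file.
#' @param alphabet token set, as in [read_genotype_table()].
#' @param sep field separator.
#' @export
write_genotype_table <- function(x, path, alphabet = .default_alphabet, sep = ",") {
  chr <- decode_calls(x$calls, alphabet)
  df <- data.frame(sample_id = rownames(chr), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path delimited file with columns `individual_id`, `subpopulation`,
#'   `treatment`.
#' @return data.frame with one row per individual.
#' @export
read_metadata <- function(path) {
  meta <- as.data.frame(data.table::fread(path, colClasses = "character"))
  need <- c("individual_id", "subpopulation", "treatment")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$individual_id))
    stop("duplicated individual ids in metadata")
  meta[, need]
}

#' Informative (heterozygous) markers of one individual
#'
#' Gamete genotypes are only informative about recombination at markers where
#' the parent plant is heterozygous; this returns that subset in map order.
#'
#' @param diploid a diploid `genotype_matrix`.
#' @param individual_id row to use.
#' @param map a [marker_map()].
#' @return character vector of marker ids, sorted by (chromosome, position).
#' @export
informative_markers <- function(diploid, individual_id, map) {
  stopifnot(inherits(diploid, "genotype_matrix"), diploid$ploidy == "diploid")
  if (!individual_id %in% rownames(diploid$calls))
    stop("individual '", individual_id, "' absent from diploid genotype matrix")
  g <- diploid$calls[individual_id, ]
  het <- names(g)[which(g == 0L)]
  if (!length(het)) {
    warning("individual '", individual_id, "' has no heterozygous markers")
    return(character(0))
  }
  # map is already sorted by (chromosome, position_bp)
  map$marker_id[map$marker_id %in% het]
}

#' Quality-control filter for gamete genotype sets
#'
#' Applies the array QC rules: nuclei with an allele call rate below 10% are
#' removed; individuals left with fewer than three nuclei are removed; and
#' individuals whose remaining set of nuclei exceeds 50% missing data at the
#' individual's informative markers are removed. Thresholds are strict, so
#' boundary cases (call rate exactly 0.10, missing exactly 0.50) are kept.
#' The call rate is computed over all assayed markers; the missing fraction
#' over the concatenated informative-marker calls of the retained nuclei.
#'
#' @param gametes haploid `genotype_matrix` of nucleus calls (all markers).
#' @param nuclei_map data.frame with columns `nucleus_id`, `individual_id`.
#' @param diploid diploid `genotype_matrix` of the parent plants.
#' @param map a [marker_map()].
#' @param min_call_rate nuclei below this call rate are dropped (default 0.10).
#' @param max_missing individuals above this missing fraction are dropped
#'   (default 0.50).
#' @return list with `sets` (named list of `gamete_set` objects: calls
#'   restricted to the individual's informative markers) and `report`
#'   (data.frame of every removal with its reason).
#' @export
qc_filter <- function(gametes, nuclei_map, diploid, map,
                      min_call_rate = 0.10, max_missing = 0.50) {
  stopifnot(inherits(gametes, "genotype_matrix"), gametes$ploidy == "haploid")
  if (!all(c("nucleus_id", "individual_id") %in% names(nuclei_map)))
    stop("nuclei_map needs columns nucleus_id, individual_id")
  if (nrow(gametes$calls) == 0L) {
    warning("empty gamete matrix: nothing to filter")
    return(list(sets = list(),
                report = data.frame(level = character(0), id = character(0),
                                    reason = character(0), value = numeric(0))))
  }
  removals <- list()
  note <- function(level, id, reason, value)
    removals[[length(removals) + 1L]] <<-
      data.frame(level = level, id = id, reason = reason, value = value)

  call_rate <- rowMeans(!is.na(gametes$calls))
  bad_nuc <- names(call_rate)[call_rate < min_call_rate]
  for (n in bad_nuc) note("nucleus", n, "call_rate_below_min", call_rate[[n]])
  keep_nuc <- setdiff(rownames(gametes$calls), bad_nuc)

  sets <- list()
  for (ind in unique(nuclei_map$individual_id)) {
    nuc <- intersect(nuclei_map$nucleus_id[nuclei_map$individual_id == ind], keep_nuc)
    if (length(nuc) < 3L) {
      note("individual", ind, "fewer_than_three_nuclei", length(nuc))
      next
    }
    if (!ind %in% rownames(diploid$calls)) {
      note("individual", ind, "no_diploid_genotype", NA_real_)
      next
    }
    inf <- suppressWarnings(informative_markers(diploid, ind, map))
    if (!length(inf)) {
      note("individual", ind, "no_informative_markers", 0)
      next
    }
    calls <- gametes$calls[nuc, inf, drop = FALSE]
    miss <- mean(is.na(calls))
    if (miss > max_missing) {
      note("individual", ind, "missing_fraction_above_max", miss)
      next
    }
    sets[[ind]] <- structure(
      list(individual_id = ind, nuclei_ids = nuc, marker_ids = inf,
           calls = calls,
           qc = data.frame(nucleus_id = nuc, call_rate = unname(call_rate[nuc]))),
      class = "gamete_set")
  }
  report <- if (length(removals)) do.call(rbind, removals)
            else data.frame(level = character(0), id = character(0),
                            reason = character(0), value = numeric(0))
  list(sets = sets, report = report)
}

#' @export
print.gamete_set <- function(x, ...) {
  cat(sprintf("gamete_set '%s': %d nuclei x %d informative markers (%.1f%% missing)\n",
              x$individual_id, nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}
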