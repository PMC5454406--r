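.conservation_levels <- c("ALL_CONSERVED", "GROUP_CONSERVED", "VARIABLE")

#' Read a grouped multiple alignment
#'
#' Loads an aligned FASTA (via Biostrings) or Clustal file together with a
#' group manifest (TSV: `id`, `group`). All aligned sequences must have
#' equal length; the manifest must cover every sequence.
#'
#' @param path alignment file
#' @param manifest path to the group manifest TSV, or a data.frame with
#'   columns `id` and `group`
#' @param reference_id id of the reference sequence for coordinate mapping
#' @param format "fasta" or "clustal"
#' @return list of class `grouped_alignment`: `seqs` (named character
#'   vector of aligned sequences), `groups` (named character vector),
#'   `reference_id`
#' @export
read_grouped_alignment <- function(path, manifest, reference_id,
                                   format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- setNames(as.character(ss), names(ss))
  } else {
    seqs <- .read_clustal(path)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.character(manifest))
    manifest <- read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  grouped_alignment(seqs, setNames(manifest$group, manifest$id), reference_id)
}

## Clustal reading via Biostrings' multiple-alignment reader; sequences may
## be RNA or DNA, so try both string classes
.read_clustal <- function(path) {
  aln <- tryCatch(
    Biostrings::readRNAMultipleAlignment(path, format = "clustal"),
    error = function(e)
      Biostrings::readDNAMultipleAlignment(path, format = "clustal"))
  s <- as.character(aln)
  setNames(as.character(s), rownames(aln))
}

#' Construct a grouped alignment object
#' @param seqs named character vector of equal-length aligned sequences
#' @param groups named character vector of group labels (names = sequence ids)
#' @param reference_id one of `names(seqs)`
#' @export
grouped_alignment <- function(seqs, groups, reference_id) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences differ in length")
  if (!reference_id %in% names(seqs))
    stop("reference sequence '", reference_id, "' absent from the alignment")
  missing_ids <- setdiff(names(seqs), names(groups))
  if (length(missing_ids))
    stop("sequences missing from the group manifest: ",
         paste(head(missing_ids, 5), collapse = ", "))
  structure(list(seqs = seqs,
                 groups = groups[names(seqs)],
                 reference_id = reference_id),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat("Grouped alignment:", length(x$seqs), "sequences x",
      nchar(x$seqs[[1]]), "columns; reference:", x$reference_id, "\n")
  print(table(x$groups))
  invisible(x)
}

#' Map alignment columns to reference coordinates
#'
#' Non-gap columns of the reference sequence map to consecutive 1-based
#' reference positions; gap columns are unmapped (NA).
#'
#' @param aln [grouped_alignment()]
#' @return integer vector over alignment columns; NA where the reference
#'   has a gap
#' @export
map_columns_to_reference <- function(aln) {
  ref <- strsplit(aln$seqs[[aln$reference_id]], "")[[1]]
  out <- rep(NA_integer_, length(ref))
  nongap <- ref != "-"
  out[nongap] <- seq_len(sum(nongap))
  out
}

#' Classify reference positions into three conservation categories
#'
#' For each reference position: ALL_CONSERVED when one identical non-gap
#' residue is present in every sequence; otherwise GROUP_CONSERVED when
#' identical (non-gap) across the focal subgroup; otherwise VARIABLE. A gap
#' in any sequence fails the corresponding test (conservation is read
#' strictly). Comparison is case-insensitive and treats T and U as the
#' same residue.
#'
#' @param aln [grouped_alignment()]
#' @param focal_groups character vector of group labels forming the focal
#'   subgroup
#' @return object of class `conservation_track`: a factor vector over
#'   reference positions 1..L with levels ALL_CONSERVED, GROUP_CONSERVED,
#'   VARIABLE
#' @export
classify_conservation <- function(aln, focal_groups) {
  focal <- aln$groups %in% focal_groups
  if (!any(focal)) stop("focal subgroup is empty")
  mat <- do.call(rbind, strsplit(chartr("tT", "uU", toupper(aln$seqs)), ""))
  colmap <- map_columns_to_reference(aln)
  cols <- which(!is.na(colmap))
  conserved_in <- function(colv) {
    !any(colv == "-") && length(unique(colv)) == 1L
  }
  cat_ <- vapply(cols, function(cc) {
    colv <- mat[, cc]
    if (conserved_in(colv)) "ALL_CONSERVED"
    else if (conserved_in(colv[focal])) "GROUP_CONSERVED"
    else "VARIABLE"
  }, character(1))
  track <- factor(cat_, levels = .conservation_levels)
  names(track) <- colmap[cols]
  class(track) <- c("conservation_track", class(track))
  track
}

#' Category counts and fractions over a reference interval
#'
#' @param track [classify_conservation()] output
#' @param interval c(start, end), 1-based inclusive reference coordinates
#' @return data.frame with one row per category: count and fraction
#' @export
summarize_interval <- function(track, interval) {
  stopifnot(length(interval) == 2L, interval[1L] >= 1L,
            interval[2L] <= length(track), interval[1L] <= interval[2L])
  sub <- track[interval[1L]:interval[2L]]
  counts <- table(factor(sub, levels = .conservation_levels))
  data.frame(category = names(counts),
             count = as.integer(counts),
             fraction = as.numeric(counts) / length(sub))
}

#' Export a conservation track as TSV
#' @param track conservation track
#' @param path output file
#' @export
write_conservation_tsv <- function(track, path) {
  write.table(data.frame(position = seq_along(track),
                         category = as.character(track)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a conservation track as BED intervals (one per category run)
#' @param track conservation track
#' @param path output file
#' @param chrom sequence name
#' @export
write_conservation_bed <- function(track, path, chrom = "ref") {
  r <- rle(as.character(track))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  export_bed(data.frame(name = r$values, start = starts, end = ends),
             path, chrom = chrom)
}
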