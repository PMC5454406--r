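#' Decompose a structure into stems and loop elements
#'
#' Stems are maximal stacks of consecutive pairs; by default a single
#' bulged nucleotide terminates a stem, but `collapse_single_bulges = TRUE`
#' merges stems separated by a 1-nt bulge into one (the view used when
#' describing bulged hairpins such as SL1a/SL3a). Loop elements (hairpin,
#' bulge, internal, multibranch, exterior) are assigned on the nested
#' backbone (layer 1); positions belonging to crossing helices are reported
#' with their stems. Every unpaired position lands in exactly one element.
#'
#' @param x [rna_structure()]
#' @param collapse_single_bulges merge stems across 1-nt bulges
#' @return list with `stems` (data.frame: i5, i3, j5, j3, length, layer),
#'   `hairpins`, `bulges`, `internals`, `multibranch` (lists with closing
#'   pair(s) and unpaired positions) and `exterior` (integer positions)
#' @export
enumerate_elements <- function(x, collapse_single_bulges = FALSE) {
  pairs <- x$pairs
  layer <- pair_layers(x)
  stems_all <- list()
  for (l in sort(unique(layer))) {
    st <- .stems(pairs[layer == l, , drop = FALSE])
    for (s in st) stems_all[[length(stems_all) + 1L]] <- list(pairs = s,
                                                             layer = l)
  }
  if (collapse_single_bulges && length(stems_all) > 1L) {
    merged <- list()
    for (s in stems_all) {
      m <- length(merged)
      if (m > 0L && merged[[m]]$layer == s$layer) {
        a <- merged[[m]]$pairs; b <- s$pairs
        inner <- a[nrow(a), ]; outer <- b[1L, ]
        gap5 <- outer[1L] - inner[1L] - 1L
        gap3 <- inner[2L] - outer[2L] - 1L
        if ((gap5 + gap3) == 1L && gap5 >= 0L && gap3 >= 0L) {
          merged[[m]]$pairs <- rbind(a, b)
          next
        }
      }
      merged[[length(merged) + 1L]] <- s
    }
    stems_all <- merged
  }
  stems <- do.call(rbind, lapply(stems_all, function(s) {
    p <- s$pairs
    data.frame(i5 = p[1L, 1L], i3 = p[nrow(p), 1L],
               j5 = p[nrow(p), 2L], j3 = p[1L, 2L],
               length = nrow(p), layer = s$layer)
  }))
  if (is.null(stems))
    stems <- data.frame(i5 = integer(0), i3 = integer(0), j5 = integer(0),
                        j3 = integer(0), length = integer(0),
                        layer = integer(0))

  ## loop classification on the nested backbone
  bb <- pairs[layer == 1L, , drop = FALSE]
  bb <- bb[order(bb[, 1L]), , drop = FALSE]
  np <- nrow(bb)
  parent <- rep(0L, np)
  open <- integer(0); openj <- integer(0)
  for (r in seq_len(np)) {
    while (length(open) && openj[length(open)] < bb[r, 1L]) {
      open <- open[-length(open)]; openj <- openj[-length(openj)]
    }
    if (length(open)) parent[r] <- open[length(open)]
    open <- c(open, r); openj <- c(openj, bb[r, 2L])
  }
  kids_of <- split(seq_len(np), factor(parent, levels = 0:np))
  hairpins <- list(); bulges <- list(); internals <- list(); multis <- list()
  backbone_paired <- if (np) c(bb) else integer(0)
  for (r in seq_len(np)) {
    i <- bb[r, 1L]; j <- bb[r, 2L]
    kids <- kids_of[[as.character(r)]]
    inner <- setdiff(seq(i + 1L, j - 1L), unlist(lapply(kids, function(k)
      seq(bb[k, 1L], bb[k, 2L]))))
    inner <- setdiff(inner, c(pairs))    # paired in any layer is not loop
    if (length(kids) == 0L) {
      hairpins[[length(hairpins) + 1L]] <-
        list(closing = c(i, j), positions = inner)
    } else if (length(kids) == 1L) {
      k <- bb[kids, 1L]; l <- bb[kids, 2L]
      l1 <- k - i - 1L; l2 <- j - l - 1L
      if (l1 + l2 == 0L) next                    # stacked, no loop
      el <- list(closing = c(i, j), inner_pair = c(k, l), positions = inner)
      if (l1 == 0L || l2 == 0L) bulges[[length(bulges) + 1L]] <- el
      else internals[[length(internals) + 1L]] <- el
    } else {
      multis[[length(multis) + 1L]] <-
        list(closing = c(i, j),
             branches = lapply(kids, function(k) bb[k, ]),
             positions = inner)
    }
  }
  exterior <- setdiff(seq_len(x$length), c(backbone_paired,
                                           unlist(lapply(c(hairpins, bulges,
                                                           internals, multis),
                                                         `[[`, "positions"))))
  ## crossing-helix positions are paired, not exterior
  exterior <- setdiff(exterior, c(pairs))
  list(stems = stems, hairpins = hairpins, bulges = bulges,
       internals = internals, multibranch = multis, exterior = exterior)
}

#' Extract the H-type pseudoknot core (S1/L2/S2) of a structure
#'
#' The two crossing stems are named by the 5'-position of their 5' strands:
#' S1 is the stem whose 5' strand is 5'-most, S2 the stem it crosses. L2 is
#' the set of unpaired positions between the end of S2's 5' strand and the
#' start of S1's 3' strand (the interhelical loop); L1 and L3 are the loop
#' spans bridged by S1 and S2 respectively.
#'
#' @param x [rna_structure()]
#' @return NULL when the structure has no crossing pairs, otherwise a list
#'   of class `pseudoknot_core` with elements `S1_pairs`, `S2_pairs`,
#'   `S1_length`, `S2_length`, `L2_positions`, `L1_span`, `L3_span`,
#'   `span_3prime`
#' @export
pseudoknot_core <- function(x) {
  if (!has_crossing(x)) return(NULL)
  stems <- .stems(x$pairs)
  ns <- length(stems)
  edges <- NULL
  for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
    if (.pairs_cross(stems[[a]][1L, ], stems[[b]][1L, ]))
      edges <- rbind(edges, c(a, b))
  }
  if (is.null(edges) || nrow(edges) != 1L)
    stop("unsupported pseudoknot topology: expected exactly one pair of ",
         "crossing stems, found ", NROW(edges))
  sa <- stems[[edges[1L, 1L]]]; sb <- stems[[edges[1L, 2L]]]
  ## every pair of one stem must cross every pair of the other
  for (ra in seq_len(nrow(sa))) for (rb in seq_len(nrow(sb))) {
    if (!.pairs_cross(sa[ra, ], sb[rb, ]))
      stop("unsupported pseudoknot topology: stems cross only partially")
  }
  if (sa[1L, 1L] > sb[1L, 1L]) { tmp <- sa; sa <- sb; sb <- tmp }
  S1 <- sa; S2 <- sb
  colnames(S1) <- colnames(S2) <- c("i", "j")
  partner <- partner_vector(x)
  s1_3p_start <- min(S1[, 2L])           # start of S1's 3' strand
  s2_5p_end <- max(S2[, 1L])             # end of S2's 5' strand
  l2 <- if (s2_5p_end + 1L > s1_3p_start - 1L) integer(0) else
    setdiff(seq(s2_5p_end + 1L, s1_3p_start - 1L), which(partner > 0L))
  core <- list(
    S1_pairs = S1, S2_pairs = S2,
    S1_length = nrow(S1), S2_length = nrow(S2),
    L2_positions = l2,
    L1_span = c(max(S1[, 1L]) + 1L, min(S2[, 1L]) - 1L),
    L3_span = c(max(S1[, 2L]) + 1L, min(S2[, 2L]) - 1L),
    span_3prime = max(S1, S2))
  class(core) <- "pseudoknot_core"
  core
}

#' @export
print.pseudoknot_core <- function(x, ...) {
  cat(sprintf("Pseudoknot core: S1 %d bp (%d-%d : %d-%d), S2 %d bp (%d-%d : %d-%d)\n",
              x$S1_length, min(x$S1_pairs[, 1]), max(x$S1_pairs[, 1]),
              min(x$S1_pairs[, 2]), max(x$S1_pairs[, 2]),
              x$S2_length, min(x$S2_pairs[, 1]), max(x$S2_pairs[, 1]),
              min(x$S2_pairs[, 2]), max(x$S2_pairs[, 2])))
  cat(sprintf("  L2 (%d nt): %s; L1 span %d-%d; L3 span %d-%d; 3' extent %d\n",
              length(x$L2_positions),
              paste(x$L2_positions, collapse = ","),
              x$L1_span[1], x$L1_span[2], x$L3_span[1], x$L3_span[2],
              x$span_3prime))
  invisible(x)
}

#' Validate and annotate named motif intervals
#'
#' Intervals are 1-based inclusive, matching the coordinate style used for
#' leader-region motifs (PBS, Box 0/1/2.1, CYC5, PAL1-3, ...).
#'
#' @param motifs data.frame with columns `name`, `start`, `end`, or a path
#'   to a whitespace-separated key-value file with those columns
#' @param seq_length sequence length the intervals must fit
#' @return data.frame: name, start, end, length
#' @export
annotate_motifs <- function(motifs, seq_length) {
  if (is.character(motifs) && length(motifs) == 1L)
    motifs <- read_motif_config(motifs)
  stopifnot(all(c("name", "start", "end") %in% names(motifs)))
  if (any(motifs$start < 1L) || any(motifs$end > seq_length) ||
      any(motifs$start > motifs$end))
    stop("motif interval out of range for sequence of length ", seq_length)
  data.frame(name = as.character(motifs$name),
             start = as.integer(motifs$start),
             end = as.integer(motifs$end),
             length = as.integer(motifs$end - motifs$start + 1L))
}

#' Read a motif configuration file
#' @param path whitespace-separated file with header `name start end`
#' @export
read_motif_config <- function(path) {
  read.table(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Canonical Ty1 leader motif coordinates
#'
#' The classical cis-acting motifs of the Ty1 5' leader on Ty1-H3
#' coordinates: the 5' UTR, the primer-binding site, the tRNA-iMet contact
#' boxes, and the CYC5 circularization motif.
#' @return data.frame usable with [annotate_motifs()]
#' @export
ty1_leader_motifs <- function() {
  data.frame(
    name = c("UTR5", "PBS", "Box0", "Box1", "Box2.1", "CYC5"),
    start = c(1L, 95L, 110L, 144L, 162L, 155L),
    end = c(53L, 104L, 116L, 149L, 168L, 168L))
}

#' Export intervals as BED (0-based half-open)
#'
#' @param df data.frame with columns `name`, `start`, `end` (1-based
#'   inclusive) and optionally `score`
#' @param path output file
#' @param chrom chromosome/sequence name for column 1
#' @export
export_bed <- function(df, path, chrom = "ref") {
  bed <- data.frame(chrom = chrom,
                    start = as.integer(df$start) - 1L,
                    end = as.integer(df$end),
                    name = df$name,
                    score = if ("score" %in% names(df)) df$score else 0L)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
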