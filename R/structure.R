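#' RNA secondary structure container
#'
#' A set of base pairs `(i, j)` with `i < j` over 1-based positions of a
#' sequence of known length. Crossing (pseudoknotted) pairs are permitted;
#' they are detected and handled downstream (layer assignment, pseudoknot
#' core extraction, energy evaluation).
#'
#' @param pairs two-column integer matrix (or NULL for the empty structure);
#'   one row per base pair, columns are the 5' and 3' partner
#' @param length sequence length the structure lives on
#' @param min_hairpin minimum number of unpaired nucleotides enclosed by any
#'   pair (default 3); every pair must satisfy `j - i > min_hairpin`
#' @return object of class `rna_structure`
#' @export
rna_structure <- function(pairs = NULL, length, min_hairpin = 3L) {
  length <- as.integer(length)
  stopifnot(length >= 0L)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2L)
    if (any(!is.finite(pairs))) stop("non-finite pair coordinates")
    ## orient every pair 5' -> 3'
    flip <- pairs[, 1L] > pairs[, 2L]
    if (any(flip)) pairs[flip, ] <- pairs[flip, 2:1]
    if (any(pairs[, 1L] < 1L) || any(pairs[, 2L] > length))
      stop("pair coordinates outside 1..", length)
    if (any(pairs[, 1L] == pairs[, 2L]))
      stop("a position cannot pair with itself")
    occ <- c(pairs)
    if (anyDuplicated(occ))
      stop("a position participates in more than one pair")
    if (any(pairs[, 2L] - pairs[, 1L] <= min_hairpin))
      stop("pair violates the minimum hairpin length (j - i must exceed ",
           min_hairpin, ")")
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  dimnames(pairs) <- NULL   # columns are (i, j); names would leak into math
  structure(list(pairs = pairs, length = length,
                 min_hairpin = as.integer(min_hairpin)),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA structure:", nrow(x$pairs), "pairs over", x$length, "nt",
      if (has_crossing(x)) "(pseudoknotted)" else "(nested)", "\n")
  if (!is.null(attr(x, "energy")))
    cat("  energy:", format(attr(x, "energy"), digits = 4), "kcal/mol\n")
  invisible(x)
}

#' Number of base pairs
#' @param x rna_structure
#' @export
n_pairs <- function(x) nrow(x$pairs)

#' Pairing partner vector
#'
#' @param x rna_structure
#' @return integer vector of length `x$length`; 0 for unpaired positions
#' @export
partner_vector <- function(x) {
  p <- integer(x$length)
  if (nrow(x$pairs)) {
    p[x$pairs[, 1L]] <- x$pairs[, 2L]
    p[x$pairs[, 2L]] <- x$pairs[, 1L]
  }
  p
}

## do two pairs (vectors c(i,j)) cross?
.pairs_cross <- function(p, q) {
  (p[1L] < q[1L] && q[1L] < p[2L] && p[2L] < q[2L]) ||
    (q[1L] < p[1L] && p[1L] < q[2L] && q[2L] < p[2L])
}

#' Does the structure contain crossing (pseudoknotted) pairs?
#' @param x rna_structure
#' @export
has_crossing <- function(x) {
  pr <- x$pairs
  n <- nrow(pr)
  if (n < 2L) return(FALSE)
  ## pairs are sorted by i; (a,b) cross iff i_a < i_b < j_a < j_b
  for (a in seq_len(n - 1L)) {
    b <- which(pr[, 1L] > pr[a, 1L] & pr[, 1L] < pr[a, 2L] &
                 pr[, 2L] > pr[a, 2L])
    if (length(b)) return(TRUE)
  }
  FALSE
}

#' Assign pairs to non-crossing layers
#'
#' Greedy assignment in 5'-order: each pair goes to the first layer in which
#' it crosses no previously assigned pair. Layer 1 is the nested backbone;
#' higher layers hold pseudoknotted helices.
#'
#' @param x rna_structure
#' @return integer vector, one layer index per row of `x$pairs`
#' @export
pair_layers <- function(x) {
  pr <- x$pairs
  n <- nrow(pr)
  layer <- integer(n)
  for (a in seq_len(n)) {
    l <- 1L
    repeat {
      members <- which(layer == l)
      ok <- !any(vapply(members, function(b) .pairs_cross(pr[a, ], pr[b, ]),
                        logical(1)))
      if (ok) { layer[a] <- l; break }
      l <- l + 1L
    }
  }
  layer
}

#' Multi-layer dot-bracket string
#'
#' Nested pairs use `()`; the first pseudoknot layer `[]`; the second `{}`.
#' @param x rna_structure
#' @return single string of length `x$length`
#' @export
as_dotbracket <- function(x) {
  open <- c("(", "[", "{"); close <- c(")", "]", "}")
  layer <- pair_layers(x)
  if (any(layer > 3L)) stop("more than 3 crossing layers; cannot serialize")
  s <- rep(".", x$length)
  if (nrow(x$pairs)) {
    s[x$pairs[, 1L]] <- open[layer]
    s[x$pairs[, 2L]] <- close[layer]
  }
  paste(s, collapse = "")
}

#' Parse a multi-layer dot-bracket string
#' @param db dot-bracket string using `()`, `[]`, `{}` and `.`
#' @param min_hairpin passed to [rna_structure()]
#' @export
parse_dotbracket <- function(db, min_hairpin = 3L) {
  ch <- strsplit(db, "")[[1]]
  open <- c("(" = 1L, "[" = 2L, "{" = 3L)
  close <- c(")" = 1L, "]" = 2L, "}" = 3L)
  stacks <- list(integer(0), integer(0), integer(0))
  pairs <- NULL
  for (pos in seq_along(ch)) {
    c0 <- ch[pos]
    if (c0 %in% names(open)) {
      l <- open[[c0]]
      stacks[[l]] <- c(stacks[[l]], pos)
    } else if (c0 %in% names(close)) {
      l <- close[[c0]]
      if (!length(stacks[[l]])) stop("unbalanced bracket at position ", pos)
      i <- stacks[[l]][length(stacks[[l]])]
      stacks[[l]] <- stacks[[l]][-length(stacks[[l]])]
      pairs <- rbind(pairs, c(i, pos))
    } else if (c0 != ".") stop("unexpected character '", c0, "'")
  }
  if (any(lengths(stacks) > 0L)) stop("unbalanced brackets")
  rna_structure(pairs, length(ch), min_hairpin = min_hairpin)
}

#' Write a structure as a connectivity table (CT) file
#'
#' Standard CT layout: a header line with the length and a title, then one
#' line per nucleotide: index, base, index-1, index+1, pairing partner
#' (0 = unpaired), index.
#'
#' @param x rna_structure
#' @param seq RNA string of matching length
#' @param path output file
#' @param title header title (the energy is prepended when available)
#' @export
write_ct <- function(x, seq, path, title = "structure") {
  bases <- rna_chars(seq)
  if (length(bases) != x$length) stop("sequence length does not match structure")
  en <- attr(x, "energy")
  hdr <- sprintf("%d %s%s", x$length,
                 if (!is.null(en)) sprintf("ENERGY = %.2f  ", en) else "",
                 title)
  p <- partner_vector(x)
  lines <- sprintf("%d %s %d %d %d %d", seq_len(x$length), bases,
                   seq_len(x$length) - 1L,
                   ifelse(seq_len(x$length) == x$length, 0L,
                          seq_len(x$length) + 1L),
                   p, seq_len(x$length))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a CT file
#' @param path CT file
#' @return list with elements `structure` (rna_structure) and `seq` (string)
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  body <- lines[-1][seq_len(n)]
  f <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  idx <- as.integer(f[, 1]); partner <- as.integer(f[, 5])
  keep <- partner > idx
  pairs <- cbind(idx[keep], partner[keep])
  list(structure = rna_structure(pairs, n),
       seq = paste(f[, 2], collapse = ""))
}
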