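#' Apical motif of a hairpin
#'
#' The contiguous window covering a hairpin loop plus the `k` apical base
#' pairs of its stem on both strands, the motif definition used for
#' kissing-loop candidates (a 3-nt loop with k = 2 gives a 7-nt window).
#'
#' @param x [rna_structure()]
#' @param seq RNA string
#' @param hairpin either a hairpin index (in the order returned by
#'   [enumerate_elements()]) or a `list(closing=, positions=)` element
#' @param k number of apical stem pairs to include (default 2)
#' @return list of class `apical_motif`: `window` (start, end), `seq`,
#'   `loop` (positions), `k`, `hairpin_id`
#' @export
apical_motif <- function(x, seq, hairpin = 1L, k = 2L) {
  chars <- rna_chars(seq)
  el <- enumerate_elements(x)
  if (is.numeric(hairpin)) {
    if (hairpin < 1L || hairpin > length(el$hairpins))
      stop("no such hairpin (structure has ", length(el$hairpins), ")")
    id <- as.integer(hairpin)
    hairpin <- el$hairpins[[id]]
  } else id <- NA_integer_
  i <- hairpin$closing[1L]; j <- hairpin$closing[2L]
  partner <- partner_vector(x)
  if (k > 0L) {
    ## the closing pair is apical pair 1; verify k consecutive stacked pairs
    for (t in seq_len(k) - 1L) {
      ii <- i - t; jj <- j + t
      if (ii < 1L || jj > x$length || partner[ii] != jj)
        stop("k = ", k, " exceeds the apical stem depth of this hairpin")
    }
  }
  win <- if (k > 0L) c(i - k + 1L, j + k - 1L)
         else c(min(hairpin$positions), max(hairpin$positions))
  structure(list(window = win,
                 seq = paste(chars[win[1L]:win[2L]], collapse = ""),
                 loop = hairpin$positions,
                 k = as.integer(k),
                 hairpin_id = id),
            class = "apical_motif")
}

#' Best antiparallel duplex between two motif sequences
#'
#' Maximizes the longest contiguous run of complementary pairs over all
#' antiparallel alignments of the two sequences. Watson-Crick pairs always
#' count; G-U wobble only when `allow_wobble`. Ties are broken toward the
#' 5'-most alignment of the first sequence, deterministically.
#'
#' @param a,b RNA strings (nonempty)
#' @param allow_wobble count G-U pairs (default FALSE: "perfect"
#'   complementarity is strict Watson-Crick)
#' @return list: `duplex_length`, `map` (matrix with columns pos_a, pos_b),
#'   `wobble_used`
#' @export
duplex_score <- function(a, b, allow_wobble = FALSE) {
  ca <- rna_chars(a); cb <- rna_chars(b)
  if (!length(ca) || !length(cb)) stop("empty motif sequence")
  best_len <- 0L; best_map <- matrix(integer(0), ncol = 2L)
  ## antiparallel pairing: position i of a pairs position j of b with
  ## i + (la - ?) ... along each constant (i + j) anti-register
  for (s in 2L:(length(ca) + length(cb))) {
    i_lo <- max(1L, s - length(cb))
    i_hi <- min(length(ca), s - 1L)
    if (i_hi < i_lo) next
    idx <- i_lo:i_hi
    ok <- can_pair(ca[idx], cb[s - idx], allow_wobble = allow_wobble)
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      L <- r$lengths[q]
      if (L > best_len) {
        i0 <- idx[starts[q]]
        best_len <- L
        best_map <- cbind(pos_a = i0 + 0:(L - 1L), pos_b = s - (i0 + 0:(L - 1L)))
      }
    }
  }
  wob <- FALSE
  if (best_len > 0L)
    wob <- any(pair_class(ca[best_map[, 1L]], cb[best_map[, 2L]]) == "GU")
  list(duplex_length = best_len, map = best_map, wobble_used = wob)
}

#' Scan structures for kissing-loop candidate motif pairs
#'
#' Extracts apical motifs from every hairpin of one or two structures and
#' scores all motif pairs for antiparallel complementarity. Candidates with
#' duplex length >= `min_len` are reported, ranked by duplex length and
#' then by mean loop reactivity (more reactive loops rank higher, since an
#' unreactive loop is unlikely to be available for intermolecular pairing);
#' reactivity is a ranking feature, never a filter. When the scan is run as
#' a dimer (two copies), a candidate whose motif pair passes in both
#' orientations is flagged as a symmetric kissing complex with two
#' duplexes.
#'
#' @param x [rna_structure()] (molecule A)
#' @param seq RNA string of molecule A
#' @param x2,seq2 optional second molecule; defaults to a second copy of
#'   the first (the homodimer scan)
#' @param k apical stem depth (default 2)
#' @param min_len minimum duplex length to report (default 6)
#' @param allow_wobble count G-U pairs in the duplex
#' @param reactivity,reactivity2 optional reactivity vectors/profiles for
#'   loop-support ranking
#' @param conservation,conservation2 optional conservation tracks (see
#'   [classify_conservation()]); adds the fraction of window positions
#'   conserved in the focal group or better
#' @return data.frame of candidates, one row per unordered motif pair, with
#'   coordinates, sequences, duplex length, support scores and the
#'   `symmetric_complex` flag
#' @export
scan_kissing_pairs <- function(x, seq, x2 = NULL, seq2 = NULL, k = 2L,
                               min_len = 6L, allow_wobble = FALSE,
                               reactivity = NULL, reactivity2 = NULL,
                               conservation = NULL, conservation2 = NULL) {
  two_mols <- !is.null(x2)
  if (!two_mols) { x2 <- x; seq2 <- seq; reactivity2 <- reactivity
                   conservation2 <- conservation }
  motifs_of <- function(st, sq) {
    el <- enumerate_elements(st)
    out <- list()
    for (h in seq_along(el$hairpins)) {
      m <- tryCatch(apical_motif(st, sq, h, k = k), error = function(e) NULL)
      if (!is.null(m)) { m$hairpin_id <- h; out[[length(out) + 1L]] <- m }
    }
    out
  }
  ma <- motifs_of(x, seq); mb <- motifs_of(x2, seq2)
  loop_react <- function(m, reac) {
    if (is.null(reac)) return(NA_real_)
    v <- if (inherits(reac, "reactivity_profile")) reac$values else reac
    mean(v[m$loop], na.rm = TRUE)
  }
  cons_frac <- function(m, track) {
    if (is.null(track)) return(NA_real_)
    cat_ <- track[m$window[1L]:m$window[2L]]
    mean(cat_ %in% c("ALL_CONSERVED", "GROUP_CONSERVED"))
  }
  rows <- list()
  for (ia in seq_along(ma)) {
    jb_range <- if (two_mols) seq_along(mb) else seq(ia, length(mb))
    for (jb in jb_range) {
      A <- ma[[ia]]; B <- mb[[jb]]
      d1 <- duplex_score(A$seq, B$seq, allow_wobble = allow_wobble)
      if (d1$duplex_length < min_len) next
      d2 <- duplex_score(B$seq, A$seq, allow_wobble = allow_wobble)
      rows[[length(rows) + 1L]] <- data.frame(
        hairpin_a = A$hairpin_id, hairpin_b = B$hairpin_id,
        window_a_start = A$window[1L], window_a_end = A$window[2L],
        window_b_start = B$window[1L], window_b_end = B$window[2L],
        seq_a = A$seq, seq_b = B$seq,
        duplex_length = d1$duplex_length,
        wobble_used = d1$wobble_used,
        loop_reactivity_a = loop_react(A, reactivity),
        loop_reactivity_b = loop_react(B, reactivity2),
        conservation_a = cons_frac(A, conservation),
        conservation_b = cons_frac(B, conservation2),
        symmetric_complex = d1$duplex_length >= min_len &&
          d2$duplex_length >= min_len)
    }
  }
  if (!length(rows)) {
    return(data.frame(hairpin_a = integer(0), hairpin_b = integer(0),
                      window_a_start = integer(0), window_a_end = integer(0),
                      window_b_start = integer(0), window_b_end = integer(0),
                      seq_a = character(0), seq_b = character(0),
                      duplex_length = integer(0), wobble_used = logical(0),
                      loop_reactivity_a = numeric(0),
                      loop_reactivity_b = numeric(0),
                      conservation_a = numeric(0), conservation_b = numeric(0),
                      symmetric_complex = logical(0)))
  }
  out <- do.call(rbind, rows)
  mean_loop <- rowMeans(cbind(out$loop_reactivity_a, out$loop_reactivity_b),
                        na.rm = TRUE)
  mean_loop[is.nan(mean_loop)] <- -Inf
  out <- out[order(-out$duplex_length, -mean_loop, out$window_a_start,
                   out$window_b_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a sequence for palindromic (self-reverse-complementary) runs
#'
#' Reports all maximal even-length windows equal to their own reverse
#' complement (strict Watson-Crick), of length at least `min_len`; windows
#' longer than `max_len` are trimmed symmetrically to `max_len` (the core
#' of a palindrome is itself a palindrome).
#'
#' @param seq RNA string
#' @param min_len minimum window length (even, >= 4)
#' @param max_len maximum reported window length
#' @return data.frame: start, end, length, seq
#' @export
palindrome_scan <- function(seq, min_len = 6L, max_len = Inf) {
  if (min_len %% 2L != 0L || min_len < 4L)
    stop("min_len must be an even number >= 4")
  chars <- rna_chars(seq)
  n <- length(chars)
  rows <- list()
  wc <- function(a, b) {
    cls <- pair_class(a, b)
    !is.na(cls) & cls != "GU"
  }
  for (c0 in seq_len(max(n - 1L, 0L))) {
    t <- 0L
    while (c0 - t >= 1L && c0 + 1L + t <= n &&
           wc(chars[c0 - t], chars[c0 + 1L + t])) t <- t + 1L
    len <- 2L * t
    if (len >= min_len) {
      if (len > max_len) {
        trim <- (len - max_len) / 2
        t <- t - trim
        len <- 2L * t
      }
      rows[[length(rows) + 1L]] <-
        data.frame(start = c0 - t + 1L, end = c0 + t,
                   length = len,
                   seq = paste(chars[(c0 - t + 1L):(c0 + t)], collapse = ""))
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), seq = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
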