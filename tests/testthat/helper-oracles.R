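# Independent oracles used across the suite. These deliberately avoid the
# package's internal algorithms: structure enumeration is plain recursion,
# quartiles come from stats::quantile, duplexes from a substring scan.

random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# all legal nested structures (pair matrices) by exhaustive recursion
enum_nested_structures <- function(seq, min_hairpin = 3L) {
  chars <- tipirt::rna_chars(seq)
  n <- length(chars)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_hairpin) return(list(NULL))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(rec(i + 1L, j), identity)        # i unpaired
    if (i + min_hairpin + 1L <= j) {
      for (k in seq(i + min_hairpin + 1L, j)) {
        if (!tipirt::can_pair(chars[i], chars[k])) next
        left <- rec(i + 1L, k - 1L)
        right <- if (k < j) rec(k + 1L, j) else list(NULL)
        for (a in left) for (b in right)
          out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# minimum energy over all nested structures, scored through energy_of
brute_min_energy <- function(seq, model = default_energy_model(),
                             shape = NULL, params = restraint_params()) {
  n <- nchar(seq)
  structs <- enum_nested_structures(seq, model$min_hairpin)
  es <- vapply(structs, function(p) {
    energy_of(rna_structure(p, n, min_hairpin = model$min_hairpin),
              seq, model, shape, params)
  }, numeric(1))
  list(energy = min(es), n_structures = length(structs))
}

# maximal complementary runs by a direct double scan (independent of the
# package's anti-diagonal enumeration)
maximal_runs_oracle <- function(seq, min_hairpin = 3L, min_len = 3L) {
  chars <- tipirt::rna_chars(seq)
  n <- length(chars)
  runs <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || j - i <= min_hairpin) next
    if (!tipirt::can_pair(chars[i], chars[j])) next
    # start of a run only if it cannot be extended outward
    if (i > 1L && j < n && tipirt::can_pair(chars[i - 1L], chars[j + 1L]))
      next
    L <- 0L
    while (i + L < j - L && (j - L) - (i + L) > min_hairpin &&
           tipirt::can_pair(chars[i + L], chars[j - L])) L <- L + 1L
    if (L >= min_len)
      runs[[length(runs) + 1L]] <- c(i = i, j = j, len = L)
  }
  runs
}

# brute-force best antiparallel duplex: longest common substring between a
# and the reverse complement of b equals the longest complementary run
duplex_oracle <- function(a, b) {
  ca <- tipirt::rna_chars(a)
  cb <- tipirt::rna_chars(tipirt::rna_revcomp(b))
  best <- 0L
  for (i in seq_along(ca)) for (j in seq_along(cb)) {
    L <- 0L
    while (i + L <= length(ca) && j + L <= length(cb) &&
           ca[i + L] == cb[j + L]) L <- L + 1L
    best <- max(best, L)
  }
  best
}

# exhaustive palindrome check over all even windows, keeping maximal ones
palindrome_oracle <- function(seq, min_len = 6L) {
  chars <- tipirt::rna_chars(seq)
  n <- length(chars)
  hits <- list()
  for (st in seq_len(n)) for (en in seq_len(n)) {
    len <- en - st + 1L
    if (en <= st || len %% 2L != 0L || len < min_len) next
    w <- paste(chars[st:en], collapse = "")
    if (w != tipirt::rna_revcomp(w)) next
    # keep only maximal windows (not extendable outward on both sides)
    if (st > 1L && en < n) {
      wex <- paste(chars[(st - 1L):(en + 1L)], collapse = "")
      if (wex == tipirt::rna_revcomp(wex)) next
    }
    hits[[length(hits) + 1L]] <- c(start = st, end = en)
  }
  hits
}

# a tiny nested-structure sampler for decomposition tests
random_nested_structure <- function(n, p_pair = 0.6, min_hairpin = 3L) {
  pairs <- NULL
  free <- rep(TRUE, n)
  for (tries in seq_len(3L * n)) {
    i <- sample(n, 1L)
    j <- sample(n, 1L)
    if (i > j) { t <- i; i <- j; j <- t }
    if (j - i <= min_hairpin || !free[i] || !free[j]) next
    ok <- TRUE
    if (!is.null(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        p <- pairs[r, ]
        crossing <- (p[1] < i && i < p[2] && p[2] < j) ||
          (i < p[1] && p[1] < j && j < p[2])
        if (crossing) { ok <- FALSE; break }
      }
    }
    if (ok && runif(1) < p_pair) {
      pairs <- rbind(pairs, c(i, j))
      free[c(i, j)] <- FALSE
    }
  }
  rna_structure(pairs, n, min_hairpin = min_hairpin)
}
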