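.encode_rna <- function(chars) {
  match(chars, c("A", "C", "G", "U", "N")) - 1L
}

.fold_nested_raw <- function(chars, dg, model, params, masked = NULL) {
  if (is.null(masked)) masked <- rep(FALSE, length(chars))
  .fold_nested_cpp(.encode_rna(chars), dg, masked, unclass(model),
                   params$double_charge)
}

#' Minimum-free-energy nested secondary structure
#'
#' Zuker-style dynamic programming over the simplified nearest-neighbor
#' model, optionally restrained by SHAPE reactivities through the linear-log
#' pseudo-energy charged on helix stacks. Returns a nested (non-crossing)
#' structure that minimizes the total energy; ties prefer fewer pairs and
#' are otherwise resolved by a fixed evaluation order, so the result is
#' deterministic.
#'
#' @param seq RNA string (A/C/G/U/N; N never pairs)
#' @param model [default_energy_model()]
#' @param shape optional [reactivity_profile()] or numeric vector (NA =
#'   missing) on the same coordinates as `seq`
#' @param params [restraint_params()]
#' @return [rna_structure()] with an `energy` attribute (kcal/mol)
#' @export
mfe_fold <- function(seq, model = default_energy_model(), shape = NULL,
                     params = restraint_params()) {
  chars <- rna_chars(seq)
  if (length(chars) == 0L) {
    out <- rna_structure(NULL, 0L)
    attr(out, "energy") <- 0
    return(out)
  }
  dg <- .shape_dg_vector(shape, length(chars), params)
  res <- .fold_nested_raw(chars, dg, model, params)
  out <- rna_structure(res$pairs, length(chars),
                       min_hairpin = model$min_hairpin)
  attr(out, "energy") <- res$energy
  out
}

## maximal stacked runs of consecutive pairs; returns list of pair matrices
.stems <- function(pairs) {
  if (nrow(pairs) == 0L) return(list())
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  stems <- list()
  cur <- pairs[1L, , drop = FALSE]
  for (r in seq_len(nrow(pairs))[-1L]) {
    prev <- cur[nrow(cur), ]
    if (pairs[r, 1L] == prev[1L] + 1L && pairs[r, 2L] == prev[2L] - 1L) {
      cur <- rbind(cur, pairs[r, ])
    } else {
      stems[[length(stems) + 1L]] <- cur
      cur <- pairs[r, , drop = FALSE]
    }
  }
  stems[[length(stems) + 1L]] <- cur
  stems
}

## stacks + SHAPE charges of an isolated helix (no loop-closure terms)
.helix_energy <- function(hel, chars, model, dg, double_charge) {
  e <- 0
  if (nrow(hel) >= 2L) {
    for (r in seq_len(nrow(hel) - 1L)) {
      c1 <- pair_class(chars[hel[r, 1L]], chars[hel[r, 2L]])
      c2 <- pair_class(chars[hel[r + 1L, 1L]], chars[hel[r + 1L, 2L]])
      e <- e + model$stack[c1, c2] + dg[hel[r, 1L]] + dg[hel[r, 2L]]
      if (double_charge) e <- e + dg[hel[r + 1L, 1L]] + dg[hel[r + 1L, 2L]]
    }
  }
  e
}

## score a nested pair set: stacks, loop penalties, multibranch terms,
## SHAPE charges; exterior bases are free
.score_nested <- function(pairs, chars, model, dg, double_charge) {
  if (nrow(pairs) == 0L) return(0)
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  np <- nrow(pairs)
  parent <- rep(0L, np)
  open <- integer(0)                    # stack of open pair row indices
  openj <- integer(0)
  for (r in seq_len(np)) {
    while (length(open) && openj[length(open)] < pairs[r, 1L]) {
      open <- open[-length(open)]; openj <- openj[-length(openj)]
    }
    if (length(open)) parent[r] <- open[length(open)]
    open <- c(open, r); openj <- c(openj, pairs[r, 2L])
  }
  children <- split(seq_len(np), factor(parent, levels = 0:np))
  e <- 0
  for (r in seq_len(np)) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    kids <- children[[as.character(r)]]
    if (length(kids) == 0L) {
      e <- e + hairpin_penalty(j - i - 1L, model)
    } else if (length(kids) == 1L) {
      k <- pairs[kids, 1L]; l <- pairs[kids, 2L]
      l1 <- k - i - 1L; l2 <- j - l - 1L
      if (l1 == 0L && l2 == 0L) {
        c1 <- pair_class(chars[i], chars[j])
        c2 <- pair_class(chars[k], chars[l])
        e <- e + model$stack[c1, c2] + dg[i] + dg[j]
        if (double_charge) e <- e + dg[k] + dg[l]
      } else if (l1 == 0L || l2 == 0L) {
        e <- e + bulge_penalty(l1 + l2, model)
      } else {
        e <- e + internal_penalty(l1 + l2, model)
      }
    } else {
      spans <- sum(pairs[kids, 2L] - pairs[kids, 1L] + 1L)
      unpaired <- (j - i - 1L) - spans
      e <- e + model$mb_offset + model$mb_branch * (length(kids) + 1L) +
        model$mb_unpaired * unpaired
    }
  }
  e
}

#' Free energy of an explicit structure
#'
#' Scores a structure under the same conventions as the folding DP: stack
#' energies, logarithmic loop penalties, affine multibranch terms and SHAPE
#' pseudo-energies charged per stack. A pseudoknotted structure is scored by
#' peeling crossing helices: every way of removing one stem per crossing
#' component that leaves the remainder non-crossing is evaluated (the peeled
#' helix contributes its stacks plus the pseudoknot initiation penalty; its
#' positions count as unpaired in the remaining loops) and the minimum is
#' returned.
#'
#' @param x [rna_structure()]
#' @param seq RNA string
#' @param model [default_energy_model()]
#' @param shape optional reactivities, as in [mfe_fold()]
#' @param params [restraint_params()]
#' @return energy in kcal/mol
#' @export
energy_of <- function(x, seq, model = default_energy_model(), shape = NULL,
                      params = restraint_params()) {
  chars <- rna_chars(seq)
  if (x$length != length(chars)) stop("structure/sequence length mismatch")
  pairs <- x$pairs
  if (nrow(pairs) == 0L) return(0)
  ok <- can_pair(chars[pairs[, 1L]], chars[pairs[, 2L]])
  if (!all(ok)) stop("illegal base pair at rows: ",
                     paste(which(!ok), collapse = ", "))
  if (any(pairs[, 2L] - pairs[, 1L] <= model$min_hairpin))
    stop("pair violates the model's minimum hairpin length")
  dg <- .shape_dg_vector(shape, length(chars), params)
  dc <- params$double_charge

  if (!has_crossing(x)) return(.score_nested(pairs, chars, model, dg, dc))

  stems <- .stems(pairs)
  ns <- length(stems)
  cross <- matrix(FALSE, ns, ns)
  for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
    if (.pairs_cross(stems[[a]][1L, ], stems[[b]][1L, ]))
      cross[a, b] <- cross[b, a] <- TRUE
  }
  involved <- which(rowSums(cross) > 0)
  ## connected components of the crossing graph
  comp <- rep(NA_integer_, ns); cid <- 0L
  for (s in involved) if (is.na(comp[s])) {
    cid <- cid + 1L; queue <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, which(cross[u, ] & is.na(comp)))
    }
  }
  ## per component: stems whose removal de-crosses that component
  choices <- lapply(seq_len(cid), function(cc) {
    members <- which(comp == cc)
    keep <- members[vapply(members, function(s) {
      rest <- setdiff(members, s)
      !any(cross[rest, rest])
    }, logical(1))]
    if (!length(keep)) stop("unsupported pseudoknot topology: a crossing ",
                            "component cannot be resolved by one helix")
    keep
  })
  combos <- expand.grid(choices)
  if (nrow(combos) > 64L) stop("unsupported pseudoknot topology: too many ",
                               "crossing helices")
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    peeled <- as.integer(unlist(combos[r, ]))
    rest <- do.call(rbind, stems[setdiff(seq_len(ns), peeled)])
    if (is.null(rest)) rest <- matrix(integer(0), ncol = 2L)
    rest_struct <- rna_structure(rest, x$length, min_hairpin = model$min_hairpin)
    if (has_crossing(rest_struct)) next
    e <- .score_nested(rest_struct$pairs, chars, model, dg, dc) +
      sum(vapply(stems[peeled], .helix_energy, numeric(1),
                 chars = chars, model = model, dg = dg, double_charge = dc)) +
      model$pk_init_penalty * length(peeled)
    best <- min(best, e)
  }
  if (!is.finite(best)) stop("unsupported pseudoknot topology")
  best
}

#' Enumerate candidate helices (maximal complementary runs)
#'
#' All maximal antiparallel runs of stackable Watson-Crick/GU pairs of at
#' least `min_len` base pairs, respecting the minimum hairpin span. Each
#' helix is scored in isolation (stacks plus SHAPE charges) and the list is
#' returned ranked best-first.
#'
#' @param seq RNA string
#' @param model energy model
#' @param shape,params optional SHAPE restraint inputs
#' @param min_len minimum helix length in base pairs (default 3)
#' @return data.frame: `i`, `j` (outermost pair), `length`, `energy`
#' @export
helix_candidates <- function(seq, model = default_energy_model(),
                             shape = NULL, params = restraint_params(),
                             min_len = 3L) {
  chars <- rna_chars(seq)
  n <- length(chars)
  dg <- .shape_dg_vector(shape, n, params)
  minh <- model$min_hairpin
  rows <- list()
  if (n >= 2L * min_len + minh) {
    for (s in seq(3L, 2L * n - 1L)) {      # anti-diagonal i + j = s
      ## feasible 5' indices: j = s - i in range and span j - i > minh
      i_lo <- max(1L, s - n)
      i_hi <- (s - minh - 1L) %/% 2L
      if (i_hi < i_lo) next
      idx <- i_lo:i_hi
      ok <- can_pair(chars[idx], chars[s - idx])
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (q in which(r$values & r$lengths >= min_len)) {
        i0 <- idx[starts[q]]
        L <- r$lengths[q]
        hel <- cbind(i0 + 0:(L - 1L), (s - i0) - 0:(L - 1L))
        rows[[length(rows) + 1L]] <-
          data.frame(i = i0, j = s - i0, length = L,
                     energy = .helix_energy(hel, chars, model, dg,
                                            params$double_charge))
      }
    }
  }
  if (!length(rows))
    return(data.frame(i = integer(0), j = integer(0), length = integer(0),
                      energy = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$energy, out$i, out$j), , drop = FALSE]
}

#' SHAPE-restrained folding with H-type pseudoknot discovery
#'
#' A forced-helix heuristic in the spirit of pseudoknot discovery by helix
#' candidacy: (1) the nested MFE structure is computed; (2) candidate
#' helices (maximal complementary runs of >= 3 bp) are ranked by isolated
#' helix energy; (3) each of the top `max_candidates` helices is forced in
#' turn, its positions are masked, and the rest of the sequence is refolded
#' by the nested DP (pairs of the refold may cross the forced helix, giving
#' the H-type topology); the forced helix contributes its stack energies,
#' SHAPE charges and the pseudoknot initiation penalty; (4) the lowest-total
#' structure over all runs, the plain nested fold included, is returned. The
#' result is therefore never worse than the nested MFE.
#'
#' @inheritParams mfe_fold
#' @param max_candidates number of top-ranked helices to force (default 20)
#' @return [rna_structure()] with attributes `energy` and, when a crossing
#'   helix was kept, `pk_helix` (its pair matrix)
#' @export
shapeknots_fold <- function(seq, shape = NULL, model = default_energy_model(),
                            params = restraint_params(), max_candidates = 20L) {
  chars <- rna_chars(seq)
  nested <- mfe_fold(seq, model, shape, params)
  if (length(chars) == 0L) return(nested)
  dg <- .shape_dg_vector(shape, length(chars), params)

  best_e <- attr(nested, "energy")
  best_n <- n_pairs(nested)
  best_pairs <- nested$pairs
  best_helix <- NULL

  cands <- helix_candidates(seq, model, shape, params)
  cands <- head(cands, max_candidates)
  for (r in seq_len(nrow(cands))) {
    L <- cands$length[r]
    hel <- cbind(cands$i[r] + 0:(L - 1L), cands$j[r] - 0:(L - 1L))
    masked <- rep(FALSE, length(chars))
    masked[c(hel)] <- TRUE
    rest <- .fold_nested_raw(chars, dg, model, params, masked)
    tot <- rest$energy + cands$energy[r] + model$pk_init_penalty
    ntot <- nrow(rest$pairs) + L
    if (tot < best_e - 1e-9 ||
        (tot <= best_e + 1e-9 && ntot < best_n)) {
      ## a refolded pair crosses the helix iff exactly one endpoint lies
      ## strictly between the helix's two strands
      inside <- function(x) x > hel[L, 1L] & x < hel[L, 2L]
      cross_any <- nrow(rest$pairs) > 0L &&
        any(xor(inside(rest$pairs[, 1L]), inside(rest$pairs[, 2L])))
      best_e <- tot
      best_n <- ntot
      best_pairs <- rbind(rest$pairs, hel)
      best_helix <- if (cross_any) hel else NULL
    }
  }
  out <- rna_structure(best_pairs, length(chars),
                       min_hairpin = model$min_hairpin)
  attr(out, "energy") <- best_e
  if (!is.null(best_helix)) {
    colnames(best_helix) <- c("i", "j")
    attr(out, "pk_helix") <- best_helix
  }
  out
}
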