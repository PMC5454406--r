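#' Default layout for the synthetic structured sequence
#'
#' Mirrors the topology of the Ty1 leader model at reduced scale: an S1
#' stem whose 5' strand opens the molecule, a hairpin (the SL1a analog,
#' with a 3-nt loop) inside loop L1, the S2 5' strand, a 1-nt interhelical
#' loop L2, the S1 3' strand, a second hairpin (the SL3a analog) filling
#' loop L3 whose loop carries the reverse complement of the first
#' hairpin's 7-nt apical motif, and finally the S2 3' strand. S1 and S2
#' cross, giving the planted H-type pseudoknot; the two apical motifs are
#' fully complementary, giving the planted kissing pair.
#'
#' @param s1_len,s2_len pseudoknot stem lengths in bp (defaults 7 and 8,
#'   the dimensions of the study system)
#' @param l2_len interhelical loop length (default 1)
#' @param stem_a,loop_a first (SL1a-like) hairpin stem/loop sizes
#' @param stem_b second (SL3a-like) hairpin stem size; its loop length is
#'   `loop_a + 2 * motif_k` so the full apical window of hairpin A fits
#' @param motif_k apical stem pairs included in the motif window
#' @param spacer unpaired spacer length between consecutive elements
#' @param tail unpaired 3' tail length
#' @return named list (a truth spec) for [gen_structured_sequence()]
#' @export
default_truth_spec <- function(s1_len = 7L, s2_len = 8L, l2_len = 1L,
                               stem_a = 8L, loop_a = 3L, stem_b = 8L,
                               motif_k = 2L, spacer = 5L, tail = 6L) {
  list(s1_len = as.integer(s1_len), s2_len = as.integer(s2_len),
       l2_len = as.integer(l2_len), stem_a = as.integer(stem_a),
       loop_a = as.integer(loop_a), stem_b = as.integer(stem_b),
       motif_k = as.integer(motif_k), spacer = as.integer(spacer),
       tail = as.integer(tail))
}

## random Watson-Crick pair columns, GC-biased for stable planted stems
.random_stem <- function(n) {
  types <- sample(c("GC", "CG", "AU", "UA"), n, replace = TRUE,
                  prob = c(0.35, 0.35, 0.15, 0.15))
  list(p5 = substr(types, 1L, 1L), p3 = substr(types, 2L, 2L))
}

## unpaired filler biased to A/C: A and C cannot pair with each other, so
## unpaired regions generate almost no decoy helices among themselves
.random_fill <- function(n) sample(c("A", "C"), n, replace = TRUE,
                                   prob = c(0.7, 0.3))

#' Generate a structured sequence with known ground truth
#'
#' Realizes the element layout of a truth spec as an RNA sequence with a
#' fully determined planted structure: complementary strands for every
#' stem, an H-type pseudoknot (S1/S2 crossing), and a complementary apical
#' motif pair mirroring the SL1a/SL3a arrangement. Deterministic under the
#' seed.
#'
#' @param spec [default_truth_spec()] (or a modified copy)
#' @param seed RNG seed
#' @return list of class `synthetic_truth`: `seq`, `structure`
#'   ([rna_structure()] of all planted pairs), `pk_pairs` (S1 and S2 pair
#'   matrix), `motif_a`, `motif_b` (window coordinate pairs), `elements`
#'   (coordinate table), `spec`, `seed`
#' @export
gen_structured_sequence <- function(spec = default_truth_spec(), seed = 1L) {
  with(spec, {
    if (loop_a < 3L || stem_a < motif_k || s1_len < 3L || s2_len < 3L ||
        l2_len < 0L || spacer < 1L || tail < 0L)
      stop("infeasible truth spec")
  })
  loop_b <- spec$loop_a + 2L * spec$motif_k
  set.seed(seed)
  s1 <- .random_stem(spec$s1_len)
  s2 <- .random_stem(spec$s2_len)
  ha <- .random_stem(spec$stem_a)
  hb <- .random_stem(spec$stem_b)
  loopA <- .random_fill(spec$loop_a)

  ## element layout, 5' to 3'
  lens <- c(S1_5 = spec$s1_len, sp1 = spec$spacer,
            hairpinA = 2L * spec$stem_a + spec$loop_a, sp2 = spec$spacer,
            S2_5 = spec$s2_len, L2 = max(spec$l2_len, 0L),
            S1_3 = spec$s1_len, sp3 = spec$spacer,
            hairpinB = 2L * spec$stem_b + loop_b, sp4 = spec$spacer,
            S2_3 = spec$s2_len, tail = spec$tail)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  n <- ends[["tail"]]
  chars <- rep(NA_character_, n)
  at <- function(el) if (lens[[el]] > 0L) starts[[el]]:ends[[el]] else integer(0)

  chars[at("S1_5")] <- s1$p5
  chars[at("S1_3")] <- rev(s1$p3)
  chars[at("S2_5")] <- s2$p5
  chars[at("S2_3")] <- rev(s2$p3)
  ia <- at("hairpinA")
  chars[ia[seq_len(spec$stem_a)]] <- ha$p5
  chars[ia[spec$stem_a + seq_len(spec$loop_a)]] <- loopA
  chars[ia[spec$stem_a + spec$loop_a + seq_len(spec$stem_a)]] <- rev(ha$p3)
  ## apical motif of hairpin A: k apical pairs + loop + k apical pairs
  motif_a <- c(ia[spec$stem_a - spec$motif_k + 1L],
               ia[spec$stem_a + spec$loop_a + spec$motif_k])
  ib <- at("hairpinB")
  chars[ib[seq_len(spec$stem_b)]] <- hb$p5
  chars[ib[spec$stem_b + loop_b + seq_len(spec$stem_b)]] <- rev(hb$p3)
  for (el in c("sp1", "sp2", "sp3", "sp4", "L2", "tail"))
    chars[at(el)] <- .random_fill(lens[[el]])
  ## hairpin B loop = reverse complement of motif A's window
  win_a <- paste(chars[motif_a[1L]:motif_a[2L]], collapse = "")
  loopB <- rna_chars(rna_revcomp(win_a))
  chars[ib[spec$stem_b + seq_len(loop_b)]] <- loopB
  motif_b <- c(ib[spec$stem_b + 1L], ib[spec$stem_b + loop_b])

  ## planted pairs
  mk_stem_pairs <- function(pos5, pos3) cbind(pos5, rev(pos3))
  s1p <- mk_stem_pairs(at("S1_5"), at("S1_3"))
  s2p <- mk_stem_pairs(at("S2_5"), at("S2_3"))
  hap <- mk_stem_pairs(ia[seq_len(spec$stem_a)],
                       ia[spec$stem_a + spec$loop_a + seq_len(spec$stem_a)])
  hbp <- mk_stem_pairs(ib[seq_len(spec$stem_b)],
                       ib[spec$stem_b + loop_b + seq_len(spec$stem_b)])
  pairs <- rbind(s1p, s2p, hap, hbp)
  truth <- list(
    seq = paste(chars, collapse = ""),
    structure = rna_structure(pairs, n),
    pk_pairs = rbind(s1p, s2p),
    motif_a = motif_a, motif_b = motif_b,
    elements = data.frame(name = names(lens), start = unname(starts),
                          end = unname(ends)),
    spec = spec, seed = seed)
  class(truth) <- "synthetic_truth"
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", nchar(x$seq), "nt,", n_pairs(x$structure),
      "planted pairs (", nrow(x$pk_pairs), "in the pseudoknot ), seed",
      x$seed, "\n")
  invisible(x)
}

#' Simulate replicate SHAPE intensity tables from a planted structure
#'
#' Paired positions draw low reactivities and unpaired positions high ones
#' (gamma-distributed around the respective means), emulating the inverse
#' relation between SHAPE reactivity and base-pairing. Each replicate
#' multiplies the per-position reactivity by lognormal noise (unit mean)
#' and embeds it in treated/control intensity pairs that round-trip through
#' the processing chain.
#'
#' @param truth [gen_structured_sequence()] output
#' @param paired_mean,unpaired_mean mean reactivity of paired/unpaired
#'   positions (defaults 0.05 and 0.9)
#' @param noise_sd lognormal sdlog of the replicate noise (default 0.2)
#' @param n_replicates number of replicate tables (default 3)
#' @param seed RNG seed
#' @param signal_scale intensity units per reactivity unit
#' @param control_mean mean background intensity of the control channel
#' @return list: `replicates` (list of data.frames position/treated/
#'   control), `true_reactivity` (per-position base reactivity),
#'   `unpaired` (logical truth vector)
#' @export
simulate_shape <- function(truth, paired_mean = 0.05, unpaired_mean = 0.9,
                           noise_sd = 0.2, n_replicates = 3L, seed = 1L,
                           signal_scale = 200, control_mean = 100) {
  stopifnot(paired_mean > 0, unpaired_mean > 0, noise_sd >= 0)
  set.seed(seed)
  n <- nchar(truth$seq)
  unpaired <- partner_vector(truth$structure) == 0L
  mu <- ifelse(unpaired, unpaired_mean, paired_mean)
  r0 <- rgamma(n, shape = 4, rate = 4 / mu)
  reps <- lapply(seq_len(n_replicates), function(r) {
    noise <- rlnorm(n, meanlog = -noise_sd^2 / 2, sdlog = noise_sd)
    control <- runif(n, 0.5, 1.5) * control_mean
    data.frame(position = seq_len(n),
               treated = control + r0 * noise * signal_scale,
               control = control)
  })
  list(replicates = reps, true_reactivity = r0, unpaired = unpaired)
}

#' Generate a grouped alignment with planted conservation categories
#'
#' Every position's category is realized exactly: ALL_CONSERVED positions
#' are untouched, GROUP_CONSERVED positions receive substitutions only in
#' non-focal sequences (at least one), and VARIABLE positions receive at
#' least one substitution within the focal subgroup. No gaps are
#' introduced, so the aligned length equals the reference length.
#'
#' @param reference reference RNA string, or NULL to draw one of length
#'   `ref_length`
#' @param ref_length used when `reference` is NULL
#' @param group_sizes named integer vector of sequences per group; the
#'   default reproduces the study's manifest (31 + 15 + 35 + 17 + 4)
#' @param focal_groups group labels forming the focal subgroup (default
#'   the two S. cerevisiae Ty1 groups, 31 + 35 = 66 sequences)
#' @param plan optional character vector of per-position categories; drawn
#'   from `category_probs` when NULL
#' @param category_probs sampling weights for the three categories
#' @param max_extra_subs at most this many additional substituted
#'   sequences beyond the one required (per position)
#' @param seed RNG seed
#' @return list: `alignment` ([grouped_alignment()]), `truth_track`
#'   (factor of planted categories), `manifest` (data.frame id/group)
#' @export
gen_alignment <- function(reference = NULL, ref_length = 120L,
                          group_sizes = c(Ty1_S288C = 31L, Ty2_S288C = 15L,
                                          Ty1_other = 35L, Ty2_other = 17L,
                                          Ty_spp = 4L),
                          focal_groups = c("Ty1_S288C", "Ty1_other"),
                          plan = NULL,
                          category_probs = c(ALL_CONSERVED = 0.5,
                                             GROUP_CONSERVED = 0.3,
                                             VARIABLE = 0.2),
                          max_extra_subs = 2L, seed = 1L) {
  set.seed(seed)
  if (is.null(reference))
    reference <- paste(sample(.rna_alphabet, ref_length, replace = TRUE),
                       collapse = "")
  ref <- rna_chars(reference)
  L <- length(ref)
  if (is.null(plan))
    plan <- sample(names(category_probs), L, replace = TRUE,
                   prob = category_probs)
  stopifnot(length(plan) == L, all(plan %in% .conservation_levels))
  groups <- rep(names(group_sizes), group_sizes)
  ids <- paste0(groups, "_", unlist(lapply(group_sizes, seq_len)))
  focal <- groups %in% focal_groups
  if (sum(focal) < 2L || sum(!focal) < 1L)
    stop("need at least 2 focal and 1 non-focal sequence")
  mat <- matrix(rep(ref, each = length(ids)), nrow = length(ids),
                dimnames = list(ids, NULL))
  ## the reference row (first focal sequence) is never mutated, so the
  ## reference sequence is recoverable from the alignment verbatim
  ref_row <- which(focal)[1L]
  substitute_rows <- function(rows, col) {
    alt <- setdiff(.rna_alphabet, ref[col])
    mat[rows, col] <<- sample(alt, length(rows), replace = TRUE)
  }
  for (col in seq_len(L)) {
    if (plan[col] == "ALL_CONSERVED") next
    if (plan[col] == "GROUP_CONSERVED") {
      pool <- which(!focal)
    } else {
      pool <- setdiff(which(focal), ref_row)
    }
    nsub <- 1L + sample(0:max_extra_subs, 1L)
    rows <- sample(pool, min(nsub, length(pool)))
    substitute_rows(rows, col)
  }
  seqs <- setNames(apply(mat, 1L, paste, collapse = ""), ids)
  aln <- grouped_alignment(seqs, setNames(groups, ids), ids[ref_row])
  track <- factor(plan, levels = .conservation_levels)
  class(track) <- c("conservation_track", class(track))
  list(alignment = aln, truth_track = track,
       manifest = data.frame(id = ids, group = groups))
}

#' Simulate colony counts at a known retrotransposition frequency
#'
#' CFU counts are Poisson around `cfu_mean`; His+ counts are Poisson with
#' mean `true_freq` times the culture's CFU, the standard counting model
#' for plating assays.
#'
#' @param true_freq true retrotransposition frequency
#' @param cfu_mean expected CFU per culture (default 1e7)
#' @param n number of replicate cultures (default 7, the study design)
#' @param seed RNG seed
#' @param strain label for the output table
#' @return data.frame: strain, replicate, his_positive, cfu, his_fraction,
#'   cfu_fraction
#' @export
gen_colony_counts <- function(true_freq, cfu_mean = 1e7, n = 7L, seed = 1L,
                              strain = "synthetic") {
  stopifnot(true_freq >= 0, cfu_mean > 0, n >= 1L)
  set.seed(seed)
  cfu <- rpois(n, cfu_mean)
  his <- rpois(n, true_freq * cfu)
  data.frame(strain = strain, replicate = seq_len(n),
             his_positive = his, cfu = cfu,
             his_fraction = 1, cfu_fraction = 1)
}
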