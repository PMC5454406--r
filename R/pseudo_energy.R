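#' SHAPE restraint parameters
#'
#' Parameters of the linear-log pseudo-free-energy restraint
#' `dG(i) = m * ln(S(i) + 1) + b` that converts a normalized SHAPE
#' reactivity `S` into a per-nucleotide energy term charged on helix
#' stacks. The defaults (m = 1.8, b = -0.6 kcal/mol) are the widely used
#' values from the restrained-folding literature; both are configurable
#' because published analyses vary them.
#'
#' `double_charge` selects the stacking convention: when TRUE (default)
#' each stack charges all four participating nucleotides, so a nucleotide
#' interior to a helix (flanked by stacks on both sides) is charged twice,
#' while terminal helix nucleotides are charged once. When FALSE only the
#' outer (closing) pair of each stack is charged.
#'
#' @param m slope, kcal/mol per ln-unit (must be >= 0)
#' @param b intercept, kcal/mol
#' @param double_charge charge helix-interior nucleotides twice (see above)
#' @return list of class `restraint_params`
#' @export
restraint_params <- function(m = 1.8, b = -0.6, double_charge = TRUE) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 0,
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.logical(double_charge), length(double_charge) == 1L)
  structure(list(m = m, b = b, double_charge = double_charge),
            class = "restraint_params")
}

#' Per-nucleotide SHAPE pseudo-free energy
#'
#' Missing (NA) and negative reactivities contribute 0: a negative value
#' carries no structural information and a missing one none at all, so
#' neither should bias the fold.
#'
#' @param S numeric vector of normalized reactivities (NA = missing)
#' @param params [restraint_params()]
#' @return numeric vector of energies (kcal/mol), 0 where S is absent
#' @export
shape_pseudo_energy <- function(S, params = restraint_params()) {
  out <- numeric(length(S))
  ok <- !is.na(S) & S >= 0
  out[ok] <- params$m * log(S[ok] + 1) + params$b
  out
}

## per-position energy vector over a sequence of length n, from either a
## reactivity_profile or a plain numeric vector (NA = missing)
.shape_dg_vector <- function(shape, n, params) {
  if (is.null(shape)) return(numeric(n))
  v <- if (inherits(shape, "reactivity_profile")) shape$values else as.numeric(shape)
  if (length(v) != n)
    stop("reactivity vector length (", length(v),
         ") does not match sequence length (", n, ")")
  shape_pseudo_energy(v, params)
}
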