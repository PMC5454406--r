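#' Simplified nearest-neighbor energy model
#'
#' A compact, editable parameterization of the nearest-neighbor free-energy
#' rules: stacking energies resolved by the classes of the two stacked pairs
#' (GC, AU, GU), logarithmic loop-length penalties, an affine multibranch
#' cost and a pseudoknot initiation penalty. The defaults are deliberately
#' coarse: the pipeline's claims are about structural topology under SHAPE
#' restraints, not about quantitative thermodynamics, so a transparent table
#' that is easy to audit and to override is preferred over a full Turner
#' parameter set.
#'
#' `loop_log_coef` is 1.75 * R * T at 310 K (about 1.08 kcal/mol), the usual
#' Jacobson-Stockmayer extrapolation slope.
#'
#' @param ... named overrides of any default component
#' @return list of class `energy_model`
#' @export
default_energy_model <- function(...) {
  stack <- matrix(c(-3.3, -2.2, -1.5,
                    -2.2, -1.1, -0.8,
                    -1.5, -0.8, -0.5),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(c("GC", "AU", "GU"), c("GC", "AU", "GU")))
  model <- list(
    stack = stack,
    hairpin_base = 5.0,     # kcal/mol at the 3-nt reference length
    bulge_base = 3.8,       # kcal/mol at length 1
    internal_base = 4.1,    # kcal/mol at total size 2
    loop_log_coef = 1.08,   # kcal/mol per ln-unit of loop length
    mb_offset = 3.4,        # multibranch closing offset
    mb_branch = 0.4,        # per branch, the closing pair included
    mb_unpaired = 0.1,      # per unpaired nucleotide in a multibranch loop
    pk_init_penalty = 3.5,  # per crossing helix
    min_hairpin = 3L,
    max_internal = 30L      # largest bulge/internal loop the DP considers
  )
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(model))
    if (length(unknown)) stop("unknown model components: ",
                              paste(unknown, collapse = ", "))
    model <- modifyList(model, ov)
  }
  stopifnot(model$min_hairpin >= 3L, all(is.finite(unlist(model))))
  class(model) <- "energy_model"
  model
}

#' Hairpin loop penalty
#' @param len number of unpaired loop nucleotides (>= min_hairpin)
#' @param model energy_model
#' @return kcal/mol
#' @export
hairpin_penalty <- function(len, model) {
  stopifnot(all(len >= model$min_hairpin))
  model$hairpin_base + model$loop_log_coef * log(len / 3)
}

#' Bulge loop penalty
#' @param len bulged nucleotides on the single strand (>= 1)
#' @param model energy_model
#' @export
bulge_penalty <- function(len, model) {
  stopifnot(all(len >= 1))
  model$bulge_base + model$loop_log_coef * log(len)
}

#' Internal loop penalty
#' @param size total unpaired nucleotides on both strands (>= 2)
#' @param model energy_model
#' @export
internal_penalty <- function(size, model) {
  stopifnot(all(size >= 2))
  model$internal_base + model$loop_log_coef * log(size / 2)
}

#' Stacking energy between two adjacent base pairs
#' @param cls1,cls2 pair classes ("GC", "AU", "GU") of the outer and inner pair
#' @param model energy_model
#' @export
stack_energy <- function(cls1, cls2, model) model$stack[cbind(cls1, cls2)]

#' Write an energy model to an editable JSON file
#' @param model energy_model
#' @param path output path
#' @export
write_energy_model <- function(model, path) {
  x <- unclass(model)
  x$stack <- list(labels = rownames(model$stack),
                  values = unname(apply(model$stack, 1, as.list)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an energy model from JSON
#' @param path JSON file written by [write_energy_model()] (or hand-edited)
#' @export
read_energy_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lab <- x$stack$labels
  st <- matrix(as.numeric(unlist(x$stack$values)), nrow = length(lab),
               byrow = TRUE, dimnames = list(lab, lab))
  x$stack <- st
  x$min_hairpin <- as.integer(x$min_hairpin)
  x$max_internal <- as.integer(x$max_internal)
  do.call(default_energy_model, x)
}
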