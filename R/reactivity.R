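#' Raw reactivity from treated/control intensities
#'
#' Elementwise difference of integrated peak intensities from the
#' reagent-treated and control channels. Negative differences are retained;
#' they are only neutralized downstream (a negative reactivity contributes
#' no restraint energy).
#'
#' @param treated,control nonnegative intensity vectors of equal length
#' @return numeric vector of raw reactivities
#' @export
compute_raw_reactivity <- function(treated, control) {
  if (length(treated) != length(control))
    stop("treated and control intensity vectors differ in length")
  if (any(treated < 0, na.rm = TRUE) || any(control < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  treated - control
}

## type-7 quantile by explicit linear interpolation of order statistics;
## written out so the convention is pinned in code, not in a default argument
.quantile_type7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

#' Boxplot-based top-10% normalization of a reactivity profile
#'
#' High outliers are flagged by the standard upper boxplot fence
#' (values above Q3 + 1.5 IQR, quartiles by type-7 interpolation); the scale
#' factor is the mean of the top `ceil(0.10 * n)` non-outlier values, where
#' `n` counts the finite non-outlier values; every value, outliers included,
#' is divided by that factor. After normalization the mean of the selected
#' top-10% set is exactly 1.
#'
#' @param raw numeric vector of raw reactivities (NA allowed, >= 10 finite
#'   values required)
#' @return list with `values` (normalized vector, same length/NA pattern as
#'   input), `scale_factor`, `outliers` (indices above the fence) and
#'   `top_set` (indices averaged into the scale factor)
#' @export
boxplot_normalize <- function(raw) {
  fin <- which(is.finite(raw))
  if (length(fin) < 10L)
    stop("need at least 10 finite reactivities to normalize")
  v <- raw[fin]
  q1 <- .quantile_type7(v, 0.25)
  q3 <- .quantile_type7(v, 0.75)
  fence <- q3 + 1.5 * (q3 - q1)
  out_idx <- fin[v > fence]
  keep <- setdiff(fin, out_idx)
  n_top <- ceiling(0.10 * length(keep))
  top_idx <- keep[order(raw[keep], decreasing = TRUE)[seq_len(n_top)]]
  scale_factor <- mean(raw[top_idx])
  if (!is.finite(scale_factor) || scale_factor <= 0)
    stop("degenerate reactivity profile: nonpositive normalization scale")
  list(values = raw / scale_factor,
       scale_factor = scale_factor,
       outliers = out_idx,
       top_set = top_idx)
}

#' Replicate standard-deviation filter
#'
#' Positions whose sample standard deviation (n-1 denominator) across
#' normalized replicate profiles exceeds the threshold are flagged for
#' exclusion.
#'
#' @param profiles numeric matrix (positions x replicates) or list of
#'   equal-length numeric vectors
#' @param threshold SD cutoff; the study's processing used 0.7
#' @return logical vector, TRUE where the position is excluded
#' @export
filter_by_sd <- function(profiles, threshold = 0.7) {
  if (is.list(profiles)) {
    if (length(unique(lengths(profiles))) != 1L)
      stop("replicate profiles differ in length")
    profiles <- do.call(cbind, profiles)
  }
  stopifnot(is.matrix(profiles), threshold > 0)
  if (ncol(profiles) < 2L) {
    warning("single replicate: SD filter is a no-op")
    return(rep(FALSE, nrow(profiles)))
  }
  sds <- apply(profiles, 1L, sd, na.rm = TRUE)
  !is.na(sds) & sds > threshold
}

#' Reactivity profile on reference coordinates
#'
#' @param values numeric vector over reference positions 1..L, NA = missing
#' @param n_contrib integer vector: replicates/transcripts contributing per
#'   position
#' @param scale_factors numeric vector of normalization divisors used
#' @param excluded integer vector of positions removed by QC
#' @return object of class `reactivity_profile`
#' @export
reactivity_profile <- function(values, n_contrib = NULL, scale_factors = numeric(0),
                               excluded = integer(0)) {
  if (is.null(n_contrib)) n_contrib <- as.integer(!is.na(values))
  stopifnot(length(n_contrib) == length(values), all(scale_factors > 0))
  structure(list(values = as.numeric(values),
                 n_contrib = as.integer(n_contrib),
                 scale_factors = scale_factors,
                 excluded = as.integer(excluded)),
            class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat("Reactivity profile:", length(x$values), "positions,",
      sum(is.na(x$values)), "missing\n")
  invisible(x)
}

#' Merge per-transcript profiles into a composite reference profile
#'
#' Each transcript profile is placed on the reference by its offset (the
#' reference position of transcript nucleotide 1); where transcripts
#' overlap, available values are averaged without weighting. Reference
#' positions covered by no transcript are missing.
#'
#' @param profiles list of numeric vectors (NA = missing/excluded)
#' @param offsets integer vector, same length as `profiles`
#' @param ref_length reference length; default spans the right-most transcript
#' @param scale_factors optional normalization divisors to record
#' @return [reactivity_profile()] over 1..ref_length
#' @export
composite_merge <- function(profiles, offsets, ref_length = NULL,
                            scale_factors = numeric(0)) {
  stopifnot(is.list(profiles), length(profiles) == length(offsets),
            all(offsets >= 1L))
  ends <- offsets + lengths(profiles) - 1L
  if (is.null(ref_length)) ref_length <- max(ends, 0L)
  if (any(ends > ref_length)) stop("a transcript extends beyond the reference")
  total <- numeric(ref_length)
  count <- integer(ref_length)
  for (t in seq_along(profiles)) {
    pos <- offsets[t] + seq_along(profiles[[t]]) - 1L
    ok <- !is.na(profiles[[t]])
    total[pos[ok]] <- total[pos[ok]] + profiles[[t]][ok]
    count[pos[ok]] <- count[pos[ok]] + 1L
  }
  values <- ifelse(count > 0L, total / pmax(count, 1L), NA_real_)
  reactivity_profile(values, n_contrib = count, scale_factors = scale_factors)
}

#' Read a per-nucleotide intensity table
#'
#' TSV with columns `position`, `treated`, `control` and optionally
#' `transcript`. Positions must be unique and contiguous per transcript.
#'
#' @param path TSV file
#' @return data.frame (with a `transcript` column, "tx1" when absent)
#' @export
read_intensity_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("position", "treated", "control")
  if (!all(need %in% names(df)))
    stop("intensity table must have columns: ", paste(need, collapse = ", "))
  if (!"transcript" %in% names(df)) df$transcript <- "tx1"
  for (tx in unique(df$transcript)) {
    p <- sort(df$position[df$transcript == tx])
    if (anyDuplicated(p)) stop("duplicate positions in transcript ", tx)
    if (!all(diff(p) == 1L)) stop("positions not contiguous in transcript ", tx)
  }
  df
}

#' Process replicate intensity tables for one transcript
#'
#' Runs the full within-transcript chain: raw reactivity (treated minus
#' control) per replicate, boxplot/top-10% normalization per replicate, the
#' cross-replicate SD filter, and replicate averaging.
#'
#' @param replicates list of data.frames with columns `position`, `treated`,
#'   `control` (identical position sets)
#' @param sd_threshold cutoff for [filter_by_sd()]
#' @return list: `values` (averaged normalized reactivities, NA at excluded
#'   positions), `positions`, `scale_factors`, `excluded_positions`, and the
#'   per-replicate normalized matrix `replicate_values`
#' @export
process_replicates <- function(replicates, sd_threshold = 0.7) {
  stopifnot(length(replicates) >= 1L)
  pos <- replicates[[1]]$position
  norm <- matrix(NA_real_, length(pos), length(replicates))
  scales <- numeric(length(replicates))
  for (r in seq_along(replicates)) {
    rep_r <- replicates[[r]]
    if (!identical(sort(rep_r$position), sort(pos)))
      stop("replicates cover different position sets")
    rep_r <- rep_r[match(pos, rep_r$position), ]
    raw <- compute_raw_reactivity(rep_r$treated, rep_r$control)
    bn <- boxplot_normalize(raw)
    norm[, r] <- bn$values
    scales[r] <- bn$scale_factor
  }
  excl <- if (length(replicates) >= 2L) filter_by_sd(norm, sd_threshold)
          else rep(FALSE, length(pos))
  values <- rowMeans(norm, na.rm = TRUE)
  values[excl] <- NA_real_
  values[!is.finite(values)] <- NA_real_
  list(values = values, positions = pos, scale_factors = scales,
       excluded_positions = pos[excl], replicate_values = norm)
}

#' Write a reactivity profile in .shape format
#'
#' Two whitespace-separated columns: 1-based index and reactivity, with
#' -999 marking missing/excluded positions.
#'
#' @param profile reactivity_profile or plain numeric vector (NA = missing)
#' @param path output file
#' @export
write_shape <- function(profile, path) {
  v <- if (inherits(profile, "reactivity_profile")) profile$values else profile
  out <- ifelse(is.na(v), -999, v)
  writeLines(sprintf("%d\t%.6f", seq_along(v), out), path)
  invisible(path)
}

#' Read a .shape reactivity file
#' @param path two-column file (index, reactivity; -999 = missing)
#' @return [reactivity_profile()]
#' @export
read_shape <- function(path) {
  df <- read.table(path, header = FALSE)
  v <- rep(NA_real_, max(df[[1]]))
  v[df[[1]]] <- df[[2]]
  v[v <= -998] <- NA_real_
  reactivity_profile(v)
}

#' Write a normalization QC report as JSON
#' @param processed output of [process_replicates()] (or a list of them,
#'   named by transcript)
#' @param path output JSON file
#' @export
write_qc_json <- function(processed, path) {
  if (!is.null(processed$values)) processed <- list(tx1 = processed)
  report <- lapply(processed, function(p) list(
    scale_factors = p$scale_factors,
    excluded_positions = p$excluded_positions,
    n_positions = length(p$positions),
    n_replicates = ncol(p$replicate_values)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
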