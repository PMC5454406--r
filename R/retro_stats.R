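#' Per-culture retrotransposition frequency
#'
#' The number of His+ prototrophs divided by the number of colony-forming
#' units in the same culture volume. Plated fractions scale each count back
#' to the whole culture, so equal fractions cancel.
#'
#' @param his_positive His+ colony count (>= 0)
#' @param cfu colony-forming units counted (> 0)
#' @param his_fraction fraction of the culture plated for His+ selection
#' @param cfu_fraction fraction of the culture plated for the CFU count
#' @return frequency (unitless); vectorized over cultures
#' @export
frequency <- function(his_positive, cfu, his_fraction = 1, cfu_fraction = 1) {
  stopifnot(all(his_positive >= 0), all(his_fraction > 0),
            all(cfu_fraction > 0))
  if (any(cfu <= 0)) stop("CFU count must be positive")
  (his_positive / his_fraction) / (cfu / cfu_fraction)
}

#' Median with a distribution-free 95% confidence interval
#'
#' The median uses the midpoint convention for even n. The confidence
#' interval is the exact sign-test (binomial) order-statistic interval
#' `(x(k), x(n+1-k))` with `k` the largest order index whose coverage
#' `1 - 2 P(Binom(n, 1/2) <= k - 1)` is at least `level`; for n = 7 at the
#' 95% level this is the full range `(x(1), x(7))`. When no k achieves the
#' requested level the interval degenerates to the full range with a
#' warning.
#'
#' @param frequencies numeric vector of per-culture frequencies (n >= 1)
#' @param level confidence level (default 0.95)
#' @return list of class `frequency_summary`: `frequencies`, `n`, `median`,
#'   `ci_lower`, `ci_upper`, `level`, `k`, `achieved_coverage`
#' @export
median_ci <- function(frequencies, level = 0.95) {
  n <- length(frequencies)
  stopifnot(n >= 1L, level > 0, level < 1)
  xs <- sort(frequencies)
  coverage <- function(k) 1 - 2 * pbinom(k - 1, n, 0.5)
  ks <- seq_len(floor(n / 2))
  ok <- ks[vapply(ks, coverage, numeric(1)) >= level]
  if (!length(ok)) {
    if (coverage(1) < level)
      warning("n = ", n, " cannot achieve a ", level,
              " order-statistic interval; reporting the full range")
    k <- 1L
  } else k <- max(ok)
  out <- list(frequencies = frequencies, n = n,
              median = median(xs),
              ci_lower = xs[k], ci_upper = xs[n + 1L - k],
              level = level, k = k,
              achieved_coverage = max(coverage(k), 0))
  class(out) <- "frequency_summary"
  out
}

#' @export
print.frequency_summary <- function(x, ...) {
  cat(sprintf("n = %d cultures; median frequency %.3g (95%% CI %.3g - %.3g)\n",
              x$n, x$median, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Mutant activity as percent of a reference strain
#'
#' @param mutant,reference [median_ci()] summaries (or lists with a
#'   `median` element)
#' @return 100 * mutant median / reference median
#' @export
percent_of_reference <- function(mutant, reference) {
  if (!is.finite(reference$median) || reference$median <= 0)
    stop("reference median must be positive")
  100 * mutant$median / reference$median
}

#' Read a culture-count table
#'
#' TSV with columns `strain`, `replicate`, `his_positive`, `cfu` and
#' optionally `his_fraction`, `cfu_fraction` (default 1).
#' @param path TSV file
#' @export
read_culture_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("strain", "replicate", "his_positive", "cfu")
  if (!all(need %in% names(df)))
    stop("culture table must have columns: ", paste(need, collapse = ", "))
  if (!"his_fraction" %in% names(df)) df$his_fraction <- 1
  if (!"cfu_fraction" %in% names(df)) df$cfu_fraction <- 1
  df
}

#' Summarize retrotransposition frequencies per strain
#'
#' Computes per-culture frequencies, the per-strain median with its
#' order-statistic confidence interval, and percent-of-reference against a
#' designated reference strain.
#'
#' @param counts data.frame as from [read_culture_tsv()]
#' @param reference_strain strain name used as the 100% reference
#' @param level confidence level
#' @return data.frame: strain, n, median, ci_lower, ci_upper,
#'   percent_of_reference
#' @export
summarize_strains <- function(counts, reference_strain, level = 0.95) {
  strains <- unique(counts$strain)
  if (!reference_strain %in% strains)
    stop("reference strain '", reference_strain, "' not in the table")
  summaries <- lapply(setNames(strains, strains), function(s) {
    d <- counts[counts$strain == s, ]
    median_ci(frequency(d$his_positive, d$cfu, d$his_fraction,
                        d$cfu_fraction), level = level)
  })
  ref <- summaries[[reference_strain]]
  do.call(rbind, lapply(strains, function(s) {
    sm <- summaries[[s]]
    data.frame(strain = s, n = sm$n, median = sm$median,
               ci_lower = sm$ci_lower, ci_upper = sm$ci_upper,
               percent_of_reference = percent_of_reference(sm, ref))
  }))
}
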