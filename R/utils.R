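#' @keywords internal
"_PACKAGE"

# default column order shared by every writer so re-reading preserves equality
.SAMPLE_COLS <- c("sample_id", "array_id", "channel", "stage", "genotype",
                  "tissue", "replicate")
.PROBE_COLS <- c("probe_id", "gene_id", "is_negative_control", "tf_family")

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Convert a fold-change cutoff to its log2 threshold
#'
#' The log2 threshold is carried at full precision internally; printed
#' summaries round it to two decimals (1.5-fold displays as 0.58).
#'
#' @param fold fold-change cutoff (> 1)
#' @return log2(fold), full precision
#' @export
fold_to_log2 <- function(fold) {
  if (!is.numeric(fold) || length(fold) != 1L || !is.finite(fold) || fold <= 0)
    .stopf("'fold' must be a single positive number")
  log2(fold)
}

# deterministic substream seed derived from a master seed (kept < 2^31)
.derive_seed <- function(master, k) {
  as.integer((as.double(master) + 1000003 * as.double(k)) %% 2147483647)
}

#' Place a query set within the quartiles of a reference distribution
#'
#' Quartile boundaries (type-7 quantiles) are computed over the reference
#' values; the query values are then binned. Conventions: "below the median"
#' means strictly less than the median; "in the lowest quartile" means at or
#' below the first-quartile boundary; "above" means strictly greater.
#'
#' @param query numeric values of the query set
#' @param reference numeric values defining the quartile boundaries
#' @return list with `n`, per-quartile `counts`, `frac_lowest_quartile`,
#'   `frac_below_median`, `frac_above_q1`, `frac_above_median`, `boundaries`
#' @export
quartile_placement <- function(query, reference) {
  if (length(reference) == 0L) .stopf("reference distribution is empty")
  if (length(query) == 0L) {
    return(list(n = 0L, counts = c(Q1 = 0L, Q2 = 0L, Q3 = 0L, Q4 = 0L),
                frac_lowest_quartile = NA_real_, frac_below_median = NA_real_,
                frac_above_q1 = NA_real_, frac_above_median = NA_real_,
                boundaries = stats::quantile(reference, c(.25, .5, .75))))
  }
  b <- stats::quantile(reference, c(.25, .5, .75), names = FALSE)
  bin <- findInterval(query, b, left.open = TRUE) + 1L  # value <= b[1] -> 1
  counts <- vapply(1:4, function(i) sum(bin == i), integer(1))
  names(counts) <- paste0("Q", 1:4)
  n <- length(query)
  list(n = n, counts = counts,
       frac_lowest_quartile = counts[["Q1"]] / n,
       frac_below_median = sum(query < b[2]) / n,
       frac_above_q1 = sum(query > b[1]) / n,
       frac_above_median = sum(query > b[2]) / n,
       boundaries = stats::setNames(b, c("Q1", "median", "Q3")))
}
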