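# Present/absent (ON/OFF) calling from negative-control statistics.
#
# A probe measurement scores ON when it exceeds its own array-channel's
# threshold, mean + multiplier * SD of that column's negative-control
# foregrounds. Per (stage, genotype, tissue) group the replicate support
# fraction drives a three-valued call: ON (support >= support_on), OFF
# (support = 0), otherwise AMBIGUOUS.

#' Detection threshold of one sample column
#'
#' @param em ExpressionMatrix
#' @param sample_id column to compute the threshold for
#' @param multiplier SD multiplier (default 3.0)
#' @return list: `sample_id`, `array_id`, `channel`, `mean`, `sd` (sample SD,
#'   n-1 denominator), `multiplier`, `threshold`
#' @export
compute_threshold <- function(em, sample_id, multiplier = 3.0) {
  if (!is.numeric(multiplier) || multiplier <= 0)
    .stopf("'multiplier' must be positive")
  if (!sample_id %in% colnames(em$values))
    .stopf("unknown sample id: %s", sample_id)
  neg <- em$annotation$is_negative_control
  if (sum(neg) < 30L)
    .stopf("only %d negative-control probes; >= 30 required", sum(neg))
  x <- em$values[neg, sample_id]
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) .warnf("negative controls of '%s' have zero SD", sample_id)
  meta <- em$samples[em$samples$sample_id == sample_id, ]
  list(sample_id = sample_id, array_id = meta$array_id, channel = meta$channel,
       mean = m, sd = s, multiplier = multiplier,
       threshold = m + multiplier * s)
}

#' Detection thresholds for every sample column
#'
#' @inheritParams compute_threshold
#' @return data.frame, one row per column
#' @export
detection_thresholds <- function(em, multiplier = 3.0) {
  do.call(rbind, lapply(colnames(em$values), function(id)
    as.data.frame(compute_threshold(em, id, multiplier),
                  stringsAsFactors = FALSE)))
}

#' Analytic false detection rate of the mean + k SD rule
#'
#' Under a Gaussian negative-control model, a null probe exceeds the
#' threshold with the standard-normal upper-tail probability beyond the
#' multiplier. At the default multiplier 3.0 this is 0.00135, i.e. 0.13%.
#'
#' @param multiplier SD multiplier (> 0 not required; 0 gives 0.5)
#' @return expected false-ON fraction
#' @export
estimate_fdr <- function(multiplier) {
  stats::pnorm(multiplier, lower.tail = FALSE)
}

#' Call detection per probe per sample group
#'
#' Non-control probes only. Per group (default grouping: stage x genotype x
#' tissue) the support is the fraction of the group's measurements above
#' their own column's threshold.
#'
#' @param em ExpressionMatrix
#' @param thresholds data.frame from [detection_thresholds()]; computed if
#'   `NULL`
#' @param multiplier SD multiplier used when computing thresholds
#' @param group_by metadata columns defining replicate groups
#' @param support_on support fraction at or above which the call is ON
#' @return data.frame of class `DetectionTable`: `probe_id`, grouping
#'   columns, `n` (replicates), `support`, `call`
#' @export
call_detection <- function(em, thresholds = NULL, multiplier = 3.0,
                           group_by = c("stage", "genotype", "tissue"),
                           support_on = 0.75) {
  if (is.null(thresholds)) thresholds <- detection_thresholds(em, multiplier)
  ids <- colnames(em$values)
  if (!all(ids %in% thresholds$sample_id))
    .stopf("no threshold for sample '%s'",
           setdiff(ids, thresholds$sample_id)[1])
  thr <- thresholds$threshold[match(ids, thresholds$sample_id)]
  sig <- !em$annotation$is_negative_control
  above <- sweep(em$values[sig, , drop = FALSE], 2, thr, `>`)
  key <- do.call(paste, c(em$samples[group_by], list(sep = "\r")))
  groups <- split(seq_along(ids), key)
  if (any(lengths(groups) == 0L)) .stopf("group with 0 replicates")
  res <- lapply(names(groups), function(k) {
    cols <- groups[[k]]
    supp <- rowMeans(above[, cols, drop = FALSE])
    meta <- em$samples[cols[1], group_by, drop = FALSE]
    cbind(data.frame(probe_id = rownames(above), stringsAsFactors = FALSE),
          meta[rep(1, length(supp)), , drop = FALSE],
          data.frame(n = length(cols), support = supp,
                     call = ifelse(supp >= support_on, "ON",
                                   ifelse(supp == 0, "OFF", "AMBIGUOUS")),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("DetectionTable", "data.frame")
  out
}

#' Probe x stage call matrix for one condition
#'
#' @param calls DetectionTable
#' @param stage_order ordered stage labels
#' @param genotype,tissue condition selectors
#' @return character matrix (probes x stages) of calls; probes lacking a
#'   call at some stage are dropped
#' @export
calls_matrix <- function(calls, stage_order, genotype = "wild-type",
                         tissue = "whole") {
  d <- calls[calls$genotype == genotype & calls$tissue == tissue &
               calls$stage %in% stage_order, ]
  if (!all(stage_order %in% d$stage))
    .stopf("no calls for stage '%s' (%s, %s)",
           setdiff(stage_order, d$stage)[1], genotype, tissue)
  probes <- unique(d$probe_id)
  m <- matrix(NA_character_, length(probes), length(stage_order),
              dimnames = list(probes, stage_order))
  for (s in stage_order) {
    ds <- d[d$stage == s, ]
    m[ds$probe_id, s] <- ds$call
  }
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Fraction of a probe set detected at one stage
#'
#' @param probes probe ids
#' @param calls DetectionTable
#' @param stage stage label
#' @param genotype,tissue condition selectors
#' @return list: `n_on`, `n_total`, `percentage` (one decimal)
#' @export
detected_fraction <- function(probes, calls, stage, genotype = "wild-type",
                              tissue = "whole") {
  if (length(probes) == 0L)
    return(list(n_on = 0L, n_total = 0L, percentage = NA_real_))
  d <- calls[calls$stage == stage & calls$genotype == genotype &
               calls$tissue == tissue, ]
  d <- d[d$probe_id %in% probes, ]
  n_on <- sum(d$call == "ON")
  list(n_on = n_on, n_total = nrow(d),
       percentage = round(100 * n_on / nrow(d), 1))
}
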