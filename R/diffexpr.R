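# Differential expression with the fold-change / p-value rule, the
# constitutive between-stage series, and pathway-level flagging.

.de_call <- function(ratio, p, log2_fold, alpha) {
  ifelse(!is.na(p) & p <= alpha & ratio >= log2_fold, "UP",
         ifelse(!is.na(p) & p <= alpha & ratio <= -log2_fold, "DOWN", "NS"))
}

# vectorised two-sample Welch t on log2 intensities (rows = probes)
.welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  # degenerate zero-variance rows: identical groups are NS, separated ones
  # maximally significant
  zero <- is.finite(ma - mb) & se2 == 0
  p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  list(ratio = ma - mb, p = p)
}

# paired one-sample t on per-array log2 ratios against 0
.paired_rows <- function(r) {
  n <- ncol(r)
  m <- rowMeans(r)
  s <- apply(r, 1, stats::sd)
  tt <- m / (s / sqrt(n))
  p <- 2 * stats::pt(abs(tt), n - 1, lower.tail = FALSE)
  p[s == 0] <- ifelse(m[s == 0] == 0, 1, 0)
  list(ratio = m, p = p)
}

#' Differential expression between two sample groups
#'
#' Mean log2 ratio (A vs B) with a two-sided t-test at replicate level. If
#' the two conditions co-hybridized on the same arrays (every array carries
#' one A and one B sample), a one-sample t-test on the per-array log2 ratios
#' is used; otherwise a Welch two-sample t-test on log2 intensities. The
#' log2 fold threshold is evaluated internally at full precision
#' (log2(1.5) = 0.585, displayed to two decimals as 0.58).
#'
#' @param em ExpressionMatrix (normalized)
#' @param samples_a,samples_b sample ids of the two groups (>= 2 each)
#' @param fold fold-change cutoff (default 1.5)
#' @param alpha p-value cutoff (default 0.05); no multiple-testing
#'   correction is applied, matching the bare p <= alpha rule; set
#'   `adjust = "BH"` to add Benjamini-Hochberg adjustment
#' @param method `"auto"` (detect pairing), `"paired"` or `"welch"`
#' @param adjust `"none"` (default) or `"BH"`
#' @return data.frame of class `DifferentialResult`: `probe_id`,
#'   `log2_ratio`, `p_value`, `call`; attributes `fold`, `log2_fold`,
#'   `alpha`, `method`
#' @export
de_test <- function(em, samples_a, samples_b, fold = 1.5, alpha = 0.05,
                    method = c("auto", "paired", "welch"), adjust = "none") {
  method <- match.arg(method)
  if (length(samples_a) < 2L)
    .stopf("group 'A' has %d replicate(s); >= 2 required", length(samples_a))
  if (length(samples_b) < 2L)
    .stopf("group 'B' has %d replicate(s); >= 2 required", length(samples_b))
  sig <- !em$annotation$is_negative_control
  la <- log2(em$values[sig, samples_a, drop = FALSE])
  lb <- log2(em$values[sig, samples_b, drop = FALSE])
  arr <- function(ids) em$samples$array_id[match(ids, em$samples$sample_id)]
  aa <- arr(samples_a); ab <- arr(samples_b)
  paired <- length(samples_a) == length(samples_b) &&
    !anyDuplicated(aa) && setequal(aa, ab)
  if (method == "paired" && !paired)
    .stopf("groups do not share arrays pairwise; paired test impossible")
  use_paired <- method == "paired" || (method == "auto" && paired)
  res <- if (use_paired) {
    .paired_rows(la - lb[, match(aa, ab), drop = FALSE])
  } else {
    .welch_rows(la, lb)
  }
  p <- if (identical(adjust, "BH")) stats::p.adjust(res$p, "BH") else res$p
  lf <- fold_to_log2(fold)
  out <- data.frame(probe_id = rownames(la), log2_ratio = res$ratio,
                    p_value = p,
                    call = .de_call(res$ratio, p, lf, alpha),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fold") <- fold
  attr(out, "log2_fold") <- lf
  attr(out, "alpha") <- alpha
  attr(out, "method") <- if (use_paired) "paired" else "welch"
  class(out) <- c("DifferentialResult", "data.frame")
  out
}

#' @export
print.DifferentialResult <- function(x, ...) {
  cat(sprintf("DifferentialResult: %d probes; %d UP, %d DOWN (%.2g-fold, log2 %.2f; p <= %g, %s test)\n",
              nrow(x), sum(x$call == "UP"), sum(x$call == "DOWN"),
              attr(x, "fold"), attr(x, "log2_fold"), attr(x, "alpha"),
              attr(x, "method")))
  invisible(x)
}

#' Between-stage fold changes among constitutive probes
#'
#' For each consecutive stage pair, the log2 ratio of average (arithmetic
#' mean linear) replicate intensities is computed per constitutive probe and
#' compared to a bare fold cutoff (default two-fold; no p-value, matching
#' the average-intensity pathway rule).
#'
#' @param em normalized ExpressionMatrix
#' @param patterns StagePatternTable restricting to `constitutive_on` probes
#' @param stage_order ordered stage labels
#' @param fold fold cutoff (default 2)
#' @param genotype,tissue condition selectors
#' @return named list, one entry per transition (`"s1->s2"`), each a list
#'   with `up`, `down` (probe id vectors) and `ratios` (named log2 ratios)
#' @export
constitutive_de_series <- function(em, patterns, stage_order, fold = 2.0,
                                   genotype = "wild-type", tissue = "whole") {
  const <- pattern_probes(patterns, "constitutive_on")
  lf <- fold_to_log2(fold)
  means <- sapply(stage_order, function(s) {
    ids <- sample_ids(em, stage = s, genotype = genotype, tissue = tissue)
    rowMeans(em$values[const, ids, drop = FALSE])
  })
  out <- list()
  for (t in seq_along(stage_order)[-1]) {
    ratio <- log2(means[, t] / means[, t - 1])
    nm <- paste0(stage_order[t - 1], "->", stage_order[t])
    out[[nm]] <- list(up = const[ratio >= lf], down = const[ratio <= -lf],
                      ratios = stats::setNames(ratio, const))
  }
  out
}

#' Flag gene sets by their changed-member fraction
#'
#' @param changed_genes gene ids scored as changed (differentially expressed
#'   or enriched)
#' @param gene_set_map named list: set id -> gene ids
#' @param rule `"any"` (>= 1 changed member) or `"fraction"` (changed
#'   fraction strictly greater than `fraction`)
#' @param fraction threshold for the fraction rule (default 0.45: more than
#'   45 percent of a set's composite enzymes must be changed)
#' @param universe optional gene universe; set members outside it are not
#'   counted as mapped. Sets with zero mapped members are skipped with a
#'   warning.
#' @return data.frame: `set_id`, `n_mapped`, `n_changed`, `fraction`,
#'   `flagged`
#' @export
pathway_flags <- function(changed_genes, gene_set_map,
                          rule = c("any", "fraction"), fraction = 0.45,
                          universe = NULL) {
  rule <- match.arg(rule)
  rows <- lapply(names(gene_set_map), function(id) {
    members <- gene_set_map[[id]]
    if (!is.null(universe)) members <- intersect(members, universe)
    if (length(members) == 0L) {
      .warnf("gene set '%s' has no mapped members; skipped", id)
      return(NULL)
    }
    nch <- length(intersect(members, changed_genes))
    fr <- nch / length(members)
    data.frame(set_id = id, n_mapped = length(members), n_changed = nch,
               fraction = fr,
               flagged = if (rule == "any") nch >= 1 else fr > fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_id = character(0), n_mapped = integer(0),
                      n_changed = integer(0), fraction = numeric(0),
                      flagged = logical(0))
  rownames(out) <- NULL
  out
}
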