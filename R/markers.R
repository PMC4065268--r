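# Sequential marker filters and curated-list scoring: pluripotency-decline
# candidates, constitutive fractions of curated gene lists, mutant
# persistence of the trough set, and direct-target overlap between stages.

#' Build one criterion of a sequential marker filter
#'
#' @param type `"log2_below"` / `"log2_above"` (a differential-expression
#'   threshold with p-value at one transition), `"call_is"` (detection call
#'   at one stage), or `"low_or_off"` (at each given stage the probe is not
#'   ON, or its stage-mean log2 intensity lies below the stage's lower
#'   quartile over expressed probes)
#' @param transition transition name for the log2 criteria (must index the
#'   `de` list passed to [sequential_filter()])
#' @param stage,stages stage label(s) for `call_is` / `low_or_off`
#' @param threshold log2 threshold for the log2 criteria
#' @param alpha p-value cutoff for the log2 criteria
#' @param call required call for `call_is`
#' @return a `marker_criterion` list
#' @export
marker_criterion <- function(type, transition = NULL, stage = NULL,
                             stages = NULL, threshold = NULL, alpha = 0.05,
                             call = "ON") {
  type <- match.arg(type, c("log2_below", "log2_above", "call_is", "low_or_off"))
  if (type %in% c("log2_below", "log2_above")) {
    if (is.null(transition) || is.null(threshold) || !is.finite(threshold))
      .stopf("criterion '%s' needs a transition and a finite threshold", type)
  }
  structure(list(type = type, transition = transition, stage = stage,
                 stages = stages, threshold = threshold, alpha = alpha,
                 call = call), class = "marker_criterion")
}

.apply_criterion <- function(cr, candidates, de, calls, em, genotype, tissue) {
  if (cr$type %in% c("log2_below", "log2_above")) {
    if (is.null(de[[cr$transition]]))
      .stopf("no differential result for transition '%s'", cr$transition)
    d <- de[[cr$transition]]
    d <- d[d$probe_id %in% candidates, ]
    keep <- if (cr$type == "log2_below")
      d$log2_ratio < cr$threshold & d$p_value < cr$alpha
    else d$log2_ratio > cr$threshold & d$p_value < cr$alpha
    d$probe_id[keep]
  } else if (cr$type == "call_is") {
    d <- calls[calls$stage == cr$stage & calls$genotype == genotype &
                 calls$tissue == tissue & calls$probe_id %in% candidates, ]
    d$probe_id[d$call == cr$call]
  } else {  # low_or_off
    keep <- candidates
    for (s in cr$stages) {
      ids <- sample_ids(em, stage = s, genotype = genotype, tissue = tissue)
      lvl <- mean_log2(em, ids)
      d <- calls[calls$stage == s & calls$genotype == genotype &
                   calls$tissue == tissue, ]
      on_probes <- d$probe_id[d$call == "ON"]
      q1 <- stats::quantile(lvl[on_probes], 0.25, names = FALSE)
      ok <- vapply(keep, function(p) {
        !(p %in% on_probes) || lvl[p] < q1
      }, logical(1))
      keep <- keep[ok]
    }
    keep
  }
}

#' Sequential marker filtering
#'
#' Applies an ordered list of criteria, each restricting the survivors of
#' the previous step, so the returned sets are nested.
#'
#' @param candidates starting probe ids
#' @param criteria list of [marker_criterion()] objects
#' @param de named list of [de_test()] results indexed by transition name
#' @param calls DetectionTable (for call criteria)
#' @param em normalized ExpressionMatrix (for `low_or_off` criteria)
#' @param genotype,tissue condition selectors for call criteria
#' @return list: `steps` (surviving probe ids after each criterion),
#'   `final`, `counts` (survivor count per step, starting with the input)
#' @export
sequential_filter <- function(candidates, criteria, de = list(),
                              calls = NULL, em = NULL,
                              genotype = "wild-type", tissue = "whole") {
  steps <- list()
  current <- candidates
  for (k in seq_along(criteria)) {
    current <- .apply_criterion(criteria[[k]], current, de, calls, em,
                                genotype, tissue)
    steps[[k]] <- current
  }
  step_counts <- if (length(steps))
    stats::setNames(lengths(steps), paste0("step", seq_along(steps)))
  else integer(0)
  list(steps = steps, final = current,
       counts = c(input = length(candidates), step_counts))
}

.gene_probe_map <- function(annotation) {
  a <- annotation[!annotation$is_negative_control & !is.na(annotation$gene_id), ]
  split(a$probe_id, a$gene_id)
}

#' Constitutive fraction of a curated gene list
#'
#' A gene counts as constitutive when at least one of its probes is
#' `constitutive_on`. Genes without a probe on the array are reported
#' separately (N/A), mirroring curated-table conventions.
#'
#' @param genes curated gene ids (nonempty)
#' @param patterns StagePatternTable
#' @param annotation probe annotation data.frame (probe -> gene map)
#' @return list: `n_constitutive`, `n_total` (genes with >= 1 probe),
#'   `n_na` (genes without probes), `percentage` (one decimal; `NA` when no
#'   gene has a probe)
#' @export
constitutive_fraction <- function(genes, patterns, annotation) {
  if (length(genes) == 0L) .stopf("empty gene list")
  gp <- .gene_probe_map(annotation)
  const <- pattern_probes(patterns, "constitutive_on")
  has_probe <- genes %in% names(gp)
  is_const <- vapply(genes[has_probe],
                     function(g) any(gp[[g]] %in% const), logical(1))
  n_total <- sum(has_probe)
  list(n_constitutive = sum(is_const), n_total = n_total,
       n_na = sum(!has_probe),
       percentage = if (n_total == 0) NA_real_
       else round(100 * sum(is_const) / n_total, 1))
}

#' Array representation of a locus list
#'
#' @param loci gene/locus ids
#' @param annotation probe annotation data.frame
#' @return list: `n_on_array`, `n_total`, `percentage` (one decimal)
#' @export
array_representation <- function(loci, annotation) {
  if (length(loci) == 0L) .stopf("empty locus list")
  gp <- .gene_probe_map(annotation)
  n_on <- sum(loci %in% names(gp))
  list(n_on_array = n_on, n_total = length(loci),
       percentage = round(100 * n_on / length(loci), 1))
}

#' Probes ON at earlier stages but not at a focal stage
#'
#' The reference universe of the mutant-persistence question: probes ON at
#' every earlier stage given and not ON at the focal stage (wild-type).
#'
#' @param calls DetectionTable
#' @param earlier_stages stages that must be ON
#' @param focal_stage stage that must not be ON
#' @param genotype,tissue condition selectors
#' @return character vector of probe ids
#' @export
off_after_on_set <- function(calls, earlier_stages, focal_stage,
                             genotype = "wild-type", tissue = "whole") {
  m <- calls_matrix(calls, c(earlier_stages, focal_stage), genotype, tissue)
  on <- m == "ON"
  rownames(m)[rowSums(on[, earlier_stages, drop = FALSE]) ==
                length(earlier_stages) & !on[, focal_stage]]
}

#' Persistence of a reference set in the mutant
#'
#' Fraction of a wild-type-derived probe set that is called ON in the
#' mutant at the focal stage.
#'
#' @param probes reference probe ids (e.g. from [off_after_on_set()])
#' @param mutant_calls DetectionTable containing the mutant condition
#' @param stage focal stage
#' @param genotype mutant genotype label
#' @param tissue tissue selector
#' @return list: `n_on`, `n_total`, `percentage` (one decimal)
#' @export
persistence_fraction <- function(probes, mutant_calls, stage,
                                 genotype = "mac1", tissue = "whole") {
  if (length(probes) == 0L)
    return(list(n_on = 0L, n_total = 0L, percentage = NA_real_))
  detected_fraction(probes, mutant_calls, stage, genotype, tissue)
}

#' Same-direction overlap of two differential results
#'
#' @param de_early,de_late [de_test()] results against the same reference
#' @return list: `down` (probes DOWN in both), `up` (probes UP in both)
#' @export
direct_target_overlap <- function(de_early, de_late) {
  pick <- function(d, what) d$probe_id[d$call == what]
  list(down = intersect(pick(de_early, "DOWN"), pick(de_late, "DOWN")),
       up = intersect(pick(de_early, "UP"), pick(de_late, "UP")))
}
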