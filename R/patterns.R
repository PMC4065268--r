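# Stage-pattern taxonomy over the ordered developmental series, transition
# gain/loss accounting, three-way stage overlaps, and intensity placement of
# probe sets within a reference stage's distribution.

#' Classify per-probe call vectors over the ordered stage series
#'
#' Pattern classes: `constitutive_on` (ON at every stage), `constitutive_off`
#' (not-ON at every stage), `stage_specific` (ON only at the anchor stage),
#' `trough` (ON at every stage except the anchor stage), `other`. "Not
#' detected" means call != ON; by default an AMBIGUOUS call counts as
#' not-ON (`ambiguous = "not_on"`), or probes with any AMBIGUOUS call can be
#' excluded outright (`ambiguous = "exclude"`). Probes lacking a call at some
#' stage are labelled `excluded`.
#'
#' @param calls DetectionTable (or a probe x stage character call matrix)
#' @param stage_order ordered stage labels
#' @param genotype,tissue condition selectors (ignored for a matrix input)
#' @param ambiguous how AMBIGUOUS calls enter classification
#' @return data.frame of class `StagePatternTable`: `probe_id`, one call
#'   column per stage, `pattern`, `anchor_stage`
#' @export
classify_patterns <- function(calls, stage_order, genotype = "wild-type",
                              tissue = "whole",
                              ambiguous = c("not_on", "exclude")) {
  ambiguous <- match.arg(ambiguous)
  if (is.matrix(calls)) {
    if (!all(stage_order %in% colnames(calls)))
      .stopf("unknown stage in order list: %s",
             setdiff(stage_order, colnames(calls))[1])
    m <- calls[, stage_order, drop = FALSE]
    universe <- rownames(calls)
  } else {
    m <- calls_matrix(calls, stage_order, genotype, tissue)
    universe <- unique(calls$probe_id)
  }
  if (length(stage_order) < 2L) .stopf(">= 2 stages required")
  excluded <- setdiff(universe, rownames(m))
  if (ambiguous == "exclude") {
    amb <- rownames(m)[rowSums(m == "AMBIGUOUS") > 0]
    excluded <- c(excluded, amb)
    m <- m[!rownames(m) %in% amb, , drop = FALSE]
  }
  on <- m == "ON"
  n_on <- rowSums(on)
  S <- length(stage_order)
  pattern <- rep("other", nrow(m))
  anchor <- rep(NA_character_, nrow(m))
  pattern[n_on == S] <- "constitutive_on"
  pattern[n_on == 0] <- "constitutive_off"
  sp <- which(n_on == 1)
  pattern[sp] <- "stage_specific"
  anchor[sp] <- stage_order[apply(on[sp, , drop = FALSE], 1, which)]
  tr <- which(n_on == S - 1)
  pattern[tr] <- "trough"
  anchor[tr] <- stage_order[apply(!on[tr, , drop = FALSE], 1, which)]
  out <- data.frame(probe_id = rownames(m), stringsAsFactors = FALSE)
  for (s in stage_order) out[[paste0("call_", s)]] <- m[, s]
  out$pattern <- pattern
  out$anchor_stage <- anchor
  if (length(excluded)) {
    ex <- data.frame(probe_id = excluded, stringsAsFactors = FALSE)
    for (s in stage_order) ex[[paste0("call_", s)]] <- NA_character_
    ex$pattern <- "excluded"
    ex$anchor_stage <- NA_character_
    out <- rbind(out, ex)
  }
  rownames(out) <- NULL
  class(out) <- c("StagePatternTable", "data.frame")
  out
}

#' Probe ids matching a pattern
#'
#' @param patterns StagePatternTable
#' @param pattern pattern label
#' @param anchor_stage optional anchor stage restriction
#' @return character vector of probe ids
#' @export
pattern_probes <- function(patterns, pattern, anchor_stage = NULL) {
  keep <- patterns$pattern == pattern
  if (!is.null(anchor_stage))
    keep <- keep & !is.na(patterns$anchor_stage) &
      patterns$anchor_stage == anchor_stage
  patterns$probe_id[keep]
}

#' Per-transition gain/loss ledger
#'
#' For each stage t the ON set is split into three disjoint parts that sum to
#' |ON at t|: `shared` (also ON at t-1), `newly` (not ON at t-1 and not
#' stage-specific) and `specific` (ON only at t over the whole series).
#' `lost` counts probes ON at t-1 but not at t, split by their own category
#' at t-1. The first stage reports all its ON probes as newly (or specific).
#'
#' @inheritParams classify_patterns
#' @return data.frame of class `TransitionLedger`, one row per stage
#' @export
transition_ledger <- function(calls, stage_order, genotype = "wild-type",
                              tissue = "whole") {
  m <- if (is.matrix(calls)) calls[, stage_order, drop = FALSE]
  else calls_matrix(calls, stage_order, genotype, tissue)
  on <- m == "ON"
  S <- length(stage_order)
  specific <- rowSums(on) == 1
  cat_at <- function(t) {
    # category of each ON probe at stage t: shared / newly / specific
    is_on <- on[, t]
    prev <- if (t == 1) rep(FALSE, nrow(on)) else on[, t - 1]
    ifelse(!is_on, NA,
           ifelse(specific, "specific", ifelse(prev, "shared", "newly")))
  }
  rows <- lapply(seq_len(S), function(t) {
    cat_t <- cat_at(t)
    lost <- if (t == 1) rep(FALSE, nrow(on)) else on[, t - 1] & !on[, t]
    cat_prev <- if (t == 1) rep(NA_character_, nrow(on)) else cat_at(t - 1)
    data.frame(stage = stage_order[t],
               prev_stage = if (t == 1) NA_character_ else stage_order[t - 1],
               n_on = sum(on[, t]),
               shared = sum(cat_t == "shared", na.rm = TRUE),
               newly = sum(cat_t == "newly", na.rm = TRUE),
               specific = sum(cat_t == "specific", na.rm = TRUE),
               lost = sum(lost),
               lost_from_shared = sum(lost & cat_prev == "shared", na.rm = TRUE),
               lost_from_newly = sum(lost & cat_prev == "newly", na.rm = TRUE),
               lost_from_specific = sum(lost & cat_prev == "specific",
                                        na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("TransitionLedger", "data.frame")
  out
}

#' Three-stage overlap of ON sets
#'
#' @inheritParams classify_patterns
#' @param stages exactly three distinct stage labels
#' @return named integer vector of the seven membership regions, names in
#'   `{100, 010, 001, 110, 101, 011, 111}` ordered by the three stages
#' @export
venn_three <- function(calls, stages, genotype = "wild-type",
                       tissue = "whole") {
  if (length(stages) != 3L || anyDuplicated(stages))
    .stopf("exactly three distinct stage labels required")
  m <- if (is.matrix(calls)) calls[, stages, drop = FALSE]
  else calls_matrix(calls, stages, genotype, tissue)
  on <- m == "ON"
  key <- paste0(on[, 1] + 0L, on[, 2] + 0L, on[, 3] + 0L)
  regions <- c("100", "010", "001", "110", "101", "011", "111")
  stats::setNames(vapply(regions, function(r) sum(key == r), integer(1)),
                  regions)
}

#' Place a probe set within a reference stage's intensity distribution
#'
#' Per-probe stage intensity is the mean log2 of the stage's replicate
#' columns. Quartile boundaries are computed over all probes called ON at
#' the reference stage; the query set is then binned (see
#' [quartile_placement()] for boundary conventions).
#'
#' @param em normalized ExpressionMatrix
#' @param probes query probe ids
#' @param reference_stage stage defining the distribution
#' @param calls DetectionTable for the same experiment
#' @param genotype,tissue condition selectors
#' @return [quartile_placement()] result
#' @export
intensity_placement <- function(em, probes, reference_stage, calls,
                                genotype = "wild-type", tissue = "whole") {
  ids <- sample_ids(em, stage = reference_stage, genotype = genotype,
                    tissue = tissue)
  if (length(ids) == 0L) .stopf("no samples at stage '%s'", reference_stage)
  lvl <- mean_log2(em, ids)
  d <- calls[calls$stage == reference_stage & calls$genotype == genotype &
               calls$tissue == tissue & calls$call == "ON", ]
  quartile_placement(lvl[intersect(probes, names(lvl))], lvl[d$probe_id])
}

#' Annotation-tag histogram of a probe set
#'
#' @param probes probe ids
#' @param tags data.frame with columns `probe_id`, `tag` (long format; a
#'   probe may carry several tags)
#' @return list: `histogram` (named counts per tag over probes having at
#'   least one tag), `n_untagged`
#' @export
annotate_counts <- function(probes, tags) {
  t2 <- tags[tags$probe_id %in% probes, , drop = FALSE]
  tagged <- unique(t2$probe_id)
  h <- if (nrow(t2)) table(t2$tag) else table(character(0))
  list(histogram = stats::setNames(as.integer(h), names(h)),
       n_untagged = length(setdiff(probes, tagged)))
}
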