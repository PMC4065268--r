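# LCM cell-type analysis: per-zone enrichment versus whole anther, zone
# sharing partitions, non-lobe tissue assignment, TF-family tabulation and
# spatial refinement of the trough set.

#' Per-zone enrichment versus whole anther
#'
#' For each zone the zone samples are tested against the whole-anther
#' samples with [de_test()] (1.5-fold, p <= 0.05 by default). A probe is
#' enriched in a zone when called UP there and detected (ON) in that zone's
#' LCM sample.
#'
#' @param em normalized ExpressionMatrix of the LCM experiment
#' @param calls DetectionTable of the same experiment (grouped by tissue)
#' @param zones zone tissue labels to test
#' @param whole whole-anther tissue label
#' @param stage stage of the comparison
#' @param fold,alpha thresholds passed to [de_test()]
#' @return object of class `ZoneEnrichment`: list with `table` (per probe:
#'   `ratio_<zone>`, `p_<zone>`, `call_<zone>`, `detected_<zone>`,
#'   `enriched_<zone>`), `zones`, `zone_cols` (sanitized column suffixes),
#'   `fold`, `alpha`
#' @export
enrichment_vs_whole <- function(em, calls, zones = c("AR", "ML/TAP", "EPI/EN"),
                                whole = "whole", stage = NULL,
                                fold = 1.5, alpha = 0.05) {
  wids <- sample_ids(em, stage = stage, tissue = whole)
  if (length(wids) == 0L) .stopf("missing whole-anther group")
  zones <- zones[vapply(zones, function(z)
    length(sample_ids(em, stage = stage, tissue = z)) > 0, logical(1))]
  sig <- !em$annotation$is_negative_control
  tab <- data.frame(probe_id = em$annotation$probe_id[sig],
                    stringsAsFactors = FALSE)
  zcols <- gsub("[^A-Za-z]", "", zones)
  for (k in seq_along(zones)) {
    z <- zones[k]
    zc <- zcols[k]
    zids <- sample_ids(em, stage = stage, tissue = z)
    de <- de_test(em, zids, wids, fold = fold, alpha = alpha)
    d <- calls[calls$tissue == z &
                 (if (is.null(stage)) TRUE else calls$stage == stage), ]
    det <- d$call[match(tab$probe_id, d$probe_id)] == "ON"
    tab[[paste0("ratio_", zc)]] <- de$log2_ratio
    tab[[paste0("p_", zc)]] <- de$p_value
    tab[[paste0("call_", zc)]] <- de$call
    tab[[paste0("detected_", zc)]] <- det
    tab[[paste0("enriched_", zc)]] <- de$call == "UP" & det
  }
  structure(list(table = tab, zones = zones, zone_cols = zcols,
                 fold = fold, alpha = alpha),
            class = "ZoneEnrichment")
}

.enriched_matrix <- function(enr) {
  m <- sapply(enr$zone_cols, function(zc) enr$table[[paste0("enriched_", zc)]])
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(enr$table))
  dimnames(m) <- list(enr$table$probe_id, enr$zones)
  m
}

#' Zone-sharing partition of enriched probes
#'
#' @param enr ZoneEnrichment
#' @return named list of probe-id vectors over the disjoint membership
#'   regions (one entry per nonempty zone combination, names joined by `+`)
#' @export
zone_partition <- function(enr) {
  m <- .enriched_matrix(enr)
  any_enr <- rowSums(m) > 0
  key <- apply(m[any_enr, , drop = FALSE], 1, function(r)
    paste(enr$zones[r], collapse = "+"))
  split(rownames(m)[any_enr], key)
}

#' Assign probes to non-lobe (connective/vasculature) tissue
#'
#' Union of two disjoint reason classes: probes significantly DOWN in all
#' three LCM collections relative to whole anther (and detected in at least
#' one collection, i.e. present in the LCM data), and probes detected in
#' whole anther but in no LCM collection whose whole-anther intensity lies
#' above the whole-anther median (over probes called ON in whole anther).
#' The two reasons are disjoint by construction: the first requires
#' detection in some collection, the second detection in none.
#'
#' @param enr ZoneEnrichment
#' @param whole_calls DetectionTable rows for the whole-anther condition
#' @param whole_intensity named per-probe whole-anther mean log2 intensity
#' @return list: `assigned` (data.frame `probe_id`, `reason`), `n_down_all`,
#'   `n_absent_above_median`, `n_total`
#' @export
nonlobe_assignment <- function(enr, whole_calls, whole_intensity) {
  tab <- enr$table
  down_all <- rep(TRUE, nrow(tab))
  det_any <- rep(FALSE, nrow(tab))
  for (zc in enr$zone_cols) {
    down_all <- down_all & tab[[paste0("call_", zc)]] == "DOWN"
    det_any <- det_any | (tab[[paste0("detected_", zc)]] %in% TRUE)
  }
  if (length(enr$zones) == 0L) down_all <- rep(FALSE, nrow(tab))
  down_all <- down_all & det_any
  on_whole <- whole_calls$probe_id[whole_calls$call == "ON"]
  med <- stats::median(whole_intensity[intersect(on_whole,
                                                 names(whole_intensity))])
  absent <- tab$probe_id %in% on_whole & !det_any &
    whole_intensity[tab$probe_id] > med
  absent[is.na(absent)] <- FALSE
  ids_down <- tab$probe_id[down_all]
  ids_abs <- tab$probe_id[absent]
  df <- data.frame(
    probe_id = c(ids_down, ids_abs),
    reason = c(rep("down_in_all_three", length(ids_down)),
               rep("absent_in_LCM_above_whole_median", length(ids_abs))),
    stringsAsFactors = FALSE)
  list(assigned = df, n_down_all = sum(down_all),
       n_absent_above_median = sum(absent), n_total = nrow(df))
}

#' Quartile placement of the absent-from-LCM set in whole anther
#'
#' @param probes probe ids absent from every LCM collection
#' @param whole_calls DetectionTable rows for whole anther
#' @param whole_intensity named per-probe whole-anther mean log2 intensity
#' @return [quartile_placement()] result over the ON-in-whole universe
#' @export
absent_set_placement <- function(probes, whole_calls, whole_intensity) {
  on_whole <- whole_calls$probe_id[whole_calls$call == "ON"]
  ref <- whole_intensity[intersect(on_whole, names(whole_intensity))]
  if (length(ref) == 0L) .stopf("empty whole-anther distribution")
  quartile_placement(whole_intensity[intersect(probes, names(whole_intensity))],
                     ref)
}

#' Zone x TF-family table of exclusively enriched probes
#'
#' @param enr ZoneEnrichment
#' @param annotation probe annotation with `tf_family`
#' @return integer matrix, zones x families, counting probes enriched in
#'   exactly one zone and carrying a family label
#' @export
family_tabulation <- function(enr, annotation) {
  m <- .enriched_matrix(enr)
  excl <- rowSums(m) == 1
  fam <- annotation$tf_family[match(rownames(m), annotation$probe_id)]
  keep <- excl & !is.na(fam)
  if (!any(keep))
    return(matrix(integer(0), nrow = length(enr$zones), ncol = 0,
                  dimnames = list(enr$zones, NULL)))
  zone_of <- enr$zones[apply(m[keep, , drop = FALSE], 1, which)]
  t2 <- table(factor(zone_of, levels = enr$zones), fam[keep])
  out <- matrix(as.integer(t2), nrow = nrow(t2), dimnames = dimnames(t2))
  out
}

#' Spatial refinement of the trough set at a later stage
#'
#' Exhaustive disjoint partition of a trough probe set by its behaviour in
#' the LCM dataset: `off` (detected in no LCM collection), `no_enrichment`
#' (detected somewhere, enriched nowhere), enriched in exactly one zone
#' (one category per zone), in exactly two (per pair), or in all three.
#'
#' @param probes trough probe ids
#' @param enr ZoneEnrichment at the later stage
#' @return list: `partition` (named list of probe-id vectors), `counts`,
#'   `fractions` (sum to 1)
#' @export
trough_refinement <- function(probes, enr) {
  if (length(probes) == 0L)
    return(list(partition = list(), counts = integer(0), fractions = numeric(0)))
  tab <- enr$table[match(probes, enr$table$probe_id), , drop = FALSE]
  miss <- probes[is.na(tab$probe_id)]
  if (length(miss)) .stopf("probe '%s' not in enrichment table", miss[1])
  m <- .enriched_matrix(enr)[probes, , drop = FALSE]
  det <- sapply(enr$zone_cols, function(zc)
    tab[[paste0("detected_", zc)]] %in% TRUE)
  if (is.null(dim(det))) det <- matrix(det, nrow = length(probes))
  n_enr <- rowSums(m)
  cat <- character(length(probes))
  cat[rowSums(det) == 0] <- "off"
  cat[rowSums(det) > 0 & n_enr == 0] <- "no_enrichment"
  multi <- n_enr >= 1
  cat[multi] <- apply(m[multi, , drop = FALSE], 1, function(r)
    paste(enr$zones[r], collapse = "+"))
  part <- split(probes, cat)
  counts <- lengths(part)
  list(partition = part, counts = counts,
       fractions = counts / length(probes))
}
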