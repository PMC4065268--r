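# Transcript-protein concordance: pairing of stage log2 ratios across
# platforms, decile binning, and cross-study protein-set overlap with
# molecular-weight filters.

.decile_rank <- function(x) {
  # deterministic decile index: stable first-occurrence tie-break
  ceiling(rank(x, ties.method = "first") * 10 / length(x))
}

#' Pair protein and RNA stage log2 ratios by gene
#'
#' Protein abundances are replicate-averaged (linear) per stage, summed over
#' a gene's proteins, and log2-ratioed between the two stages; RNA ratios
#' use gene-collapsed (mean over a gene's probes) stage-mean log2
#' intensities. Only proteins with abundances at both stages are ratioed;
#' the tables are inner-joined on gene id.
#'
#' @param prot protein abundance table ([read_protein_table()] format)
#' @param em normalized ExpressionMatrix
#' @param stages length-2 character vector `c(A, B)`: ratios are A vs B
#' @param genotype,tissue RNA condition selectors
#' @return data.frame of class `PairedRatioTable`: `gene_id`,
#'   `protein_ratio`, `rna_ratio`, `protein_decile`, `rna_decile`
#' @export
pair_stage_ratios <- function(prot, em, stages, genotype = "wild-type",
                              tissue = "whole") {
  if (length(stages) != 2L) .stopf("exactly two stages required")
  pr <- prot[prot$stage %in% stages & !is.na(prot$gene_id), ]
  # replicate-average per (protein, stage), then sum a gene's proteins
  ag <- stats::aggregate(abundance ~ protein_id + gene_id + stage, pr, mean)
  gg <- stats::aggregate(abundance ~ gene_id + stage, ag, sum)
  wide <- merge(gg[gg$stage == stages[1], c("gene_id", "abundance")],
                gg[gg$stage == stages[2], c("gene_id", "abundance")],
                by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(wide)) {
    wide$protein_ratio <- log2(wide$abundance_a / wide$abundance_b)
  } else wide$protein_ratio <- numeric(0)
  rna_lvl <- function(s) {
    ids <- sample_ids(em, stage = s, genotype = genotype, tissue = tissue)
    lvl <- mean_log2(em, ids)
    gene <- em$annotation$gene_id[match(names(lvl), em$annotation$probe_id)]
    keep <- !is.na(gene)
    tapply(lvl[keep], gene[keep], mean)
  }
  ra <- rna_lvl(stages[1])
  rb <- rna_lvl(stages[2])
  shared <- intersect(wide$gene_id, intersect(names(ra), names(rb)))
  if (length(shared) == 0L) {
    .warnf("no shared genes between platforms")
    out <- data.frame(gene_id = character(0), protein_ratio = numeric(0),
                      rna_ratio = numeric(0), protein_decile = integer(0),
                      rna_decile = integer(0))
    class(out) <- c("PairedRatioTable", "data.frame")
    return(out)
  }
  out <- data.frame(gene_id = shared,
                    protein_ratio = wide$protein_ratio[match(shared, wide$gene_id)],
                    rna_ratio = unname(ra[shared] - rb[shared]),
                    stringsAsFactors = FALSE)
  out$protein_decile <- .decile_rank(out$protein_ratio)
  out$rna_decile <- .decile_rank(out$rna_ratio)
  class(out) <- c("PairedRatioTable", "data.frame")
  out
}

#' 10 x 10 decile table of paired ratios
#'
#' Deciles are computed independently per axis over the paired set, so each
#' margin is n/10 (plus or minus one, ties broken deterministically).
#'
#' @param paired PairedRatioTable (>= 10 rows)
#' @return list: `table` (10 x 10 integer matrix, protein deciles in rows),
#'   `row_margin`, `col_margin`
#' @export
decile_table <- function(paired) {
  if (nrow(paired) < 10L) .stopf("decile table needs >= 10 rows")
  tab <- table(factor(paired$protein_decile, levels = 1:10),
               factor(paired$rna_decile, levels = 1:10))
  m <- matrix(as.integer(tab), 10, 10,
              dimnames = list(protein = 1:10, rna = 1:10))
  list(table = m, row_margin = rowSums(m), col_margin = colSums(m))
}

#' Protein-set overlap restricted to a molecular-weight range
#'
#' Both sets are first restricted to proteins whose MW fraction bin lies
#' fully inside the range; bins straddling a boundary are excluded.
#'
#' @param set_a,set_b protein id vectors
#' @param mw named character vector: protein id -> MW bin label (one of the
#'   11 bins of [mw_bins()])
#' @param range numeric `c(lo, hi)` in kD
#' @return list: `common`, `only_a`, `only_b` (id vectors) and their counts
#'   `n_common`, `n_only_a`, `n_only_b`
#' @export
set_overlap_mw <- function(set_a, set_b, mw, range = c(3.5, 20)) {
  bins <- mw_bins()
  bad <- setdiff(unique(mw), bins$label)
  if (length(bad)) .stopf("unknown MW bin label: %s", bad[1])
  ok_bins <- bins$label[bins$lo >= range[1] & bins$hi <= range[2]]
  keep <- names(mw)[mw %in% ok_bins]
  a <- intersect(set_a, keep)
  b <- intersect(set_b, keep)
  list(common = intersect(a, b), only_a = setdiff(a, b),
       only_b = setdiff(b, a),
       n_common = length(intersect(a, b)),
       n_only_a = length(setdiff(a, b)), n_only_b = length(setdiff(b, a)))
}
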