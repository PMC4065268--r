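# Two-step normalization: within-array intensity-dependent loess on M, then
# between-array quantile normalization. The loess and quantile engines are
# limma's (loessFit, normalizeQuantiles); this module fixes the channel
# conventions and the reconstruction of per-channel intensities.

#' M/A transform of one two-color array
#'
#' Channel order is fixed by dye label: M = log2(Cy5) - log2(Cy3),
#' A = (log2 Cy5 + log2 Cy3) / 2.
#'
#' @param em ExpressionMatrix
#' @param array_id array to transform (must have exactly two channels)
#' @return list of class `MAPair`: `M`, `A` (named by probe), `array_id`,
#'   `channels` (sample ids of the Cy5 and Cy3 columns)
#' @export
ma_transform <- function(em, array_id) {
  s <- em$samples[em$samples$array_id == array_id, ]
  if (nrow(s) != 2L)
    .stopf("array '%s' has %d channels; exactly 2 required", array_id, nrow(s))
  cy5 <- s$sample_id[s$channel == "Cy5"]
  cy3 <- s$sample_id[s$channel == "Cy3"]
  if (length(cy5) != 1L || length(cy3) != 1L)
    .stopf("array '%s' must have one Cy5 and one Cy3 channel", array_id)
  l5 <- log2(em$values[, cy5])
  l3 <- log2(em$values[, cy3])
  structure(list(M = l5 - l3, A = (l5 + l3) / 2, array_id = array_id,
                 channels = c(Cy5 = cy5, Cy3 = cy3)),
            class = "MAPair")
}

#' Invert an M/A pair back to the two channel intensities
#'
#' @param ma an `MAPair`
#' @return matrix with columns `Cy5`, `Cy3` of linear intensities
#' @export
ma_invert <- function(ma) {
  cbind(Cy5 = 2^(ma$A + ma$M / 2), Cy3 = 2^(ma$A - ma$M / 2))
}

#' Within-array loess correction of M on A
#'
#' Subtracts a locally weighted regression fit of M on A (tricube weights,
#' robustifying iterations), removing smooth intensity-dependent dye bias.
#' A is unchanged.
#'
#' @param ma an `MAPair`
#' @param span loess span (fraction of probes in each local window)
#' @param iterations robustifying iterations passed to the fitter
#' @return corrected `MAPair`
#' @export
within_array_loess <- function(ma, span = 0.5, iterations = 4) {
  if (length(ma$M) < 50L)
    .stopf("loess fit needs >= 50 probes (%d given); skip the within-array step instead",
           length(ma$M))
  fit <- limma::loessFit(ma$M, ma$A, span = span, iterations = iterations)
  out <- ma
  out$M <- ma$M - fit$fitted
  out
}

#' Between-array quantile normalization
#'
#' Forces every sample column to the common distribution given by the
#' across-column mean of sorted values (rank-mean quantile normalization;
#' ties share the mean of their positions' reference values). Operates on
#' the matrix values as given.
#'
#' @param em ExpressionMatrix
#' @return ExpressionMatrix with normalized values
#' @export
between_array_quantile <- function(em) {
  if (ncol(em$values) < 2L) {
    .warnf("single sample column: quantile normalization is the identity")
    return(em)
  }
  v <- limma::normalizeQuantiles(em$values, ties = TRUE)
  dimnames(v) <- dimnames(em$values)
  out <- em
  out$values <- v
  out
}

#' Scale columns to a common 75th percentile
#'
#' The literal "quartile" reading of between-array scaling: every column is
#' multiplied so its upper quartile equals the geometric mean of the
#' columns' upper quartiles.
#'
#' @param em ExpressionMatrix
#' @return scaled ExpressionMatrix
#' @export
between_array_q75 <- function(em) {
  q <- apply(em$values, 2, stats::quantile, probs = 0.75, names = FALSE)
  target <- 2^mean(log2(q))
  out <- em
  out$values <- sweep(em$values, 2, target / q, `*`)
  out
}

#' Full two-step normalization of an experiment
#'
#' Per array: M/A transform, loess correction of M on A, reconstruction of
#' the two channel intensities from (A, corrected M); then between-array
#' alignment of all columns, by rank-mean quantile normalization (default)
#' or 75th-percentile scaling.
#'
#' @param em ExpressionMatrix (raw linear intensities)
#' @param method between-array method, `"quantile"` or `"q75"`
#' @param span within-array loess span
#' @return normalized ExpressionMatrix
#' @export
normalize_experiment <- function(em, method = c("quantile", "q75"),
                                 span = 0.5) {
  method <- match.arg(method)
  out <- em
  for (aid in unique(em$samples$array_id)) {
    ma <- ma_transform(em, aid)
    ma <- within_array_loess(ma, span = span)
    ch <- ma_invert(ma)
    out$values[, ma$channels["Cy5"]] <- ch[, "Cy5"]
    out$values[, ma$channels["Cy3"]] <- ch[, "Cy3"]
  }
  if (method == "quantile") between_array_quantile(out) else between_array_q75(out)
}
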