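# Shared data model and TSV readers/writers.
#
# All tabular formats are tab-separated UTF-8 with '.' decimal. Writers emit a
# fixed column order so that read(write(x)) reproduces x exactly on the
# textual representation.

#' Construct an ExpressionMatrix
#'
#' Container for probe x sample linear fluorescence intensities with sample
#' metadata and probe annotation, the shared currency of the pipeline.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids); all intensities must be > 0
#' @param samples data.frame with columns `sample_id`, `array_id`, `channel`,
#'   `stage`, `genotype`, `tissue`, `replicate`; one row per matrix column
#' @param annotation data.frame with columns `probe_id`, `gene_id`,
#'   `is_negative_control`, `tf_family`; one row per matrix probe.
#'   Negative-control probes must have no gene id.
#' @return an object of class `ExpressionMatrix`
#' @export
expression_matrix <- function(values, samples, annotation) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    if (nrow(values) > 0) .stopf("matrix must have probe-id rownames")
    rownames(values) <- character(0)
  }
  if (nrow(values) > 0 && anyDuplicated(rownames(values)))
    .stopf("duplicate probe id: %s",
           rownames(values)[duplicated(rownames(values))][1])
  if (ncol(values) > 0 && is.null(colnames(values)))
    .stopf("matrix must have sample-id colnames")
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    .stopf("non-positive intensity at probe '%s', sample '%s'",
           rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]])
  samples <- as.data.frame(samples)
  missing_cols <- setdiff(.SAMPLE_COLS, names(samples))
  if (length(missing_cols))
    .stopf("sample metadata lacks column(s): %s",
           paste(missing_cols, collapse = ", "))
  samples <- samples[, .SAMPLE_COLS]
  if (!identical(as.character(samples$sample_id), colnames(values) %||% character(0)))
    .stopf("sample metadata rows must match matrix columns in order")
  key <- paste(samples$array_id, samples$channel)
  if (anyDuplicated(key))
    .stopf("duplicate (array id, channel): %s", key[duplicated(key)][1])
  annotation <- as.data.frame(annotation)
  if (!"tf_family" %in% names(annotation)) annotation$tf_family <- NA_character_
  missing_cols <- setdiff(.PROBE_COLS, names(annotation))
  if (length(missing_cols))
    .stopf("probe annotation lacks column(s): %s",
           paste(missing_cols, collapse = ", "))
  annotation <- annotation[, .PROBE_COLS]
  if (!identical(as.character(annotation$probe_id), rownames(values) %||% character(0)))
    .stopf("probe annotation rows must match matrix probes in order")
  nc <- annotation$is_negative_control
  if (any(nc & !is.na(annotation$gene_id)))
    .stopf("negative-control probes must have no gene id (probe '%s')",
           annotation$probe_id[nc & !is.na(annotation$gene_id)][1])
  rownames(samples) <- NULL
  rownames(annotation) <- NULL
  structure(list(values = values, samples = samples, annotation = annotation),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples (%d negative controls)\n",
              nrow(x$values), ncol(x$values), sum(x$annotation$is_negative_control)))
  cat("stages:", paste(unique(x$samples$stage), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Select sample ids by metadata
#'
#' @param em ExpressionMatrix
#' @param stage,genotype,tissue optional filters; `NULL` means no restriction
#' @return character vector of sample ids
#' @export
sample_ids <- function(em, stage = NULL, genotype = NULL, tissue = NULL) {
  s <- em$samples
  keep <- rep(TRUE, nrow(s))
  if (!is.null(stage)) keep <- keep & s$stage %in% stage
  if (!is.null(genotype)) keep <- keep & s$genotype %in% genotype
  if (!is.null(tissue)) keep <- keep & s$tissue %in% tissue
  s$sample_id[keep]
}

#' Per-probe mean log2 intensity of a sample group
#'
#' @param em ExpressionMatrix
#' @param ids sample ids to average over
#' @return named numeric vector (probe id -> mean log2 intensity)
#' @export
mean_log2 <- function(em, ids) {
  if (!all(ids %in% colnames(em$values)))
    .stopf("unknown sample id: %s", setdiff(ids, colnames(em$values))[1])
  rowMeans(log2(em$values[, ids, drop = FALSE]))
}

.fmt_num <- function(x) formatC(x, format = "g", digits = 12)

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

#' Write an ExpressionMatrix to TSV
#'
#' Writes three files: `path` (probe_id + one column per sample), plus the
#' companion metadata files `<path minus .tsv>.samples.tsv` and
#' `<path minus .tsv>.probes.tsv`.
#'
#' @param em ExpressionMatrix
#' @param path path of the values TSV
#' @return invisibly, the three paths written
#' @export
write_matrix <- function(em, path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  base <- sub("\\.tsv$", "", path)
  df <- data.frame(probe_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  sp <- paste0(base, ".samples.tsv")
  pp <- paste0(base, ".probes.tsv")
  .write_tsv(em$samples, sp)
  .write_tsv(em$annotation, pp)
  invisible(c(path, sp, pp))
}

#' Read an ExpressionMatrix written by [write_matrix()]
#'
#' @param path path of the values TSV; the companion `.samples.tsv` and
#'   `.probes.tsv` files must sit beside it
#' @return ExpressionMatrix
#' @export
read_matrix <- function(path) {
  base <- sub("\\.tsv$", "", path)
  sp <- paste0(base, ".samples.tsv")
  pp <- paste0(base, ".probes.tsv")
  for (p in c(path, sp, pp))
    if (!file.exists(p)) .stopf("missing file: %s", p)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) > 0 && anyDuplicated(df$probe_id))
    .stopf("duplicate probe id in %s: %s", path,
           df$probe_id[duplicated(df$probe_id)][1])
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$probe_id
  samples <- utils::read.delim(sp, stringsAsFactors = FALSE,
                               colClasses = c(replicate = "integer"))
  ann <- utils::read.delim(pp, stringsAsFactors = FALSE,
                           colClasses = c(is_negative_control = "logical",
                                          gene_id = "character",
                                          tf_family = "character"))
  expression_matrix(values, samples, ann)
}

#' Read a curated gene list (one gene id per line)
#'
#' Order is preserved; duplicates are collapsed with a warning.
#'
#' @param path text file, one non-empty gene id per line
#' @return character vector of gene ids
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  if (length(x) == 0L) .stopf("empty gene list: %s", path)
  if (anyDuplicated(x)) {
    .warnf("%d duplicate id(s) collapsed in %s", sum(duplicated(x)), path)
    x <- x[!duplicated(x)]
  }
  x
}

#' Read a gene-set map (two-column TSV: set id, gene id)
#'
#' @param path TSV with columns `set_id` and `gene_id` (header required)
#' @return named list: set id -> character vector of gene ids
#' @export
read_gene_set_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) .stopf("empty gene-set map: %s", path)
  if (!all(c("set_id", "gene_id") %in% names(df)))
    .stopf("gene-set map needs columns set_id, gene_id: %s", path)
  if (any(!nzchar(df$gene_id) | is.na(df$gene_id)))
    .stopf("empty gene id in gene-set map: %s", path)
  m <- split(df$gene_id, df$set_id)
  lapply(m, unique)
}

#' Write a protein abundance table (long TSV)
#'
#' @param prot data.frame as returned by [generate_protein_table()]
#' @param path output path
#' @export
write_protein_table <- function(prot, path) {
  cols <- c("protein_id", "gene_id", "mw_fraction", "stage", "replicate",
            "abundance")
  .write_tsv(prot[, cols], path)
  invisible(path)
}

#' Read a protein abundance table (long TSV)
#'
#' Columns: `protein_id`, `gene_id`, `mw_fraction`, `stage`, `replicate`,
#' `abundance` (linear, > 0). (protein, stage, replicate) must be unique.
#'
#' @param path TSV path
#' @return data.frame
#' @export
read_protein_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(stage = "character"))
  if (nrow(df) == 0L) .stopf("empty protein table: %s", path)
  need <- c("protein_id", "gene_id", "mw_fraction", "stage", "replicate",
            "abundance")
  if (!all(need %in% names(df)))
    .stopf("protein table needs columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(df$abundance) | df$abundance <= 0))
    .stopf("non-positive protein abundance (row %d)",
           which(!is.finite(df$abundance) | df$abundance <= 0)[1])
  key <- paste(df$protein_id, df$stage, df$replicate)
  if (anyDuplicated(key))
    .stopf("duplicate (protein, sample): %s", key[duplicated(key)][1])
  df[, need]
}
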