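#' Construct an expression dataset
#'
#' Container for an entities x samples value matrix with entity metadata
#' (id, type in miRNA/mRNA) and sample metadata (time-point, replicate,
#' control flag). Entity ids and (time-point, replicate) pairs must be
#' unique and values must be complete.
#'
#' @param values numeric matrix, entities in rows, samples in columns.
#' @param entity_meta data.frame with columns `id`, `type`.
#' @param sample_meta data.frame with columns `sample_id`, `timepoint`,
#'   `replicate`, `control`.
#' @return object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(values, entity_meta, sample_meta) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_invalid_input("values must be numeric")
  if (anyNA(values)) stop_invalid_input("values contain missing entries")
  if (anyDuplicated(entity_meta$id))
    stop_invalid_input(sprintf("duplicate entity id: %s",
                               entity_meta$id[duplicated(entity_meta$id)][1]))
  if (!all(entity_meta$type %in% c("miRNA", "mRNA")))
    stop_invalid_input("entity type must be miRNA or mRNA")
  if (nrow(values) != nrow(entity_meta))
    stop_invalid_input("values rows do not match entity_meta")
  if (ncol(values) != nrow(sample_meta))
    stop_invalid_input("values columns do not match sample_meta")
  key <- paste(sample_meta$timepoint, sample_meta$replicate)
  if (anyDuplicated(key))
    stop_invalid_input("duplicate (time-point, replicate) pair in sample_meta")
  rownames(values) <- entity_meta$id
  colnames(values) <- sample_meta$sample_id
  structure(list(values = values,
                 entity_meta = as.data.frame(entity_meta, stringsAsFactors = FALSE),
                 sample_meta = as.data.frame(sample_meta, stringsAsFactors = FALSE)),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d entities (%d miRNA, %d mRNA) x %d samples\n",
              nrow(x$values), sum(x$entity_meta$type == "miRNA"),
              sum(x$entity_meta$type == "mRNA"), ncol(x$values)))
  cat(sprintf("time-points: %s\n",
              paste(unique(x$sample_meta$timepoint), collapse = ", ")))
  invisible(x)
}

#' Entity types as a named vector
#' @param dataset an `ExpressionDataset`.
#' @return named character vector, id -> type.
#' @export
entity_types <- function(dataset) {
  setNames(dataset$entity_meta$type, dataset$entity_meta$id)
}

#' Write an expression dataset as TSV files
#'
#' The value matrix goes to `<prefix>_values.tsv` (first column `entity_id`,
#' header row of sample ids), entity metadata to `<prefix>_entities.tsv` and
#' sample metadata to `<prefix>_samples.tsv`.
#'
#' @param dataset an `ExpressionDataset`.
#' @param prefix path prefix for the three files.
#' @return character vector of the three paths, invisibly.
#' @export
write_expression_tsv <- function(dataset, prefix) {
  vp <- paste0(prefix, "_values.tsv")
  ep <- paste0(prefix, "_entities.tsv")
  sp <- paste0(prefix, "_samples.tsv")
  df <- data.frame(entity_id = rownames(dataset$values), dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, vp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$entity_meta, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$sample_meta, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(values = vp, entities = ep, samples = sp))
}

#' Read an expression dataset from TSV files
#'
#' Counterpart of [write_expression_tsv()]. Rejects duplicate entity ids and
#' non-numeric cells with a parse error naming the offender; tolerates
#' Windows line endings.
#'
#' @param prefix path prefix used when writing.
#' @return an `ExpressionDataset`.
#' @export
read_expression_tsv <- function(prefix) {
  vp <- paste0(prefix, "_values.tsv")
  ep <- paste0(prefix, "_entities.tsv")
  sp <- paste0(prefix, "_samples.tsv")
  for (p in c(vp, ep, sp))
    if (!file.exists(p)) stop_configuration(sprintf("missing input file: %s", p))
  df <- tryCatch(
    read.delim(vp, check.names = FALSE, stringsAsFactors = FALSE,
               colClasses = NA),
    error = function(e) stop_parse(sprintf("cannot parse %s: %s", vp, conditionMessage(e))))
  if (ncol(df) < 2) stop_parse(sprintf("%s has no sample columns", vp))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    line <- which(ids == dup)[2] + 1L  # +1 for the header row
    stop_parse(sprintf("duplicate entity id '%s' at line %d of %s", dup, line, vp))
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    suppressWarnings(num <- as.numeric(vals[[j]]))
    if (anyNA(num) && !anyNA(vals[[j]])) {
      bad <- which(is.na(num))[1] + 1L
      stop_parse(sprintf("non-numeric cell at line %d, column '%s' of %s",
                         bad, names(vals)[j], vp))
    }
    vals[[j]] <- num
  }
  values <- as.matrix(vals)
  rownames(values) <- ids
  entity_meta <- read.delim(ep, stringsAsFactors = FALSE)
  sample_meta <- read.delim(sp, stringsAsFactors = FALSE)
  sample_meta$control <- as.logical(sample_meta$control)
  entity_meta <- entity_meta[match(ids, entity_meta$id), , drop = FALSE]
  expression_dataset(values, entity_meta, sample_meta)
}

#' Subset the non-control samples of a dataset
#'
#' @param dataset an `ExpressionDataset`.
#' @return value matrix restricted to non-control samples, in the dataset's
#'   column order.
#' @export
noncontrol_values <- function(dataset) {
  dataset$values[, !dataset$sample_meta$control, drop = FALSE]
}
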