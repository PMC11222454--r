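#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction, the multiplicity correction used
#' throughout the pipeline (DE calling at adjusted p < 0.05).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop_invalid_input("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Welch-test stand-in differential expression
#'
#' Per-entity Welch two-sample comparison of one time-point's replicates
#' against the control replicates, with BH correction applied separately
#' within each entity type (miRNA and mRNA are analysed as separate
#' families). This is a stand-in DE engine for the simulated Gaussian data;
#' externally produced DE tables can be supplied to the pipeline instead.
#' The effect column reported as `log2fc` is the mean group difference on
#' the (already log-like) simulated scale.
#'
#' @param dataset an `ExpressionDataset` containing control samples.
#' @param timepoint time-point label to test.
#' @param alpha adjusted-p cut-off for the DE flag (default 0.05).
#' @return a DE table: one row per entity with columns `entity_id`,
#'   `entity_type`, `timepoint`, `log2fc`, `p`, `p_adjusted`, `direction`,
#'   `de` (logical flag).
#' @export
stand_in_de_test <- function(dataset, timepoint, alpha = 0.05) {
  sm <- dataset$sample_meta
  ctrl <- sm$control
  if (!any(ctrl)) stop_configuration("dataset has no control samples")
  grp <- !ctrl & sm$timepoint == timepoint
  if (!any(grp)) stop_configuration(sprintf("no samples at time-point '%s'", timepoint))
  if (sum(grp) < 2 || sum(ctrl) < 2)
    stop_configuration("need >= 2 replicates per group for the Welch test")
  if (alpha < 0 || alpha > 1) stop_invalid_parameter("alpha must be in [0, 1]")

  x <- dataset$values[, grp, drop = FALSE]
  y <- dataset$values[, ctrl, drop = FALSE]
  n <- nrow(x)
  p <- numeric(n); fc <- numeric(n)
  for (i in seq_len(n)) {
    fc[i] <- mean(x[i, ]) - mean(y[i, ])
    if (var(x[i, ]) == 0 && var(y[i, ]) == 0) {
      # no within-group variability: identical means carry no evidence
      p[i] <- if (isTRUE(all.equal(mean(x[i, ]), mean(y[i, ])))) 1 else 0
    } else {
      p[i] <- t.test(x[i, ], y[i, ])$p.value
    }
  }
  type <- dataset$entity_meta$type
  padj <- numeric(n)
  for (ty in unique(type))
    padj[type == ty] <- bh_adjust(p[type == ty])
  data.frame(entity_id = dataset$entity_meta$id,
             entity_type = type,
             timepoint = timepoint,
             log2fc = fc,
             p = p,
             p_adjusted = padj,
             direction = ifelse(fc >= 0, "up", "down"),
             de = padj < alpha,
             stringsAsFactors = FALSE)
}

#' Stand-in DE across all time-points
#'
#' Runs [stand_in_de_test()] at every non-control time-point and binds the
#' rows into one DE table (one row per entity and time-point).
#'
#' @inheritParams stand_in_de_test
#' @return combined DE table.
#' @export
de_all_timepoints <- function(dataset, alpha = 0.05) {
  tps <- unique(dataset$sample_meta$timepoint[!dataset$sample_meta$control])
  do.call(rbind, lapply(tps, function(t) stand_in_de_test(dataset, t, alpha)))
}

#' Row-wise z-score normalisation
#'
#' Centres and scales each row to mean 0 and standard deviation 1, using the
#' population (1/n) standard deviation. Constant rows are a degenerate-row
#' error naming the entity.
#'
#' @param x numeric matrix with >= 2 columns.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop_invalid_input("need >= 2 columns to z-score")
  mu <- rowMeans(x)
  centred <- x - mu
  sdev <- sqrt(rowMeans(centred^2))
  if (any(sdev == 0)) {
    bad <- rownames(x)[which(sdev == 0)[1]]
    stop_degenerate_row(sprintf("constant row cannot be z-scored: %s",
                                if (is.null(bad)) "<unnamed>" else bad))
  }
  centred / sdev
}

#' Assemble the per-time-point model input
#'
#' The variables entering the Bayesian network at a time-point are the DE
#' miRNAs at that time-point united with the bi-clustered mRNAs merged for
#' that time-point. Their expression over all non-control samples (15 in the
#' default design) is row z-scored.
#'
#' @param de a DE table as from [stand_in_de_test()] (needs columns
#'   `entity_id`, `entity_type`, `timepoint`, `de`).
#' @param biclustered named list of per-time-point mRNA id sets (see
#'   [merge_per_timepoint()]).
#' @param timepoint time-point label.
#' @param dataset the `ExpressionDataset` supplying expression values.
#' @return object of class `ModelInput`: z-scored `values` (entities x
#'   non-control samples), `types` named vector, `timepoint`.
#' @export
select_model_variables <- function(de, biclustered, timepoint, dataset) {
  if (!timepoint %in% de$timepoint)
    stop_invalid_parameter(sprintf("time-point '%s' absent from DE table", timepoint))
  mirnas <- unique(de$entity_id[de$timepoint == timepoint & de$de &
                                  de$entity_type == "miRNA"])
  mrnas <- unique(as.character(biclustered[[timepoint]]))
  wanted <- c(mirnas, mrnas)
  wanted <- wanted[wanted %in% rownames(dataset$values)]
  if (length(wanted) == 0)
    stop_empty_model(sprintf("no model variables selected at '%s'", timepoint))
  vals <- noncontrol_values(dataset)[wanted, , drop = FALSE]
  structure(list(values = zscore_rows(vals),
                 types = entity_types(dataset)[wanted],
                 timepoint = timepoint),
            class = "ModelInput")
}

#' Write / read a DE table as TSV
#'
#' @param de DE table.
#' @param path file path.
#' @return `path` / the DE table.
#' @export
write_de_tsv <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) {
  if (!file.exists(path)) stop_configuration(sprintf("missing DE table: %s", path))
  de <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("entity_id", "entity_type", "timepoint", "p_adjusted")
  if (!all(need %in% names(de)))
    stop_parse(sprintf("DE table lacks columns: %s",
                       paste(setdiff(need, names(de)), collapse = ", ")))
  if (!"de" %in% names(de)) de$de <- de$p_adjusted < 0.05
  de$de <- as.logical(de$de)
  de
}
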