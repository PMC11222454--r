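# End-to-end orchestration: DE -> bi-clustering -> per-time-point model
# input -> bootstrap structure learning -> quartile filter -> statistics ->
# prioritisation, with every stage's output persisted and a run manifest.

#' Pipeline configuration
#'
#' Houses the pipeline constants: DE cut-off 0.05, 10% bi-cluster overlap,
#' 1000 bootstrap replicates, highest-quartile (0.75) edge retention and the
#' nt 2-8 seed region.
#'
#' @param outdir output directory (created if absent).
#' @param timepoints ordered time-point labels.
#' @param alpha DE adjusted-p cut-off.
#' @param bicluster_overlap maximum bi-cluster gene overlap fraction.
#' @param response_threshold bi-clustering response threshold.
#' @param B bootstrap replicates.
#' @param quartile strength-retention quantile.
#' @param seed_region 1-based inclusive seed positions (fixed at 2:8).
#' @param rng_seed master seed; each stochastic stage derives its own
#'   stream as `rng_seed * 1000 + stage index` so stages are reproducible
#'   independently of execution order.
#' @param strength_mode arc-strength convention, see [learn_config()].
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(outdir = tempfile("epimirnet_run_"),
                            timepoints = default_timepoints(),
                            alpha = 0.05,
                            bicluster_overlap = 0.10,
                            response_threshold = 2,
                            B = 1000L,
                            quartile = 0.75,
                            seed_region = 2:8,
                            rng_seed = 1L,
                            strength_mode = "directed") {
  if (anyDuplicated(timepoints)) stop_invalid_parameter("duplicate time-point labels")
  if (alpha < 0 || alpha > 1) stop_invalid_parameter("alpha must be in [0, 1]")
  if (bicluster_overlap < 0 || bicluster_overlap > 1)
    stop_invalid_parameter("bicluster_overlap must be in [0, 1]")
  if (B < 1) stop_invalid_parameter("B must be >= 1")
  if (quartile <= 0 || quartile >= 1) stop_invalid_parameter("quartile must be in (0, 1)")
  if (!identical(as.integer(seed_region), 2:8))
    stop_invalid_parameter("seed_region is fixed to nt 2-8")
  structure(list(outdir = outdir, timepoints = as.character(timepoints),
                 alpha = alpha, bicluster_overlap = bicluster_overlap,
                 response_threshold = response_threshold, B = as.integer(B),
                 quartile = quartile, seed_region = 2:8,
                 rng_seed = as.integer(rng_seed),
                 strength_mode = strength_mode),
            class = "PipelineConfig")
}

stage_seed <- function(config, stage_index) {
  (config$rng_seed * 1000L + as.integer(stage_index)) %% .Machine$integer.max
}

#' Run the full inference pipeline
#'
#' Executes DE calling (the Welch stand-in, or a supplied DE table),
#' bi-clustering, per-time-point variable selection and z-scoring, bootstrap
#' hill-climbing structure learning, quartile filtering, network statistics
#' and the miRNA prioritisation cascade. Every stage's tables are written
#' under `config$outdir` and a JSON manifest records the package version,
#' seeds and configuration. Reruns with the same config are reproducible.
#'
#' @param dataset an `ExpressionDataset` (with control samples unless `de`
#'   is supplied).
#' @param config a [pipeline_config()].
#' @param de optional externally produced DE table (see [read_de_tsv()]);
#'   when `NULL` the stand-in Welch test is used.
#' @param orthology,rat_seqs,human_seqs optional prioritisation inputs, see
#'   [build_mirna_records()].
#' @param annotation optional list of resource tables passed on to
#'   [annotate_resources()] (elements `prediction`, `validated`, `iclip`,
#'   `human_de_mirna`, `human_de_mrna`).
#' @return a result bundle: `de`, `biclusters`, `model_inputs`, `networks`,
#'   `stats`, `edge_type_counts`, `beta`, `mti`, `records`, `overlaps`,
#'   `manifest`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(), de = NULL,
                         orthology = NULL, rat_seqs = NULL, human_seqs = NULL,
                         annotation = NULL) {
  if (!inherits(dataset, "ExpressionDataset"))
    stop_configuration("dataset must be an ExpressionDataset")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  fail <- function(stage, e)
    stop_configuration(sprintf("pipeline stage '%s' failed: %s",
                               stage, conditionMessage(e)))

  # 1. differential expression
  de <- tryCatch({
    if (is.null(de)) de_all_timepoints(dataset, config$alpha) else de
  }, error = function(e) fail("differential expression", e))
  write_de_tsv(de, file.path(config$outdir, "de_table.tsv"))

  # 2. bi-clustering
  bic <- tryCatch(
    bicluster_pipeline(dataset, de, config$response_threshold,
                       config$bicluster_overlap, seed = stage_seed(config, 2L)),
    error = function(e) fail("bi-clustering", e))
  write_biclusters_tsv(bic$modules, file.path(config$outdir, "biclusters.tsv"))
  for (t in names(bic$merged))
    writeLines(bic$merged[[t]],
               file.path(config$outdir, sprintf("bicluster_mrnas_%s.txt", t)))

  # 3-4. per-time-point model input and structure learning
  networks <- list(); model_inputs <- list()
  for (k in seq_along(config$timepoints)) {
    t <- config$timepoints[k]
    mi <- tryCatch(select_model_variables(de, bic$merged, t, dataset),
                   error = function(e) fail(sprintf("model input (%s)", t), e))
    cfg <- learn_config(B = config$B, rng_seed = stage_seed(config, 10L + k),
                        quartile = config$quartile,
                        strength_mode = config$strength_mode)
    net <- tryCatch(learn_timepoint_network(mi, cfg),
                    error = function(e) fail(sprintf("structure learning (%s)", t), e))
    model_inputs[[t]] <- mi
    networks[[t]] <- net
    write_network(net, file.path(config$outdir, sprintf("network_%s.tsv", t)),
                  "edge-tsv")
    write_network(net, file.path(config$outdir, sprintf("network_%s.graphml", t)),
                  "graphml")
  }

  # 5. network statistics and overlaps
  stats <- tryCatch(do.call(rbind, lapply(networks, degree_stats)),
                    error = function(e) fail("network statistics", e))
  rownames(stats) <- NULL
  write.table(stats, file.path(config$outdir, "node_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  edge_type_counts <- vapply(networks, classify_edges, integer(4))
  beta <- vapply(networks, function(n) suppressWarnings(beta_index(n)), numeric(1))
  overlaps <- list(
    edges = overlap_counts(lapply(networks, edge_keys)),
    edges_pairwise = pairwise_overlap(lapply(networks, edge_keys)),
    mirnas = overlap_counts(split(de$entity_id[de$de & de$entity_type == "miRNA"],
                                  de$timepoint[de$de & de$entity_type == "miRNA"])),
    mrnas = overlap_counts(bic$merged))
  write.table(overlaps$edges, file.path(config$outdir, "edge_overlap_upset.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # 6. prioritisation
  mti <- tryCatch(clean_symbols(extract_mti(networks)),
                  error = function(e) fail("MTI extraction", e))
  mirna_universe <- unique(de$entity_id[de$de & de$entity_type == "miRNA"])
  records <- build_mirna_records(mirna_universe, mti, config$timepoints,
                                 orthology, rat_seqs, human_seqs)
  records <- shortlist_cascade(records)
  if (!is.null(annotation))
    mti <- annotate_resources(mti, annotation$prediction, annotation$validated,
                              annotation$iclip, annotation$human_de_mirna,
                              annotation$human_de_mrna, orthology)
  mti_out <- mti
  mti_out$timepoints <- vapply(mti_out$timepoints, paste, "", collapse = ";")
  write.table(mti_out, file.path(config$outdir, "mti_records.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(records, file.path(config$outdir, "mirna_records.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "epimirnet",
    version = as.character(packageVersion("epimirnet")),
    r_version = R.version.string,
    rng_seed = config$rng_seed,
    stage_seeds = setNames(as.list(c(stage_seed(config, 2L),
                                     vapply(seq_along(config$timepoints),
                                            function(k) stage_seed(config, 10L + k),
                                            numeric(1)))),
                           c("biclustering",
                             paste0("learning_", config$timepoints))),
    config = unclass(config[setdiff(names(config), "outdir")]),
    stage_counts = attr(records, "stage_counts"),
    timestamp_utc = format(Sys.time(), tz = "UTC", "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(de = de, biclusters = bic, model_inputs = model_inputs,
       networks = networks, stats = stats,
       edge_type_counts = edge_type_counts, beta = beta, mti = mti,
       records = records, overlaps = overlaps, manifest = manifest)
}
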