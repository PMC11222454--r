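#' Default time-point labels of the epileptogenesis study design
#'
#' Five post-insult sampling times: 24 h, 72 h and 10 days after the insult,
#' the day of the first spontaneous seizure (DOFS), and chronic epilepsy.
#' Controls form a sixth, unstimulated condition.
#'
#' @export
default_timepoints <- function() c("24h", "72h", "10d", "DOFS", "Chronic")

#' Generate a planted temporal regulatory scenario
#'
#' Draws a ground-truth directed regulatory network over miRNA and mRNA
#' nodes. Edges respect a random topological order (so every per-time-point
#' active edge set is acyclic by construction), miRNA->mRNA edges are
#' predominantly repressive (negative coefficients), and a fraction of edges
#' is active only at a subset of time-points. A fraction of nodes receives a
#' baseline shift at one to three time-points relative to control, so that
#' downstream differential-expression calling has planted positives.
#'
#' @param n_mirna,n_mrna number of miRNA / mRNA nodes (>= 1).
#' @param edge_density fraction of admissible ordered pairs that carry an
#'   edge, in `[0, 1]`.
#' @param frac_repressive probability that a miRNA->mRNA edge gets a negative
#'   coefficient.
#' @param frac_timepoint_specific fraction of edges active only at a proper
#'   subset of time-points.
#' @param seed integer RNG seed; identical seeds give identical scenarios.
#' @param coef_range magnitude range of edge coefficients.
#' @param noise_sd residual standard deviation of every node.
#' @param frac_de fraction of nodes given a differential baseline shift.
#' @param de_shift baseline shift in units of `noise_sd`.
#' @param timepoints ordered time-point labels.
#' @param n_replicates,n_controls replicates per time-point and number of
#'   control samples.
#' @return an object of class `RegulatoryScenario`: node table, edge table
#'   (with per-edge active time-points), baseline matrix (nodes x
#'   time-points plus a Control column), per-node noise SDs and the design
#'   constants.
#' @export
generate_scenario <- function(n_mirna, n_mrna,
                              edge_density = 0.05,
                              frac_repressive = 0.8,
                              frac_timepoint_specific = 0.5,
                              seed = 1L,
                              coef_range = c(0.5, 1),
                              noise_sd = 1,
                              frac_de = 0.6,
                              de_shift = 5,
                              timepoints = default_timepoints(),
                              n_replicates = 3L,
                              n_controls = 3L) {
  if (length(n_mirna) != 1 || length(n_mrna) != 1 ||
      is.na(n_mirna) || is.na(n_mrna) || n_mirna < 1 || n_mrna < 1)
    stop_invalid_parameter("n_mirna and n_mrna must both be >= 1")
  for (f in c(edge_density, frac_repressive, frac_timepoint_specific, frac_de))
    if (is.na(f) || f < 0 || f > 1)
      stop_invalid_parameter("fractions must lie in [0, 1]")
  if (noise_sd < 0) stop_invalid_parameter("noise_sd must be non-negative")
  if (n_replicates < 1 || n_controls < 0)
    stop_invalid_parameter("n_replicates must be >= 1 and n_controls >= 0")
  if (anyDuplicated(timepoints) || "Control" %in% timepoints)
    stop_invalid_parameter("time-point labels must be unique and not 'Control'")

  set.seed(as.integer(seed))
  ids <- c(sprintf("miR_%02d", seq_len(n_mirna)),
           sprintf("gene_%03d", seq_len(n_mrna)))
  types <- c(rep("miRNA", n_mirna), rep("mRNA", n_mrna))
  nodes <- data.frame(id = ids, type = types, stringsAsFactors = FALSE)
  p <- nrow(nodes)
  tp <- as.character(timepoints)
  ntp <- length(tp)

  # a random topological order guarantees global (hence per-time-point)
  # acyclicity; miRNAs are placed upstream so that planted miRNA-mRNA
  # regulation flows miRNA -> mRNA, the direction miRNAs act in
  pos <- c(sample(which(types == "miRNA")), sample(which(types == "mRNA")))
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  from_idx <- pos[pairs[, 1]]
  to_idx <- pos[pairs[, 2]]
  n_edges <- round(edge_density * nrow(pairs))
  sel <- if (n_edges > 0) sort(sample.int(nrow(pairs), n_edges)) else integer(0)

  from <- ids[from_idx[sel]]
  to <- ids[to_idx[sel]]
  magnitude <- runif(length(sel), coef_range[1], coef_range[2])
  sign_vec <- ifelse(runif(length(sel)) < 0.5, -1, 1)
  is_mir_mrna <- types[from_idx[sel]] == "miRNA" & types[to_idx[sel]] == "mRNA"
  repress <- is_mir_mrna & runif(length(sel)) < frac_repressive
  sign_vec[repress] <- -1
  sign_vec[is_mir_mrna & !repress] <- 1
  coefficient <- magnitude * sign_vec

  active <- lapply(seq_along(sel), function(i) {
    if (runif(1) < frac_timepoint_specific && ntp > 1) {
      k <- sample.int(ntp - 1, 1)
      sort(sample.int(ntp, k))
    } else seq_len(ntp)
  })
  edges <- data.frame(from = from, to = to, coefficient = coefficient,
                      stringsAsFactors = FALSE)
  edges$active_timepoints <- lapply(active, function(ix) tp[ix])

  baseline <- matrix(0, p, ntp + 1,
                     dimnames = list(ids, c(tp, "Control")))
  n_de <- round(frac_de * p)
  de_nodes <- if (n_de > 0) sample.int(p, n_de) else integer(0)
  for (i in de_nodes) {
    k <- sample.int(min(3L, ntp), 1)
    at <- sample.int(ntp, k)
    baseline[i, at] <- sample(c(-1, 1), k, replace = TRUE) * de_shift * noise_sd
  }

  scenario <- structure(list(
    nodes = nodes,
    edges = edges,
    baseline = baseline,
    noise_sd = setNames(rep(noise_sd, p), ids),
    timepoints = tp,
    n_replicates = as.integer(n_replicates),
    n_controls = as.integer(n_controls),
    rng_seed = as.integer(seed)
  ), class = "RegulatoryScenario")
  validate_scenario(scenario)
  scenario
}

#' Construct a regulatory scenario explicitly
#'
#' Lower-level companion of [generate_scenario()] for building a scenario
#' from explicit node, edge and baseline specifications (planted networks in
#' examples and validation studies).
#'
#' @param nodes data.frame with columns `id`, `type` (miRNA/mRNA).
#' @param edges data.frame with columns `from`, `to`, `coefficient` and
#'   optionally `active_timepoints` (list column of label vectors; default
#'   all time-points).
#' @param baseline numeric matrix nodes x (timepoints, "Control"), or a
#'   single value recycled (default 0).
#' @param noise_sd per-node residual SD, scalar or named vector.
#' @param timepoints,n_replicates,n_controls,rng_seed design constants.
#' @return a validated `RegulatoryScenario`.
#' @export
regulatory_scenario <- function(nodes, edges = NULL, baseline = 0,
                                noise_sd = 1,
                                timepoints = default_timepoints(),
                                n_replicates = 3L, n_controls = 3L,
                                rng_seed = 1L) {
  nodes <- data.frame(id = as.character(nodes$id), type = as.character(nodes$type),
                      stringsAsFactors = FALSE)
  tp <- as.character(timepoints)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(0), to = character(0),
                        coefficient = numeric(0), stringsAsFactors = FALSE)
    edges$active_timepoints <- list()
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$active_timepoints))
      edges$active_timepoints <- rep(list(tp), nrow(edges))
  }
  if (length(baseline) == 1)
    baseline <- matrix(baseline, nrow(nodes), length(tp) + 1,
                       dimnames = list(nodes$id, c(tp, "Control")))
  if (length(noise_sd) == 1) noise_sd <- setNames(rep(noise_sd, nrow(nodes)), nodes$id)
  scenario <- structure(list(nodes = nodes, edges = edges, baseline = baseline,
                             noise_sd = noise_sd, timepoints = tp,
                             n_replicates = as.integer(n_replicates),
                             n_controls = as.integer(n_controls),
                             rng_seed = as.integer(rng_seed)),
                        class = "RegulatoryScenario")
  validate_scenario(scenario)
  scenario
}

#' Validate a regulatory scenario
#'
#' Checks node/edge referential integrity, absence of self-edges, positive
#' design counts and per-time-point acyclicity (by topological sort of every
#' active edge set).
#'
#' @param scenario a `RegulatoryScenario`.
#' @return the scenario, invisibly; errors on violation.
#' @export
validate_scenario <- function(scenario) {
  if (!inherits(scenario, "RegulatoryScenario"))
    stop_invalid_parameter("not a RegulatoryScenario")
  ids <- scenario$nodes$id
  if (anyDuplicated(ids)) stop_invalid_parameter("duplicate node ids")
  e <- scenario$edges
  if (nrow(e) > 0) {
    if (!all(e$from %in% ids) || !all(e$to %in% ids))
      stop_invalid_parameter("edge endpoint not among nodes")
    if (any(e$from == e$to)) stop_invalid_parameter("self-edges are not allowed")
    for (t in scenario$timepoints) {
      keep <- vapply(e$active_timepoints, function(a) t %in% a, logical(1))
      if (!is_acyclic_edgelist(e$from[keep], e$to[keep], ids))
        stop_invalid_parameter(sprintf("active edge set at %s is cyclic", t))
    }
  }
  if (any(scenario$noise_sd < 0)) stop_invalid_parameter("negative noise_sd")
  invisible(scenario)
}

# Kahn topological sort on an edge list; TRUE iff acyclic.
is_acyclic_edgelist <- function(from, to, ids) {
  indeg <- setNames(integer(length(ids)), ids)
  tab <- table(to)
  indeg[names(tab)] <- as.integer(tab)
  adj <- split(to, factor(from, levels = ids))
  queue <- ids[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  seen == length(ids)
}

topological_order <- function(scenario) {
  ids <- scenario$nodes$id
  e <- scenario$edges
  indeg <- setNames(integer(length(ids)), ids)
  if (nrow(e)) {
    tab <- table(e$to)
    indeg[names(tab)] <- as.integer(tab)
  }
  adj <- split(e$to, factor(e$from, levels = ids))
  queue <- ids[indeg == 0]
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(ids)) stop_invalid_parameter("scenario edges are cyclic")
  out
}

#' Simulate expression data from a planted scenario
#'
#' Linear-Gaussian structural-equation sampling: at each time-point, nodes
#' are evaluated in topological order as
#' `value = baseline(node, t) + sum(coefficient * parent) + N(0, noise_sd)`,
#' using only the edges active at that time-point. Control samples use the
#' control baselines with every planted edge inactive. The sampler is
#' self-consistent with the Gaussian BIC scorer of the network-learning
#' stage.
#'
#' @param scenario a valid `RegulatoryScenario`.
#' @param n_replicates optional override of the per-time-point replicate
#'   count (used for large-n covariance checks).
#' @return an [expression_dataset()] with
#'   `n_timepoints * n_replicates + n_controls` samples.
#' @export
simulate_expression <- function(scenario, n_replicates = NULL) {
  validate_scenario(scenario)
  set.seed(scenario$rng_seed)
  nrep <- if (is.null(n_replicates)) scenario$n_replicates else as.integer(n_replicates)
  ids <- scenario$nodes$id
  ord <- topological_order(scenario)

  sim_condition <- function(label, n, edges_active) {
    vals <- matrix(0, length(ids), n, dimnames = list(ids, NULL))
    for (v in ord) {
      mu <- rep(scenario$baseline[v, label], n)
      if (nrow(edges_active)) {
        pe <- edges_active[edges_active$to == v, , drop = FALSE]
        for (k in seq_len(nrow(pe)))
          mu <- mu + pe$coefficient[k] * vals[pe$from[k], ]
      }
      sdv <- scenario$noise_sd[[v]]
      vals[v, ] <- mu + if (sdv > 0) rnorm(n, 0, sdv) else 0
    }
    vals
  }

  blocks <- list(); meta <- list()
  for (t in scenario$timepoints) {
    keep <- vapply(scenario$edges$active_timepoints, function(a) t %in% a, logical(1))
    vals <- sim_condition(t, nrep, scenario$edges[keep, , drop = FALSE])
    colnames(vals) <- sprintf("%s_rep%d", t, seq_len(nrep))
    blocks[[t]] <- vals
    meta[[t]] <- data.frame(sample_id = colnames(vals), timepoint = t,
                            replicate = seq_len(nrep), control = FALSE,
                            stringsAsFactors = FALSE)
  }
  if (scenario$n_controls > 0) {
    vals <- sim_condition("Control", scenario$n_controls,
                          scenario$edges[0, , drop = FALSE])
    colnames(vals) <- sprintf("Control_rep%d", seq_len(scenario$n_controls))
    blocks[["Control"]] <- vals
    meta[["Control"]] <- data.frame(sample_id = colnames(vals),
                                    timepoint = "Control",
                                    replicate = seq_len(scenario$n_controls),
                                    control = TRUE, stringsAsFactors = FALSE)
  }
  expression_dataset(do.call(cbind, blocks), scenario$nodes,
                     do.call(rbind, c(meta, list(make.row.names = FALSE))))
}

#' Write the planted ground truth as an edge-list TSV
#'
#' Columns: source, target, coefficient, active_timepoints
#' (semicolon-separated labels).
#'
#' @param scenario a `RegulatoryScenario`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_edges <- function(scenario, path) {
  e <- scenario$edges
  out <- data.frame(source = e$from, target = e$to,
                    coefficient = e$coefficient,
                    active_timepoints = vapply(e$active_timepoints,
                                               paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
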