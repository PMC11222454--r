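# SAMBA-style bi-clustering of DE mRNAs against time-points. The search is a
# deterministic greedy seed-and-extend maximiser of the SAMBA log-likelihood
# module weight on the bipartite response graph; with a handful of condition
# columns this explores seeds from every condition singleton and pair and
# hill-climbs on the condition set with exact per-step gene reselection.

#' Replicate-averaged standardised response matrix
#'
#' For each entity and time-point, the mean expression at the time-point
#' minus the control mean, divided by the entity's pooled within-condition
#' standard deviation. This is the "response" thresholded into the bipartite
#' graph for bi-clustering.
#'
#' @param dataset an `ExpressionDataset` with control samples.
#' @param entities entity ids to include (rows); defaults to all mRNAs.
#' @return matrix entities x time-points.
#' @export
response_matrix <- function(dataset, entities = NULL) {
  sm <- dataset$sample_meta
  if (!any(sm$control)) stop_configuration("dataset has no control samples")
  if (is.null(entities))
    entities <- dataset$entity_meta$id[dataset$entity_meta$type == "mRNA"]
  tps <- unique(sm$timepoint[!sm$control])
  vals <- dataset$values[entities, , drop = FALSE]
  ctrl_mean <- rowMeans(vals[, sm$control, drop = FALSE])
  # pooled within-condition variance across all conditions (controls included)
  groups <- split(seq_len(ncol(vals)), sm$timepoint)
  wvar <- rowMeans(vapply(groups, function(ix) {
    v <- vals[, ix, drop = FALSE]
    rowMeans((v - rowMeans(v))^2)
  }, numeric(length(entities))))
  scale <- sqrt(pmax(wvar, .Machine$double.eps))
  out <- vapply(tps, function(t) {
    (rowMeans(vals[, sm$timepoint == t & !sm$control, drop = FALSE]) - ctrl_mean) / scale
  }, numeric(length(entities)))
  out <- matrix(out, nrow = length(entities),
                dimnames = list(entities, tps))
  out
}

#' Build the bipartite response graph
#'
#' Gene g and condition c are connected iff the absolute standardised
#' response of g in c exceeds `response_threshold`.
#'
#' @param de_mrna_profile matrix mRNAs x time-points of standardised
#'   responses (see [response_matrix()]).
#' @param response_threshold positive threshold on `|response|`.
#' @return object of class `ResponseGraph`: logical incidence matrix genes x
#'   conditions.
#' @export
build_response_graph <- function(de_mrna_profile, response_threshold = 2) {
  m <- as.matrix(de_mrna_profile)
  if (anyNA(m) || any(!is.finite(m))) stop_invalid_input("profile must be finite")
  inc <- abs(m) > response_threshold
  structure(inc, class = c("ResponseGraph", class(inc)))
}

bicluster_log_weights <- function(graph, p_edge = 0.9, p_null = NULL) {
  dens <- mean(graph)
  if (is.null(p_null)) p_null <- min(max(dens, 0.05), 0.5)
  if (p_edge <= p_null) p_edge <- (1 + p_null) / 2
  list(edge = log(p_edge / p_null),
       nonedge = log((1 - p_edge) / (1 - p_null)),
       p_edge = p_edge, p_null = p_null)
}

#' Weight of a candidate bi-cluster
#'
#' SAMBA log-likelihood weight: each present (gene, condition) edge inside
#' the module contributes `log(p_edge/p_null)`, each absent pair
#' `log((1-p_edge)/(1-p_null))`, with `p_edge > p_null`.
#'
#' @param graph a `ResponseGraph`.
#' @param genes,conditions module members.
#' @param p_edge assumed within-module edge probability.
#' @param p_null background edge probability (default: observed density,
#'   floored at 0.05).
#' @return scalar weight.
#' @export
bicluster_weight <- function(graph, genes, conditions, p_edge = 0.9, p_null = NULL) {
  w <- bicluster_log_weights(graph, p_edge, p_null)
  sub <- graph[genes, conditions, drop = FALSE]
  sum(sub) * w$edge + sum(!sub) * w$nonedge
}

#' Find bi-clusters by greedy seed-and-extend search
#'
#' Seeds every condition singleton and pair (ordered by incident-edge count),
#' selects for each candidate condition set the exactly optimal gene set
#' (genes with positive weight contribution), and hill-climbs on condition
#' additions/removals until no move improves the module weight. The seed
#' conditions stay anchored during a climb, so different seeds recover
#' different modules rather than all converging on the single heaviest one.
#' Duplicate modules are collapsed; results are sorted by weight descending
#' (ties by gene-set key). The search is deterministic; `seed` is accepted
#' for interface stability.
#'
#' @param graph a `ResponseGraph`.
#' @param max_modules maximum number of modules returned.
#' @param min_genes minimum module gene count.
#' @param seed unused RNG seed (search is deterministic).
#' @param p_edge,p_null weight-model probabilities, see [bicluster_weight()].
#' @return list of `Bicluster` objects: `mrnas`, `conditions`, `weight`.
#' @export
find_biclusters <- function(graph, max_modules = 20L, min_genes = 2L,
                            seed = 1L, p_edge = 0.9, p_null = NULL) {
  genes <- rownames(graph); conds <- colnames(graph)
  if (length(genes) == 0 || length(conds) == 0 || sum(graph) == 0) return(list())
  w <- bicluster_log_weights(graph, p_edge, p_null)

  best_genes <- function(cset) {
    k <- rowSums(graph[, cset, drop = FALSE])
    contrib <- k * w$edge + (length(cset) - k) * w$nonedge
    genes[contrib > 0]
  }
  module_weight <- function(g, cset) {
    sub <- graph[g, cset, drop = FALSE]
    sum(sub) * w$edge + sum(!sub) * w$nonedge
  }
  climb <- function(cset, anchor = cset) {
    repeat {
      g <- best_genes(cset)
      if (length(g) < min_genes) return(NULL)
      cur <- module_weight(g, cset)
      # the seed conditions stay anchored so each seed explores its own
      # neighbourhood; only added conditions may be removed again
      removable <- setdiff(cset, anchor)
      cands <- c(lapply(setdiff(conds, cset), function(a) sort(c(cset, a))),
                 if (length(removable) > 0)
                   lapply(removable, function(d) setdiff(cset, d)))
      best <- NULL; best_w <- cur
      for (cc in cands) {
        gg <- best_genes(cc)
        if (length(gg) < min_genes) next
        ww <- module_weight(gg, cc)
        if (ww > best_w + 1e-12) { best <- cc; best_w <- ww }
      }
      if (is.null(best)) return(list(mrnas = g, conditions = cset, weight = cur))
      cset <- best
    }
  }

  seeds <- c(as.list(conds),
             if (length(conds) > 1) utils::combn(conds, 2, simplify = FALSE))
  seed_deg <- vapply(seeds, function(s) sum(graph[, s]), numeric(1))
  seeds <- seeds[order(-seed_deg, vapply(seeds, paste, "", collapse = ","))]

  mods <- list(); keys <- character(0)
  for (s in seeds) {
    m <- climb(s)
    if (is.null(m)) next
    key <- paste(paste(sort(m$mrnas), collapse = ","),
                 paste(sort(m$conditions), collapse = ","), sep = "|")
    if (key %in% keys) next
    keys <- c(keys, key)
    mods[[length(mods) + 1L]] <- structure(m, class = "Bicluster")
  }
  if (length(mods) == 0) return(list())
  key <- vapply(mods, function(m) paste(sort(m$mrnas), collapse = ","), "")
  ord <- order(-vapply(mods, `[[`, numeric(1), "weight"), key)
  mods <- mods[ord]
  mods[seq_len(min(length(mods), max_modules))]
}

#' Filter bi-clusters by pairwise gene overlap
#'
#' Greedy acceptance in weight order: a module is kept iff its gene overlap
#' (intersection size over the smaller gene set) with every already kept
#' module is at most `max_overlap` (default 10%).
#'
#' @param modules list of `Bicluster`, sorted by weight descending (re-sorted
#'   defensively, ties broken lexicographically).
#' @param max_overlap maximum allowed overlap fraction.
#' @return filtered list.
#' @export
filter_overlap <- function(modules, max_overlap = 0.10) {
  if (length(modules) == 0) return(modules)
  key <- vapply(modules, function(m) paste(sort(m$mrnas), collapse = ","), "")
  modules <- modules[order(-vapply(modules, `[[`, numeric(1), "weight"), key)]
  kept <- list()
  for (m in modules) {
    ok <- TRUE
    for (k in kept) {
      ov <- length(intersect(m$mrnas, k$mrnas)) /
        min(length(m$mrnas), length(k$mrnas))
      if (ov > max_overlap) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- m
  }
  kept
}

#' Merge kept modules into a single per-time-point mRNA set
#'
#' @param modules list of `Bicluster`.
#' @param timepoint time-point label.
#' @return character vector: union of gene sets of modules whose condition
#'   set contains the time-point.
#' @export
merge_per_timepoint <- function(modules, timepoint) {
  if (length(modules) == 0) return(character(0))
  hit <- vapply(modules, function(m) timepoint %in% m$conditions, logical(1))
  out <- unique(unlist(lapply(modules[hit], `[[`, "mrnas")))
  if (is.null(out)) character(0) else sort(out)
}

#' Run the full bi-clustering stage
#'
#' Restricts to mRNAs DE at any time-point, builds the response graph, finds
#' and overlap-filters modules, and merges them per time-point.
#'
#' @param dataset an `ExpressionDataset`.
#' @param de DE table covering all time-points.
#' @param response_threshold threshold for [build_response_graph()].
#' @param max_overlap overlap fraction for [filter_overlap()].
#' @param ... passed to [find_biclusters()].
#' @return list with `modules` (kept modules) and `merged` (named list of
#'   per-time-point mRNA sets).
#' @export
bicluster_pipeline <- function(dataset, de, response_threshold = 2,
                               max_overlap = 0.10, ...) {
  de_mrnas <- unique(de$entity_id[de$de & de$entity_type == "mRNA"])
  tps <- unique(de$timepoint)
  if (length(de_mrnas) == 0)
    return(list(modules = list(),
                merged = setNames(rep(list(character(0)), length(tps)), tps)))
  resp <- response_matrix(dataset, de_mrnas)
  graph <- build_response_graph(resp, response_threshold)
  mods <- filter_overlap(find_biclusters(graph, ...), max_overlap)
  merged <- setNames(lapply(tps, function(t) merge_per_timepoint(mods, t)), tps)
  list(modules = mods, merged = merged)
}

#' Write bi-cluster modules as TSV
#'
#' Columns: module id, weight, semicolon-separated gene and condition lists.
#'
#' @param modules list of `Bicluster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biclusters_tsv <- function(modules, path) {
  df <- data.frame(
    module = seq_along(modules),
    weight = vapply(modules, `[[`, numeric(1), "weight"),
    genes = vapply(modules, function(m) paste(sort(m$mrnas), collapse = ";"), ""),
    conditions = vapply(modules, function(m) paste(m$conditions, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
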