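# Network statistics over the per-time-point filtered networks.

strength_igraph <- function(network, retained_only = TRUE) {
  arcs <- if (retained_only) retained_arcs(network) else network$arcs
  igraph::graph_from_data_frame(arcs[, c("from", "to"), drop = FALSE],
                                directed = TRUE,
                                vertices = network$nodes$id)
}

#' Per-node degree statistics
#'
#' Degree is the number of in-coming plus out-going retained arcs. Nodes are
#' ranked descending on degree and on betweenness, ties sharing the smaller
#' rank.
#'
#' @param network a `StrengthNetwork`.
#' @param directed_betweenness passed to [node_betweenness()].
#' @return data.frame: `id`, `type`, `timepoint`, `degree`, `betweenness`,
#'   `degree_rank`, `betweenness_rank`.
#' @export
degree_stats <- function(network, directed_betweenness = TRUE) {
  if (nrow(network$nodes) == 0)
    return(data.frame(id = character(0), type = character(0),
                      timepoint = character(0), degree = integer(0),
                      betweenness = numeric(0), degree_rank = integer(0),
                      betweenness_rank = integer(0)))
  g <- strength_igraph(network)
  deg <- igraph::degree(g, mode = "all")
  btw <- node_betweenness(network, directed = directed_betweenness)
  data.frame(id = network$nodes$id,
             type = network$nodes$type,
             timepoint = network$timepoint,
             degree = as.integer(deg[network$nodes$id]),
             betweenness = btw[network$nodes$id],
             degree_rank = rank(-deg[network$nodes$id], ties.method = "min"),
             betweenness_rank = rank(-btw[network$nodes$id], ties.method = "min"),
             stringsAsFactors = FALSE)
}

#' Shortest-path betweenness centrality
#'
#' Unweighted, unnormalised betweenness counting all shortest paths, on the
#' directed graph by default (the undirected variant is exposed because the
#' convention is a modelling choice).
#'
#' @param network a `StrengthNetwork`.
#' @param directed treat arcs as directed (default TRUE).
#' @return named numeric vector of betweenness per node.
#' @export
node_betweenness <- function(network, directed = TRUE) {
  g <- strength_igraph(network)
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
  b <- igraph::betweenness(g, directed = directed, normalized = FALSE)
  setNames(as.numeric(b), names(b))[network$nodes$id]
}

#' Beta-index (connectivity measure)
#'
#' Number of retained arcs divided by the number of nodes incident to at
#' least one retained arc (isolated entities are excluded from the
#' denominator).
#'
#' @param network a `StrengthNetwork`.
#' @return scalar; 0 with a warning when no arcs survive filtering.
#' @export
beta_index <- function(network) {
  arcs <- retained_arcs(network)
  if (nrow(network$nodes) == 0) stop_invalid_input("beta-index undefined: no nodes")
  if (nrow(arcs) == 0) {
    warning("no retained arcs; beta-index is 0")
    return(0)
  }
  nrow(arcs) / length(unique(c(arcs$from, arcs$to)))
}

#' Label the top fraction of nodes per statistic
#'
#' Rank cut-off with ties included, mirroring the "top 20% labelled"
#' visualisation convention.
#'
#' @param stats output of [degree_stats()].
#' @param top fraction of nodes labelled (default 0.2).
#' @return the stats data.frame with logical `top_degree`, `top_betweenness`.
#' @export
label_top_nodes <- function(stats, top = 0.2) {
  cutoff <- max(1L, floor(top * nrow(stats)))
  stats$top_degree <- stats$degree_rank <= cutoff
  stats$top_betweenness <- stats$betweenness_rank <= cutoff
  stats
}

#' Exclusive-intersection (upset) counts
#'
#' For every non-empty subset of the input sets, counts the items belonging
#' to exactly that subset (upset semantics). Counts over all cells sum to
#' the size of the union.
#'
#' @param item_sets named list of character vectors (e.g. per-time-point DE
#'   miRNA sets, or edge keys).
#' @return data.frame: `subset` (comma-joined member names, in input order),
#'   `degree` (subset size), `count`; only non-empty cells unless
#'   `keep_empty`.
#' @param keep_empty also report zero cells.
#' @export
overlap_counts <- function(item_sets, keep_empty = FALSE) {
  if (length(item_sets) == 0) stop_invalid_input("need >= 1 set")
  nm <- names(item_sets)
  if (is.null(nm)) nm <- paste0("set", seq_along(item_sets))
  items <- unique(unlist(item_sets, use.names = FALSE))
  membership <- vapply(item_sets, function(s) items %in% s,
                       logical(length(items)))
  membership <- matrix(membership, nrow = length(items))
  sig <- apply(membership, 1, function(r) paste(nm[r], collapse = ","))
  subsets <- unlist(lapply(seq_along(nm), function(k)
    apply(utils::combn(nm, k), 2, paste, collapse = ",")))
  tab <- table(factor(sig, levels = subsets))
  out <- data.frame(subset = names(tab),
                    degree = lengths(strsplit(names(tab), ",", fixed = TRUE)),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  if (!keep_empty) out <- out[out$count > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise intersection counts
#'
#' Full pairwise intersections (the "shared" view, complementary to the
#' exclusive upset cells).
#'
#' @param item_sets named list of character vectors.
#' @return symmetric integer matrix of `|A intersect B|`.
#' @export
pairwise_overlap <- function(item_sets) {
  nm <- names(item_sets)
  k <- length(item_sets)
  out <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k))
    out[i, j] <- length(intersect(item_sets[[i]], item_sets[[j]]))
  out
}

#' Edge keys of the retained arcs
#'
#' Arc identity for cross-time-point edge overlap: the ordered
#' `source->target` pair.
#'
#' @param network a `StrengthNetwork`.
#' @return character vector of `from->to` keys.
#' @export
edge_keys <- function(network) {
  arcs <- retained_arcs(network)
  paste0(arcs$from, "->", arcs$to)
}

#' Binary membership matrix of the overlap input
#'
#' @param item_sets named list of character vectors.
#' @return 0/1 integer matrix items x sets, for external upset plotting.
#' @export
membership_matrix <- function(item_sets) {
  items <- sort(unique(unlist(item_sets, use.names = FALSE)))
  out <- vapply(item_sets, function(s) as.integer(items %in% s),
                integer(length(items)))
  out <- matrix(out, nrow = length(items),
                dimnames = list(items, names(item_sets)))
  out
}
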