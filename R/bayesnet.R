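# Per-time-point Gaussian Bayesian network structure learning: decomposable
# BIC scoring, hill climbing (C++ core), bootstrap arc-strength estimation
# and highest-quartile edge retention.

model_values <- function(data) {
  if (inherits(data, "ModelInput")) data$values
  else if (is.matrix(data)) data
  else stop_invalid_input("data must be a ModelInput or an entities x samples matrix")
}

model_types <- function(data) {
  if (inherits(data, "ModelInput")) data$types
  else setNames(rep(NA_character_, nrow(data)), rownames(data))
}

#' Learning configuration
#'
#' Bundles the structure-learning constants: bootstrap replicate count
#' (default 1000), RNG seed, optional parent cap, retention quartile
#' (default 0.75) and the arc-strength convention.
#'
#' @param B bootstrap replicates (>= 1).
#' @param rng_seed integer seed.
#' @param max_parents optional cap on parents per node; default
#'   `min(p - 1, n - 3)` at learning time.
#' @param quartile retention quantile in (0, 1).
#' @param strength_mode `"directed"` (frequency of the directed arc, the
#'   default) or `"undirected"` (frequency of the skeleton edge, reported in
#'   its majority orientation with a direction probability).
#' @param tabu length of the tabu list that lets the search walk through
#'   score-degrading moves out of a local optimum while keeping the best
#'   structure visited (0 = plain greedy ascent); the walk gives up after
#'   `tabu` consecutive moves without a new best.
#' @return a `LearnConfig` list.
#' @export
learn_config <- function(B = 1000L, rng_seed = 1L, max_parents = NULL,
                         quartile = 0.75,
                         strength_mode = c("directed", "undirected"),
                         tabu = 10L) {
  if (B < 1) stop_invalid_parameter("B must be >= 1")
  if (quartile <= 0 || quartile >= 1)
    stop_invalid_parameter("quartile must lie in (0, 1)")
  if (tabu < 0) stop_invalid_parameter("tabu must be >= 0")
  structure(list(B = as.integer(B), rng_seed = as.integer(rng_seed),
                 max_parents = max_parents, quartile = quartile,
                 strength_mode = match.arg(strength_mode),
                 tabu = as.integer(tabu)),
            class = "LearnConfig")
}

#' Gaussian BIC family score
#'
#' Ordinary-least-squares fit of a child on its parents (with intercept);
#' returns the Gaussian log-likelihood at the MLE residual variance minus
#' `((|parents| + 2) / 2) * log(n)` (coefficients, intercept and variance are
#' the penalised parameters). A singular (collinear) or exactly-fitting
#' design scores `-Inf`, disallowing the family. The network score of a DAG
#' is the sum of its family scores (decomposability).
#'
#' @param data `ModelInput` or entities x samples matrix.
#' @param child child entity id.
#' @param parents character vector of parent ids (possibly empty).
#' @return scalar score.
#' @export
family_bic <- function(data, child, parents = character(0)) {
  vals <- model_values(data)
  if (!child %in% rownames(vals)) stop_invalid_input(sprintf("unknown child '%s'", child))
  if (!all(parents %in% rownames(vals)))
    stop_invalid_input("unknown parent id")
  y <- vals[child, ]
  n <- length(y)
  k <- length(parents)
  if (n < k + 2) stop_invalid_input("need n >= |parents| + 2 samples")
  X <- cbind(`(Intercept)` = rep(1, n))
  if (k > 0) X <- cbind(X, t(vals[parents, , drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(-Inf)
  rss <- sum(qr.resid(qx, y)^2)
  if (rss <= max(1e-12, 1e-9 * sum((y - mean(y))^2))) return(-Inf)
  loglik <- -n / 2 * (log(2 * pi * rss / n) + 1)
  loglik - (k + 2) / 2 * log(n)
}

#' Total BIC score of a DAG
#'
#' @param data `ModelInput` or matrix.
#' @param arcs data.frame with columns `from`, `to`.
#' @return sum of family scores over all nodes.
#' @export
bic_network_score <- function(data, arcs) {
  vals <- model_values(data)
  sum(vapply(rownames(vals), function(v) {
    family_bic(data, v, arcs$from[arcs$to == v])
  }, numeric(1)))
}

#' Hill-climbing structure search
#'
#' Greedy search from the empty graph over single-arc additions, deletions
#' and reversals, taking at each step the move with the largest positive
#' BIC improvement while maintaining acyclicity. When no move improves and
#' `config$tabu > 0`, the search continues through the best non-tabu move
#' regardless of sign (a fixed-length tabu list of inverse moves prevents
#' immediate undo), returns to greedy ascent whenever a new best structure
#' is found, and reports the best structure visited - the standard
#' deterministic escape from single-move local optima such as unshielded
#' colliders whose parents are marginally independent. Ties are broken by
#' (parent, child) lexicographic scan order, so the result is deterministic
#' for fixed data.
#'
#' @param data `ModelInput` or entities x samples matrix (>= 3 samples).
#' @param config a [learn_config()].
#' @return a `DAGStructure`: `nodes` (id, type) and `arcs` (from, to).
#' @export
hill_climb <- function(data, config = learn_config()) {
  vals <- model_values(data)
  n <- ncol(vals); p <- nrow(vals)
  if (n < 3) stop_invalid_input("need >= 3 samples")
  maxp <- config$max_parents
  if (is.null(maxp)) maxp <- max(1L, min(p - 1L, n - 3L))
  X <- t(vals)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc)
  A <- hc_gaussian_cpp(S, n, as.integer(maxp), config$tabu, max(config$tabu, 1L))
  ids <- rownames(vals)
  idx <- which(A == 1, arr.ind = TRUE)
  arcs <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                     stringsAsFactors = FALSE)
  arcs <- arcs[order(arcs$from, arcs$to), , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(nodes = data.frame(id = ids, type = unname(model_types(data)[ids]),
                                    stringsAsFactors = FALSE),
                 arcs = arcs),
            class = "DAGStructure")
}

#' Bootstrap arc-strength estimation
#'
#' Resamples the samples (columns) with replacement `B` times, relearns the
#' structure on each replicate and scores each directed arc by its empirical
#' frequency across the `B` learned DAGs. A degenerate replicate in which
#' some variable becomes constant is redrawn (and counted in the
#' `n_redrawn` attribute). Deterministic for a fixed seed.
#'
#' @param data `ModelInput` or matrix.
#' @param config a [learn_config()].
#' @return a `StrengthNetwork` (pre-filter): `arcs` (from, to, strength for
#'   every arc ever learned; plus `direction_prob` in undirected mode),
#'   `nodes`, `timepoint`, `B`, `quartile_threshold = NA`.
#' @export
bootstrap_strength <- function(data, config = learn_config()) {
  vals <- model_values(data)
  n <- ncol(vals); p <- nrow(vals)
  ids <- rownames(vals)
  set.seed(config$rng_seed)
  counts <- matrix(0L, p, p, dimnames = list(ids, ids))
  n_redrawn <- 0L
  for (b in seq_len(config$B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- vals[, idx, drop = FALSE]
      if (all(apply(Xb, 1, function(r) any(r != r[1])))) break
      n_redrawn <- n_redrawn + 1L
    }
    sub <- if (inherits(data, "ModelInput"))
      structure(list(values = Xb, types = data$types, timepoint = data$timepoint),
                class = "ModelInput") else Xb
    dag <- hill_climb(sub, config)
    if (nrow(dag$arcs))
      counts[cbind(dag$arcs$from, dag$arcs$to)] <-
        counts[cbind(dag$arcs$from, dag$arcs$to)] + 1L
  }
  if (n_redrawn > 0)
    message(sprintf("bootstrap_strength: %d degenerate replicate(s) redrawn", n_redrawn))

  if (config$strength_mode == "directed") {
    idx <- which(counts > 0, arr.ind = TRUE)
    arcs <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                       strength = counts[idx] / config$B,
                       stringsAsFactors = FALSE)
  } else {
    und <- counts + t(counts)
    idx <- which(und > 0 & upper.tri(und), arr.ind = TRUE)
    fw <- counts[idx]; bw <- t(counts)[idx]
    maj_from <- ifelse(fw >= bw, ids[idx[, 1]], ids[idx[, 2]])
    maj_to <- ifelse(fw >= bw, ids[idx[, 2]], ids[idx[, 1]])
    arcs <- data.frame(from = maj_from, to = maj_to,
                       strength = und[idx] / config$B,
                       direction_prob = pmax(fw, bw) / pmax(und[idx], 1L),
                       stringsAsFactors = FALSE)
  }
  arcs <- arcs[order(arcs$from, arcs$to), , drop = FALSE]
  rownames(arcs) <- NULL
  net <- structure(list(
    arcs = arcs,
    nodes = data.frame(id = ids, type = unname(model_types(data)[ids]),
                       stringsAsFactors = FALSE),
    timepoint = if (inherits(data, "ModelInput")) data$timepoint else NA_character_,
    B = config$B,
    quartile_threshold = NA_real_
  ), class = "StrengthNetwork")
  attr(net, "n_redrawn") <- n_redrawn
  attr(net, "counts") <- counts
  net
}

#' @export
print.StrengthNetwork <- function(x, ...) {
  cat(sprintf("StrengthNetwork (%s): %d nodes, %d arcs (%d retained), B = %d\n",
              ifelse(is.na(x$timepoint), "?", x$timepoint), nrow(x$nodes),
              nrow(x$arcs), sum(retained_flags(x)), x$B))
  if (!is.na(x$quartile_threshold))
    cat(sprintf("quartile threshold: %.4g\n", x$quartile_threshold))
  invisible(x)
}

retained_flags <- function(network) {
  if ("retained" %in% names(network$arcs)) network$arcs$retained
  else rep(TRUE, nrow(network$arcs))
}

#' Retained arcs of a strength network
#'
#' @param network a `StrengthNetwork`.
#' @return arc data.frame restricted to retained arcs.
#' @export
retained_arcs <- function(network) {
  network$arcs[retained_flags(network), , drop = FALSE]
}

#' Highest-quartile strength filter
#'
#' Retains, per time-point network, only the arcs whose bootstrap strength
#' reaches the upper quartile of the strengths of all observed (strength
#' greater than zero) arcs. The quartile is the linear-interpolation sample
#' quantile (R's default type 7); arcs with strength at or above it are
#' retained and the threshold is recorded on the network.
#'
#' @param network a `StrengthNetwork` from [bootstrap_strength()].
#' @param quartile retention quantile (default 0.75).
#' @return the network with a `retained` arc flag and `quartile_threshold`
#'   set; an empty-arc network (with a warning) when no arc has positive
#'   strength.
#' @export
quartile_filter <- function(network, quartile = 0.75) {
  s <- network$arcs$strength
  pos <- s > 0
  if (!any(pos)) {
    warning("no positive-strength arcs; returning empty network")
    network$arcs <- network$arcs[0, , drop = FALSE]
    network$quartile_threshold <- NA_real_
    return(network)
  }
  thr <- unname(quantile(s[pos], probs = quartile, type = 7))
  network$arcs$retained <- pos & s >= thr
  network$quartile_threshold <- thr
  network
}

#' Classify arcs by endpoint entity types
#'
#' @param network a `StrengthNetwork` with node types.
#' @param retained_only count only retained arcs (default) or all arcs.
#' @return named integer vector over `miRNA->miRNA`, `miRNA->mRNA`,
#'   `mRNA->miRNA`, `mRNA->mRNA`; sums to the number of (retained) arcs.
#' @export
classify_edges <- function(network, retained_only = TRUE) {
  arcs <- if (retained_only) retained_arcs(network) else network$arcs
  types <- setNames(network$nodes$type, network$nodes$id)
  if (anyNA(types) || !all(types %in% c("miRNA", "mRNA"))) {
    bad <- network$nodes$id[is.na(types) | !types %in% c("miRNA", "mRNA")][1]
    stop_invalid_input(sprintf("unknown node type for '%s'", bad))
  }
  lab <- c("miRNA->miRNA", "miRNA->mRNA", "mRNA->miRNA", "mRNA->mRNA")
  out <- setNames(integer(4), lab)
  if (nrow(arcs)) {
    key <- paste0(types[arcs$from], "->", types[arcs$to])
    tab <- table(factor(key, levels = lab))
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Learn the filtered network for one time-point
#'
#' The per-time-point inference used by the pipeline: the network structure
#' is learned on the full data by hill climbing; each structure edge is then
#' assigned its bootstrap skeleton strength (the frequency, over the `B`
#' resampled structures, of the edge being present in either orientation -
#' score-equivalent DAGs flip orientations freely across resamples, so the
#' orientation-agnostic frequency is the stable measure of edge support,
#' while the reported direction is the full-data structure's orientation);
#' finally only the edges in the highest quartile of those strengths are
#' retained. The arc table also carries `direction_prob`, the fraction of
#' bootstrap occurrences agreeing with the reported orientation.
#'
#' @param data `ModelInput` for the time-point.
#' @param config a [learn_config()].
#' @return filtered `StrengthNetwork`.
#' @export
learn_timepoint_network <- function(data, config = learn_config()) {
  dag <- hill_climb(data, config)
  boot <- bootstrap_strength(data, config)
  counts <- attr(boot, "counts")
  arcs <- dag$arcs
  if (nrow(arcs)) {
    fw <- counts[cbind(arcs$from, arcs$to)]
    bw <- counts[cbind(arcs$to, arcs$from)]
    arcs$strength <- (fw + bw) / config$B
    arcs$direction_prob <- ifelse(fw + bw > 0, fw / (fw + bw), NA_real_)
  } else {
    arcs$strength <- numeric(0)
    arcs$direction_prob <- numeric(0)
  }
  net <- structure(list(arcs = arcs, nodes = dag$nodes,
                        timepoint = boot$timepoint, B = config$B,
                        quartile_threshold = NA_real_),
                   class = "StrengthNetwork")
  if (nrow(arcs) == 0) {
    warning("hill climbing learned an empty structure")
    return(net)
  }
  quartile_filter(net, config$quartile)
}
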