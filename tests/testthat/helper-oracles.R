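# Independent oracles: naive reference implementations kept deliberately
# separate from the package code paths they check.

# Benjamini-Hochberg by direct evaluation of the step-up definition,
# O(m^2): adj_i = min over j with p_(j) >= p_i of p_(j) * m / rank(j).
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- ranked[i:m] * m / (i:m)
    adj[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Unnormalised directed betweenness by exhaustive enumeration of all
# shortest paths between every ordered pair (BFS distances + DFS path
# enumeration over the shortest-path DAG).
brute_betweenness <- function(adj) {
  p <- nrow(adj)
  btw <- numeric(p)
  dist_from <- function(s) {
    d <- rep(Inf, p); d[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in which(adj[v, ] == 1))
        if (d[w] == Inf) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  for (s in seq_len(p)) {
    d <- dist_from(s)
    for (t in seq_len(p)) {
      if (t == s || !is.finite(d[t]) || d[t] == 0) next
      paths <- list()
      walk <- function(v, path) {
        if (v == t) { paths[[length(paths) + 1L]] <<- path; return(invisible()) }
        for (w in which(adj[v, ] == 1))
          if (d[w] == d[v] + 1 && d[w] <= d[t]) walk(w, c(path, w))
      }
      walk(s, integer(0))
      keep <- vapply(paths, function(pt) pt[length(pt)] == t, logical(1))
      paths <- paths[keep]
      if (length(paths) == 0) next
      inner <- unlist(lapply(paths, function(pt) pt[-length(pt)]))
      if (length(inner))
        for (v in inner) btw[v] <- btw[v] + 1 / length(paths)
    }
  }
  btw
}

# All DAGs over the given ids, as a list of arc data.frames, by filtering
# every directed graph without self-loops for acyclicity.
enumerate_dags <- function(ids) {
  p <- length(ids)
  off <- which(diag(p) == 0)
  n_slots <- length(off)
  out <- list()
  is_dag <- function(A) {
    indeg <- colSums(A)
    active <- rep(TRUE, p)
    repeat {
      src <- which(active & indeg == 0)
      if (!length(src)) break
      for (v in src) {
        active[v] <- FALSE
        indeg <- indeg - A[v, ]
      }
    }
    !any(active)
  }
  for (code in 0:(2^n_slots - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n_slots)]
    A <- matrix(0L, p, p)
    A[off] <- bits
    if (!is_dag(A)) next
    idx <- which(A == 1, arr.ind = TRUE)
    out[[length(out) + 1L]] <- data.frame(from = ids[idx[, 1]],
                                          to = ids[idx[, 2]],
                                          stringsAsFactors = FALSE)
  }
  out
}

# Best BIC over all DAGs by exhaustive search with family-score caching.
# `dags` may be precomputed (enumerate_dags is id-order independent) to
# amortise the enumeration across datasets sharing variable names.
exhaustive_best_bic <- function(data, dags = NULL) {
  vals <- if (inherits(data, "ModelInput")) data$values else data
  ids <- rownames(vals)
  p <- length(ids)
  cache <- new.env()
  fam <- function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- family_bic(data, child, parents)
    cache[[key]]
  }
  if (is.null(dags)) dags <- enumerate_dags(ids)
  best <- -Inf
  for (arcs in dags) {
    s <- sum(vapply(ids, function(v) fam(v, arcs$from[arcs$to == v]), numeric(1)))
    if (s > best) best <- s
  }
  best
}

# Covariance implied by a linear-Gaussian SEM x = A x + e, A[i, j] the
# coefficient of parent j on child i: Sigma = (I - A)^-1 D (I - A)^-T.
sem_covariance <- function(A, noise_var) {
  p <- nrow(A)
  M <- solve(diag(p) - A)
  M %*% diag(noise_var, p) %*% t(M)
}

# Small random Gaussian dataset from a random DAG respecting the id order;
# returns a z-scored entities x samples matrix.
random_gaussian_dataset <- function(p, n, seed, edge_prob = 0.4,
                                    coef_range = c(0.4, 1)) {
  set.seed(seed)
  ids <- paste0("v", seq_len(p))
  X <- matrix(0, p, n, dimnames = list(ids, NULL))
  for (i in seq_len(p)) {
    mu <- rep(0, n)
    if (i > 1) for (j in seq_len(i - 1)) {
      if (runif(1) < edge_prob) {
        b <- sample(c(-1, 1), 1) * runif(1, coef_range[1], coef_range[2])
        mu <- mu + b * X[j, ]
      }
    }
    X[i, ] <- mu + rnorm(n)
  }
  zscore_rows(X)
}

as_model_input <- function(values, types = NULL, timepoint = "24h") {
  if (is.null(types))
    types <- setNames(ifelse(grepl("^miR", rownames(values)), "miRNA", "mRNA"),
                      rownames(values))
  structure(list(values = values, types = types, timepoint = timepoint),
            class = "ModelInput")
}

# Study-shaped scenario in which every time-point carries dysregulated
# miRNAs and mRNAs (two-time-point baseline windows, 6 noise-sd strong).
study_shaped_dataset <- function(seed, n_mirna = 12, n_mrna = 36) {
  sc0 <- generate_scenario(n_mirna, n_mrna,
                           edge_density = 30 / choose(n_mirna + n_mrna, 2),
                           frac_de = 0, seed = seed)
  tp <- default_timepoints()
  base <- sc0$baseline
  set.seed(seed + 1L)
  mir <- sc0$nodes$id[sc0$nodes$type == "miRNA"]
  mr <- sc0$nodes$id[sc0$nodes$type == "mRNA"]
  for (i in seq_along(mir))
    base[mir[i], tp[c(i %% 5, (i + 1) %% 5) + 1]] <- 6 * sample(c(-1, 1), 1)
  for (j in seq_along(mr))
    base[mr[j], tp[c(j %% 5, (j + 2) %% 5) + 1]] <- 6 * sample(c(-1, 1), 1)
  sc <- regulatory_scenario(sc0$nodes, sc0$edges, baseline = base,
                            noise_sd = 1, rng_seed = seed)
  simulate_expression(sc)
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "epimirnet", mustWork = TRUE)
}
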