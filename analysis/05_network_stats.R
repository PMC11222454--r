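#!/usr/bin/env Rscript

# Stage 5 - network statistics.
#
# Degree (in + out), unnormalised directed betweenness centrality, top-20%
# labelling, the beta-index (edges / connected nodes) per time-point, and
# cross-time-point edge overlap in both upset (exclusive) and pairwise
# (shared) form.

suppressPackageStartupMessages(library(epimirnet))

timepoints <- default_timepoints()
networks <- list()
for (t in timepoints) {
  f <- sprintf("results/network_%s.tsv", t)
  if (file.exists(f)) networks[[t]] <- read_network_tsv(f, timepoint = t)
}

stats <- do.call(rbind, lapply(networks, function(n)
  label_top_nodes(degree_stats(n))))
rownames(stats) <- NULL
write.table(stats, "results/node_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("beta-index per time-point:\n")
print(round(vapply(networks, function(n) suppressWarnings(beta_index(n)),
                   numeric(1)), 3))

cat("\nmost connected node per time-point:\n")
for (t in names(networks)) {
  st <- stats[stats$timepoint == t, ]
  top <- st[which.min(st$degree_rank), ]
  cat(sprintf("  %-8s %s (degree %d, betweenness %.1f)\n", t, top$id,
              top$degree, top$betweenness))
}

edge_sets <- lapply(networks, edge_keys)
up <- overlap_counts(edge_sets)
write.table(up, "results/edge_overlap_upset.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(membership_matrix(edge_sets), "results/edge_overlap_membership.tsv",
            sep = "\t", quote = FALSE)
cat("\nshared (pairwise) retained interactions between time-points:\n")
print(pairwise_overlap(edge_sets))
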