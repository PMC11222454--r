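#!/usr/bin/env Rscript

# Stage 6 - miRNA prioritisation and MTI annotation.
#
# Extracts the inferred miRNA->mRNA target interactions (direct retained
# arcs only), cleans gene symbols, and runs the shortlisting cascade:
# (1) drop miRNAs with no inferred targets anywhere, (2) drop those without
# a human orthologue, (3) keep those with targets at two or more
# time-points, (4) keep those with a rat-to-human conserved seed (nt 2-8).
# Orthology and mature sequences come from the package's synthetic stand-in
# resources; swap in a real orthology table and miRBase FASTA to run on
# real identifiers. Finishes with the recurrence tables and the z-scored
# target-count heatmap matrix.

suppressPackageStartupMessages(library(epimirnet))

timepoints <- default_timepoints()
networks <- list()
for (t in timepoints) {
  f <- sprintf("results/network_%s.tsv", t)
  if (file.exists(f)) networks[[t]] <- read_network_tsv(f, timepoint = t)
}
de <- read_de_tsv("results/de_table.tsv")

mti <- clean_symbols(extract_mti(networks))
removed <- attr(mti, "removed")
if (length(removed)) cat("removed unofficial symbols:", removed, "\n")

# synthetic stand-in resources: the scenario's miRNA ids are mapped onto the
# stand-in identifier space (most-targeting miRNAs first, so every cascade
# stage is exercised end to end)
orth_map <- read.delim(system.file("extdata", "synthetic_orthology.tsv",
                                   package = "epimirnet"),
                       na.strings = "NA", stringsAsFactors = FALSE)
seqs <- read_mature_fasta(system.file("extdata", "synthetic_mature_mirnas.fa",
                                      package = "epimirnet"))
mirnas <- unique(de$entity_id[de$de & de$entity_type == "miRNA"])
totals <- vapply(mirnas, function(m) sum(mti$mirna == m), numeric(1))
mirnas <- mirnas[order(-totals, mirnas)]
alias <- setNames(orth_map$rat_id[(seq_along(mirnas) - 1) %% nrow(orth_map) + 1],
                  mirnas)
orthology <- data.frame(rat_id = mirnas,
                        human_id = orth_map$human_id[match(alias, orth_map$rat_id)],
                        stringsAsFactors = FALSE)
rat_seqs <- setNames(seqs[alias], mirnas)
rat_seqs <- rat_seqs[!is.na(rat_seqs)]

records <- build_mirna_records(mirnas, mti, timepoints, orthology,
                               rat_seqs = rat_seqs, human_seqs = seqs)
records <- shortlist_cascade(records)
write.table(records, "results/mirna_records.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nshortlist cascade:\n")
print(attr(records, "stage_counts"))

shortlist <- records$rat_id[records$stage4_seed_conserved]
tabs <- recurrence_tables(mti, shortlist, de)
cat(sprintf("\n%d MTIs of shortlisted miRNAs target mRNAs DE at >= 2 time-points\n",
            nrow(tabs$recurrent_target_mtis)))
if (nrow(tabs$multi_targeted_mrnas)) {
  cat("mRNAs targeted by > 2 shortlisted miRNAs:\n")
  print(tabs$multi_targeted_mrnas)
}

counts <- matrix(NA_real_, length(shortlist), length(timepoints),
                 dimnames = list(shortlist, timepoints))
for (m in shortlist) {
  r <- records[records$rat_id == m, paste0("targets_", timepoints)]
  v <- as.numeric(r)
  v[v == 0] <- NA  # no network presence at that time-point
  counts[m, ] <- v
}
if (length(shortlist)) {
  heat <- normalized_degree_heat(counts)
  write.table(heat, "results/shortlist_degree_zscores.tsv", sep = "\t",
              quote = FALSE)
}

mti_out <- mti
mti_out$timepoints <- vapply(mti_out$timepoints, paste, "", collapse = ";")
write.table(mti_out, "results/mti_records.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nwrote %d distinct MTI records\n", nrow(mti_out)))
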