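mk_net <- function(arcs, timepoint) {
  strength_network(arcs, timepoint = timepoint)
}

test_that("extract_mti aggregates direct miRNA->mRNA arcs across time-points", {
  nets <- list(
    `24h` = mk_net(data.frame(from = c("miR_a", "gene_X"),
                              to = c("gene_X", "gene_Y")), "24h"),
    `72h` = mk_net(data.frame(from = "miR_a", to = "gene_X"), "72h"))
  mti <- extract_mti(nets)
  expect_equal(nrow(mti), 1)
  expect_equal(mti$mirna, "miR_a")
  expect_setequal(unlist(mti$timepoints), c("24h", "72h"))
  expect_equal(mti$n_timepoints, 2L)
})

test_that("mRNA->miRNA arcs never produce target records", {
  nets <- list(`24h` = mk_net(data.frame(from = "gene_X", to = "miR_a"), "24h"))
  expect_equal(nrow(extract_mti(nets)), 0)
})

test_that("MTI record count equals the number of distinct miRNA->mRNA pairs", {
  set.seed(31)
  for (i in 1:5) {
    tps <- default_timepoints()[1:3]
    nets <- lapply(tps, function(t) {
      k <- sample(3:8, 1)
      arcs <- data.frame(from = sample(paste0("miR_", 1:4), k, replace = TRUE),
                         to = sample(paste0("gene_", 1:5), k, replace = TRUE))
      arcs <- unique(arcs)
      mk_net(arcs, t)
    })
    names(nets) <- tps
    mti <- extract_mti(nets)
    all_pairs <- unique(do.call(rbind, lapply(nets, function(n) n$arcs[, 1:2])))
    expect_equal(nrow(mti), nrow(all_pairs))
  }
})

test_that("clean_symbols drops unofficial symbols, maps synonyms, and is idempotent", {
  expect_equal(as.character(clean_symbols("Cecr6")), "TMEM121B")
  expect_equal(as.character(clean_symbols("Pnmal2")), "PNMA8B")
  expect_equal(as.character(clean_symbols("Oasl2")), "OASL")
  expect_equal(as.character(clean_symbols("Gfap")), "Gfap")
  out <- clean_symbols(c("LOC102551234", "RGD1311933", "AABR07015080.1", "Gfap"))
  expect_equal(as.character(out), "Gfap")
  expect_setequal(attr(out, "removed"),
                  c("LOC102551234", "RGD1311933", "AABR07015080.1"))

  df <- data.frame(mirna = c("miR_a", "miR_b", "miR_c"),
                   mrna = c("Cecr6", "LOC1", "Gfap"), stringsAsFactors = FALSE)
  once <- clean_symbols(df)
  twice <- clean_symbols(once)
  attr(once, "removed") <- NULL; attr(twice, "removed") <- NULL
  expect_identical(once, twice)
  expect_equal(once$mrna, c("TMEM121B", "Gfap"))
})

test_that("seed_conserved compares exactly nucleotides 2-8 and is symmetric", {
  expect_true(seed_conserved("UAGCUUAUCAGACUGAUGUUGA", "UAGCUUAUCAGACUGAUGUUGA"))
  # position 1 excluded
  expect_true(seed_conserved("AAGCUUAUCAGA", "UAGCUUAUCAGA"))
  # mismatch at position 7
  expect_false(seed_conserved("UAGCUUAUCAGA", "UAGCUUGUCAGA"))
  # position 9 onwards irrelevant
  expect_true(seed_conserved("UAGCUUAUCAGA", "UAGCUUAUGGGG"))
  # U/T and case unification
  expect_true(seed_conserved("uagcuuaucaga", "TAGCTTATCAGA"))
  # symmetry
  a <- "UAGCUUAUCAGA"; b <- "UAGCUUGUCAGA"
  expect_equal(seed_conserved(a, b), seed_conserved(b, a))
  expect_error(seed_conserved("UAGCU", "UAGCUUAUCAGA"),
               class = "epimirnet_invalid_input")
})

test_that("the synthetic stand-in FASTA reproduces the designed conservation pattern", {
  seqs <- read_mature_fasta(fixture_path("synthetic_mature_mirnas.fa"))
  non_conserved <- c("rno-miR-496-3p", "rno-miR-21-3p", "rno-miR-361-3p")
  for (m in non_conserved)
    expect_false(seed_conserved(seqs[[m]], seqs[[sub("rno-", "hsa-", m)]]))
  conserved <- c("rno-let-7c-5p", "rno-miR-132-3p", "rno-miR-155-5p",
                 "rno-miR-665", "rno-miR-130b-3p", "rno-miR-223-3p")
  for (m in conserved)
    expect_true(seed_conserved(seqs[[m]], seqs[[sub("rno-", "hsa-", m)]]))
})

make_records <- function(counts, human, cons) {
  records <- data.frame(rat_id = rownames(counts), human_id = human,
                        seed_conserved = cons, stringsAsFactors = FALSE)
  records[paste0("targets_", colnames(counts))] <- as.data.frame(counts)
  records
}

test_that("the shortlist cascade drops and keeps the right miRNAs", {
  counts <- rbind(m_notargets = c(0, 0, 0),
                  m_onetp = c(0, 3, 0),
                  m_nohuman = c(1, 2, 0),
                  m_notcons = c(1, 0, 2),
                  m_pass = c(2, 1, 0))
  colnames(counts) <- c("24h", "72h", "DOFS")
  rec <- make_records(counts,
                      human = c("h1", "h2", NA, "h4", "h5"),
                      cons = c(TRUE, TRUE, NA, FALSE, TRUE))
  out <- shortlist_cascade(rec)
  expect_false(out$stage1_has_targets[out$rat_id == "m_notargets"])
  expect_true(out$stage2_has_orthologue[out$rat_id == "m_onetp"])
  expect_false(out$stage3_multi_timepoint[out$rat_id == "m_onetp"])
  expect_false(out$stage2_has_orthologue[out$rat_id == "m_nohuman"])
  expect_false(out$stage4_seed_conserved[out$rat_id == "m_notcons"])
  expect_true(out$stage4_seed_conserved[out$rat_id == "m_pass"])
  sc <- attr(out, "stage_counts")
  expect_equal(unname(sc["excluded_no_targets"]), 1L)
  expect_equal(unname(sc["excluded_no_orthologue"]), 1L)
  expect_equal(unname(sc["multi_timepoint"]), 2L)
  expect_equal(unname(sc["seed_conserved"]), 1L)
})

test_that("cascade stages are monotone nested on fuzzed inputs", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    counts <- matrix(rpois(n * 5, 0.7), n,
                     dimnames = list(paste0("m", 1:n), default_timepoints()))
    rec <- make_records(counts,
                        human = ifelse(runif(n) < 0.8, paste0("h", 1:n), NA),
                        cons = sample(c(TRUE, FALSE, NA), n, replace = TRUE))
    out <- shortlist_cascade(rec)
    expect_true(all(out$stage2_has_orthologue <= out$stage1_has_targets))
    expect_true(all(out$stage3_multi_timepoint <= out$stage2_has_orthologue))
    expect_true(all(out$stage4_seed_conserved <= out$stage3_multi_timepoint))
  }
})

test_that("build_mirna_records counts targets per time-point and joins orthology", {
  nets <- list(
    `24h` = mk_net(data.frame(from = c("miR_a", "miR_a"),
                              to = c("gene_X", "gene_Y")), "24h"),
    `72h` = mk_net(data.frame(from = "miR_a", to = "gene_X"), "72h"))
  mti <- extract_mti(nets)
  rec <- build_mirna_records(c("miR_a", "miR_b"), mti,
                             timepoints = c("24h", "72h"),
                             orthology = data.frame(rat_id = "miR_a",
                                                    human_id = "hsa-miR-a"))
  expect_equal(rec$targets_24h, c(2L, 0L))
  expect_equal(rec$targets_72h, c(1L, 0L))
  expect_equal(rec$human_id, c("hsa-miR-a", NA))
  # target count at a time-point never exceeds total degree there
  expect_lte(rec$targets_24h[1], nrow(nets$`24h`$arcs))
})

test_that("recurrence tables apply the >=2 time-point and >2 miRNA thresholds", {
  mti <- data.frame(mirna = c("m1", "m2", "m3", "m1"),
                    mrna = c("gA", "gA", "gA", "gB"), stringsAsFactors = FALSE)
  mti$timepoints <- list("24h", "24h", "24h", c("24h", "72h"))
  mti$n_timepoints <- lengths(mti$timepoints)
  de <- data.frame(entity_id = c("gA", "gA", "gB"),
                   timepoint = c("24h", "72h", "24h"),
                   de = TRUE)
  out <- recurrence_tables(mti, c("m1", "m2", "m3"), de)
  # gA DE at 2 time-points -> its MTIs kept; gB at 1 -> dropped
  expect_setequal(out$recurrent_target_mtis$mrna, "gA")
  expect_equal(nrow(out$recurrent_target_mtis), 3)
  # gA targeted by 3 shortlist miRNAs at 24h -> reported with count 3
  expect_equal(out$multi_targeted_mrnas$mrna, "gA")
  expect_equal(out$multi_targeted_mrnas$n_mirnas, 3L)
})

test_that("normalized_degree_heat z-scores rows and flags degenerate ones", {
  counts <- rbind(two = c(1, 3, NA), flat = c(2, 2, 2), single = c(4, NA, NA))
  colnames(counts) <- c("24h", "72h", "10d")
  h <- normalized_degree_heat(counts)
  expect_equal(unname(h["two", 1:2]), c(-1, 1))
  expect_true(is.na(h["two", "10d"]))
  expect_equal(unname(h["flat", ]), c(0, 0, 0))
  expect_true(all(is.na(h["single", ])))
  expect_equal(attr(h, "degenerate"), "flat")
  expect_equal(attr(h, "non_normalisable"), "single")
  # the maximum cell per time-point identifies the top-targeting miRNA
  expect_equal(rownames(counts)[which.max(h[, "72h"])], "two")
})

test_that("annotate_resources joins confidence and flags without changing the MTI set", {
  mti <- data.frame(mirna = c("rno-miR-1", "rno-miR-2"),
                    mrna = c("GENEA", "GENEB"), stringsAsFactors = FALSE)
  mti$timepoints <- list("24h", "72h")
  orth <- data.frame(rat_id = c("rno-miR-1", "rno-miR-2"),
                     human_id = c("hsa-miR-1", "hsa-miR-2"))
  pred <- data.frame(mirna = c("hsa-miR-1", "hsa-miR-9"),
                     gene = c("GENEA", "GENEA"),
                     confidence = c("Very High", "Low"), stringsAsFactors = FALSE)
  val <- data.frame(mirna = "hsa-miR-1", gene = "GENEA")
  out <- annotate_resources(mti, pred, validated = val,
                            human_de_mirna = "hsa-miR-2",
                            human_de_mrna = "GENEA", orthology = orth)
  expect_equal(nrow(out), 2)
  expect_equal(out$confidence, c("Very High", NA))
  expect_equal(out$validated, c(TRUE, FALSE))
  expect_equal(out$iclip, c(FALSE, FALSE))
  expect_equal(out$human_dysregulated_mirna, c(FALSE, TRUE))
  expect_equal(out$human_dysregulated_mrna, c(TRUE, FALSE))
  expect_equal(out[, c("mirna", "mrna")], mti[, c("mirna", "mrna")])
})

test_that("malformed resource rows are skipped with a warning", {
  mti <- data.frame(mirna = "rno-miR-1", mrna = "GENEA", stringsAsFactors = FALSE)
  pred <- data.frame(mirna = c("rno-miR-1", NA), gene = c("GENEA", "GENEB"),
                     confidence = c("High", "Low"), stringsAsFactors = FALSE)
  expect_warning(out <- annotate_resources(mti, pred), "malformed")
  expect_equal(out$confidence, "High")
})

test_that("planted confidence enrichment is visible in the class profile", {
  # network MTIs drawn mostly from High/Medium classes; the background for
  # the same miRNAs is mostly Low - the profiles must reflect that
  set.seed(55)
  mirnas <- paste0("hsa-miR-", 1:5)
  background <- data.frame(
    mirna = rep(mirnas, each = 40),
    gene = paste0("G", 1:200),
    confidence = sample(c("Low", "Medium", "High"), 200, TRUE,
                        prob = c(0.8, 0.15, 0.05)),
    stringsAsFactors = FALSE)
  enriched_pairs <- background[background$confidence != "Low", ]
  picked <- enriched_pairs[sample(nrow(enriched_pairs), 20), ]
  mti <- data.frame(mirna = picked$mirna, mrna = picked$gene,
                    stringsAsFactors = FALSE)
  out <- annotate_resources(mti, background)
  net_prof <- confidence_profile(out$confidence)
  bg_prof <- confidence_profile(background$confidence)
  expect_gt(net_prof[["High"]] + net_prof[["Medium"]],
            bg_prof[["High"]] + bg_prof[["Medium"]])
})
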