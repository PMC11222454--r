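test_that("bh_adjust matches hand-evaluated step-up cases", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.2, 0.9)), c(0.4, 0.9))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.2, 1.4)), class = "epimirnet_invalid_input")
  expect_error(bh_adjust(c(-0.1)), class = "epimirnet_invalid_input")
})

test_that("bh_adjust equals the naive O(m^2) reference and is permutation-invariant", {
  set.seed(42)
  for (i in 1:30) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), naive_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
  }
})

test_that("zscore_rows uses the population sd and flags degenerate rows", {
  m <- matrix(c(1, 2, 3), 1, dimnames = list("g", NULL))
  z <- zscore_rows(m)
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # idempotence
  expect_equal(zscore_rows(z), z, tolerance = 1e-12)
  expect_error(zscore_rows(matrix(5, 1, 3, dimnames = list("flat", NULL))),
               "flat", class = "epimirnet_degenerate_row")
})

test_that("the Welch stand-in flags planted shifts and respects alpha", {
  nodes <- data.frame(id = paste0("gene_", 1:20), type = rep("mRNA", 20))
  base <- matrix(0, 20, 6, dimnames = list(nodes$id, c(default_timepoints(), "Control")))
  base["gene_3", "72h"] <- 5
  sc <- regulatory_scenario(nodes, baseline = base, rng_seed = 4)
  ds <- simulate_expression(sc)
  de <- stand_in_de_test(ds, "72h")
  expect_true(de$de[de$entity_id == "gene_3"])
  expect_true(all(de$p_adjusted >= de$p))
  # alpha = 0 rejects nothing
  de0 <- stand_in_de_test(ds, "72h", alpha = 0)
  expect_false(any(de0$de))
})

test_that("identical constant groups are not DE and missing controls error", {
  vals <- matrix(3, 2, 6, dimnames = list(c("a", "b"), NULL))
  em <- data.frame(id = c("a", "b"), type = "mRNA")
  sm <- data.frame(sample_id = paste0("s", 1:6),
                   timepoint = rep(c("24h", "Control"), each = 3),
                   replicate = rep(1:3, 2),
                   control = rep(c(FALSE, TRUE), each = 3))
  ds <- expression_dataset(vals, em, sm)
  de <- stand_in_de_test(ds, "24h")
  expect_false(any(de$de))

  sm2 <- sm; sm2$control <- FALSE; sm2$timepoint <- rep(c("24h", "72h"), each = 3)
  ds2 <- expression_dataset(vals, em, sm2)
  expect_error(stand_in_de_test(ds2, "24h"), class = "epimirnet_configuration_error")
})

test_that("BH is applied separately within entity types", {
  set.seed(1)
  nodes <- data.frame(id = c(paste0("miR_", 1:2), paste0("gene_", 1:40)),
                      type = c("miRNA", "miRNA", rep("mRNA", 40)))
  base <- matrix(0, 42, 6, dimnames = list(nodes$id, c(default_timepoints(), "Control")))
  sc <- regulatory_scenario(nodes, baseline = base, rng_seed = 4)
  ds <- simulate_expression(sc)
  de <- stand_in_de_test(ds, "10d")
  mir <- de[de$entity_type == "miRNA", ]
  expect_equal(mir$p_adjusted, unname(bh_adjust(mir$p)))
  mr <- de[de$entity_type == "mRNA", ]
  expect_equal(mr$p_adjusted, unname(bh_adjust(mr$p)))
})

test_that("select_model_variables unions DE miRNAs with bi-clustered mRNAs", {
  sc <- generate_scenario(4, 10, edge_density = 0.1, seed = 31)
  ds <- simulate_expression(sc)
  de <- data.frame(entity_id = c("miR_01", "miR_02", "miR_02", "gene_001"),
                   entity_type = c("miRNA", "miRNA", "miRNA", "mRNA"),
                   timepoint = c("24h", "DOFS", "72h", "24h"),
                   de = c(TRUE, TRUE, FALSE, TRUE))
  bic <- list(`24h` = c("gene_002", "gene_003"), `72h` = character(0))
  mi <- select_model_variables(de, bic, "24h", ds)
  # DE miRNA at 24h + bi-clustered mRNAs at 24h; miR_02 (DOFS only) excluded
  expect_setequal(rownames(mi$values), c("miR_01", "gene_002", "gene_003"))
  expect_equal(ncol(mi$values), sum(!ds$sample_meta$control))
  expect_equal(unname(rowMeans(mi$values)), rep(0, 3), tolerance = 1e-8)
  sds <- apply(mi$values, 1, function(r) sqrt(mean((r - mean(r))^2)))
  expect_equal(unname(sds), rep(1, 3), tolerance = 1e-8)

  expect_error(select_model_variables(de, bic, "72h", ds),
               class = "epimirnet_empty_model")
  expect_error(select_model_variables(de, bic, "Chronic", ds),
               class = "epimirnet_invalid_parameter")
})

test_that("model-variable count is always |DE miRNA_t| + |bicluster mRNA_t|", {
  sc <- generate_scenario(8, 25, edge_density = 0.08, seed = 13)
  ds <- simulate_expression(sc)
  de <- de_all_timepoints(ds)
  bic <- bicluster_pipeline(ds, de)
  for (t in default_timepoints()) {
    n_mir <- length(unique(de$entity_id[de$timepoint == t & de$de &
                                          de$entity_type == "miRNA"]))
    n_mrna <- length(bic$merged[[t]])
    if (n_mir + n_mrna == 0) next
    mi <- select_model_variables(de, bic$merged, t, ds)
    expect_equal(nrow(mi$values), n_mir + n_mrna)
  }
})

test_that("DE tables round-trip through TSV", {
  de <- data.frame(entity_id = c("a", "b"), entity_type = c("miRNA", "mRNA"),
                   timepoint = "24h", log2fc = c(1.5, -2), p = c(0.01, 0.2),
                   p_adjusted = c(0.02, 0.2), direction = c("up", "down"),
                   de = c(TRUE, FALSE))
  tmp <- tempfile(fileext = ".tsv")
  write_de_tsv(de, tmp)
  back <- read_de_tsv(tmp)
  expect_equal(back$entity_id, de$entity_id)
  expect_equal(back$p_adjusted, de$p_adjusted)
  expect_equal(back$de, de$de)
})
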