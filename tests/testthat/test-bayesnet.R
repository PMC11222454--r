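test_that("family_bic matches the closed-form Gaussian score", {
  m <- matrix(c(-1, 0, 1), 1, dimnames = list("x", NULL))
  expected <- -(3 / 2) * (log(2 * pi * 2 / 3) + 1) - (2 / 2) * log(3)
  expect_equal(family_bic(m, "x"), expected, tolerance = 1e-10)
  expect_equal(family_bic(m, "x"), -4.7472, tolerance = 1e-4)
})

test_that("the network score decomposes into family scores", {
  set.seed(2)
  X <- random_gaussian_dataset(4, 50, seed = 2)
  arcs <- data.frame(from = c("v1", "v1", "v2"), to = c("v2", "v3", "v4"))
  total <- bic_network_score(X, arcs)
  manual <- family_bic(X, "v1") + family_bic(X, "v2", "v1") +
    family_bic(X, "v3", "v1") + family_bic(X, "v4", "v2")
  expect_equal(total, manual, tolerance = 1e-10)
})

test_that("an independent-noise parent changes the family score by about -log(n)/2", {
  set.seed(33)
  n <- 10000
  X <- rbind(child = rnorm(n), noise = rnorm(n))
  delta <- family_bic(X, "child", "noise") - family_bic(X, "child")
  # the penalty is exactly -log(n)/2; the fitted coefficient adds O(1) noise
  expect_lt(abs(delta + log(n) / 2), 2)
})

test_that("collinear parents are scored -Inf", {
  x <- rnorm(30)
  X <- rbind(a = x, b = 2 * x, child = rnorm(30))
  expect_identical(family_bic(X, "child", c("a", "b")), -Inf)
})

test_that("hill_climb returns the empty DAG on independent noise", {
  set.seed(5)
  X <- zscore_rows(matrix(rnorm(3 * 5000), 3,
                          dimnames = list(c("a", "b", "c"), NULL)))
  expect_equal(nrow(hill_climb(X)$arcs), 0)
})

test_that("hill_climb recovers a strong pairwise dependence (either orientation)", {
  set.seed(6)
  n <- 500
  x <- rnorm(n); y <- 0.9 * x + rnorm(n)
  X <- zscore_rows(rbind(X = x, Y = y))
  arcs <- hill_climb(X)$arcs
  expect_equal(nrow(arcs), 1)
  expect_true(all(sort(c(arcs$from, arcs$to)) == c("X", "Y")))
})

test_that("hill_climb attains the exhaustive 25-DAG optimum on 3 variables", {
  dags3 <- enumerate_dags(paste0("v", 1:3))
  expect_equal(length(dags3), 25)
  for (s in 1:10) {
    X <- random_gaussian_dataset(3, 200, seed = 300 + s)
    hc_score <- bic_network_score(X, hill_climb(X)$arcs)
    expect_equal(hc_score, exhaustive_best_bic(X, dags3), tolerance = 1e-8)
  }
})

test_that("hill_climb improves on the empty graph whenever it adds arcs", {
  for (s in 1:5) {
    X <- random_gaussian_dataset(5, 100, seed = 500 + s)
    dag <- hill_climb(X)
    empty <- bic_network_score(X, data.frame(from = character(0), to = character(0)))
    score <- bic_network_score(X, dag$arcs)
    expect_gte(score, empty)
    if (nrow(dag$arcs) > 0) expect_gt(score, empty)
  }
})

test_that("bootstrap strengths are exact replicate frequencies in [0,1]", {
  set.seed(9)
  n <- 60
  x <- rnorm(n); y <- 0.95 * x + rnorm(n, 0, 0.3); z <- rnorm(n)
  X <- zscore_rows(rbind(A = x, B = y, C = z))
  cfg <- learn_config(B = 50, rng_seed = 4)
  net <- bootstrap_strength(as_model_input(X), cfg)
  expect_true(all(net$arcs$strength >= 0 & net$arcs$strength <= 1))
  counts <- attr(net, "counts")
  expect_equal(net$arcs$strength,
               counts[cbind(net$arcs$from, net$arcs$to)] / cfg$B)
  # determinism
  net2 <- bootstrap_strength(as_model_input(X), cfg)
  expect_equal(net$arcs, net2$arcs)
  # the planted strong edge outscores any absent edge in skeleton strength
  skel <- counts + t(counts)
  expect_gt(skel["A", "B"] / cfg$B, max(skel["A", "C"], skel["B", "C"]) / cfg$B)
})

test_that("a planted strong edge beats absent edges across 10 scenario draws", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(700 + s)
    n <- 40
    x <- rnorm(n); y <- 0.9 * x + rnorm(n, 0, sqrt(1 - 0.81)); z <- rnorm(n)
    X <- zscore_rows(rbind(P = x, Q = y, R = z))
    net <- bootstrap_strength(as_model_input(X), learn_config(B = 200, rng_seed = s))
    counts <- attr(net, "counts")
    skel <- counts + t(counts)
    if (skel["P", "Q"] > max(skel["P", "R"], skel["Q", "R"])) wins <- wins + 1L
  }
  expect_equal(wins, 10L)
})

test_that("quartile_filter implements the interpolated upper quartile", {
  net <- strength_network(data.frame(from = c("a", "b", "c", "d"),
                                     to = c("b", "c", "d", "a"),
                                     strength = c(0.1, 0.2, 0.3, 0.9)),
                          nodes = data.frame(id = letters[1:4], type = "mRNA"))
  f <- quartile_filter(net)
  expect_equal(f$quartile_threshold, 0.45)
  kept <- f$arcs[f$arcs$retained, ]
  expect_equal(kept$strength, 0.9)

  # all-equal strengths: everything retained
  net2 <- strength_network(data.frame(from = c("a", "b"), to = c("b", "c"),
                                      strength = c(0.5, 0.5)),
                           nodes = data.frame(id = letters[1:3], type = "mRNA"))
  f2 <- quartile_filter(net2)
  expect_true(all(f2$arcs$retained))

  # zero-strength network: empty result with a warning
  net3 <- strength_network(data.frame(from = "a", to = "b", strength = 0),
                           nodes = data.frame(id = c("a", "b"), type = "mRNA"))
  expect_warning(f3 <- quartile_filter(net3), "empty")
  expect_equal(nrow(f3$arcs), 0)
})

test_that("quartile_filter keeps about a quarter of distinct strengths", {
  set.seed(10)
  strengths <- sample(seq(0.001, 1, length.out = 100))
  arcs <- data.frame(from = paste0("n", 1:100), to = paste0("n", c(2:100, 1)),
                     strength = strengths)
  net <- strength_network(arcs, nodes = data.frame(id = paste0("n", 1:100),
                                                   type = "mRNA"))
  f <- quartile_filter(net)
  expect_lte(abs(sum(f$arcs$retained) - 25), 2)
})

test_that("classify_edges partitions arcs by endpoint types", {
  net <- strength_network(data.frame(from = c("miR_a", "gene_X"),
                                     to = c("gene_X", "gene_Y")))
  counts <- classify_edges(net)
  expect_equal(unname(counts["miRNA->mRNA"]), 1L)
  expect_equal(unname(counts["mRNA->mRNA"]), 1L)
  expect_equal(sum(counts), 2L)

  empty <- strength_network(data.frame(from = character(0), to = character(0),
                                       strength = numeric(0)),
                            nodes = data.frame(id = "gene_1", type = "mRNA"))
  expect_equal(sum(classify_edges(empty)), 0L)

  badnet <- strength_network(data.frame(from = "a", to = "b"),
                             nodes = data.frame(id = c("a", "b"),
                                                type = c("mRNA", "protein")))
  expect_error(classify_edges(badnet), "b", class = "epimirnet_invalid_input")
})

test_that("classify_edges counts always sum to the number of arcs", {
  set.seed(12)
  for (i in 1:5) {
    ids <- c(paste0("miR_", 1:4), paste0("gene_", 1:6))
    pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    arcs <- pairs[sample(nrow(pairs), 12), ]
    arcs$strength <- runif(12)
    net <- strength_network(arcs)
    expect_equal(sum(classify_edges(net)), 12L)
  }
})

test_that("learn_config validates its ranges", {
  expect_error(learn_config(B = 0), class = "epimirnet_invalid_parameter")
  expect_error(learn_config(quartile = 1), class = "epimirnet_invalid_parameter")
  expect_equal(learn_config()$B, 1000L)
  expect_equal(learn_config()$quartile, 0.75)
})

test_that("undirected strength mode reports skeleton frequency and majority direction", {
  set.seed(14)
  n <- 80
  x <- rnorm(n); y <- 0.9 * x + rnorm(n, 0, 0.4)
  X <- zscore_rows(rbind(U = x, V = y))
  net <- bootstrap_strength(as_model_input(X),
                            learn_config(B = 100, rng_seed = 2,
                                         strength_mode = "undirected"))
  expect_equal(nrow(net$arcs), 1)
  expect_equal(net$arcs$strength, 1)
  expect_gte(net$arcs$direction_prob, 0.5)
})
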