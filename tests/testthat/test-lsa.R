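test_that("abundance filter uses a strict threshold on the row mean", {
  m <- matrix(c(rep(6e-4, 4), rep(5e-4, 4), rep(1e-5, 4)), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("S", 1:4)))
  kept <- abundance_filter(m)
  expect_identical(rownames(kept), "a")
  expect_identical(nrow(abundance_filter(m, min_mean = 1)), 0L)
})

test_that("normal scores match the closed-form quantiles, with midranks", {
  z <- normal_score_transform(c(5, 1, 9))
  expect_equal(z, qnorm(c(0.5, 0.25, 0.75)), tolerance = 1e-12)
  expect_equal(z[1], 0)
  expect_equal(z[3], -z[2])
  mono <- normal_score_transform(c(2, 5, 11, 40))
  expect_true(all(diff(mono) > 0))
  tied <- normal_score_transform(c(1, 1, 2))
  expect_equal(tied, qnorm(c(1.5, 1.5, 3) / 4))
  const <- normal_score_transform(rep(3, 5))
  expect_equal(unclass(const), rep(0, 5), ignore_attr = TRUE)
  expect_true(attr(const, "constant"))
})

test_that("the dynamic program equals exhaustive enumeration", {
  set.seed(11)
  for (i in 1:300) {
    n <- 8; D <- sample(0:2, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(local_similarity(x, y, D)$score, brute_lsa(x, y, D)$score,
                 tolerance = 1e-9)
  }
})

test_that("self-alignment, antisymmetry and symmetry hold", {
  set.seed(12)
  x <- normal_score_transform(rnorm(30))
  self <- local_similarity(x, x, 3)
  expect_identical(self$sign, 1L)
  expect_identical(self$delay, 0L)
  expect_equal(self$score, sum(x^2) / length(x))  # all-positive products
  neg <- local_similarity(x, -x, 3)
  expect_identical(neg$sign, -1L)
  expect_equal(abs(neg$score), self$score)
  y <- normal_score_transform(rnorm(30))
  expect_equal(abs(local_similarity(x, y, 3)$score),
               abs(local_similarity(y, x, 3)$score))
  expect_error(local_similarity(x, y[-1], 3), "length mismatch")
})

test_that("ls score sign tracks the Pearson sign for strong correlations", {
  set.seed(13)
  agree <- replicate(200, {
    x <- rnorm(20); y <- 0.8 * x + rnorm(20) * sample(c(0.5, -0.5), 1)
    r <- cor(x, y)
    if (abs(r) <= 0.3) NA
    else sign(local_similarity(normal_score_transform(x),
                               normal_score_transform(y), 0)$score) == sign(r)
  })
  expect_gte(mean(agree, na.rm = TRUE), 0.99)
})

test_that("permutation p-values behave at the extremes and are seeded", {
  set.seed(14)
  x <- normal_score_transform(rnorm(30))
  p_self <- permutation_significance(x, x, 3, n_perm = 500)
  expect_equal(p_self, 1 / 501)
  expect_error(permutation_significance(x, x, 3, n_perm = 50), "100")
  set.seed(99); p1 <- permutation_significance(x, rev(x), 3, n_perm = 200)
  set.seed(99); p2 <- permutation_significance(x, rev(x), 3, n_perm = 200)
  expect_identical(p1, p2)
})

test_that("network thresholds retain |score| > 0.6 with q < 0.01", {
  edges <- data.frame(feature_a = c("a", "a", "b"),
                      feature_b = c("b", "c", "c"),
                      score = c(0.61, 0.74, -0.8), sign = c(1, 1, -1),
                      delay = 0L, p = c(0.001, 0.004, 0.001),
                      q = c(0.005, 0.02, 0.005))
  rel <- matrix(0.1, 3, 2, dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  g <- build_network(edges, rel)
  expect_equal(igraph::ecount(g), 2)
  kept <- igraph::as_data_frame(g)
  expect_true(all(abs(kept$score) > 0.6 & kept$q < 0.01))
  # raw-p mode keeps the 0.74 edge
  g2 <- build_network(edges, rel, use_raw_p = TRUE)
  expect_equal(igraph::ecount(g2), 3)
})

test_that("positive k-core keeps cliques and discards stars", {
  clique <- t(combn(paste0("v", 1:12), 2))
  edges <- data.frame(feature_a = clique[, 1], feature_b = clique[, 2],
                      score = 0.9, sign = 1, delay = 0L, p = 1e-3, q = 1e-3)
  rel <- matrix(0.01, 12, 2, dimnames = list(paste0("v", 1:12), c("S1", "S2")))
  g <- build_network(edges, rel)
  core <- kcore_positive(g, k = 10)
  expect_length(core, 1)
  expect_setequal(core[[1]], paste0("v", 1:12))
  star <- data.frame(feature_a = "hub", feature_b = paste0("leaf", 1:6),
                     score = 0.9, sign = 1, delay = 0L, p = 1e-3, q = 1e-3)
  rel_s <- matrix(0.01, 7, 2,
                  dimnames = list(c("hub", paste0("leaf", 1:6)), c("S1", "S2")))
  expect_length(kcore_positive(build_network(star, rel_s), k = 2), 0)
})

test_that("cluster abundance series are per-sample member sums", {
  rel <- matrix(c(0.1, 0.2, 0.3, 0.05, 0.15, 0.25), 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  ser <- cluster_abundance_series(list(g1 = c("a", "b"), g2 = "c"), rel)
  expect_equal(unname(ser["g1", ]), c(0.1 + 0.3, 0.2 + 0.05))
  expect_true(all(colSums(ser) <= 1 + 1e-12))
  expect_error(cluster_abundance_series(list(g1 = c("a", "b"), g2 = "a"),
                                        rel), "disjoint")
})

test_that("all-pairs LSA drops constant features and yields BH q-values", {
  set.seed(15)
  m <- rbind(matrix(rlnorm(5 * 20), 5), rep(0.2, 20))
  rownames(m) <- paste0("f", 1:6); colnames(m) <- paste0("S", 1:20)
  expect_warning(tab <- lsa_all_pairs(m, max_delay = 2, n_perm = 200,
                                      seed = 1), "constant")
  expect_equal(nrow(tab), choose(5, 2))
  expect_equal(tab$q, p.adjust(tab$p, "BH"))
})
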