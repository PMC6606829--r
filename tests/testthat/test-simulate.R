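test_that("generator is deterministic under a fixed seed", {
  a <- small_sim(seed = 7)
  b <- small_sim(seed = 7)
  expect_identical(a$depth, b$depth)
  expect_identical(a$otu_counts, b$otu_counts)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_community(a, d1); f2 <- write_community(b, d2)
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     info = nm)
})

test_that("abundance columns sum to one and regime boosts act as specified", {
  sim <- small_sim(seed = 2)
  expect_equal(unname(colSums(sim$truth$abundance)), rep(1, 24),
               tolerance = 1e-12)
  # one disturbed-affine genome on a half/half schedule: pre-normalization
  # disturbed/stable abundance ratio is boost^2 = 64 in expectation
  cfg <- simulate_config(
    n_genomes = 20, n_samples = 40,
    regime_schedule = rep(c("disturbed", "stable"), each = 20),
    affinity = c("disturbed", rep("neutral", 19)),
    temporal_sdlog = 0, rng_seed = 3)
  tr <- generate_abundances(cfg)
  g <- tr$abundance["MAG001", ]
  others <- colSums(tr$abundance[-1, , drop = FALSE])
  # undo the per-column renormalization using the neutral genomes
  raw_ratio <- mean(g[1:20] / others[1:20]) / mean(g[21:40] / others[21:40])
  expect_equal(raw_ratio, 64, tolerance = 1e-6)
})

test_that("neutral genomes are regime-independent", {
  # distribution of a neutral genome's abundance must not differ between
  # disturbed and stable samples
  rejections <- sum(vapply(1:20, function(s) {
    cfg <- simulate_config(n_genomes = 10, n_samples = 60,
                           affinity = rep("neutral", 10), rng_seed = s)
    sim <- generate_abundances(cfg)
    sched <- cfg$regime_schedule
    x <- sim$abundance[1, sched == "disturbed"]
    y <- sim$abundance[1, sched == "stable"]
    suppressWarnings(stats::ks.test(x, y)$p.value) < 0.01
  }, logical(1)))
  expect_lte(rejections, 3)
})

test_that("coverage tables imprint the copy-number ratio", {
  cfg0 <- copy_fixture_config(seed = 5, noise_cv = 0)
  sim0 <- simulate_community(cfg0)
  ratio <- sim0$ma16s_cov[names(sim0$truth$true_match), ] /
    sim0$truth$genome_cov[sim0$truth$true_match, ]
  expect_equal(unname(ratio),
               matrix(rep(sim0$truth$rrn_copies, 60), 40), tolerance = 1e-12)

  cfg <- copy_fixture_config(seed = 5, noise_cv = 0.10)
  sim <- simulate_community(cfg)
  mean_ratio <- rowMeans(sim$ma16s_cov[names(sim$truth$true_match), ] /
                           sim$truth$genome_cov[sim$truth$true_match, ])
  expect_true(all(abs(mean_ratio / sim$truth$rrn_copies - 1) < 0.05))
})

test_that("decoy 16S profiles are uncorrelated with genomes", {
  frac <- vapply(1:5, function(s) {
    cfg <- simulate_config(n_genomes = 20, n_decoy_16s = 10, rng_seed = s)
    sim <- simulate_community(cfg)
    decoys <- grep("^DECOY", rownames(sim$ma16s_cov), value = TRUE)
    r <- stats::cor(t(sim$ma16s_cov[decoys, ]), t(sim$truth$genome_cov))
    mean(abs(r) < 0.7)
  }, numeric(1))
  expect_true(all(frac >= 0.95))
})

test_that("window profiles carry the imprinted gradient", {
  w0 <- generate_window_profile(10, 2, 500, noise_cv = 0)
  expect_equal(max(w0) / min(w0), 2, tolerance = 1e-12)
  w1 <- generate_window_profile(10, 1, 500, noise_cv = 0)
  expect_equal(sd(w1), 0)
})

test_that("amplicon counts reproduce the copy-number bias", {
  cfg <- simulate_config(n_genomes = 2, n_samples = 30,
                         regime_schedule = rep("transition", 30),
                         copies = c(1, 4),
                         affinity = rep("neutral", 2),
                         temporal_sdlog = 0, amplicon_reads = 50000,
                         rng_seed = 8)
  sim <- simulate_community(cfg)
  expect_true(all(colSums(sim$otu_counts) == 50000))
  ab <- sim$truth$abundance
  expected <- (ab[2, ] * 4) / (ab[1, ] * 1)
  observed <- sim$otu_counts[2, ] / sim$otu_counts[1, ]
  expect_equal(mean(observed / expected), 1, tolerance = 0.05)
  # regression of log count ratio on log copy ratio over several genomes
  cfg2 <- simulate_config(n_genomes = 8, n_samples = 60,
                          copies = c(1, 1, 2, 2, 4, 4, 8, 8),
                          affinity = rep("neutral", 8),
                          amplicon_reads = 50000, rng_seed = 9)
  sim2 <- simulate_community(cfg2)
  counts <- rowSums(sim2$otu_counts)
  abund <- rowSums(sim2$truth$abundance)
  fit <- lm(log(counts / abund) ~ log(sim2$truth$rrn_copies))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
})

test_that("support evidence passes for every true pair and re-parses losslessly", {
  sim <- small_sim(seed = 4, n_decoy_16s = 5)
  for (m16 in names(sim$truth$true_match)) {
    mag <- sim$truth$true_match[[m16]]
    contigs <- sim$membership$contig_id[sim$membership$mag_id == mag]
    sup <- evaluate_support(sim$blast, sim$pe_links, m16, contigs)
    expect_true(sup$blast_support || sup$pelink_support, info = m16)
  }
  f <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tab(sim$blast, f)
  re <- read_blast_tab(f)
  expect_equal(re$percent_identity, sim$blast$percent_identity)
  expect_equal(re$alignment_length, sim$blast$alignment_length)
})

test_that("generator configs are validated", {
  expect_error(simulate_config(noise_cv = 1.2), "noise_cv")
  expect_error(simulate_config(ptr_range = c(0.5, 2)), "ptr_range")
  expect_error(simulate_config(copies = c(0, 3), n_genomes = 2), "copies")
  expect_error(simulate_config(n_samples = 10), "regime_schedule")
  cfg <- simulate_config(n_genomes = 5,
                         n_samples = 10,
                         regime_schedule = rep(c("stable", "disturbed"), 5))
  expect_length(validate_generator_config(cfg), 0)
})
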