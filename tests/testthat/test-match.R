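mk_cov <- function(values, ids, samples = NULL) {
  m <- if (is.matrix(values)) values
       else matrix(values, nrow = length(ids), byrow = TRUE)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(m)))
  dimnames(m) <- list(ids, samples)
  coverage_matrix(m)
}

test_that("profile correlation recovers proportionality and orthogonality", {
  set.seed(1)
  base <- rlnorm(20)
  mag <- mk_cov(rbind(base), "M1")
  m16 <- mk_cov(rbind(3 * base), "A1")
  r <- correlate_profiles(m16, mag)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-10)

  # construct a pair with exact zero sample correlation (residualize, then
  # shift positive; shifting does not change the correlation)
  x <- rnorm(20)
  y <- unname(residuals(lm(rnorm(20) ~ x)))
  y <- y - min(y) + 0.1
  x <- x - min(x) + 0.1
  r0 <- correlate_profiles(mk_cov(rbind(y), "A1"), mk_cov(rbind(x), "M1"))
  expect_equal(r0$r, 0, tolerance = 1e-10)
  expect_equal(r0$p, 1, tolerance = 1e-10)
})

test_that("zero-variance profiles are flagged unusable, not NaN", {
  mag <- mk_cov(rbind(rep(2, 12)), "M1")
  m16 <- mk_cov(rbind(rlnorm(12)), "A1")
  r <- correlate_profiles(m16, mag)
  expect_false(r$usable)
  expect_true(is.na(r$r))
})

test_that("correlation p-values are calibrated under the null", {
  # Gaussian profiles: the exact null of the t-based p-value formula
  # (correlate_profiles itself only needs dimnamed matrices)
  set.seed(42)
  a <- matrix(rnorm(200 * 60, 10), 200,
              dimnames = list(paste0("A", 1:200), paste0("S", 1:60)))
  b <- matrix(rnorm(100 * 60, 10), 100,
              dimnames = list(paste0("M", 1:100), paste0("S", 1:60)))
  r <- correlate_profiles(a, b)
  frac <- mean(r$p < 0.001)
  expect_lt(frac, 0.0025)  # 20000 null pairs, nominal 0.001
  expect_gt(frac, 0)
  # cross-check p-value formula against cor.test on a few pairs
  for (i in c(1, 57, 311)) {
    ct <- cor.test(a[r$ma16s_id[i], ], b[r$mag_id[i], ])
    expect_equal(r$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(r$p[i], ct$p.value, tolerance = 1e-9)
  }
})

test_that("taxonomy concordance follows deepest-resolved-rank semantics", {
  a <- "Bacteria;Proteobacteria;Gammaproteobacteria;Betaproteobacteriales;Rhodocyclaceae"
  expect_true(taxonomy_concordant(a, "Bacteria;Proteobacteria")$concordant)
  expect_identical(taxonomy_concordant(a, "Bacteria;Proteobacteria")$shared_rank, 2L)
  expect_false(taxonomy_concordant("Bacteria;Proteobacteria",
                                   "Bacteria;Bacteroidetes")$concordant)
  full <- paste0(a, ";Zoogloea")
  tc <- taxonomy_concordant(full, full)
  expect_true(tc$concordant)
  expect_identical(tc$shared_rank, 6L)
  none <- taxonomy_concordant("", "")
  expect_false(none$concordant)
  expect_identical(none$reason, "no information")
})

test_that("physical support applies the BLAST and paired-end thresholds", {
  hit <- function(id, len, mm)
    data.frame(query_id = "A1", subject_id = "c1", percent_identity = id,
               alignment_length = len, mismatches = mm, gap_opens = 0,
               q_start = 1, q_end = len, s_start = 1, s_end = len,
               e_value = 1e-30, bit_score = 100)
  expect_true(evaluate_support(hit(98.2, 150, 2), NULL, "A1", "c1")$blast_support)
  expect_false(evaluate_support(hit(97.9, 300, 1), NULL, "A1", "c1")$blast_support)
  expect_false(evaluate_support(hit(99, 100, 1), NULL, "A1", "c1")$blast_support)
  expect_false(evaluate_support(hit(99, 150, 5), NULL, "A1", "c1")$blast_support)
  links <- data.frame(ma16s_id = "A1", contig_id = c("c1", "c2"),
                      n_pairs = c(3, 2))
  expect_true(evaluate_support(NULL, links, "A1", c("c1", "c2"))$pelink_support)
  expect_false(evaluate_support(NULL, links, "A1", "c1")$pelink_support)
})

test_that("matching recovers the truth exactly on synthetic fixtures", {
  for (s in 1:3) {
    sim <- small_sim(seed = s, n_decoy_16s = 4)
    mc <- mag_coverage(sim$depth, sim$membership, sim$contig_lengths)
    m <- run_matching(sim, mc)
    q <- match_quality(m, sim$truth$true_match)
    expect_equal(unname(q), c(1, 1), info = paste("seed", s))
    expect_false(any(grepl("^DECOY", m$accepted$ma16s_id)))
  }
})

test_that("the filter conjunction rejects with the right reasons", {
  set.seed(9)
  base <- rlnorm(30)
  mag <- mk_cov(rbind(base), "M1", paste0("S", 1:30))
  tax <- "Bacteria;Proteobacteria"
  member <- data.frame(contig_id = "c1", mag_id = "M1")
  # strong correlation, concordant, but no physical evidence
  m16 <- mk_cov(rbind(base * rlnorm(30, 0, 0.05) * 2), "A1", paste0("S", 1:30))
  m <- match_ma16s(m16, mag, c(A1 = tax), c(M1 = tax), member,
                   hits = NULL, links = NULL)
  expect_identical(nrow(m$accepted), 0L)
  expect_identical(m$rejected$reason, "no physical support")
  # correlation below threshold, full support
  noise <- rlnorm(30, 0, 1)
  weak <- mk_cov(rbind(noise), "A1", paste0("S", 1:30))
  stopifnot(cor(noise, base) < 0.7)
  links <- data.frame(ma16s_id = "A1", contig_id = "c1", n_pairs = 10)
  m2 <- match_ma16s(weak, mag, c(A1 = tax), c(M1 = tax), member,
                    hits = NULL, links = links)
  expect_identical(nrow(m2$accepted), 0L)
  expect_identical(m2$rejected$reason, "correlation")
})

test_that("acceptance is monotone in evidence and one-to-one", {
  set.seed(10)
  base <- rlnorm(30)
  samples <- paste0("S", 1:30)
  mag <- mk_cov(rbind(base), "M1", samples)
  m16 <- mk_cov(rbind(base * 2 * rlnorm(30, 0, 0.03)), "A1", samples)
  tax <- "Bacteria;Proteobacteria"
  member <- data.frame(contig_id = "c1", mag_id = "M1")
  links <- data.frame(ma16s_id = "A1", contig_id = "c1", n_pairs = 6)
  hits <- data.frame(query_id = "A1", subject_id = "c1",
                     percent_identity = 99, alignment_length = 500,
                     mismatches = 1, gap_opens = 0, q_start = 1, q_end = 500,
                     s_start = 1, s_end = 500, e_value = 0, bit_score = 900)
  m_links <- match_ma16s(m16, mag, c(A1 = tax), c(M1 = tax), member,
                         hits = NULL, links = links)
  expect_identical(nrow(m_links$accepted), 1L)
  m_both <- match_ma16s(m16, mag, c(A1 = tax), c(M1 = tax), member,
                        hits = hits, links = links)
  expect_identical(nrow(m_both$accepted), 1L)
  # two MA16S competing for one MAG: one-to-one keeps the higher r
  m16b <- mk_cov(rbind(base * 2 * rlnorm(30, 0, 0.03),
                       base * 3 * rlnorm(30, 0, 0.2)),
                 c("A1", "A2"), samples)
  links2 <- rbind(links, data.frame(ma16s_id = "A2", contig_id = "c1",
                                    n_pairs = 6))
  m3 <- match_ma16s(m16b, mag, c(A1 = tax, A2 = tax), c(M1 = tax), member,
                    hits = NULL, links = links2)
  expect_identical(nrow(m3$accepted), 1L)
  expect_identical(m3$accepted$ma16s_id, "A1")
  expect_true("one-to-one conflict" %in% m3$rejected$reason)
})
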