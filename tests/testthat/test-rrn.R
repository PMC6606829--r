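mk_pair_cov <- function(ma16s, mag) {
  samples <- paste0("S", seq_along(ma16s))
  list(m16 = coverage_matrix(matrix(ma16s, 1, dimnames = list("A1", samples))),
       mag = coverage_matrix(matrix(mag, 1, dimnames = list("M1", samples))))
}
pair_df <- data.frame(ma16s_id = "A1", mag_id = "M1")

test_that("per-MAG copy number is the mean coverage ratio above threshold", {
  cv <- mk_pair_cov(c(10, 20, 5), c(5, 10, 2.5))
  est <- per_mag_copy_number(pair_df, cv$m16, cv$mag, min_samples = 3)
  expect_equal(est$mean_ratio, 2)
  expect_identical(est$copy_number, 2L)
  expect_identical(est$n_samples_used, 3L)

  # the sample below the coverage-1 admission threshold is excluded
  cv2 <- mk_pair_cov(c(9, 30, 30), c(0.5, 10, 10))
  est2 <- per_mag_copy_number(pair_df, cv2$m16, cv2$mag, min_samples = 2)
  expect_equal(est2$mean_ratio, 3)
  expect_identical(est2$n_samples_used, 2L)

  est3 <- per_mag_copy_number(pair_df, cv2$m16, cv2$mag, min_samples = 5)
  expect_identical(est3$flag, "insufficient coverage")
  expect_true(is.na(est3$copy_number))
})

test_that("copy numbers are scale invariant per sample", {
  set.seed(1)
  m16 <- rlnorm(12, 2); mag <- m16 / 3
  cv <- mk_pair_cov(m16, mag)
  base <- per_mag_copy_number(pair_df, cv$m16, cv$mag)
  k <- rlnorm(12, 1)
  cvs <- mk_pair_cov(m16 * k, mag * k)
  scaled <- per_mag_copy_number(pair_df, cvs$m16, cvs$mag,
                                cov_threshold = min(mag * k) / 2)
  expect_equal(scaled$mean_ratio, base$mean_ratio, tolerance = 1e-12)
})

test_that("abundance-weighted mean copy number follows the defining formula", {
  est <- data.frame(mag_id = c("M1", "M2", "M3"),
                    ma16s_id = c("A1", "A2", "A3"),
                    mean_ratio = c(1, 2, 4), median_ratio = c(1, 2, 4),
                    copy_number = c(1L, 2L, 4L), n_samples_used = 10L,
                    flag = "ok")
  ab <- coverage_matrix(matrix(c(0.5, 0.3, 0.2), 3,
                               dimnames = list(c("M1", "M2", "M3"), "S1")))
  w <- weighted_mean_copy_number(est, ab)
  expect_equal(w$per_sample$weighted_mean, 1.9)
  # equal copies k give W = k regardless of abundance
  est$copy_number <- 3L
  set.seed(2)
  ab2 <- coverage_matrix(matrix(rlnorm(15), 3,
                                dimnames = list(c("M1", "M2", "M3"),
                                                paste0("S", 1:5))))
  w2 <- weighted_mean_copy_number(est, ab2)
  expect_equal(w2$per_sample$weighted_mean, rep(3, 5), tolerance = 1e-12)
})

test_that("marker-normalized community copy number matches coverage weighting", {
  # single genome with 3 copies, noiseless: every marker ratio is 3
  samples <- paste0("S", 1:4)
  m16 <- coverage_matrix(matrix(rep(c(30, 15, 6, 9), each = 1), 1,
                                dimnames = list("A1", samples)))
  markers <- coverage_matrix(matrix(rep(c(10, 5, 2, 3), times = 3), 3,
                                    dimnames = list(paste0("m", 1:3), samples),
                                    byrow = TRUE))
  mg <- metagenome_copy_number(m16, markers)
  expect_equal(unname(mg$median), rep(3, 4))
  expect_true(all(mg$ratios == 3))
  # two genomes with copies 1 and 5 at equal coverage average to 3
  m16b <- coverage_matrix(matrix(c(10, 50), 2,
                                 dimnames = list(c("A1", "A2"), "S1")))
  markerb <- coverage_matrix(matrix(20, 1, dimnames = list("m1", "S1")))
  expect_equal(unname(metagenome_copy_number(m16b, markerb)$median), 3)
  # zero marker coverage in one sample is flagged missing, median over rest
  markers2 <- markers; markers2["m2", "S3"] <- 0
  mg2 <- metagenome_copy_number(m16, markers2)
  expect_true(is.na(mg2$ratios["m2", "S3"]))
  expect_equal(unname(mg2$median["S3"]), 3)
})

test_that("reference comparison reports per-MAG concordance", {
  est <- data.frame(mag_id = c("M1", "M2", "M3"), ma16s_id = NA,
                    mean_ratio = c(2, 4, 3), median_ratio = c(2, 4, 3),
                    copy_number = c(2L, 4L, 3L), n_samples_used = 10L,
                    flag = "ok")
  tax <- c(M1 = "Bacteria;Proteobacteria;Gp;Op;Fp;Zoogloea",
           M2 = "Bacteria;Proteobacteria;Gp;Op;Fp;Dechloromonas",
           M3 = "Bacteria;Unknownphylum")
  ref <- data.frame(taxon = c("Zoogloea", "Dechloromonas"),
                    copy_number = c(2, 2))
  cmp <- compare_to_reference(est, tax, ref)
  expect_equal(cmp$per_mag$abs_diff, c(0, 2, NA))
  expect_identical(cmp$per_mag$note[3], "no reference")
  expect_equal(cmp$concordance, 0.5)  # M1 within 1 copy, M2 not
  # with a reference equal to the estimates, concordance is 1
  ref2 <- data.frame(taxon = c("Zoogloea", "Dechloromonas"),
                     copy_number = c(2, 4))
  expect_equal(compare_to_reference(est, tax, ref2)$concordance, 1)
})

test_that("the shipped synthetic reference table loads", {
  path <- system.file("extdata", "rrn_reference_synthetic.tsv",
                      package = "sludgecycle")
  ref <- utils::read.delim(path)
  expect_true(all(c("taxon", "copy_number") %in% names(ref)))
  expect_true(all(ref$copy_number >= 1))
})
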