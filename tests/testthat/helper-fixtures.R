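# shared fixtures and independent oracles for the suite

# small regime-structured community (fast default for pipeline-level tests)
small_sim <- function(seed = 1, ...) {
  simulate_community(simulate_config(n_genomes = 12, n_samples = 24,
                                     regime_schedule = default_regime_schedule(
                                       24, disturbed = 5:10, stable = 17:23),
                                     rng_seed = seed, ...))
}

# the copy-number fixture: even community, copies 1..8, no regime structure
# moderately even community (abundance_sdlog 0.5) so every genome clears
# the coverage-1 admission threshold and carries an estimable ratio
copy_fixture_config <- function(seed, noise_cv = 0.10, ...) {
  simulate_config(n_genomes = 40, n_samples = 60, noise_cv = noise_cv,
                  copies = rep(1:8, each = 5),
                  affinity = rep("neutral", 40),
                  abundance_sdlog = 0.5, rng_seed = seed, ...)
}

run_matching <- function(sim, mag_cov, ...) {
  match_ma16s(sim$ma16s_cov, mag_cov, sim$ma16s_tax,
              stats::setNames(sim$mag_qc$taxonomy, sim$mag_qc$mag_id),
              sim$membership, sim$blast, sim$pe_links, ...)
}

# exhaustive local-similarity oracle: every contiguous aligned segment at
# every offset |d| <= D
brute_lsa <- function(x, y, D) {
  n <- length(x); best <- 0; bs <- 1L
  for (d in -D:D) {
    i0 <- max(1, 1 - d); i1 <- min(n, n - d)
    if (i0 > i1) next
    for (a in i0:i1) for (b in a:i1) {
      ssum <- sum(x[a:b] * y[(a:b) + d])
      if (abs(ssum) > best + 1e-12) { best <- abs(ssum); bs <- sign(ssum) }
    }
  }
  list(score = bs * best / n)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

match_quality <- function(m, true_match) {
  acc <- stats::setNames(m$accepted$mag_id, m$accepted$ma16s_id)
  correct <- sum(acc == true_match[names(acc)], na.rm = TRUE)
  c(precision = if (length(acc)) correct / length(acc) else NA_real_,
    recall = correct / length(true_match))
}
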