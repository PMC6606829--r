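#' Default regime schedule for a biweekly 3-year series
#'
#' Sixty biweekly samples with a disturbed operational period spanning
#' samples 10-25 (16 samples), a stable period spanning samples 42-58
#' (17 samples), and transition samples elsewhere.
#'
#' @param n_samples number of samples (default 60).
#' @param disturbed,stable integer sample indices of the two periods.
#' @return character vector of per-sample labels in
#'   `stable` / `disturbed` / `transition`.
#' @export
default_regime_schedule <- function(n_samples = 60,
                                    disturbed = 10:25, stable = 42:58) {
  if (max(c(disturbed, stable)) > n_samples)
    stop("period indices exceed n_samples; supply an explicit regime_schedule")
  sched <- rep("transition", n_samples)
  sched[disturbed] <- "disturbed"
  sched[stable] <- "stable"
  sched
}

# mean-one multiplicative lognormal noise with a given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Build a synthetic community configuration
#'
#' Defines the study conditions the generator emulates: a 60-sample
#' biweekly time series over ~173 genomes with contrasting disturbed and
#' stable operational periods, rrn operon copy numbers between 1 and 8
#' imprinted as 16S coverage = copies x genome coverage, and per-genome
#' per-sample peak-to-trough replication ratios imprinted as log-linear
#' origin-to-terminus coverage gradients.
#'
#' @param n_genomes number of genomes (default 173).
#' @param n_samples number of samples (default 60).
#' @param regime_schedule per-sample regime labels
#'   (default [default_regime_schedule()]).
#' @param copies optional integer vector of per-genome rrn copy numbers in
#'   1..8; by default sampled with the low-copy-skewed frequencies typical
#'   of slow activated-sludge communities.
#' @param copy_link_regime if `TRUE`, disturbed-affine genomes draw copy
#'   numbers from 4..8 and stable-affine genomes from 1..2, imprinting the
#'   community-level trait contrast between regimes.
#' @param affinity optional per-genome regime affinity in
#'   `stable` / `disturbed` / `neutral`; default an even three-way split.
#' @param regime_boost multiplicative abundance boost for a genome in a
#'   sample whose regime matches its affinity (mismatched genomes get the
#'   reciprocal; default 8).
#' @param depth_per_sample total genome coverage per sample, x-fold
#'   (default 400).
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   coverage noise, in [0, 1) (default 0.1).
#' @param window_noise_cv coefficient of variation of per-window coverage
#'   noise in the replication profiles (default 0.05): window coverages
#'   come from wide sliding windows (thousands of positions each), so
#'   their noise is smaller than contig-level sample noise.
#' @param temporal_sdlog lognormal sd of sample-to-sample abundance
#'   fluctuation around each genome's regime-adjusted baseline (default 0.3).
#' @param abundance_sdlog lognormal sd of the per-genome baseline
#'   abundances (default 0.8; smaller values give a more even community).
#' @param ptr_mean,ptr_sd mean and sd of the Normal distribution the true
#'   peak-to-trough ratios are drawn from (defaults 1.57 and 0.14).
#' @param ptr_range interval the true PTRs are clamped to; must lie within
#'   [1, 4].
#' @param ptr_link_regime if `TRUE`, disturbed-affine genomes get
#'   `ptr_mean + 0.5` in disturbed samples (a deliberately regime-linked
#'   replication signal; default `FALSE`, replication independent of regime).
#' @param n_decoy_16s number of decoy 16S sequences whose coverage profiles
#'   are independent of every genome (default 0).
#' @param amplicon_reads reads per amplicon sample (default 20000).
#' @param n_markers number of single-copy universal marker genes
#'   (default 13).
#' @param n_modules number of functional (KEGG-style) modules for the
#'   module-abundance matrix (default 30).
#' @param rng_seed integer seed; all generator randomness derives from it.
#' @return a `sludge_config` list, validated.
#' @export
simulate_config <- function(n_genomes = 173, n_samples = 60,
                            regime_schedule = default_regime_schedule(n_samples),
                            copies = NULL, copy_link_regime = FALSE,
                            affinity = NULL, regime_boost = 8,
                            depth_per_sample = 400, noise_cv = 0.1,
                            window_noise_cv = 0.05, temporal_sdlog = 0.3,
                            abundance_sdlog = 0.8,
                            ptr_mean = 1.57, ptr_sd = 0.14,
                            ptr_range = c(1, 4), ptr_link_regime = FALSE,
                            n_decoy_16s = 0, amplicon_reads = 20000,
                            n_markers = 13, n_modules = 30, rng_seed = 1) {
  cfg <- list(n_genomes = n_genomes, n_samples = n_samples,
              regime_schedule = regime_schedule, copies = copies,
              copy_link_regime = copy_link_regime, affinity = affinity,
              regime_boost = regime_boost,
              depth_per_sample = depth_per_sample, noise_cv = noise_cv,
              window_noise_cv = window_noise_cv,
              temporal_sdlog = temporal_sdlog,
              abundance_sdlog = abundance_sdlog,
              ptr_mean = ptr_mean, ptr_sd = ptr_sd, ptr_range = ptr_range,
              ptr_link_regime = ptr_link_regime,
              n_decoy_16s = n_decoy_16s, amplicon_reads = amplicon_reads,
              n_markers = n_markers, n_modules = n_modules,
              rng_seed = rng_seed)
  problems <- validate_generator_config(cfg)
  if (length(problems)) stop(paste(problems, collapse = "; "))
  class(cfg) <- "sludge_config"
  cfg
}

#' Validate a generator configuration
#' @param cfg a `sludge_config` list.
#' @return character vector of problems (empty if valid).
#' @export
validate_generator_config <- function(cfg) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(cfg$n_genomes >= 1, "n_genomes must be >= 1")
  chk(cfg$n_samples >= 2, "n_samples must be >= 2")
  chk(length(cfg$regime_schedule) == cfg$n_samples,
      "regime_schedule length must equal n_samples")
  chk(all(cfg$regime_schedule %in% c("stable", "disturbed", "transition")),
      "regime_schedule labels must be stable/disturbed/transition")
  if (!is.null(cfg$copies))
    chk(all(cfg$copies >= 1 & cfg$copies <= 8 &
              cfg$copies == round(cfg$copies)),
        "copies must be integers in 1..8")
  chk(cfg$depth_per_sample > 0, "depth_per_sample must be > 0")
  chk(cfg$noise_cv >= 0 && cfg$noise_cv < 1, "noise_cv must be in [0, 1)")
  if (!is.null(cfg$window_noise_cv))
    chk(cfg$window_noise_cv >= 0 && cfg$window_noise_cv < 1,
        "window_noise_cv must be in [0, 1)")
  chk(length(cfg$ptr_range) == 2 && cfg$ptr_range[1] >= 1 &&
        cfg$ptr_range[2] <= 4 && cfg$ptr_range[1] <= cfg$ptr_range[2],
      "ptr_range must be an interval within [1, 4]")
  chk(cfg$n_decoy_16s >= 0, "n_decoy_16s must be >= 0")
  chk(cfg$regime_boost >= 1, "regime_boost must be >= 1")
  chk(is.numeric(cfg$rng_seed) && cfg$rng_seed >= 0,
      "rng_seed must be a non-negative integer")
  p
}

# per-genome static truth: lengths, contigs, copies, affinity, taxonomy,
# baseline abundance
build_genome_table <- function(cfg) {
  n <- cfg$n_genomes
  ids <- sprintf("MAG%03d", seq_len(n))
  affinity <- cfg$affinity
  if (is.null(affinity))
    affinity <- rep(c("stable", "disturbed", "neutral"), length.out = n)
  copies <- cfg$copies
  if (is.null(copies)) {
    if (cfg$copy_link_regime) {
      copies <- integer(n)
      copies[affinity == "disturbed"] <- sample(4:8,
        sum(affinity == "disturbed"), replace = TRUE)
      copies[affinity == "stable"] <- sample(1:2,
        sum(affinity == "stable"), replace = TRUE)
      copies[affinity == "neutral"] <- sample(1:8,
        sum(affinity == "neutral"), replace = TRUE)
    } else {
      copies <- sample(1:8, n, replace = TRUE,
        prob = c(0.33, 0.24, 0.13, 0.09, 0.07, 0.06, 0.04, 0.04))
    }
  }
  phyla <- c("Proteobacteria", "Bacteroidetes", "Actinobacteria",
             "Chloroflexi", "Planctomycetes", "Acidobacteria",
             "Nitrospirae", "Patescibacteria")
  phylum <- sample(phyla, n, replace = TRUE)
  taxonomy <- sprintf("Bacteria;%s;Class_%s;Order_%s;Family_%s;Genus_%03d",
                      phylum, phylum, phylum, phylum, seq_len(n))
  data.frame(
    mag_id = ids,
    genome_length = round(stats::runif(n, 2e6, 6e6)),
    n_contigs = sample(10:60, n, replace = TRUE),
    rrn_copies = as.integer(copies),
    affinity = affinity,
    taxonomy = taxonomy,
    base_abundance = stats::rlnorm(n, meanlog = 0,
                                   sdlog = if (is.null(cfg$abundance_sdlog))
                                     0.8 else cfg$abundance_sdlog),
    stringsAsFactors = FALSE)
}

#' Generate true relative abundances
#'
#' Log-normal per-genome baselines with sample-to-sample lognormal
#' fluctuation; genomes whose regime affinity matches the sample's regime
#' are boosted by `regime_boost`, mismatched genomes damped by its
#' reciprocal, neutral genomes (and transition samples) unchanged. Columns
#' are renormalized to sum to one, producing the two anti-phased abundance
#' guilds characteristic of disturbance-structured communities.
#'
#' @param cfg a `sludge_config`.
#' @param genomes per-genome table (built internally by
#'   [simulate_community()] if omitted).
#' @return list with `abundance` (genomes x samples, columns sum to 1) and
#'   `genomes`.
#' @export
generate_abundances <- function(cfg, genomes = NULL) {
  if (is.null(genomes)) genomes <- build_genome_table(cfg)
  n <- nrow(genomes); s <- cfg$n_samples
  # per-sample disturbance intensity u: 1 in disturbed samples, 0 in stable
  # ones; transition samples sit at heterogeneous intermediate states, so
  # they do not form a third tight archetype (they scatter between the two
  # regimes, as operational transitions do)
  u <- ifelse(cfg$regime_schedule == "disturbed", 1,
              ifelse(cfg$regime_schedule == "stable", 0, NA))
  u[is.na(u)] <- stats::runif(sum(is.na(u)), 0.35, 0.65)
  boost <- matrix(1, n, s)
  boost[genomes$affinity == "disturbed", ] <-
    rep(cfg$regime_boost^(2 * u - 1),
        each = sum(genomes$affinity == "disturbed"))
  boost[genomes$affinity == "stable", ] <-
    rep(cfg$regime_boost^(1 - 2 * u),
        each = sum(genomes$affinity == "stable"))
  fluct <- matrix(stats::rlnorm(n * s, -cfg$temporal_sdlog^2 / 2,
                                cfg$temporal_sdlog), n, s)
  ab <- genomes$base_abundance * boost * fluct
  ab <- sweep(ab, 2, colSums(ab), "/")
  dimnames(ab) <- list(genomes$mag_id,
                       sprintf("S%02d", seq_len(s)))
  list(abundance = ab, genomes = genomes, intensity = u)
}

# split a genome length into n_contigs lengths (min 1500 bp each)
split_contigs <- function(total_len, n_contigs) {
  w <- stats::rgamma(n_contigs, shape = 1.2)
  len <- 1500 + round((total_len - 1500 * n_contigs) * w / sum(w))
  len[n_contigs] <- total_len - sum(len[-n_contigs])
  len
}

#' Generate contig depth and MA16S coverage tables
#'
#' Genome coverage is abundance x total depth. Contig coverages are the
#' genome coverage under multiplicative lognormal noise; MA16S coverage is
#' rrn copies x genome coverage under the same noise model, imprinting the
#' coverage-ratio signal the copy-number estimator reads out. Decoy 16S
#' sequences get independent lognormal profiles uncorrelated with every
#' genome.
#'
#' @param cfg a `sludge_config`.
#' @param truth list from [generate_abundances()].
#' @return list with `depth` (contig coverage matrix), `contig_lengths`,
#'   `membership`, `ma16s_cov`, `ma16s_tax`, `true_match`
#'   (named vector ma16s_id -> mag_id) and `genome_cov`.
#' @export
generate_coverage_tables <- function(cfg, truth) {
  genomes <- truth$genomes
  samples <- colnames(truth$abundance)
  genome_cov <- truth$abundance * cfg$depth_per_sample
  contig_rows <- list(); lengths <- list(); member <- list()
  for (i in seq_len(nrow(genomes))) {
    nc <- genomes$n_contigs[i]
    ids <- sprintf("%s_c%03d", genomes$mag_id[i], seq_len(nc))
    len <- split_contigs(genomes$genome_length[i], nc)
    noise <- matrix(rlnorm_cv(nc * cfg$n_samples, cfg$noise_cv),
                    nc, cfg$n_samples)
    cov <- noise * rep(genome_cov[i, ], each = nc)
    rownames(cov) <- ids
    contig_rows[[i]] <- cov
    lengths[[i]] <- stats::setNames(len, ids)
    member[[i]] <- data.frame(contig_id = ids, mag_id = genomes$mag_id[i],
                              stringsAsFactors = FALSE)
  }
  depth <- do.call(rbind, contig_rows)
  colnames(depth) <- samples
  ma16s_ids <- sub("MAG", "MA16S", genomes$mag_id)
  noise <- matrix(rlnorm_cv(nrow(genomes) * cfg$n_samples, cfg$noise_cv),
                  nrow(genomes), cfg$n_samples)
  ma16s_cov <- genomes$rrn_copies * genome_cov * noise
  rownames(ma16s_cov) <- ma16s_ids
  ma16s_tax <- stats::setNames(genomes$taxonomy, ma16s_ids)
  if (cfg$n_decoy_16s > 0) {
    dec_ids <- sprintf("DECOY%03d", seq_len(cfg$n_decoy_16s))
    scale <- stats::median(ma16s_cov[ma16s_cov > 0])
    dec <- matrix(stats::rlnorm(cfg$n_decoy_16s * cfg$n_samples,
                                log(max(scale, 1e-6)), 1),
                  cfg$n_decoy_16s, cfg$n_samples, dimnames = list(dec_ids, samples))
    ma16s_cov <- rbind(ma16s_cov, dec)
    dec_tax <- sprintf(
      "Bacteria;%s;Class_decoy;Order_decoy;Family_decoy;Decoygenus_%03d",
      sample(c("Proteobacteria", "Bacteroidetes", "Chloroflexi"),
             cfg$n_decoy_16s, replace = TRUE), seq_len(cfg$n_decoy_16s))
    ma16s_tax <- c(ma16s_tax, stats::setNames(dec_tax, dec_ids))
  }
  list(depth = coverage_matrix(depth),
       contig_lengths = unlist(lengths),
       membership = do.call(rbind, member),
       ma16s_cov = coverage_matrix(ma16s_cov),
       ma16s_tax = ma16s_tax,
       true_match = stats::setNames(genomes$mag_id, ma16s_ids),
       genome_cov = coverage_matrix(genome_cov))
}

#' Generate a window coverage profile for one genome in one sample
#'
#' Window positions are an equally spaced grid of origin-to-terminus
#' distance fractions d on [0, 1]; expected coverage is
#' `C * ptr^(1 - d)` (highest near the origin), with multiplicative
#' lognormal noise, and the windows are returned shuffled because the
#' genomic order of windows is unknown for draft genomes.
#'
#' @param coverage genome coverage C in the sample (x-fold).
#' @param ptr true peak-to-trough ratio (>= 1).
#' @param n_windows number of windows (default 2000).
#' @param noise_cv coefficient of variation of window noise.
#' @return numeric vector of window coverages (shuffled order).
#' @export
generate_window_profile <- function(coverage, ptr, n_windows = 2000,
                                    noise_cv = 0.05) {
  d <- seq(0, 1, length.out = n_windows)
  expected <- coverage * ptr^(1 - d)
  sample(expected * rlnorm_cv(n_windows, noise_cv))
}

#' Generate window coverage profiles for genome-sample pairs
#'
#' @param cfg a `sludge_config`.
#' @param truth list carrying `genome_cov` (from
#'   [generate_coverage_tables()]) and `true_ptr` (from
#'   [generate_true_ptr()]).
#' @param mag_ids,sample_ids subsets to generate (defaults: all).
#' @param n_windows windows per profile (default 2000).
#' @return long data.frame `mag_id`, `sample_id`, `window_index`, `coverage`.
#' @export
generate_window_profiles <- function(cfg, truth, mag_ids = NULL,
                                     sample_ids = NULL, n_windows = 2000) {
  if (is.null(mag_ids)) mag_ids <- rownames(truth$genome_cov)
  if (is.null(sample_ids)) sample_ids <- colnames(truth$genome_cov)
  out <- vector("list", length(mag_ids) * length(sample_ids)); k <- 0
  for (g in mag_ids) for (s in sample_ids) {
    w <- generate_window_profile(truth$genome_cov[g, s],
                                 truth$true_ptr[g, s],
                                 n_windows,
                                 if (is.null(cfg$window_noise_cv))
                                   cfg$noise_cv else cfg$window_noise_cv)
    k <- k + 1
    out[[k]] <- data.frame(mag_id = g, sample_id = s,
                           window_index = seq_along(w), coverage = w,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Draw true peak-to-trough ratios
#'
#' PTRs are drawn per genome-sample from Normal(`ptr_mean`, `ptr_sd`) and
#' clamped to `ptr_range`; with `ptr_link_regime = TRUE` disturbed-affine
#' genomes in disturbed samples get an elevated mean.
#'
#' @param cfg a `sludge_config`.
#' @param genomes per-genome table.
#' @return matrix genomes x samples of true PTRs.
#' @export
generate_true_ptr <- function(cfg, genomes) {
  n <- nrow(genomes); s <- cfg$n_samples
  mu <- matrix(cfg$ptr_mean, n, s)
  if (isTRUE(cfg$ptr_link_regime)) {
    dist_samples <- which(cfg$regime_schedule == "disturbed")
    mu[genomes$affinity == "disturbed", dist_samples] <-
      cfg$ptr_mean + 0.5
  }
  ptr <- matrix(stats::rnorm(n * s, mu, cfg$ptr_sd), n, s)
  ptr <- pmin(pmax(ptr, cfg$ptr_range[1]), cfg$ptr_range[2])
  dimnames(ptr) <- list(genomes$mag_id, sprintf("S%02d", seq_len(s)))
  ptr
}

#' Generate an amplicon OTU count table
#'
#' Per sample, a multinomial draw with probabilities proportional to
#' abundance x rrn copies, reproducing the copy-number bias of
#' amplicon-based relative abundances.
#'
#' @param cfg a `sludge_config`.
#' @param truth list from [generate_abundances()].
#' @return integer matrix (OTUs x samples) with column sums equal to
#'   `cfg$amplicon_reads`.
#' @export
generate_amplicon_counts <- function(cfg, truth) {
  prob <- truth$abundance * truth$genomes$rrn_copies
  counts <- apply(prob, 2, function(p)
    stats::rmultinom(1, cfg$amplicon_reads, p))
  rownames(counts) <- sub("MAG", "OTU", truth$genomes$mag_id)
  counts
}

#' Generate BLAST and paired-end support evidence
#'
#' Every true MA16S-MAG pair receives a passing BLAST hit (identity >= 98,
#' alignment > 100 nt, mismatches < 5) to one of the MAG's contigs and a
#' paired-end link record with at least five connecting read pairs. Decoy
#' sequences receive either nothing or sub-threshold evidence (identity
#' 90-97 or fewer than five read pairs), the hardest plausible negatives.
#'
#' @param cfg a `sludge_config`.
#' @param cov list from [generate_coverage_tables()].
#' @return list with `blast` (data.frame as from [read_blast_tab()]) and
#'   `pe_links` (data.frame as from [read_pe_links()]).
#' @export
generate_support_evidence <- function(cfg, cov) {
  true_ids <- names(cov$true_match)
  blast <- list(); links <- list()
  for (m in true_ids) {
    mag <- cov$true_match[[m]]
    contigs <- cov$membership$contig_id[cov$membership$mag_id == mag]
    hit_contig <- sample(contigs, 1)
    alen <- sample(120:1500, 1)
    blast[[m]] <- data.frame(
      query_id = m, subject_id = hit_contig,
      percent_identity = round(stats::runif(1, 98, 100), 2),
      alignment_length = alen, mismatches = sample(0:2, 1), gap_opens = 0,
      q_start = 1, q_end = alen, s_start = 1, s_end = alen,
      e_value = 1e-50, bit_score = 200, stringsAsFactors = FALSE)
    n_link_contigs <- sample(1:2, 1)
    lc <- sample(contigs, min(n_link_contigs, length(contigs)))
    npairs <- max(5, stats::rpois(1, 12))
    per <- c(npairs - (length(lc) - 1), rep(1, length(lc) - 1))
    links[[m]] <- data.frame(ma16s_id = m, contig_id = lc, n_pairs = per,
                             stringsAsFactors = FALSE)
  }
  decoys <- setdiff(rownames(cov$ma16s_cov), true_ids)
  all_contigs <- cov$membership$contig_id
  for (d in decoys) {
    kind <- sample(c("none", "weak_blast", "weak_link"), 1)
    if (kind == "weak_blast") {
      alen <- sample(120:800, 1)
      blast[[d]] <- data.frame(
        query_id = d, subject_id = sample(all_contigs, 1),
        percent_identity = round(stats::runif(1, 90, 97), 2),
        alignment_length = alen, mismatches = sample(6:30, 1), gap_opens = 1,
        q_start = 1, q_end = alen, s_start = 1, s_end = alen,
        e_value = 1e-10, bit_score = 80, stringsAsFactors = FALSE)
    } else if (kind == "weak_link") {
      links[[d]] <- data.frame(ma16s_id = d,
                               contig_id = sample(all_contigs, 1),
                               n_pairs = sample(0:4, 1),
                               stringsAsFactors = FALSE)
    }
  }
  list(blast = do.call(rbind, c(blast, list(NULL))),
       pe_links = do.call(rbind, c(links, list(NULL))))
}

#' Generate single-copy marker gene coverages
#'
#' Each of the `n_markers` universal single-copy marker genes is present
#' once per genome, so its aggregate coverage in a sample is the sum over
#' genomes of the genome coverage, each genome's contribution observed
#' under independent multiplicative lognormal noise (the marker sits on
#' one contig per genome).
#'
#' @param cfg a `sludge_config`.
#' @param cov list carrying `genome_cov`.
#' @return coverage matrix markers x samples.
#' @export
generate_marker_coverage <- function(cfg, cov) {
  g <- cov$genome_cov
  m <- cfg$n_markers
  out <- matrix(0, m, ncol(g),
                dimnames = list(sprintf("marker%02d", seq_len(m)),
                                colnames(g)))
  for (k in seq_len(m)) {
    noise <- matrix(rlnorm_cv(length(g), cfg$noise_cv), nrow(g))
    out[k, ] <- colSums(g * noise)
  }
  coverage_matrix(out)
}

#' Generate a functional-module abundance matrix
#'
#' Module abundance is modeled as the summed abundance of member genes:
#' regime-linked modules follow the aggregate abundance of genomes with the
#' corresponding affinity, while the remaining modules carry a slow
#' exponential drift across the series (community function turning over
#' with plant operation), each with multiplicative noise. The drift gives
#' the module view temporal structure of its own, so transition samples
#' split into early and late functional periods rather than forming a
#' third archetype.
#'
#' @param cfg a `sludge_config`.
#' @param truth list from [generate_abundances()].
#' @return matrix modules x samples of non-negative abundances.
#' @export
generate_module_matrix <- function(cfg, truth) {
  s <- cfg$n_samples
  n <- cfg$n_modules
  aff <- rep(c("stable", "disturbed", "neutral"), length.out = n)
  base <- stats::rlnorm(n, 0, 0.5)
  guild_profile <- function(a) {
    sel <- truth$genomes$affinity == a
    if (!any(sel)) return(rep(1, s))
    p <- colSums(truth$abundance[sel, , drop = FALSE])
    p / mean(p)
  }
  # smooth functional changeover centered mid-series (e.g. a progressing
  # plant upgrade), so the transition samples fall into an early and a
  # late functional state
  tt <- stats::plogis((seq_len(s) - 1) / (s - 1) - 0.5,
                      scale = 0.03) - 0.5
  drift_sign <- rep(c(1, -1), length.out = n)
  profiles <- list(stable = guild_profile("stable"),
                   disturbed = guild_profile("disturbed"))
  out <- t(vapply(seq_len(n), function(i) {
    prof <- if (aff[i] == "neutral") exp(3 * drift_sign[i] * tt)
            else profiles[[aff[i]]]
    base[i] * prof * rlnorm_cv(s, 0.1)
  }, numeric(s)))
  dimnames(out) <- list(sprintf("M%04d", seq_len(n)),
                        colnames(truth$abundance))
  out
}

# random MA16S / decoy sequences (uniform nucleotide composition)
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate a complete synthetic community
#'
#' Runs every generator stage under a single seed and returns all
#' observables plus the ground truth needed by the recovery tests.
#'
#' @param cfg a `sludge_config` from [simulate_config()].
#' @return a `sludge_sim` list with elements `config`, `truth`
#'   (abundance, genome coverage, copies, PTR matrix, true match, regimes),
#'   `depth`, `contig_lengths`, `membership`, `mag_qc`, `ma16s_cov`,
#'   `ma16s_tax`, `ma16s_seq`, `blast`, `pe_links`, `otu_counts`,
#'   `marker_cov`, `module_abund`, `metadata`.
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "sludge_config"))
  set.seed(cfg$rng_seed)
  genomes <- build_genome_table(cfg)
  truth <- generate_abundances(cfg, genomes)
  cov <- generate_coverage_tables(cfg, truth)
  truth$genome_cov <- cov$genome_cov
  truth$true_ptr <- generate_true_ptr(cfg, genomes)
  evidence <- generate_support_evidence(cfg, cov)
  otu <- generate_amplicon_counts(cfg, truth)
  markers <- generate_marker_coverage(cfg, cov)
  modules <- generate_module_matrix(cfg, truth)
  n16 <- nrow(cov$ma16s_cov)
  ma16s_seq <- data.frame(ma16s_id = rownames(cov$ma16s_cov),
                          length = 1500L,
                          sequence = random_dna(n16, 1500),
                          stringsAsFactors = FALSE)
  samples <- colnames(truth$abundance)
  metadata <- data.frame(
    sample_id = samples,
    date = as.character(seq(as.Date("2012-11-01"), by = 14,
                            length.out = cfg$n_samples)),
    regime = cfg$regime_schedule, stringsAsFactors = FALSE)
  mag_qc <- data.frame(
    mag_id = genomes$mag_id,
    completeness = round(stats::runif(nrow(genomes), 76, 99), 1),
    contamination = round(stats::runif(nrow(genomes), 0, 4.5), 2),
    genome_length = genomes$genome_length,
    n_scaffolds = genomes$n_contigs,
    taxonomy = genomes$taxonomy, stringsAsFactors = FALSE)
  structure(list(
    config = cfg,
    truth = list(abundance = truth$abundance,
                 genome_cov = cov$genome_cov,
                 rrn_copies = stats::setNames(genomes$rrn_copies,
                                              genomes$mag_id),
                 affinity = stats::setNames(genomes$affinity,
                                            genomes$mag_id),
                 true_ptr = truth$true_ptr,
                 true_match = cov$true_match,
                 regime_schedule = cfg$regime_schedule,
                 regime_intensity = truth$intensity),
    genomes = genomes,
    depth = cov$depth, contig_lengths = cov$contig_lengths,
    membership = cov$membership, mag_qc = mag_qc,
    ma16s_cov = cov$ma16s_cov, ma16s_tax = cov$ma16s_tax,
    ma16s_seq = ma16s_seq,
    blast = evidence$blast, pe_links = evidence$pe_links,
    otu_counts = otu, marker_cov = markers, module_abund = modules,
    metadata = metadata), class = "sludge_sim")
}

#' Write a simulated community as an on-disk input bundle
#'
#' Emits the full set of tab-separated inputs (plus MA16S FASTA and a
#' truth.json) that the real-mode readers consume, so the file-based
#' pipeline can be exercised end to end.
#'
#' @param sim a `sludge_sim` from [simulate_community()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)
  write_depth_table(sim$depth, path("depth.tsv"))
  write_depth_table(sim$ma16s_cov, path("ma16s_cov.tsv"),
                    id_column = "ma16sName")
  write_depth_table(sim$marker_cov, path("marker_cov.tsv"),
                    id_column = "markerName")
  write_depth_table(sim$module_abund, path("module_abund.tsv"),
                    id_column = "moduleName")
  member <- sim$membership
  member$length <- sim$contig_lengths[member$contig_id]
  write_tsv(member, path("membership.tsv"))
  write_tsv(sim$mag_qc, path("mag_qc.tsv"))
  if (!is.null(sim$blast)) write_blast_tab(sim$blast, path("blast.tsv"))
  if (!is.null(sim$pe_links)) write_tsv(sim$pe_links, path("pe_links.tsv"))
  write_tsv(data.frame(ma16s_id = names(sim$ma16s_tax),
                       taxonomy = unname(sim$ma16s_tax)),
            path("ma16s_tax.tsv"))
  otu <- data.frame(otu_id = rownames(sim$otu_counts), sim$otu_counts,
                    check.names = FALSE)
  write_tsv(otu, path("otu_counts.tsv"))
  write_tsv(sim$metadata, path("metadata.tsv"))
  seqs <- Biostrings::DNAStringSet(sim$ma16s_seq$sequence)
  names(seqs) <- sim$ma16s_seq$ma16s_id
  Biostrings::writeXStringSet(seqs, path("ma16s.fasta"))
  jsonlite::write_json(
    list(rrn_copies = as.list(sim$truth$rrn_copies),
         true_match = as.list(sim$truth$true_match),
         affinity = as.list(sim$truth$affinity),
         regime_schedule = sim$truth$regime_schedule),
    path("truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c("depth.tsv", "ma16s_cov.tsv", "marker_cov.tsv",
             "module_abund.tsv", "membership.tsv", "mag_qc.tsv",
             "ma16s_tax.tsv", "otu_counts.tsv", "metadata.tsv",
             "ma16s.fasta", "truth.json")
  if (!is.null(sim$blast)) files <- c(files, "blast.tsv")
  if (!is.null(sim$pe_links)) files <- c(files, "pe_links.tsv")
  stats::setNames(file.path(dir, files), files)
}
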