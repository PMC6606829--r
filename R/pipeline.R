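#' Validate a pipeline configuration
#'
#' @param config a nested list (or path to a YAML file) with optional
#'   sections `simulate` (generator parameters for [simulate_config()]),
#'   `match`, `rrn`, `irep`, `lsa`, `som`, and top-level `seed`.
#' @return character vector of problems; empty if valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  if (!is.null(config$seed))
    chk(config$seed >= 0, "seed must be non-negative")
  if (!is.null(config$match)) {
    if (!is.null(config$match$r_min))
      chk(config$match$r_min > 0 && config$match$r_min <= 1,
          "match$r_min must be in (0, 1]")
    if (!is.null(config$match$p_max))
      chk(config$match$p_max > 0 && config$match$p_max <= 1,
          "match$p_max must be in (0, 1]")
  }
  if (!is.null(config$rrn) && !is.null(config$rrn$cov_threshold))
    chk(config$rrn$cov_threshold >= 0, "rrn$cov_threshold must be >= 0")
  if (!is.null(config$irep)) {
    if (!is.null(config$irep$r2_min))
      chk(config$irep$r2_min >= 0 && config$irep$r2_min <= 1,
          "irep$r2_min must be in [0, 1]")
    if (!is.null(config$irep$trim_frac))
      chk(config$irep$trim_frac >= 0 && config$irep$trim_frac < 0.5,
          "irep$trim_frac must be in [0, 0.5)")
  }
  if (!is.null(config$lsa)) {
    if (!is.null(config$lsa$score_thresh))
      chk(config$lsa$score_thresh > 0 && config$lsa$score_thresh <= 1,
          "lsa score threshold must be in (0,1]")
    if (!is.null(config$lsa$q_thresh))
      chk(config$lsa$q_thresh > 0 && config$lsa$q_thresh <= 1,
          "lsa$q_thresh must be in (0, 1]")
    if (!is.null(config$lsa$max_delay))
      chk(config$lsa$max_delay >= 0, "lsa$max_delay must be >= 0")
  }
  if (!is.null(config$som)) {
    for (kk in c("k_mags", "k_modules"))
      if (!is.null(config$som[[kk]]))
        chk(config$som[[kk]] >= 2, paste0("som$", kk, " must be >= 2"))
  }
  if (!is.null(config$simulate)) {
    cfg <- try(do.call(simulate_config, config$simulate), silent = TRUE)
    if (inherits(cfg, "try-error"))
      p <- c(p, paste("simulate:", attr(cfg, "condition")$message))
  } else if (!is.null(config$inputs)) {
    for (f in unlist(config$inputs))
      chk(file.exists(f), paste("missing input file:", f))
  } else {
    p <- c(p, "config needs either a simulate block or an inputs block")
  }
  p
}

cfg_get <- function(config, section, key, default) {
  v <- config[[section]][[key]]
  if (is.null(v)) default else v
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> MA16S matching -> rrn copy numbers
#' (per-MAG, abundance-weighted and metagenome-wide) -> replication
#' indices -> LSA co-occurrence network -> SOM consensus periods ->
#' headline group statistics, and returns all stage results plus a
#' manifest echoing every parameter. With `out_dir` set, stage outputs
#' are also written as TSV and the manifest as `manifest.json`.
#'
#' @param config nested list or YAML path; see [validate_config()]. In
#'   simulate mode the `simulate` block is passed to [simulate_config()].
#' @param out_dir optional output directory.
#' @return a `sludge_run` list with elements `sim`, `match`, `rrn`,
#'   `irep`, `lsa`, `som`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config: ", paste(problems, collapse = "; "))
  seed <- if (is.null(config$seed)) 1L else config$seed
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  simulate_mode <- !is.null(config$simulate) || is.null(config$inputs)
  if (simulate_mode) {
    sim_args <- config$simulate
    sim_args$rng_seed <- seed
    sim <- stage("simulate", simulate_community(do.call(simulate_config,
                                                        sim_args)))
  } else {
    sim <- stage("load", load_community(config$inputs))
  }
  mag_cov <- stage("mag_coverage",
                   mag_coverage(sim$depth, sim$membership,
                                sim$contig_lengths))
  match <- stage("match", match_ma16s(
    sim$ma16s_cov, mag_cov, sim$ma16s_tax,
    stats::setNames(sim$mag_qc$taxonomy, sim$mag_qc$mag_id),
    sim$membership, sim$blast, sim$pe_links,
    r_min = cfg_get(config, "match", "r_min", 0.7),
    p_max = cfg_get(config, "match", "p_max", 0.001),
    require_both = cfg_get(config, "match", "require_both", FALSE)))
  estimates <- stage("rrn", per_mag_copy_number(
    match, sim$ma16s_cov, mag_cov,
    cov_threshold = cfg_get(config, "rrn", "cov_threshold", 1),
    min_samples = cfg_get(config, "rrn", "min_samples", 5)))
  regimes <- sim$truth$regime_schedule
  samples <- colnames(mag_cov)
  groups <- list(disturbed = samples[regimes == "disturbed"],
                 stable = samples[regimes == "stable"])
  weighted <- weighted_mean_copy_number(
    estimates, suppressWarnings(relative_abundance(mag_cov)), groups)
  ssu_rows <- if (!is.null(sim$truth$true_match))
    names(sim$truth$true_match) else rownames(sim$ma16s_cov)
  metagenome <- metagenome_copy_number(
    sim$ma16s_cov[ssu_rows, , drop = FALSE], sim$marker_cov)
  if (simulate_mode) {
    irep_mags <- utils::head(sim$genomes$mag_id,
                             cfg_get(config, "irep", "n_mags", 6))
    irep_samples <- samples[regimes != "transition"]
    set.seed(seed + 1)
    windows <- generate_window_profiles(
      sim$config, sim$truth, irep_mags, irep_samples,
      n_windows = cfg_get(config, "irep", "n_windows", 400))
  } else if (!is.null(config$inputs$windows)) {
    windows <- utils::read.delim(config$inputs$windows,
                                 stringsAsFactors = FALSE)
  } else {
    windows <- NULL
  }
  irep <- if (is.null(windows)) NULL
          else stage("irep", irep_table(windows, sim$mag_qc))
  otu_rel <- relative_abundance(sim$otu_counts)
  lsa_tab <- stage("lsa", lsa_all_pairs(
    abundance_filter(otu_rel,
                     cfg_get(config, "lsa", "min_mean", 5e-4)),
    max_delay = cfg_get(config, "lsa", "max_delay", 3),
    n_perm = cfg_get(config, "lsa", "n_perm", 1000), seed = seed + 2))
  net <- build_network(lsa_tab, otu_rel,
                       score_thresh = cfg_get(config, "lsa", "score_thresh",
                                              0.6),
                       q_thresh = cfg_get(config, "lsa", "q_thresh", 0.01))
  clusters <- kcore_positive(net, k = cfg_get(config, "lsa", "kcore", 10))
  series <- cluster_abundance_series(clusters, otu_rel)
  som_a <- stage("som", train_som(t(log_abundance(suppressWarnings(
    relative_abundance(mag_cov))))))
  som_b <- train_som(t(log_abundance(sim$module_abund)))
  labels_a <- ward_superclusters(som_a,
                                 cfg_get(config, "som", "k_mags", 3))
  labels_b <- ward_superclusters(som_b,
                                 cfg_get(config, "som", "k_modules", 4))
  consensus <- consensus_periods(labels_a, labels_b,
                                 stats::setNames(regimes, samples))
  wstat <- compare_groups(weighted$group_values$disturbed,
                          weighted$group_values$stable)
  ir_ok <- if (is.null(irep)) data.frame()
           else irep[irep$admitted, , drop = FALSE]
  irep_stat <- NULL; normality <- NULL
  if (nrow(ir_ok) >= 26) {
    g1 <- ir_ok$irep[ir_ok$sample_id %in% groups$disturbed]
    g2 <- ir_ok$irep[ir_ok$sample_id %in% groups$stable]
    if (length(g1) >= 3 && length(g2) >= 3)
      irep_stat <- compare_groups(g1, g2)
    normality <- irep_normality(ir_ok$irep)
  }
  manifest <- list(
    seed = seed,
    parameters = list(
      simulate = sim$config[setdiff(names(sim$config), "regime_schedule")],
      match = match$thresholds,
      rrn = list(cov_threshold = cfg_get(config, "rrn", "cov_threshold", 1)),
      lsa = list(max_delay = cfg_get(config, "lsa", "max_delay", 3),
                 n_perm = cfg_get(config, "lsa", "n_perm", 1000)),
      som = list(k_mags = cfg_get(config, "som", "k_mags", 3),
                 k_modules = cfg_get(config, "som", "k_modules", 4))),
    n_accepted_matches = nrow(match$accepted),
    n_copy_estimates = sum(estimates$flag == "ok"),
    n_irep_admitted = nrow(ir_ok),
    n_lsa_edges = nrow(lsa_tab),
    n_kcore_clusters = length(clusters),
    consensus_sizes = lengths(consensus$periods))
  run <- structure(list(
    sim = sim, mag_cov = mag_cov, match = match,
    rrn = list(estimates = estimates, weighted = weighted,
               metagenome = metagenome),
    irep = irep,
    lsa = list(edges = lsa_tab, network = net, clusters = clusters,
               series = series),
    som = list(mags = som_a, modules = som_b, labels_a = labels_a,
               labels_b = labels_b, consensus = consensus),
    stats = list(weighted_copy = wstat, irep_groups = irep_stat,
                 irep_normality = normality),
    manifest = manifest), class = "sludge_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(estimates, file.path(out_dir, "rrn_estimates.tsv"))
    write_tsv(weighted$per_sample, file.path(out_dir, "rrn_per_sample.tsv"))
    write_tsv(data.frame(sample_id = names(metagenome$median),
                         median_ratio = unname(metagenome$median)),
              file.path(out_dir, "rrn_metagenome_wide.tsv"))
    if (!is.null(irep)) write_tsv(irep, file.path(out_dir, "irep.tsv"))
    write_tsv(lsa_tab, file.path(out_dir, "lsa_edges.tsv"))
    write_tsv(match$accepted, file.path(out_dir, "matches.tsv"))
    write_tsv(data.frame(sample_id = names(labels_a),
                         supercluster_mags = unname(labels_a),
                         supercluster_modules = unname(labels_b[names(labels_a)])),
              file.path(out_dir, "superclusters.tsv"))
    manifest$outputs <- as.list(tools::md5sum(list.files(out_dir,
      pattern = "[.]tsv$", full.names = TRUE)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    run$manifest <- manifest
  }
  run
}

#' @export
print.sludge_run <- function(x, ...) {
  m <- x$manifest
  cat("sludgecycle pipeline run (seed ", m$seed, ")\n",
      "  accepted MA16S-MAG matches: ", m$n_accepted_matches, "\n",
      "  rrn copy-number estimates:  ", m$n_copy_estimates, "\n",
      "  admitted iRep points:       ", m$n_irep_admitted, "\n",
      "  k-core clusters:            ", m$n_kcore_clusters, "\n",
      "  consensus period sizes:     ",
      paste(m$consensus_sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}
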