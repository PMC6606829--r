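#' Per-MAG rRNA operon copy number from coverage ratios
#'
#' For each accepted MA16S-MAG pair, the per-sample ratio of MA16S
#' coverage to MAG coverage is computed in every sample where the MAG
#' coverage exceeds `cov_threshold` (default 1, the standard admission
#' threshold for this ratio). The copy number is the mean ratio rounded to
#' the nearest integer with a floor of 1; the raw mean and a median are
#' retained alongside.
#'
#' @param match a `sludge_match` from [match_ma16s()] (or a data.frame with
#'   columns `ma16s_id`, `mag_id`).
#' @param ma16s_cov,mag_cov coverage matrices over identical samples.
#' @param cov_threshold minimum MAG coverage for a sample to be used
#'   (default 1).
#' @param min_samples minimum usable samples per estimate (default 5);
#'   estimates with fewer are flagged `insufficient coverage` and carry NA
#'   copy numbers.
#' @return data.frame `mag_id`, `ma16s_id`, `mean_ratio`, `median_ratio`,
#'   `copy_number`, `n_samples_used`, `flag`.
#' @export
per_mag_copy_number <- function(match, ma16s_cov, mag_cov,
                                cov_threshold = 1, min_samples = 5) {
  pairs <- if (inherits(match, "sludge_match")) match$accepted else match
  stopifnot(all(c("ma16s_id", "mag_id") %in% names(pairs)))
  if (!identical(colnames(ma16s_cov), colnames(mag_cov)))
    stop("sample columns differ between coverage matrices")
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    m16 <- pairs$ma16s_id[i]; mg <- pairs$mag_id[i]
    mag <- mag_cov[mg, ]
    use <- mag > cov_threshold
    ratios <- ma16s_cov[m16, use] / mag[use]
    n <- sum(use)
    if (n < min_samples)
      data.frame(mag_id = mg, ma16s_id = m16, mean_ratio = NA_real_,
                 median_ratio = NA_real_, copy_number = NA_integer_,
                 n_samples_used = n, flag = "insufficient coverage",
                 stringsAsFactors = FALSE)
    else
      data.frame(mag_id = mg, ma16s_id = m16, mean_ratio = mean(ratios),
                 median_ratio = stats::median(ratios),
                 copy_number = max(1L, as.integer(round(mean(ratios)))),
                 n_samples_used = n, flag = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(NULL)))
}

#' Abundance-weighted mean copy number per sample
#'
#' The community-level rrn trait statistic: per sample,
#' `W_s = sum(a_gs * c_g) / sum(a_gs)` over the MAGs with copy-number
#' estimates, where `a` is MAG abundance and `c` the integer copy number.
#'
#' @param estimates data.frame from [per_mag_copy_number()]; flagged rows
#'   are dropped.
#' @param mag_abundance matrix of MAG abundances (or coverages) x samples;
#'   MAGs without estimates are dropped with a warning.
#' @param groups optional named list of two sample-id vectors (e.g.
#'   disturbed/stable) for a group summary.
#' @return list with `per_sample` (data.frame `sample_id`, `weighted_mean`,
#'   `flag`) and, when `groups` is given, `group_values` (named list of the
#'   per-sample weighted means in each group).
#' @export
weighted_mean_copy_number <- function(estimates, mag_abundance,
                                      groups = NULL) {
  est <- estimates[estimates$flag == "ok", , drop = FALSE]
  known <- intersect(rownames(mag_abundance), est$mag_id)
  extra <- setdiff(rownames(mag_abundance), est$mag_id)
  if (length(extra))
    warning(length(extra), " MAG(s) without copy-number estimate dropped")
  if (!length(known)) stop("no MAG with a copy-number estimate in the matrix")
  copies <- stats::setNames(est$copy_number, est$mag_id)[known]
  ab <- mag_abundance[known, , drop = FALSE]
  tot <- colSums(ab)
  w <- colSums(ab * copies) / tot
  per_sample <- data.frame(sample_id = colnames(ab), weighted_mean = w,
                           flag = ifelse(tot > 0, "ok", "undefined"),
                           row.names = NULL, stringsAsFactors = FALSE)
  per_sample$weighted_mean[per_sample$flag != "ok"] <- NA_real_
  out <- list(per_sample = per_sample)
  if (!is.null(groups)) {
    out$group_values <- lapply(groups, function(ids)
      per_sample$weighted_mean[match(ids, per_sample$sample_id)])
  }
  out
}

#' Metagenome-wide average copy number from marker-gene normalization
#'
#' Independent of MAG matching: the community average rrn copy number per
#' sample is the ratio of the total coverage of SSU rRNA (MA16S) sequences
#' to the total coverage of a single-copy universal marker gene, repeated
#' over the marker set (default 13 markers) and summarized by the median.
#'
#' @param ma16s_cov coverage matrix of MA16S x samples (totals are taken
#'   over all rows).
#' @param marker_cov coverage matrix of markers x samples.
#' @return list with `ratios` (markers x samples matrix; cells with zero
#'   marker coverage are NA) and `median` (per-sample median over markers).
#' @export
metagenome_copy_number <- function(ma16s_cov, marker_cov) {
  if (!identical(colnames(ma16s_cov), colnames(marker_cov)))
    stop("sample columns differ between coverage matrices")
  ssu_total <- colSums(ma16s_cov)
  ratios <- sweep(1 / marker_cov, 2, ssu_total, "*")
  ratios[!is.finite(ratios)] <- NA_real_
  med <- apply(ratios, 2, stats::median, na.rm = TRUE)
  if (anyNA(med)) stop("sample(s) with no marker coverage at all")
  list(ratios = ratios, median = med)
}

#' Compare copy-number estimates against a reference table
#'
#' Looks up each estimated MAG's lineage in a reference table of known
#' copy numbers (rrnDB-style, taxon name -> copies), at the deepest rank
#' with an entry.
#'
#' @param estimates data.frame from [per_mag_copy_number()].
#' @param mag_tax named character vector, MAG id -> lineage string.
#' @param reference data.frame with columns `taxon`, `copy_number`. A small
#'   synthetic illustration (hand-written plausible values, not an excerpt
#'   of any database) ships at
#'   `system.file("extdata", "rrn_reference_synthetic.tsv", package = "sludgecycle")`;
#'   real analyses should supply a curated table.
#' @return list with `per_mag` (estimate, reference value, matched rank,
#'   absolute difference) and `concordance` (fraction of referenced
#'   estimates within 1 copy).
#' @export
compare_to_reference <- function(estimates, mag_tax, reference) {
  stopifnot(all(c("taxon", "copy_number") %in% names(reference)))
  est <- estimates[estimates$flag == "ok", , drop = FALSE]
  rows <- lapply(seq_len(nrow(est)), function(i) {
    lin <- rev(parse_lineage(mag_tax[[est$mag_id[i]]]))
    hit <- match(lin, reference$taxon)
    k <- which(!is.na(hit))[1]
    if (is.na(k))
      data.frame(mag_id = est$mag_id[i], copy_number = est$copy_number[i],
                 reference = NA_real_, matched_taxon = NA_character_,
                 abs_diff = NA_real_, note = "no reference",
                 stringsAsFactors = FALSE)
    else
      data.frame(mag_id = est$mag_id[i], copy_number = est$copy_number[i],
                 reference = reference$copy_number[hit[k]],
                 matched_taxon = lin[k],
                 abs_diff = abs(est$copy_number[i] -
                                  reference$copy_number[hit[k]]),
                 note = "ok", stringsAsFactors = FALSE)
  })
  per_mag <- do.call(rbind, c(rows, list(NULL)))
  ok <- per_mag$note == "ok"
  list(per_mag = per_mag,
       concordance = if (any(ok)) mean(per_mag$abs_diff[ok] <= 1) else NA_real_)
}
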