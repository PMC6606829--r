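#' All-pairs Pearson correlation of coverage profiles
#'
#' Correlates every MA16S coverage profile against every MAG coverage
#' profile along the whole time series, on raw (untransformed) coverages.
#' Two-sided p-values use the t distribution with n - 2 degrees of
#' freedom. Pairs involving a zero-variance profile are flagged and
#' excluded rather than propagated as NaN.
#'
#' @param ma16s_cov coverage matrix, MA16S x samples.
#' @param mag_cov coverage matrix, MAGs x samples (same sample columns).
#' @param min_samples minimum series length (default 10).
#' @return data.frame `ma16s_id`, `mag_id`, `r`, `p`, `usable`.
#' @export
correlate_profiles <- function(ma16s_cov, mag_cov, min_samples = 10) {
  if (!identical(colnames(ma16s_cov), colnames(mag_cov)))
    stop("sample columns differ between the two coverage matrices")
  n <- ncol(ma16s_cov)
  if (n < min_samples)
    stop("need at least ", min_samples, " samples, got ", n)
  sd16 <- apply(ma16s_cov, 1, stats::sd)
  sdmag <- apply(mag_cov, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(ma16s_cov), t(mag_cov)))
  grid <- expand.grid(ma16s_id = rownames(ma16s_cov),
                      mag_id = rownames(mag_cov),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rv <- r[cbind(grid$ma16s_id, grid$mag_id)]
  usable <- sd16[grid$ma16s_id] > 0 & sdmag[grid$mag_id] > 0
  tstat <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(grid, r = ifelse(usable, rv, NA_real_),
             p = ifelse(usable, p, NA_real_),
             usable = unname(usable))
}

parse_lineage <- function(tax) {
  ranks <- trimws(strsplit(tax, ";", fixed = TRUE)[[1]])
  ranks[nzchar(ranks) & !grepl("^[a-z]__$", ranks)]
}

#' Test taxonomic concordance of two lineages
#'
#' Two lineages are concordant if no named rank conflicts down to the
#' shallower lineage's resolution; missing ranks never conflict. Returns
#' the deepest shared rank index as evidence depth.
#'
#' @param tax_a,tax_b semicolon-joined lineage strings
#'   (domain;phylum;...;genus).
#' @return list with `concordant` (logical), `shared_rank` (integer depth
#'   of the deepest agreeing rank, 0 if none) and `reason`.
#' @export
taxonomy_concordant <- function(tax_a, tax_b) {
  a <- parse_lineage(tax_a); b <- parse_lineage(tax_b)
  if (!length(a) && !length(b))
    return(list(concordant = FALSE, shared_rank = 0L,
                reason = "no information"))
  depth <- min(length(a), length(b))
  if (depth == 0)
    return(list(concordant = TRUE, shared_rank = 0L,
                reason = "one lineage empty"))
  agree <- a[seq_len(depth)] == b[seq_len(depth)]
  if (all(agree))
    list(concordant = TRUE, shared_rank = depth, reason = "concordant")
  else
    list(concordant = FALSE, shared_rank = as.integer(which(!agree)[1] - 1L),
         reason = paste0("conflict at rank ", which(!agree)[1]))
}

#' Evaluate physical support evidence for a candidate pair
#'
#' BLAST support requires a hit from the MA16S to a member contig of the
#' MAG with identity >= 98 percent, alignment length > 100 nt and fewer
#' than 5 mismatches. Paired-end support requires at least `min_pairs`
#' read pairs in total connecting the MA16S with member contigs.
#'
#' @param hits data.frame of BLAST hits (may be NULL).
#' @param links data.frame of PE links (may be NULL).
#' @param ma16s_id candidate MA16S identifier.
#' @param mag_contigs character vector of the MAG's member contig ids.
#' @param min_identity,min_alignment,max_mismatches BLAST thresholds
#'   (defaults 98, >100 nt, <5).
#' @param min_pairs minimum total connecting read pairs (default 5).
#' @return list with logicals `blast_support` and `pelink_support`.
#' @export
evaluate_support <- function(hits, links, ma16s_id, mag_contigs,
                             min_identity = 98, min_alignment = 100,
                             max_mismatches = 5, min_pairs = 5) {
  blast_support <- FALSE
  if (!is.null(hits) && nrow(hits)) {
    h <- hits[hits$query_id == ma16s_id &
                hits$subject_id %in% mag_contigs, , drop = FALSE]
    blast_support <- any(h$percent_identity >= min_identity &
                           h$alignment_length > min_alignment &
                           h$mismatches < max_mismatches)
  }
  pelink_support <- FALSE
  if (!is.null(links) && nrow(links)) {
    l <- links[links$ma16s_id == ma16s_id &
                 links$contig_id %in% mag_contigs, , drop = FALSE]
    pelink_support <- sum(l$n_pairs) >= min_pairs
  }
  list(blast_support = blast_support, pelink_support = pelink_support)
}

#' Match MA16S sequences to MAGs
#'
#' Applies the four-part evidence filter: (1) Pearson correlation of the
#' coverage profiles over the whole series with r > `r_min` and
#' p < `p_max`; (2) concordant taxonomy at the deepest resolved rank;
#' (3) physical support by BLAST and/or (4) paired-end linkage. Surviving
#' candidates are resolved to a one-to-one pairing by descending r, with
#' conflicts reported.
#'
#' @param ma16s_cov,mag_cov coverage matrices over identical samples.
#' @param ma16s_tax named character vector, MA16S id -> lineage.
#' @param mag_tax named character vector, MAG id -> lineage.
#' @param membership contig-to-MAG membership data.frame.
#' @param hits,links BLAST hits and PE links (either may be NULL).
#' @param r_min,p_max correlation thresholds (defaults 0.7 and 0.001).
#' @param require_both if `TRUE`, require BLAST *and* PE support instead of
#'   at least one.
#' @return a `sludge_match` list with `accepted` (one-to-one pairs and
#'   their evidence), `rejected` (failed candidates with reasons, only
#'   pairs passing the correlation screen are enumerated) and `conflicts`.
#' @export
match_ma16s <- function(ma16s_cov, mag_cov, ma16s_tax, mag_tax,
                        membership, hits = NULL, links = NULL,
                        r_min = 0.7, p_max = 0.001,
                        require_both = FALSE) {
  cand <- correlate_profiles(ma16s_cov, mag_cov)
  cand <- cand[cand$usable & !is.na(cand$r), , drop = FALSE]
  # enumerate evidence only for pairs passing (or near) the correlation
  # screen plus the best candidate per MA16S, to keep reporting informative
  screened <- cand[cand$r > r_min, , drop = FALSE]
  rows <- lapply(seq_len(nrow(screened)), function(i) {
    row <- screened[i, ]
    tc <- taxonomy_concordant(ma16s_tax[[row$ma16s_id]],
                              mag_tax[[row$mag_id]])
    contigs <- membership$contig_id[membership$mag_id == row$mag_id]
    sup <- evaluate_support(hits, links, row$ma16s_id, contigs)
    support_ok <- if (require_both)
      sup$blast_support && sup$pelink_support
    else sup$blast_support || sup$pelink_support
    reason <- if (row$p >= p_max) "correlation"
      else if (!tc$concordant) paste0("taxonomy (", tc$reason, ")")
      else if (!support_ok) "no physical support"
      else "pass"
    data.frame(row, taxonomy_concordant = tc$concordant,
               shared_rank = tc$shared_rank,
               blast_support = sup$blast_support,
               pelink_support = sup$pelink_support,
               reason = reason, stringsAsFactors = FALSE)
  })
  evidence <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(evidence))
    evidence <- data.frame(ma16s_id = character(), mag_id = character(),
                           r = numeric(), p = numeric(), usable = logical(),
                           taxonomy_concordant = logical(),
                           shared_rank = integer(), blast_support = logical(),
                           pelink_support = logical(), reason = character())
  passing <- evidence[evidence$reason == "pass", , drop = FALSE]
  passing <- passing[order(-passing$r), , drop = FALSE]
  used16 <- character(); usedmag <- character()
  accept <- logical(nrow(passing)); conflicts <- list()
  for (i in seq_len(nrow(passing))) {
    m16 <- passing$ma16s_id[i]; mg <- passing$mag_id[i]
    if (m16 %in% used16 || mg %in% usedmag) {
      conflicts[[length(conflicts) + 1]] <- passing[i, c("ma16s_id", "mag_id", "r")]
    } else {
      accept[i] <- TRUE
      used16 <- c(used16, m16); usedmag <- c(usedmag, mg)
    }
  }
  accepted <- passing[accept, , drop = FALSE]
  dropped <- passing[!accept, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "one-to-one conflict"
  # for MA16S with no candidate above the correlation screen, report their
  # best-correlated MAG as rejected for correlation
  unscreened <- setdiff(unique(cand$ma16s_id), unique(screened$ma16s_id))
  corr_rows <- lapply(unscreened, function(m) {
    sub <- cand[cand$ma16s_id == m, , drop = FALSE]
    best <- sub[which.max(sub$r), , drop = FALSE]
    data.frame(best, taxonomy_concordant = NA, shared_rank = NA_integer_,
               blast_support = NA, pelink_support = NA,
               reason = "correlation", stringsAsFactors = FALSE)
  })
  rejected <- rbind(evidence[evidence$reason != "pass", , drop = FALSE],
                    dropped,
                    do.call(rbind, c(corr_rows, list(NULL))))
  structure(list(accepted = accepted, rejected = rejected,
                 conflicts = do.call(rbind, c(conflicts, list(NULL))),
                 thresholds = list(r_min = r_min, p_max = p_max,
                                   require_both = require_both)),
            class = "sludge_match")
}

#' @export
print.sludge_match <- function(x, ...) {
  cat("MA16S-MAG matching: ", nrow(x$accepted), " accepted pair(s), ",
      nrow(x$rejected), " rejected candidate(s)\n", sep = "")
  invisible(x)
}
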