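#' Filter features by mean relative abundance
#'
#' Keeps features whose mean relative abundance strictly exceeds
#' `min_mean` (default 0.0005, i.e. 0.05 percent), the usual admission
#' rule before all-pairs co-occurrence screening.
#'
#' @param rel_abund relative-abundance matrix (features x samples).
#' @param min_mean threshold on the row mean (strict `>`).
#' @return the filtered matrix (possibly zero rows).
#' @export
abundance_filter <- function(rel_abund, min_mean = 5e-4) {
  rel_abund[rowMeans(rel_abund) > min_mean, , drop = FALSE]
}

#' Normal-score (rank quantile) transform
#'
#' Maps a series to standard normal quantiles of its midranks,
#' `z_i = qnorm(rank_i / (n + 1))`, the conventional preprocessing before
#' local similarity analysis.
#'
#' @param series numeric vector, length >= 2.
#' @return z-scored series; a constant series maps to all zeros with a
#'   `"constant"` attribute set.
#' @export
normal_score_transform <- function(series) {
  n <- length(series)
  if (length(unique(series)) == 1) {
    out <- rep(0, n)
    attr(out, "constant") <- TRUE
    return(out)
  }
  stats::qnorm(rank(series, ties.method = "average") / (n + 1))
}

#' Local similarity of two series
#'
#' Dynamic program over aligned positions with offset at most `max_delay`:
#' running sums of elementwise products (and their negation) are reset at
#' zero, and the best segment sum over all offsets, divided by the series
#' length, is the local similarity score. The sign records whether the
#' best segment was positively or negatively associated, and the delay is
#' the offset of the maximizing alignment (ties prefer smaller |delay|,
#' then positive).
#'
#' @param x,y equal-length numeric series (normal-scored).
#' @param max_delay maximum alignment offset D >= 0 (default 3).
#' @return list with `score` in [-1, 1] (sign applied), `sign`, `delay`.
#' @export
local_similarity <- function(x, y, max_delay = 3) {
  if (length(x) != length(y)) stop("series length mismatch")
  r <- .lsa_score_cpp(as.numeric(x), as.numeric(y), as.integer(max_delay))
  list(score = r$sign * r$score, sign = r$sign, delay = r$delay)
}

#' Permutation significance of a local similarity score
#'
#' p = (1 + #{permuted |score| >= observed |score|}) / (1 + n_perm), with
#' each permutation a random shuffle of `y`.
#'
#' @param x,y equal-length numeric series.
#' @param max_delay maximum alignment offset.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param perms optional precomputed permutation-index matrix
#'   (n_perm x n); when supplied no randomness is consumed, which lets a
#'   caller share one set of permutations across many pairs.
#' @return two-sided permutation p-value.
#' @export
permutation_significance <- function(x, y, max_delay = 3, n_perm = 1000,
                                     perms = NULL) {
  if (is.null(perms)) {
    if (n_perm < 100) stop("n_perm must be >= 100")
    perms <- t(replicate(n_perm, sample.int(length(y))))
  }
  obs <- abs(local_similarity(x, y, max_delay)$score)
  null <- .lsa_perm_scores_cpp(as.numeric(x), as.numeric(y),
                               as.integer(max_delay),
                               matrix(as.integer(perms), nrow(perms)))
  (1 + sum(null >= obs - 1e-12)) / (1 + nrow(perms))
}

#' All-pairs local similarity analysis
#'
#' Normal-scores each feature's series, computes the local similarity
#' score, sign and delay for every feature pair, permutation p-values
#' (one shared set of shuffles across pairs), and Benjamini-Hochberg
#' q-values over all tested pairs.
#'
#' @param rel_abund relative-abundance matrix (features x samples),
#'   typically pre-filtered with [abundance_filter()].
#' @param max_delay maximum alignment offset (default 3).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed for the shared permutations.
#' @return data.frame `feature_a`, `feature_b`, `score`, `sign`, `delay`,
#'   `p`, `q`. Constant features are dropped with a warning.
#' @export
lsa_all_pairs <- function(rel_abund, max_delay = 3, n_perm = 1000,
                          seed = 1) {
  keep <- apply(rel_abund, 1, function(v) length(unique(v)) > 1)
  if (any(!keep))
    warning(sum(!keep), " constant feature(s) dropped")
  rel_abund <- rel_abund[keep, , drop = FALSE]
  nf <- nrow(rel_abund); n <- ncol(rel_abund)
  if (nf < 2) stop("need at least two non-constant features")
  z <- t(apply(rel_abund, 1, normal_score_transform))
  set.seed(seed)
  perms <- t(replicate(n_perm, sample.int(n)))
  ids <- rownames(rel_abund)
  pairs <- utils::combn(nf, 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ls <- local_similarity(z[i, ], z[j, ], max_delay)
    p <- permutation_significance(z[i, ], z[j, ], max_delay, perms = perms)
    out[[k]] <- data.frame(feature_a = ids[i], feature_b = ids[j],
                           score = ls$score, sign = ls$sign,
                           delay = ls$delay, p = p,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Build the co-occurrence network from LSA edges
#'
#' Retains edges with |score| strictly above `score_thresh` and q-value
#' below `q_thresh` (set `use_raw_p = TRUE` to threshold the raw
#' permutation p instead) and returns an igraph with mean relative
#' abundance as node attribute.
#'
#' @param edges data.frame from [lsa_all_pairs()].
#' @param rel_abund relative-abundance matrix for node annotation.
#' @param score_thresh,q_thresh thresholds (defaults 0.6 and 0.01).
#' @param use_raw_p threshold `p` instead of `q`.
#' @return igraph object; edge attributes `score`, `sign`, `delay`, `q`.
#' @export
build_network <- function(edges, rel_abund, score_thresh = 0.6,
                          q_thresh = 0.01, use_raw_p = FALSE) {
  crit <- if (use_raw_p) edges$p else edges$q
  keep <- abs(edges$score) > score_thresh & crit < q_thresh
  e <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("feature_a", "feature_b", "score", "sign", "delay", "p", "q")],
    directed = FALSE,
    vertices = data.frame(name = rownames(rel_abund),
                          mean_abundance = rowMeans(rel_abund)))
  g
}

#' Positive-edge k-core clusters
#'
#' Restricts the network to positive edges, extracts the maximal subgraph
#' in which every node has degree >= k, and returns its connected
#' components as clusters.
#'
#' @param network igraph from [build_network()].
#' @param k core order (default 10).
#' @return named list of character vectors (cluster membership); empty
#'   list when the k-core is empty.
#' @export
kcore_positive <- function(network, k = 10) {
  pos <- igraph::subgraph_from_edges(
    network, igraph::E(network)[igraph::E(network)$score > 0],
    delete.vertices = FALSE)
  core <- igraph::coreness(pos)
  sub <- igraph::induced_subgraph(pos, names(core)[core >= k])
  if (igraph::vcount(sub) == 0) return(list())
  comp <- igraph::components(sub)
  split(names(comp$membership), comp$membership)
}

#' Per-sample summed abundance of network clusters
#'
#' @param clusters named list of disjoint feature sets, e.g. from
#'   [kcore_positive()].
#' @param rel_abund relative-abundance matrix.
#' @return matrix clusters x samples of summed relative abundances.
#' @export
cluster_abundance_series <- function(clusters, rel_abund) {
  if (!length(clusters))
    return(matrix(numeric(), 0, ncol(rel_abund),
                  dimnames = list(NULL, colnames(rel_abund))))
  all_members <- unlist(clusters)
  if (anyDuplicated(all_members)) stop("clusters must be disjoint")
  t(vapply(clusters, function(m)
    colSums(rel_abund[m, , drop = FALSE]), numeric(ncol(rel_abund))))
}
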