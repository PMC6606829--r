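#' Log-transform an abundance matrix for clustering
#'
#' Abundances span orders of magnitude; clustering them on the raw scale
#' lets the most abundant features dominate and makes within-group spread
#' heteroscedastic. This applies log after adding half the smallest
#' positive value as pseudocount (so zeros stay finite).
#'
#' @param x non-negative matrix.
#' @return log-transformed matrix of the same shape.
#' @export
log_abundance <- function(x) {
  pos <- x[x > 0]
  if (!length(pos)) stop("all-zero matrix")
  log(x + min(pos) / 2)
}

#' Train a batch self-organizing map
#'
#' Deterministic batch Kohonen training on a rectangular grid (default
#' 5 x 5) with a Gaussian neighborhood whose radius decays linearly from
#' half the grid diameter to 1 over the epochs. Prototypes are
#' initialized on the plane of the first two principal components, which
#' makes training deterministic and invariant to sample order. Features
#' are z-scored per feature before training (constant features dropped
#' with a warning).
#'
#' @param x samples x features matrix.
#' @param shape grid dimensions `c(rows, cols)` (default `c(5, 5)`).
#' @param epochs training epochs (default 50).
#' @param seed accepted for interface stability; batch training with PCA
#'   initialization consumes no randomness.
#' @param standardize z-score features before training (default TRUE).
#' @return a `sludge_som` list with `prototypes` (units x features),
#'   `grid` (unit coordinates), `bmu` (named integer vector sample ->
#'   unit), `shape`, `epochs`.
#' @export
train_som <- function(x, shape = c(5, 5), epochs = 50, seed = 1,
                      standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("need at least one sample")
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    const <- is.na(sds) | sds == 0
    if (any(const)) {
      warning(sum(const), " constant feature(s) dropped")
      x <- x[, !const, drop = FALSE]
      sds <- sds[!const]
    }
    x <- scale(x)
  }
  n_units <- prod(shape)
  grid <- expand.grid(row = seq_len(shape[1]), col = seq_len(shape[2]))
  # PCA-plane initialization; principal axes get a fixed sign convention
  # (largest-magnitude loading positive) so training is invariant to
  # sample order
  ctr <- colMeans(x)
  nv <- min(2, ncol(x), nrow(x))
  sv <- svd(sweep(x, 2, ctr), nu = 0, nv = nv)
  u1 <- if (shape[1] > 1) seq(-1, 1, length.out = shape[1]) else 0
  u2 <- if (shape[2] > 1) seq(-1, 1, length.out = shape[2]) else 0
  proto <- matrix(rep(ctr, each = n_units), n_units)
  if (nv >= 1 && sv$d[1] > 0) {
    ax1 <- sv$v[, 1] * sign(sv$v[which.max(abs(sv$v[, 1])), 1])
    proto <- proto + outer(u1[grid$row], ax1 * sv$d[1] / sqrt(nrow(x)))
  }
  if (nv >= 2 && sv$d[2] > 0) {
    ax2 <- sv$v[, 2] * sign(sv$v[which.max(abs(sv$v[, 2])), 2])
    proto <- proto + outer(u2[grid$col], ax2 * sv$d[2] / sqrt(nrow(x)))
  }
  diam <- sqrt(sum((shape - 1)^2))
  radius <- seq(max(diam / 2, 1), 1, length.out = epochs)
  gdist2 <- as.matrix(stats::dist(grid))^2
  bmu <- integer(nrow(x))
  for (e in seq_len(epochs)) {
    d2 <- outer(rowSums(x^2), rowSums(proto^2), "+") - 2 * x %*% t(proto)
    bmu <- max.col(-d2, ties.method = "first")
    h <- exp(-gdist2 / (2 * radius[e]^2))      # units x units
    w <- h[, bmu, drop = FALSE]                # units x samples
    denom <- rowSums(w)
    upd <- (w %*% x) / denom
    nonzero <- denom > 1e-12
    proto[nonzero, ] <- upd[nonzero, , drop = FALSE]
  }
  d2 <- outer(rowSums(x^2), rowSums(proto^2), "+") - 2 * x %*% t(proto)
  bmu <- max.col(-d2, ties.method = "first")
  structure(list(prototypes = proto, grid = grid,
                 bmu = stats::setNames(bmu, rownames(x)),
                 shape = shape, epochs = epochs),
            class = "sludge_som")
}

#' @export
print.sludge_som <- function(x, ...) {
  cat("Batch SOM ", x$shape[1], "x", x$shape[2], ", ",
      length(unique(x$bmu)), " occupied unit(s), ", length(x$bmu),
      " sample(s)\n", sep = "")
  invisible(x)
}

#' Ward superclusters of SOM units
#'
#' Agglomerative clustering of the prototype vectors with Ward's minimum
#' variance linkage, cut at `k`; every sample inherits the supercluster of
#' its best-matching unit.
#'
#' @param som a `sludge_som` from [train_som()].
#' @param k number of superclusters (2 <= k <= number of occupied units).
#' @return named integer vector sample -> supercluster label.
#' @export
ward_superclusters <- function(som, k) {
  occupied <- length(unique(som$bmu))
  if (k < 2 || k > occupied)
    stop("k must be between 2 and the number of occupied units (",
         occupied, ")")
  hc <- stats::hclust(stats::dist(som$prototypes), method = "ward.D2")
  unit_cluster <- stats::cutree(hc, k = k)
  stats::setNames(unit_cluster[som$bmu], names(som$bmu))
}

#' Consensus periods from two supercluster views
#'
#' Matches superclusters across the two views greedily by descending
#' Jaccard overlap of their sample sets; the consensus set of a matched
#' pair is the intersection. The two largest disjoint consensus sets are
#' reported as the candidate periods and, when a regime key is supplied
#' (sample -> regime label), each is named by its majority regime.
#'
#' @param view_a,view_b named vectors sample -> supercluster label over
#'   the same samples.
#' @param regime_key optional named character vector sample -> regime.
#' @return a `sludge_consensus` list with `pairs` (matched cluster pairs
#'   with Jaccard), `consensus` (list of consensus sample sets), `periods`
#'   (the two largest disjoint sets, named by regime when keyed).
#' @export
consensus_periods <- function(view_a, view_b, regime_key = NULL) {
  if (!setequal(names(view_a), names(view_b)))
    stop("the two views must label the same samples")
  view_b <- view_b[names(view_a)]
  sets_a <- split(names(view_a), view_a)
  sets_b <- split(names(view_b), view_b)
  grid <- expand.grid(a = names(sets_a), b = names(sets_b),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$jaccard <- mapply(function(a, b) {
    sa <- sets_a[[a]]; sb <- sets_b[[b]]
    length(intersect(sa, sb)) / length(union(sa, sb))
  }, grid$a, grid$b)
  grid <- grid[order(-grid$jaccard), , drop = FALSE]
  used_a <- character(); used_b <- character(); pairs <- list()
  for (i in seq_len(nrow(grid))) {
    if (grid$jaccard[i] <= 0) break
    if (grid$a[i] %in% used_a || grid$b[i] %in% used_b) next
    pairs[[length(pairs) + 1]] <- grid[i, ]
    used_a <- c(used_a, grid$a[i]); used_b <- c(used_b, grid$b[i])
  }
  pairs <- do.call(rbind, c(pairs, list(NULL)))
  if (is.null(pairs)) {
    warning("no supercluster pair with positive overlap")
    return(structure(list(pairs = NULL, consensus = list(),
                          periods = list()), class = "sludge_consensus"))
  }
  consensus <- lapply(seq_len(nrow(pairs)), function(i)
    sort(intersect(sets_a[[pairs$a[i]]], sets_b[[pairs$b[i]]])))
  names(consensus) <- paste0(pairs$a, "|", pairs$b)
  # the two periods are the largest disjoint consensus sets; transition
  # samples do not survive as a large set because the two views partition
  # them differently (ties broken toward higher cross-view Jaccard)
  ord <- order(-lengths(consensus), -pairs$jaccard)
  periods <- list(); taken <- character()
  for (i in ord) {
    if (length(periods) == 2) break
    if (length(intersect(consensus[[i]], taken))) next
    periods[[names(consensus)[i]]] <- consensus[[i]]
    taken <- c(taken, consensus[[i]])
  }
  if (!is.null(regime_key) && length(periods)) {
    labs <- vapply(periods, function(s) {
      tab <- sort(table(regime_key[s]), decreasing = TRUE)
      names(tab)[1]
    }, character(1))
    if (!anyDuplicated(labs)) names(periods) <- labs
  }
  structure(list(pairs = pairs, consensus = consensus, periods = periods),
            class = "sludge_consensus")
}

#' @export
print.sludge_consensus <- function(x, ...) {
  cat("Consensus periods: ", length(x$periods), " period(s); sizes ",
      paste(lengths(x$periods), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Welch differential features between two sample groups
#'
#' Per-feature Welch's t test (two-sided, Welch-Satterthwaite degrees of
#' freedom) with Benjamini-Hochberg correction, the STAMP-style two-group
#' comparison. Features with zero variance in both groups are excluded
#' and reported.
#'
#' @param x features x samples matrix.
#' @param group_a,group_b character vectors of sample ids (each >= 3).
#' @param alpha corrected-p significance level (default 0.01).
#' @return list with `table` (feature, group means/sds, t, df, p,
#'   p_adjusted, significant) and `excluded` (zero-variance features).
#' @export
differential_features <- function(x, group_a, group_b, alpha = 0.01) {
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs at least 3 samples")
  a <- x[, group_a, drop = FALSE]; b <- x[, group_b, drop = FALSE]
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  degenerate <- va == 0 & vb == 0
  rows <- lapply(rownames(x)[!degenerate], function(f) {
    tt <- stats::t.test(a[f, ], b[f, ])
    data.frame(feature = f, mean_a = mean(a[f, ]), sd_a = stats::sd(a[f, ]),
               mean_b = mean(b[f, ]), sd_b = stats::sd(b[f, ]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(NULL)))
  if (!is.null(tab)) {
    tab$p_adjusted <- stats::p.adjust(tab$p, method = "BH")
    tab$significant <- tab$p_adjusted < alpha
  }
  list(table = tab, excluded = rownames(x)[degenerate])
}
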