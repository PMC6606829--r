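#' Construct a coverage matrix
#'
#' A coverage matrix is the package's central container: a non-negative
#' numeric matrix of mean per-base read depths (x-fold) with features
#' (contigs, MAGs, MA16S sequences or marker genes) as rows and samples as
#' columns. Column order is the time order of the series and must be
#' identical across all matrices used in one analysis.
#'
#' @param values numeric matrix of coverages, or an object coercible to one.
#' @param feature_ids optional character vector of row identifiers
#'   (defaults to existing rownames).
#' @param sample_ids optional character vector of column labels in time
#'   order (defaults to existing colnames).
#' @return a validated numeric matrix with unique rownames and colnames.
#' @export
coverage_matrix <- function(values, feature_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (!is.null(feature_ids)) rownames(m) <- feature_ids
  if (!is.null(sample_ids)) colnames(m) <- sample_ids
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("coverage matrix needs feature_ids (rownames) and sample_ids (colnames)")
  if (anyDuplicated(rownames(m)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyNA(m)) stop("coverage matrix contains missing values")
  if (any(m < 0)) stop("coverage values must be non-negative")
  m
}

#' Aggregate contig coverage to MAG coverage
#'
#' The coverage of a MAG in a sample is the length-weighted mean of the
#' coverages of its member contigs, i.e. total mapped bases divided by
#' genome length. This is invariant to how the genome happens to be split
#' into contigs.
#'
#' @param depth coverage matrix of contigs x samples.
#' @param membership data.frame with columns `contig_id`, `mag_id`.
#' @param contig_lengths named numeric vector of contig lengths (bp).
#' @return coverage matrix of MAGs x samples.
#' @export
mag_coverage <- function(depth, membership, contig_lengths) {
  stopifnot(is.matrix(depth), is.data.frame(membership))
  missing_depth <- setdiff(membership$contig_id, rownames(depth))
  if (length(missing_depth))
    stop("contigs absent from depth table: ",
         paste(missing_depth, collapse = ", "))
  missing_len <- setdiff(membership$contig_id, names(contig_lengths))
  if (length(missing_len))
    stop("contigs absent from contig_lengths: ",
         paste(missing_len, collapse = ", "))
  mags <- unique(membership$mag_id)
  out <- matrix(0, length(mags), ncol(depth),
                dimnames = list(mags, colnames(depth)))
  for (mg in mags) {
    contigs <- membership$contig_id[membership$mag_id == mg]
    len <- contig_lengths[contigs]
    out[mg, ] <- colSums(depth[contigs, , drop = FALSE] * len) / sum(len)
  }
  coverage_matrix(out)
}

#' Column-wise relative abundance
#'
#' Normalizes each sample (column) to sum to one. Features with zero
#' coverage stay zero.
#'
#' @param cov coverage matrix.
#' @return matrix of the same shape whose columns each sum to 1.
#' @export
relative_abundance <- function(cov) {
  stopifnot(is.matrix(cov))
  cs <- colSums(cov)
  if (any(cs <= 0))
    stop("all-zero sample(s): ", paste(colnames(cov)[cs <= 0], collapse = ", "))
  sweep(cov, 2, cs, "/")
}
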