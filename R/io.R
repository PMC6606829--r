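#' Read a contig depth table
#'
#' Reads a per-contig coverage table as produced by jgi-style depth
#' summarizers. The `plain` dialect expects a header line, a first column
#' of feature ids and one coverage column per sample. The `jgi` dialect
#' additionally drops the `contigLen` / `totalAvgDepth` summary columns and
#' the interleaved per-sample variance columns (names ending in `-var` or
#' `.var`).
#'
#' @param path TSV file path.
#' @param dialect `"plain"` (default) or `"jgi"`.
#' @return coverage matrix (contigs x samples, samples in file order).
#' @export
read_depth_table <- function(path, dialect = c("plain", "jgi")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (!length(lines)) stop("empty depth table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    stop("ragged depth table at line ",
         which(nf != nf[1])[1], " (expected ", nf[1], " fields, got ",
         nf[which(nf != nf[1])[1]], ")")
  header <- fields[[1]]
  body <- fields[-1]
  ids <- vapply(body, `[`, character(1), 1)
  cols <- header[-1]
  keep <- rep(TRUE, length(cols))
  if (dialect == "jgi")
    keep <- !(cols %in% c("contigLen", "totalAvgDepth") |
              grepl("([.-])var$", cols))
  vals <- vapply(body, function(f) suppressWarnings(as.numeric(f[-1])),
                 numeric(length(cols)))
  vals <- matrix(vals, ncol = length(body))  # guards 1-col case
  if (anyNA(vals)) stop("non-numeric or missing coverage value in ", path)
  m <- t(vals)[, keep, drop = FALSE]
  dimnames(m) <- list(ids, cols[keep])
  if (any(m < 0)) stop("negative coverage in ", path)
  coverage_matrix(m)
}

#' Write a coverage matrix as a plain depth table
#'
#' @param cov coverage matrix.
#' @param path output TSV path.
#' @param id_column header name of the feature-id column.
#' @export
write_depth_table <- function(cov, path, id_column = "contigName") {
  df <- data.frame(id = rownames(cov), cov, check.names = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BLAST tabular output (outfmt 6)
#'
#' @param path 12-column tab-separated BLAST tabular file.
#' @return data.frame with one row per hit: `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`.
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "e_value", "bit_score")
  empty <- as.data.frame(c(
    stats::setNames(rep(list(character()), 2), cols[1:2]),
    stats::setNames(rep(list(numeric()), 10), cols[3:12])))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 12))
    stop("BLAST tabular line with ", lengths(fields)[lengths(fields) != 12][1],
         " columns (expected 12) in ", path)
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- cols
  for (col in cols[3:12]) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop("non-numeric ", col, " in ", path)
    df[[col]] <- v
  }
  df
}

#' Write BLAST hits in tabular (outfmt 6) layout
#' @param hits data.frame as returned by [read_blast_tab()].
#' @param path output path.
#' @export
write_blast_tab <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a paired-end linkage table
#'
#' @param path TSV with header and columns `ma16s_id`, `contig_id`, `n_pairs`
#'   (count of read pairs with one mate on the 16S sequence and one on the
#'   contig).
#' @return data.frame of links.
#' @export
read_pe_links <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("ma16s_id", "contig_id", "n_pairs")
  if (!all(req %in% names(df)))
    stop("PE-link table must have columns: ", paste(req, collapse = ", "))
  if (any(df$n_pairs < 0) || any(df$n_pairs != round(df$n_pairs)))
    stop("n_pairs must be non-negative integers")
  df
}

#' Read a MAG QC table
#'
#' @param path TSV with header and columns `mag_id`, `completeness`,
#'   `contamination`, `genome_length`, `n_scaffolds`, `taxonomy`
#'   (semicolon-joined lineage).
#' @return data.frame of MAG records.
#' @export
read_mag_qc <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("mag_id", "completeness", "contamination", "genome_length",
           "n_scaffolds", "taxonomy")
  if (!all(req %in% names(df)))
    stop("MAG QC table must have columns: ", paste(req, collapse = ", "))
  bad <- df$completeness < 0 | df$completeness > 100 |
    df$contamination < 0 | df$contamination > 100
  if (any(bad))
    stop("completeness/contamination out of [0, 100] for: ",
         paste(df$mag_id[bad], collapse = ", "))
  df
}

#' Read a contig-to-MAG membership table
#' @param path TSV with header and columns `contig_id`, `mag_id` (and
#'   optionally `length`).
#' @return data.frame.
#' @export
read_contig_membership <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("contig_id", "mag_id") %in% names(df)))
    stop("membership table must have columns contig_id, mag_id")
  if (anyDuplicated(df$contig_id))
    stop("contig assigned to more than one MAG: ",
         paste(unique(df$contig_id[duplicated(df$contig_id)]), collapse = ", "))
  df
}

#' Read sample metadata
#'
#' @param path TSV with header and columns `sample_id`, `date`
#'   (ISO `YYYY-MM-DD`) and optionally `regime` with values in
#'   `stable`, `disturbed`, `transition`.
#' @return data.frame ordered by date; defines the time order of samples.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "date") %in% names(df)))
    stop("metadata must have columns sample_id, date")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  d <- as.Date(df$date)
  if (anyNA(d)) stop("unparseable date in metadata")
  if (any(diff(order(d)) != 1) || any(duplicated(d)))
    stop("metadata dates must be strictly increasing")
  df[order(d), , drop = FALSE]
}

#' Read MA16S sequences from FASTA
#'
#' Metagenome-assembled 16S rRNA gene sequences (MA16S) are admitted only
#' if at least `min_length` nucleotides long.
#'
#' @param path FASTA file.
#' @param min_length minimum admitted sequence length (default 900 nt).
#' @return data.frame with `ma16s_id`, `length`, `sequence`; shorter
#'   sequences are dropped with a warning.
#' @export
read_ma16s_fasta <- function(path, min_length = 900) {
  seqs <- Biostrings::readDNAStringSet(path)
  len <- Biostrings::width(seqs)
  short <- len < min_length
  if (any(short))
    warning(sum(short), " MA16S sequence(s) below ", min_length,
            " nt dropped")
  seqs <- seqs[!short]
  data.frame(ma16s_id = names(seqs),
             length = Biostrings::width(seqs),
             sequence = as.character(seqs),
             stringsAsFactors = FALSE)
}

# shared writer for tidy result tables
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
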