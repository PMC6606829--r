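#' Load a community input bundle from disk
#'
#' Reads the tab-separated input bundle consumed by the pipeline in
#' real-input mode (the same layout that [write_community()] emits):
#' depth table, contig membership (with lengths), MAG QC, MA16S coverage
#' and taxonomy, optional BLAST/PE-link evidence, OTU counts, marker and
#' module matrices and sample metadata. When a `truth.json` sits next to
#' the inputs (synthetic bundles) it is loaded too.
#'
#' @param inputs either a directory containing the standard file names or
#'   a named list of paths (`depth`, `membership`, `mag_qc`, `ma16s_cov`,
#'   `ma16s_tax`, `otu_counts`, `module_abund`, `metadata`, and optionally
#'   `marker_cov`, `blast`, `pe_links`, `truth`).
#' @return a `sludge_sim`-shaped list usable by [run_pipeline()].
#' @export
load_community <- function(inputs) {
  if (is.character(inputs) && length(inputs) == 1 && dir.exists(inputs)) {
    f <- function(name) {
      p <- file.path(inputs, name)
      if (file.exists(p)) p else NULL
    }
    inputs <- list(depth = f("depth.tsv"), membership = f("membership.tsv"),
                   mag_qc = f("mag_qc.tsv"), ma16s_cov = f("ma16s_cov.tsv"),
                   ma16s_tax = f("ma16s_tax.tsv"),
                   otu_counts = f("otu_counts.tsv"),
                   marker_cov = f("marker_cov.tsv"),
                   module_abund = f("module_abund.tsv"),
                   metadata = f("metadata.tsv"), blast = f("blast.tsv"),
                   pe_links = f("pe_links.tsv"), truth = f("truth.json"))
  }
  need <- c("depth", "membership", "mag_qc", "ma16s_cov", "ma16s_tax",
            "otu_counts", "module_abund", "metadata")
  for (nm in need)
    if (is.null(inputs[[nm]]))
      stop("missing required input: ", nm)
    else if (!file.exists(inputs[[nm]]))
      stop("missing input file: ", inputs[[nm]])
  member <- utils::read.delim(inputs$membership, stringsAsFactors = FALSE)
  if (!"length" %in% names(member))
    stop("membership table needs a length column in real-input mode")
  tax <- utils::read.delim(inputs$ma16s_tax, stringsAsFactors = FALSE)
  otu <- utils::read.delim(inputs$otu_counts, check.names = FALSE,
                           stringsAsFactors = FALSE)
  otu_m <- as.matrix(otu[, -1, drop = FALSE])
  rownames(otu_m) <- otu[[1]]
  meta <- read_sample_metadata(inputs$metadata)
  regimes <- if ("regime" %in% names(meta)) meta$regime
             else rep("transition", nrow(meta))
  truth <- list(regime_schedule = regimes)
  if (!is.null(inputs$truth) && file.exists(inputs$truth)) {
    tj <- jsonlite::read_json(inputs$truth, simplifyVector = TRUE)
    truth$true_match <- unlist(tj$true_match)
    truth$rrn_copies <- unlist(tj$rrn_copies)
    truth$affinity <- unlist(tj$affinity)
  }
  mag_qc <- read_mag_qc(inputs$mag_qc)
  list(config = NULL,
       truth = truth,
       genomes = data.frame(mag_id = mag_qc$mag_id,
                            stringsAsFactors = FALSE),
       depth = read_depth_table(inputs$depth),
       contig_lengths = stats::setNames(member$length, member$contig_id),
       membership = member[, c("contig_id", "mag_id")],
       mag_qc = mag_qc,
       ma16s_cov = read_depth_table(inputs$ma16s_cov),
       ma16s_tax = stats::setNames(tax$taxonomy, tax$ma16s_id),
       blast = if (!is.null(inputs$blast) && file.exists(inputs$blast))
         read_blast_tab(inputs$blast) else NULL,
       pe_links = if (!is.null(inputs$pe_links) &&
                        file.exists(inputs$pe_links))
         read_pe_links(inputs$pe_links) else NULL,
       otu_counts = otu_m,
       marker_cov = if (!is.null(inputs$marker_cov) &&
                          file.exists(inputs$marker_cov))
         read_depth_table(inputs$marker_cov) else NULL,
       module_abund = read_depth_table(inputs$module_abund),
       metadata = meta)
}
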