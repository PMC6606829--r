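#' Genome admission filter for replication-index estimation
#'
#' A genome-sample pair is admitted when the assembly is contiguous and
#' clean enough for a coverage-gradient fit: fewer than
#' `max_scaffolds_per_mbp` scaffolds per Mbp, completeness above
#' `min_completeness` percent (strict), contamination below
#' `max_contamination` percent, and mean coverage above `min_coverage`.
#'
#' @param qc one-row data.frame (or list) with `n_scaffolds`,
#'   `genome_length`, `completeness`, `contamination`.
#' @param mean_cov mean genome coverage in the sample.
#' @param max_scaffolds_per_mbp,min_completeness,max_contamination,min_coverage
#'   filter thresholds (defaults 175, 75, 5, 5).
#' @return list with `admitted` (logical) and `reasons` (character vector
#'   of failed filters, empty when admitted).
#' @export
admit_genome <- function(qc, mean_cov, max_scaffolds_per_mbp = 175,
                         min_completeness = 75, max_contamination = 5,
                         min_coverage = 5) {
  need <- c("n_scaffolds", "genome_length", "completeness", "contamination")
  vals <- lapply(need, function(f) qc[[f]])
  if (any(vapply(vals, function(v) is.null(v) || is.na(v), logical(1))))
    stop("missing QC field(s): ",
         paste(need[vapply(vals, function(v) is.null(v) || is.na(v),
                           logical(1))], collapse = ", "))
  reasons <- character()
  if (qc[["n_scaffolds"]] / (qc[["genome_length"]] / 1e6) >=
        max_scaffolds_per_mbp)
    reasons <- c(reasons, "fragmentation")
  if (qc[["completeness"]] <= min_completeness)
    reasons <- c(reasons, "completeness")
  if (qc[["contamination"]] >= max_contamination)
    reasons <- c(reasons, "contamination")
  if (is.na(mean_cov) || mean_cov <= min_coverage)
    reasons <- c(reasons, "coverage")
  list(admitted = !length(reasons), reasons = reasons)
}

# negative log-likelihood of log2 window coverage modeled as
# Uniform(a, a + s) (the ori->ter gradient) convolved with Gaussian window
# noise; s = 0 degenerates to the pure-noise Gaussian model
gradient_nll <- function(par, y) {
  a <- par[1]; s <- par[2]; sig <- par[3]
  if (s < 1e-9) return(-sum(stats::dnorm(y, a, sig, log = TRUE)))
  dens <- (stats::pnorm((y - a) / sig) -
             stats::pnorm((y - a - s) / sig)) / s
  -sum(log(pmax(dens, 1e-300)))
}

# ML estimate of the log2 gradient span, gated by BIC against the
# no-gradient model
fit_gradient_span <- function(y, slope_init) {
  n <- length(y)
  v <- stats::var(y)
  init <- c(mean(y) - max(slope_init, 0) / 2, max(slope_init, 0.02),
            sqrt(max(v - max(slope_init, 0)^2 / 12, 1e-8)) + 1e-4)
  fit <- try(stats::optim(init, gradient_nll, y = y, method = "L-BFGS-B",
                          lower = c(-Inf, 0, 1e-6),
                          control = list(maxit = 500)), silent = TRUE)
  ll0 <- -gradient_nll(c(mean(y), 0, stats::sd(y)), y)
  if (inherits(fit, "try-error")) return(max(slope_init, 0))
  bic1 <- 2 * fit$value + 3 * log(n)
  bic0 <- -2 * ll0 + 2 * log(n)
  if (bic0 <= bic1) 0 else fit$par[2]
}

#' Replication index from a window coverage profile
#'
#' Estimates the peak-to-trough coverage ratio of a population from the
#' multiset of its genome-window coverages (window order is unknown for
#' draft genomes). Windows are sorted, the extreme `trim_frac` fractions
#' are excluded, and log2 coverage is regressed on equally spaced
#' origin-to-terminus abscissae spanning [0, 1] (the trimmed windows keep
#' their positions, so the fit extrapolates to the full range); the r^2 of
#' this fit is the admission diagnostic. The default point estimate
#' (`method = "deconvolution"`) refits the sorted log2 coverages as a
#' Uniform gradient span convolved with Gaussian window noise by maximum
#' likelihood, gated by BIC against a no-gradient model: unlike the raw
#' sorted-fit slope it is not inflated by window noise when the population
#' is not replicating. `method = "quantile"` returns 2^slope of the plain
#' sorted fit.
#'
#' @param coverages numeric vector of window coverages (any order).
#' @param trim_frac fraction trimmed from each tail after sorting
#'   (default 0.05).
#' @param r2_min minimum r^2 of the sorted fit for the result to pass
#'   (default 0.90).
#' @param min_windows minimum usable windows (default 50).
#' @param method `"deconvolution"` (default) or `"quantile"`.
#' @return list with `irep`, `r_squared`, `slope` (log2 units of the
#'   sorted fit), `n_windows`, `n_zero_dropped`, `mean_coverage`,
#'   `passed_filters`, `reasons`.
#' @export
compute_irep <- function(coverages, trim_frac = 0.05, r2_min = 0.90,
                         min_windows = 50, method = c("deconvolution",
                                                      "quantile")) {
  method <- match.arg(method)
  stopifnot(all(is.finite(coverages)))
  n_zero <- sum(coverages <= 0)
  cov <- coverages[coverages > 0]
  result <- function(irep, r2, slope, reasons) {
    list(irep = irep, r_squared = r2, slope = slope,
         n_windows = length(cov), n_zero_dropped = n_zero,
         mean_coverage = if (length(cov)) mean(cov) else NA_real_,
         passed_filters = !length(reasons), reasons = reasons)
  }
  if (length(cov) < min_windows)
    return(result(NA_real_, NA_real_, NA_real_, "too few windows"))
  y <- sort(log2(cov))
  n <- length(y)
  if (stats::sd(y) < 1e-12)
    return(result(1.0, 1.0, 0.0, character()))
  x <- seq(0, 1, length.out = n)
  k <- floor(trim_frac * n)
  keep <- seq.int(k + 1, n - k)
  fit <- stats::lm.fit(cbind(1, x[keep]), y[keep])
  slope <- unname(fit$coefficients[2])
  yk <- y[keep]
  r2 <- 1 - sum(fit$residuals^2) / sum((yk - mean(yk))^2)
  # the deconvolution model is fit on the untrimmed sorted values: the
  # Uniform-plus-Gaussian likelihood would be misspecified on a truncated
  # sample, and its noise component already absorbs tail windows
  span <- if (method == "quantile") max(slope, 0)
          else fit_gradient_span(y, slope)
  reasons <- if (r2 < r2_min) "r2" else character()
  result(2^span, r2, slope, reasons)
}

#' Replication-index table over genome-sample pairs
#'
#' Applies the genome admission filter and [compute_irep()] to every
#' profile and returns a tidy table of results with per-pair admission
#' reasons.
#'
#' @param windows long data.frame with columns `mag_id`, `sample_id`,
#'   `coverage` (one row per window), e.g. from
#'   [generate_window_profiles()].
#' @param mag_qc data.frame as from [read_mag_qc()].
#' @param ... further arguments passed to [admit_genome()] and
#'   [compute_irep()] (matched by name).
#' @return data.frame `mag_id`, `sample_id`, `irep`, `r_squared`,
#'   `n_windows`, `mean_coverage`, `admitted`, `reasons`.
#' @export
irep_table <- function(windows, mag_qc, ...) {
  dots <- list(...)
  admit_args <- dots[names(dots) %in% names(formals(admit_genome))]
  irep_args <- dots[names(dots) %in% names(formals(compute_irep))]
  qc_idx <- match(unique(windows$mag_id), mag_qc$mag_id)
  if (anyNA(qc_idx))
    stop("MAG(s) missing from QC table: ",
         paste(unique(windows$mag_id)[is.na(qc_idx)], collapse = ", "))
  out <- list()
  for (key in split(seq_len(nrow(windows)),
                    paste(windows$mag_id, windows$sample_id, sep = "\r"))) {
    g <- windows$mag_id[key[1]]; s <- windows$sample_id[key[1]]
    cov <- windows$coverage[key]
    qc <- mag_qc[mag_qc$mag_id == g, ]
    adm <- do.call(admit_genome,
                   c(list(qc = qc, mean_cov = mean(cov)), admit_args))
    if (!adm$admitted) {
      out[[length(out) + 1]] <- data.frame(
        mag_id = g, sample_id = s, irep = NA_real_, r_squared = NA_real_,
        n_windows = length(cov), mean_coverage = mean(cov),
        admitted = FALSE, reasons = paste(adm$reasons, collapse = ","),
        stringsAsFactors = FALSE)
      next
    }
    est <- do.call(compute_irep, c(list(coverages = cov), irep_args))
    out[[length(out) + 1]] <- data.frame(
      mag_id = g, sample_id = s,
      irep = if (est$passed_filters) est$irep else NA_real_,
      r_squared = est$r_squared, n_windows = est$n_windows,
      mean_coverage = est$mean_coverage, admitted = est$passed_filters,
      reasons = paste(est$reasons, collapse = ","),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$mag_id, res$sample_id), , drop = FALSE]
}
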