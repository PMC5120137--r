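#' Per-sample metadata
#'
#' @param sample_id unique sample identifiers.
#' @param regime treatment/regime label (e.g. deplete, replete, vitamin, DOM).
#' @param timepoint sampling timepoint label.
#' @param replicate replicate index.
#' @param cells_collected cells captured on the filter (> 0), i.e. culture
#'   density times volume filtered.
#' @param library_size sequenced reads for the sample.
#' @return `sample_meta` data frame.
#' @export
sample_meta <- function(sample_id, regime, timepoint, replicate,
                        cells_collected, library_size = NA_real_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample ids must be unique", call. = FALSE)
  if (any(!is.finite(cells_collected)) || any(cells_collected <= 0))
    stop("cells_collected must be positive", call. = FALSE)
  structure(
    data.frame(sample_id = sample_id, regime = as.character(regime),
               timepoint = as.character(timepoint), replicate = replicate,
               cells_collected = as.numeric(cells_collected),
               library_size = as.numeric(library_size), stringsAsFactors = FALSE),
    class = c("sample_meta", "data.frame")
  )
}

#' Convert calibrated gene read counts to transcript copies per sample
#'
#' In per-copy mode `copies_g = reads_g / k`; in length-weighted mode
#' `copies_g = reads_g / (k * L_g)` with gene lengths from the genome model.
#' Zero reads convert to zero copies.
#'
#' @param counts gene read counts: matrix (genes x samples) or a
#'   [count_table()] (standard rows are dropped automatically).
#' @param fit a [fit_recovery()] calibration.
#' @param genome a [make_genome()] object; required in length-weighted mode.
#' @param mode conversion mode; must match `fit$mode`.
#' @return numeric matrix of transcript copies per gene per sample.
#' @export
transcripts_per_sample <- function(counts, fit, genome = NULL,
                                   mode = fit$mode) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (!identical(mode, fit$mode))
    stop(sprintf("conversion mode '%s' does not match calibration mode '%s'",
                 mode, fit$mode), call. = FALSE)
  if (inherits(counts, "count_table")) counts <- gene_counts(counts)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (fit$reads_per_copy <= 0) stop("calibration reads_per_copy must be > 0", call. = FALSE)
  copies <- counts / fit$reads_per_copy
  if (mode == "length-weighted") {
    if (is.null(genome)) stop("length-weighted conversion needs `genome`", call. = FALSE)
    validate_genome(genome)
    idx <- match(rownames(counts), genome$gene_ids)
    if (anyNA(idx))
      stop(sprintf("gene id(s) absent from genome: %s",
                   paste(rownames(counts)[is.na(idx)][1:min(3, sum(is.na(idx)))],
                         collapse = ", ")), call. = FALSE)
    copies <- copies / genome$gene_lengths[idx]
  }
  copies
}

#' Per-cell transcript abundance table
#'
#' Divides per-sample transcript copies by the cells collected for that
#' sample: `a_g = copies_g / N`. The per-1,000-cells view (`1000 * a_g`) is
#' the convention used for reporting low abundances.
#'
#' @param copies matrix of transcript copies (genes x samples).
#' @param meta a [sample_meta()] table covering every sample column.
#' @return `cell_abundance_table`: list with `abundances` (transcripts
#'   cell^-1, genes x samples), `totals` (per-sample column sums),
#'   `per_1000`, and `meta`.
#' @export
per_cell <- function(copies, meta) {
  stopifnot(inherits(meta, "sample_meta"))
  if (!is.matrix(copies)) copies <- as.matrix(copies)
  idx <- match(colnames(copies), meta$sample_id)
  if (anyNA(idx))
    stop(sprintf("no metadata for sample(s): %s",
                 paste(colnames(copies)[is.na(idx)], collapse = ", ")), call. = FALSE)
  ab <- sweep(copies, 2, meta$cells_collected[idx], "/")
  structure(
    list(abundances = ab, totals = colSums(ab), per_1000 = 1000 * ab,
         meta = meta[idx, , drop = FALSE]),
    class = "cell_abundance_table"
  )
}

#' @export
print.cell_abundance_table <- function(x, ...) {
  cat(sprintf("<cell_abundance_table> %d genes x %d samples, totals %.3g-%.3g transcripts/cell\n",
              nrow(x$abundances), ncol(x$abundances),
              min(x$totals), max(x$totals)))
  invisible(x)
}

#' Total mRNA content per sample, with replicate aggregation
#'
#' Totals are the per-sample column sums of the abundance table (transcripts
#' cell^-1). When metadata are present, samples are aggregated by regime and
#' timepoint into mean +/- SD of replicates (sample SD, n-1 denominator).
#'
#' @param table a [per_cell()] table.
#' @return list with `totals` (named per-sample vector) and `summary`
#'   (data frame: regime, timepoint, n, mean, sd).
#' @export
total_mrna <- function(table) {
  stopifnot(inherits(table, "cell_abundance_table"))
  totals <- table$totals
  meta <- table$meta
  key <- paste(meta$regime, meta$timepoint, sep = " / ")
  agg <- do.call(rbind, lapply(split(seq_along(totals), key), function(i) {
    data.frame(regime = meta$regime[i[1]], timepoint = meta$timepoint[i[1]],
               n = length(i), mean = mean(totals[i]),
               sd = if (length(i) > 1) stats::sd(totals[i]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(totals = totals, summary = agg)
}

#' Distribution summary of per-cell transcript abundances
#'
#' For each sample: the mean per-gene abundance over all genome genes (zeros
#' included), the span in orders of magnitude `log10(max/min)` over genes
#' with nonzero abundance, the detected fraction (genes with nonzero
#' estimated abundance, i.e. at least one read), and method-of-moments
#' lognormal parameters (mean and SD of log10 nonzero abundances).
#'
#' @param table a [per_cell()] table.
#' @param genome optional [make_genome()]; when given, genes absent from the
#'   table count as undetected zeros in the mean and detected fraction.
#' @return data frame with one row per sample: `sample_id`,
#'   `mean_abundance`, `span_orders`, `detected_fraction`, `lognormal_mu`,
#'   `lognormal_sigma`.
#' @export
distribution_summary <- function(table, genome = NULL) {
  stopifnot(inherits(table, "cell_abundance_table"))
  ab <- table$abundances
  n_genes <- if (!is.null(genome)) {
    validate_genome(genome)
    genome$n_genes
  } else nrow(ab)
  res <- lapply(colnames(ab), function(s) {
    a <- ab[, s]
    nz <- a[a > 0]
    if (length(nz) == 0) {
      warning(sprintf("sample %s has no detected genes; span undefined", s),
              call. = FALSE)
      span <- NA_real_; mu <- NA_real_; sig <- NA_real_
    } else {
      span <- log10(max(nz) / min(nz))
      lg <- log10(nz)
      mu <- mean(lg)
      sig <- if (length(nz) > 1) stats::sd(lg) else 0
    }
    data.frame(sample_id = s,
               mean_abundance = sum(a) / n_genes,
               span_orders = span,
               detected_fraction = length(nz) / n_genes,
               lognormal_mu = mu, lognormal_sigma = sig,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
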