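#' Read a count table from TSV
#'
#' Expects a tab-separated file whose first column holds feature ids and
#' whose header row holds sample ids; cells are non-negative integers.
#' Standard features are recognised either by membership in `standards` or
#' by the `"STD:"` id prefix.
#'
#' @param path TSV file path.
#' @param standards optional [standard_specs()]; its ids mark standard rows.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, standards = NULL) {
  if (!file.exists(path)) stop(sprintf("count table not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs a feature column plus >= 1 sample", call. = FALSE)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate feature id in %s: %s", path, dup[1]), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    mn <- suppressWarnings(array(as.numeric(m), dim = dim(m), dimnames = dimnames(m)))
    bad <- which(is.na(mn) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric count at row '%s', column '%s'",
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
    m <- mn
  }
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at row '%s', column '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  rownames(m) <- ids
  std_ids <- if (!is.null(standards)) intersect(standards$std_id, ids)
             else grep("^STD:", ids, value = TRUE)
  count_table(m, standard_ids = std_ids)
}

#' Write a count table as TSV
#'
#' Rows are feature ids, columns sample ids, integer counts; the paired
#' reader [read_count_table()] reproduces the object exactly.
#'
#' @param x a [count_table()].
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(feature_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tidy TSV writers/readers for growth and methanol series
#'
#' Growth curves are written long-form (`time`, `replicate`, `density`);
#' methanol series as (`time`, `concentration`).
#'
#' @param curve a [simulate_growth()] object.
#' @param path file path.
#' @name series_io
#' @export
write_growth_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "growth_curve"))
  df <- data.frame(
    time = rep(curve$times, ncol(curve$densities)),
    replicate = rep(colnames(curve$densities), each = length(curve$times)),
    density = as.vector(curve$densities),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname series_io
#' @param regime_label label attached to the curve read back.
#' @export
read_growth_tsv <- function(path, regime_label = "regime") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("time", "replicate", "density")
  if (!all(need %in% names(df)))
    stop(sprintf("growth TSV %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  reps <- unique(df$replicate)
  times <- sort(unique(df$time))
  dens <- vapply(reps, function(r) {
    sub <- df[df$replicate == r, ]
    sub$density[match(times, sub$time)]
  }, numeric(length(times)))
  dens <- matrix(dens, nrow = length(times),
                 dimnames = list(NULL, as.character(reps)))
  if (anyNA(dens)) stop("growth TSV has missing time x replicate cells", call. = FALSE)
  if (any(dens < 0)) stop("densities must be >= 0", call. = FALSE)
  structure(list(times = times, densities = dens, regime_label = regime_label),
            class = "growth_curve")
}

#' @rdname series_io
#' @param series a [simulate_drawdown()] object.
#' @export
write_methanol_tsv <- function(series, path) {
  stopifnot(inherits(series, "methanol_series"))
  utils::write.table(
    data.frame(time = series$times, concentration = series$concentrations),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname series_io
#' @export
read_methanol_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("time", "concentration") %in% names(df)))
    stop(sprintf("methanol TSV %s must have columns time, concentration", path),
         call. = FALSE)
  if (any(df$concentration < 0)) stop("concentrations must be >= 0", call. = FALSE)
  structure(list(times = df$time, concentrations = df$concentration),
            class = "methanol_series")
}

#' Abundance-table TSV export/import
#'
#' Per-cell abundances (genes x samples, floating point) plus the
#' per-1,000-cells convention used for reporting.
#'
#' @param table a [per_cell()] table.
#' @param path file path.
#' @param per_1000 write the per-1,000-cells view instead of per-cell.
#' @export
write_abundance_tsv <- function(table, path, per_1000 = FALSE) {
  stopifnot(inherits(table, "cell_abundance_table"))
  m <- if (per_1000) table$per_1000 else table$abundances
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @return `read_abundance_tsv()` returns a genes x samples numeric matrix.
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Sample-metadata TSV
#'
#' @param meta a [sample_meta()] table.
#' @param path file path.
#' @export
write_meta_tsv <- function(meta, path) {
  stopifnot(inherits(meta, "sample_meta"))
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta_tsv
#' @export
read_meta_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "regime", "timepoint", "replicate", "cells_collected")
  if (!all(need %in% names(df)))
    stop(sprintf("metadata TSV %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  sample_meta(df$sample_id, df$regime, df$timepoint, df$replicate,
              df$cells_collected,
              if ("library_size" %in% names(df)) df$library_size else NA_real_)
}

#' Write a calibration fit report as JSON
#'
#' @param fit a [fit_recovery()] object.
#' @param path output JSON path.
#' @export
write_calibration_json <- function(fit, path) {
  stopifnot(inherits(fit, "calibration_fit"))
  obj <- list(
    slope = fit$slope, intercept = fit$intercept, r_squared = fit$r_squared,
    reads_per_copy = fit$reads_per_copy, mode = fit$mode,
    excluded = as.list(fit$excluded),
    per_standard_ratio = as.list(fit$per_standard_ratio)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
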