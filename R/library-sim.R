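#' Configuration for simulating one spiked sequencing library
#'
#' @param library_size total reads R (>= 0).
#' @param cells_collected cells N captured on the filter (> 0); per-cell
#'   abundances times N give the molecule pool the library samples from.
#' @param mode read-sampling model. `"per-copy"` (default): a feature's
#'   sampling weight is its molecule count, so reads are proportional to
#'   copies — self-consistent with per-copy calibration. `"length-weighted"`:
#'   weights are additionally proportional to feature length, emulating
#'   fragment sequencing; pair it with length-weighted calibration.
#' @param seed integer seed; counts are deterministic for a fixed seed.
#' @param corrupted_standards named numeric vector of multiplicative
#'   recovery biases for badly recovered standards (e.g.
#'   `c("STD:02" = 0.05)` for a 20-fold loss); all biases must be > 0.
#' @return `library_sim_config` list.
#' @export
library_sim_config <- function(library_size, cells_collected,
                               mode = c("per-copy", "length-weighted"),
                               seed = NULL, corrupted_standards = numeric()) {
  stop_if_not_scalar_number(library_size, "library_size", lower = 0)
  stop_if_not_scalar_number(cells_collected, "cells_collected", lower = 0, strict = TRUE)
  mode <- match.arg(mode)
  if (length(corrupted_standards)) {
    if (is.null(names(corrupted_standards)) || any(names(corrupted_standards) == ""))
      stop("`corrupted_standards` must be a named vector of biases", call. = FALSE)
    if (any(corrupted_standards <= 0))
      stop("recovery bias factors must be > 0", call. = FALSE)
  }
  structure(
    list(library_size = as.numeric(library_size),
         cells_collected = as.numeric(cells_collected),
         mode = mode, seed = seed,
         corrupted_standards = corrupted_standards),
    class = "library_sim_config"
  )
}

#' Simulate read counts for one spiked library
#'
#' Reads are drawn multinomially over genome features plus internal
#' standards, with total exactly `config$library_size`. In per-copy mode the
#' sampling weight of gene g is `a_g * N` (its molecules in the sample) and
#' of standard j its copies added `S_j` (times its corruption bias, if any);
#' in length-weighted mode both weights are additionally multiplied by
#' feature length.
#'
#' @param profile an [sample_expression()] profile.
#' @param standards a [standard_specs()] data frame (must be non-empty:
#'   without standards the library could never be calibrated).
#' @param config a [library_sim_config()].
#' @param genome the [make_genome()] object; required in length-weighted
#'   mode for gene lengths.
#' @param sample_id column name for the returned one-sample count table.
#' @return A `count_table`: integer matrix (features x 1) whose rows are
#'   gene ids followed by standard ids, with attribute `standard_ids`.
#' @export
simulate_library <- function(profile, standards, config, genome = NULL,
                             sample_id = "sample1") {
  stopifnot(inherits(profile, "expression_profile"),
            inherits(config, "library_sim_config"))
  if (!inherits(standards, "standard_spec") || nrow(standards) == 0)
    stop("`standards` must be a non-empty standard_spec set", call. = FALSE)
  gene_w <- profile$abundances * config$cells_collected
  std_w <- standards$copies_added
  bias <- config$corrupted_standards
  if (length(bias)) {
    unknown <- setdiff(names(bias), standards$std_id)
    if (length(unknown))
      stop(sprintf("corrupted standard(s) not in spec: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    idx <- match(names(bias), standards$std_id)
    std_w[idx] <- std_w[idx] * bias
  }
  if (config$mode == "length-weighted") {
    if (is.null(genome)) stop("length-weighted mode needs `genome` for gene lengths",
                              call. = FALSE)
    validate_genome(genome)
    gene_w <- gene_w * genome$gene_lengths[match(names(gene_w), genome$gene_ids)]
    std_w <- std_w * standards$length
  }
  w <- c(gene_w, std_w)
  ids <- c(names(profile$abundances), standards$std_id)
  counts <- if (config$library_size == 0 || sum(w) == 0) {
    integer(length(w))
  } else {
    with_seed(config$seed,
              as.integer(stats::rmultinom(1, size = config$library_size, prob = w)))
  }
  m <- matrix(counts, ncol = 1, dimnames = list(ids, sample_id))
  count_table(m, standard_ids = standards$std_id)
}

#' Construct / validate a count table
#'
#' A count table is an integer matrix of reads per feature (genes plus
#' internal standards) per sample, with the standard rows recorded in the
#' `standard_ids` attribute.
#'
#' @param counts integer matrix, features x samples, with rownames.
#' @param standard_ids feature ids that are internal standards.
#' @return A `count_table` matrix.
#' @export
count_table <- function(counts, standard_ids = character()) {
  if (!is.matrix(counts) || is.null(rownames(counts)))
    stop("`counts` must be a matrix with feature rownames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop(sprintf("duplicate feature id: %s",
                 rownames(counts)[duplicated(rownames(counts))][1]), call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) stop("counts must be integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  missing_std <- setdiff(standard_ids, rownames(counts))
  if (length(missing_std))
    stop(sprintf("standard id(s) absent from table: %s",
                 paste(missing_std, collapse = ", ")), call. = FALSE)
  structure(counts, standard_ids = as.character(standard_ids),
            class = c("count_table", "matrix", "array"))
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
gene_counts <- function(x) {
  stopifnot(inherits(x, "count_table"))
  x[setdiff(rownames(x), attr(x, "standard_ids")), , drop = FALSE]
}

#' @rdname count_table
#' @export
standard_counts <- function(x) {
  stopifnot(inherits(x, "count_table"))
  x[intersect(rownames(x), attr(x, "standard_ids")), , drop = FALSE]
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d features (%d standards) x %d samples, %.3g reads\n",
              nrow(x), length(attr(x, "standard_ids")), ncol(x), sum(as.numeric(x))))
  invisible(x)
}

# cbind single-sample tables into one experiment table
bind_count_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  ids <- rownames(tables[[1]])
  std <- attr(tables[[1]], "standard_ids")
  mats <- lapply(tables, function(tt) {
    stopifnot(identical(rownames(tt), ids))
    unclass(tt)
  })
  count_table(do.call(cbind, mats), standard_ids = std)
}
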