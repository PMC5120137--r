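#' Draw a lognormal per-cell expression profile
#'
#' Genome-wide distributions of per-gene transcript abundance in growing
#' bacteria are well described as lognormal, with essentially every gene
#' expressed at some level and nonzero abundances spanning several orders of
#' magnitude. `sample_expression()` draws one such profile: per-gene
#' abundances are lognormal in log10 space with spread `sigma_log10`, then
#' rescaled so they sum exactly to `total_per_cell` (the cell's total mRNA
#' content in transcripts per cell).
#'
#' The default `sigma_log10 = 0.70` was calibrated by search so that, over a
#' 1,377-gene genome, the log10(max/min) span of a profile averages about
#' 4.6 orders of magnitude.
#'
#' @param genome a [make_genome()] object.
#' @param total_per_cell total mRNA content, transcripts per cell (> 0);
#'   ranges from ~1,800 in exponential growth down to ~17 in deep stationary
#'   phase for a streamlined methylotroph.
#' @param sigma_log10 lognormal spread in log10 units (>= 0). Zero gives a
#'   flat profile.
#' @param seed integer seed.
#' @return An object of class `expression_profile`: list with `abundances`
#'   (named, transcripts per cell), `total_per_cell`, `sigma_log10`.
#' @examples
#' g <- make_genome(seed = 1)
#' p <- sample_expression(g, total_per_cell = 1859, seed = 1)
#' sum(p$abundances) # exactly 1859
#' @export
sample_expression <- function(genome, total_per_cell, sigma_log10 = 0.70, seed = NULL) {
  validate_genome(genome)
  stop_if_not_scalar_number(total_per_cell, "total_per_cell", lower = 0, strict = TRUE)
  stop_if_not_scalar_number(sigma_log10, "sigma_log10", lower = 0)
  raw <- with_seed(seed, 10^stats::rnorm(genome$n_genes, mean = 0, sd = sigma_log10))
  ab <- raw * (total_per_cell / sum(raw))
  names(ab) <- genome$gene_ids
  structure(
    list(abundances = ab, total_per_cell = total_per_cell, sigma_log10 = sigma_log10),
    class = "expression_profile"
  )
}

#' @export
print.expression_profile <- function(x, ...) {
  nz <- x$abundances[x$abundances > 0]
  cat(sprintf(
    "<expression_profile> %d genes, total %.4g transcripts/cell, span %.2f orders\n",
    length(x$abundances), x$total_per_cell,
    if (length(nz)) log10(max(nz) / min(nz)) else NA_real_
  ))
  invisible(x)
}
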