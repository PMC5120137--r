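#' Construct a synthetic streamlined-genome model
#'
#' Builds a gene catalogue (identifiers and lengths) with the size structure
#' of a streamlined marine methylotroph genome: by default 1,377 genes whose
#' lengths average 944 nt, so the coding complement totals about 1.3 Mbp.
#' Lengths are drawn as `50 + Gamma(shape = 4)` (rounded), a bounded positive
#' distribution with the requested mean and a 50 nt floor.
#'
#' @param n_genes number of genes (>= 1).
#' @param mean_length mean gene length in nt (>= 50).
#' @param seed integer seed; the result is deterministic for a fixed seed.
#' @return An object of class `genome_model`: a list with `gene_ids`,
#'   `gene_lengths` (nt) and `n_genes`.
#' @examples
#' g <- make_genome(n_genes = 1377, mean_length = 944, seed = 1)
#' sum(g$gene_lengths) # ~1.3e6 nt
#' @export
make_genome <- function(n_genes = 1377L, mean_length = 944, seed = NULL) {
  stop_if_not_scalar_number(n_genes, "n_genes", lower = 1)
  stop_if_not_scalar_number(mean_length, "mean_length", lower = 50)
  n_genes <- as.integer(n_genes)
  excess <- with_seed(seed, {
    shape <- 4
    scale <- (mean_length - 50) / shape
    if (scale <= 0) rep(0, n_genes) else stats::rgamma(n_genes, shape = shape, scale = scale)
  })
  lengths <- pmax(50L, as.integer(round(50 + excess)))
  ids <- sprintf("gene_%04d", seq_len(n_genes))
  structure(
    list(gene_ids = ids, gene_lengths = lengths, n_genes = n_genes),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %d genes, total %.3g nt (mean %.0f nt)\n",
    x$n_genes, sum(as.numeric(x$gene_lengths)), mean(x$gene_lengths)
  ))
  invisible(x)
}

validate_genome <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  if (anyDuplicated(genome$gene_ids)) stop("gene ids must be unique", call. = FALSE)
  if (length(genome$gene_ids) != genome$n_genes)
    stop("n_genes does not match the number of gene ids", call. = FALSE)
  if (any(genome$gene_lengths < 50)) stop("all gene lengths must be >= 50 nt", call. = FALSE)
  invisible(genome)
}
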