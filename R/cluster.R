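#' Hierarchical clustering of sample expression profiles
#'
#' Samples are clustered on genome-wide per-cell transcript profiles with
#' distance `1 - Pearson r` and complete-linkage agglomeration. Because
#' profiles span several orders of magnitude, the default transform is
#' `log10(x + pseudocount)` with pseudocount half the smallest nonzero
#' abundance; raw-scale clustering is available with
#' `log_transform = FALSE`. Samples are ordered lexicographically by id
#' before agglomeration so ties break deterministically.
#'
#' @param table a [per_cell()] abundance table, or a plain genes x samples
#'   matrix (>= 2 samples).
#' @param log_transform apply `log10(x + pseudocount)` first.
#' @param pseudocount value added before the log; default half the smallest
#'   nonzero abundance in the table.
#' @return An object of class `hclust` (complete linkage on
#'   `1 - Pearson r`), with heights non-decreasing along merges.
#' @export
cluster_samples <- function(table, log_transform = TRUE, pseudocount = NULL) {
  x <- if (inherits(table, "cell_abundance_table")) table$abundances else as.matrix(table)
  if (ncol(x) < 2) stop("need >= 2 samples to cluster", call. = FALSE)
  x <- x[, order(colnames(x)), drop = FALSE]
  if (log_transform) {
    nz <- x[x > 0]
    if (is.null(pseudocount)) {
      pseudocount <- if (length(nz)) min(nz) / 2 else 1e-6
    }
    x <- log10(x + pseudocount)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant profile, correlation undefined for sample(s): %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")), call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(x, method = "pearson"))
  stats::hclust(d, method = "complete")
}

#' Export a dendrogram as Newick text
#'
#' @param hc an `hclust` object (e.g. from [cluster_samples()]).
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Smallest dendrogram cluster containing a set of leaves
#'
#' Walks the merge order of an `hclust` tree and returns the members of the
#' smallest internal node that contains every requested leaf — useful for
#' asking whether one treatment's replicates nest inside another's cluster.
#'
#' @param hc an `hclust` object.
#' @param leaves leaf labels that must be contained.
#' @return character vector of the cluster's member labels.
#' @export
smallest_containing_cluster <- function(hc, leaves) {
  stopifnot(inherits(hc, "hclust"))
  labels <- hc$labels
  stopifnot(all(leaves %in% labels))
  members <- list() # per merge node
  for (i in seq_len(nrow(hc$merge))) {
    row <- hc$merge[i, ]
    get <- function(v) if (v < 0) labels[-v] else members[[v]]
    members[[i]] <- c(get(row[1]), get(row[2]))
  }
  if (length(leaves) == 1) return(leaves)
  sizes <- vapply(members, length, integer(1))
  ok <- vapply(members, function(m) all(leaves %in% m), logical(1))
  members[[which(ok)[which.min(sizes[ok])]]]
}
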