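#' One-way fixed-effects ANOVA
#'
#' Classical decomposition: between-group and within-group sums of squares,
#' `F = MSB / MSW` on (k-1, N-k) degrees of freedom. When every observation
#' is identical the statistic is 0 and p is 1 by convention; when groups are
#' distinct constants (zero within-group variance) F is infinite and p is 0.
#'
#' @param groups list of numeric vectors, one per group; >= 2 groups with
#'   >= 2 replicates each.
#' @return list with `F` and `p`.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))) # F = 3, p = 0.125
#' @export
anova_oneway <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("insufficient replication: every group needs >= 2 replicates", call. = FALSE)
  invisible(groups)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q-values controlling the false discovery rate: sort p ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j`, cap at 1, and restore the input
#' order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- rev(cummin(rev(pvalues[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Pairwise t tests between groups
#'
#' With `pooled_sd = TRUE` (default) each pair's t statistic uses the common
#' within-group variance pooled over *all* groups, on `N - k` degrees of
#' freedom; with `pooled_sd = FALSE` each pair is a classical two-sample
#' equal-variance t test on `n_i + n_j - 2` df. Unadjusted two-sided
#' p-values are returned.
#'
#' @param groups named list of numeric vectors (>= 2 groups, >= 2 replicates
#'   each).
#' @param pooled_sd pool the within-group SD across all groups.
#' @return symmetric matrix of p-values (diagonal `NA`).
#' @export
pairwise_t <- function(groups, pooled_sd = TRUE) {
  check_groups(groups)
  k <- length(groups)
  nms <- names(groups) %||% paste0("group", seq_len(k))
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  ssw_i <- vapply(seq_len(k), function(i) sum((groups[[i]] - means[i])^2), numeric(1))
  p <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (pooled_sd) {
        df <- sum(n) - k
        s2 <- sum(ssw_i) / df
      } else {
        df <- n[i] + n[j] - 2
        s2 <- (ssw_i[i] + ssw_i[j]) / df
      }
      dm <- means[i] - means[j]
      if (s2 == 0) {
        pv <- if (dm == 0) 1 else {
          message("zero pooled variance with unequal means; p set to smallest representable value")
          .Machine$double.xmin
        }
      } else {
        tt <- dm / sqrt(s2 * (1 / n[i] + 1 / n[j]))
        pv <- 2 * stats::pt(-abs(tt), df)
      }
      p[i, j] <- p[j, i] <- pv
    }
  }
  p
}

#' Fold change between two abundances
#'
#' @param a,b abundances (transcripts cell^-1 or any common scale).
#' @return list with `ratio` (`a/b`) and `log2` view. `b = 0` with `a > 0`
#'   gives `Inf` with a warning; both zero gives `NA`.
#' @export
fold_change <- function(a, b) {
  ratio <- ifelse(a == 0 & b == 0, NA_real_, a / b)
  if (any(b == 0 & a > 0, na.rm = TRUE))
    warning("zero denominator: infinite fold change", call. = FALSE)
  list(ratio = ratio, log2 = log2(ratio))
}

#' Fold change of one regime against the mean of the others
#'
#' `ratio = focal mean / arithmetic mean of the other regimes' means`.
#' Ratios below 1 are reductions; `fold` reports the deviation magnitude
#' (`max(ratio, 1/ratio)`) and `direction` its sign.
#'
#' @param means named per-regime mean abundances (>= 2 regimes).
#' @param focal name of the focal regime.
#' @return list with `ratio`, `fold`, `direction` (`"up"`/`"down"`/`"none"`).
#' @examples
#' fold_vs_others(c(deplete = 869, replete = 177, vitamin = 184, DOM = 173),
#'                "deplete")
#' @export
fold_vs_others <- function(means, focal) {
  if (is.null(names(means)) || !(focal %in% names(means)))
    stop("`means` must be named and contain `focal`", call. = FALSE)
  others <- means[setdiff(names(means), focal)]
  fc <- fold_change(unname(means[[focal]]), mean(others))
  ratio <- fc$ratio
  list(ratio = ratio,
       fold = if (is.na(ratio)) NA_real_ else max(ratio, 1 / ratio),
       direction = if (is.na(ratio) || ratio == 1) "none"
                   else if (ratio > 1) "up" else "down")
}

#' Call significant regulation across four nutrient regimes
#'
#' The calling scheme applied to late-exponential-phase samples of four
#' regimes (triplicates each): per gene a one-way ANOVA across regimes; the
#' ANOVA p-values are Benjamini-Hochberg corrected *across genes*; for genes
#' with `q < alpha`, pooled-SD pairwise t tests identify differing pairs,
#' and a regime is called up (`+`) or down (`-`) against another only when
#' the pairwise p is below `alpha` *and* the fold change of regime means is
#' at least `min_fold`. Everything else is `n` (no significant difference).
#'
#' The `calls` string gives, for each regime in `regimes` order, its three
#' symbols against the other regimes (in the same order, skipping itself),
#' e.g. `"+++, -nn, -nn, -nn"` for a gene elevated in the first regime.
#'
#' @param table a [per_cell()] abundance table whose metadata assign each
#'   sample to one of the four regimes.
#' @param regimes character vector of exactly 4 regime labels, in reporting
#'   order (conventionally deplete, replete, vitamin, DOM).
#' @param alpha significance level for ANOVA q and pairwise p (default 0.05).
#' @param min_fold minimum fold change of regime means (default 2).
#' @return `diffexpr_table` data frame: per gene the regime means, `F`, `p`,
#'   `q`, pairwise p-values (`p_<A>_vs_<B>`), pairwise folds
#'   (`fold_<A>_vs_<B>`, A/B ratio), and `calls`.
#' @export
call_regulation <- function(table, regimes, alpha = 0.05, min_fold = 2) {
  stopifnot(inherits(table, "cell_abundance_table"))
  if (length(regimes) != 4)
    stop("configuration error: exactly 4 regime labels required", call. = FALSE)
  meta <- table$meta
  missing_reg <- setdiff(regimes, meta$regime)
  if (length(missing_reg))
    stop(sprintf("no samples for regime(s): %s", paste(missing_reg, collapse = ", ")),
         call. = FALSE)
  cols <- lapply(regimes, function(r) which(meta$regime == r))
  ab <- table$abundances
  genes <- rownames(ab)

  grp_of <- function(g) lapply(cols, function(ix) ab[g, ix])
  an <- lapply(genes, function(g) anova_oneway(grp_of(g)))
  pvals <- vapply(an, `[[`, numeric(1), "p")
  Fvals <- vapply(an, `[[`, numeric(1), "F")
  qvals <- bh_adjust(pvals)

  pair_idx <- utils::combn(4, 2)
  pair_names <- apply(pair_idx, 2, function(ij)
    sprintf("%s_vs_%s", regimes[ij[1]], regimes[ij[2]]))

  means_mat <- t(vapply(genes, function(g)
    vapply(grp_of(g), mean, numeric(1)), numeric(4)))
  colnames(means_mat) <- regimes

  pw_p <- matrix(NA_real_, length(genes), ncol(pair_idx),
                 dimnames = list(genes, paste0("p_", pair_names)))
  folds <- matrix(NA_real_, length(genes), ncol(pair_idx),
                  dimnames = list(genes, paste0("fold_", pair_names)))
  calls <- character(length(genes))

  for (gi in seq_along(genes)) {
    m <- means_mat[gi, ]
    folds[gi, ] <- apply(pair_idx, 2, function(ij)
      fold_change(m[ij[1]], m[ij[2]])$ratio)
    sym <- matrix("n", 4, 4)
    if (qvals[gi] < alpha) {
      groups <- grp_of(genes[gi])
      names(groups) <- regimes
      pm <- suppressMessages(pairwise_t(groups, pooled_sd = TRUE))
      pw_p[gi, ] <- apply(pair_idx, 2, function(ij) pm[ij[1], ij[2]])
      for (a_i in 1:4) for (b_i in setdiff(1:4, a_i)) {
        pv <- pm[a_i, b_i]
        r <- fold_change(m[a_i], m[b_i])$ratio
        if (!is.na(pv) && pv < alpha && !is.na(r)) {
          if (r >= min_fold) sym[a_i, b_i] <- "+"
          else if (r <= 1 / min_fold) sym[a_i, b_i] <- "-"
        }
      }
    }
    calls[gi] <- paste(vapply(1:4, function(a_i)
      paste(sym[a_i, setdiff(1:4, a_i)], collapse = ""), character(1)),
      collapse = ", ")
  }

  out <- data.frame(gene = genes, means_mat, F = Fvals, p = pvals, q = qvals,
                    pw_p, folds, calls = calls,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "regimes") <- regimes
  attr(out, "alpha") <- alpha
  attr(out, "min_fold") <- min_fold
  class(out) <- c("diffexpr_table", "data.frame")
  out
}

#' Flag genes with similar abundance across regimes
#'
#' A gene is "similar across regimes" when the maximum pairwise absolute
#' log2 fold change among its regime means is strictly below `max_log2fc`
#' (default 1, i.e. all regime means within 2-fold of each other). The
#' BH-corrected ANOVA q-value is reported alongside but does not gate the
#' similarity flag.
#'
#' @inheritParams call_regulation
#' @param max_log2fc similarity bound on |log2 fold change| (default 1).
#' @return character vector of similar gene ids, with a `details` attribute
#'   (data frame: gene, max_abs_log2fc, anova_q, similar).
#' @export
flag_similar_genes <- function(table, regimes, max_log2fc = 1, alpha = 0.05) {
  de <- call_regulation(table, regimes, alpha = alpha, min_fold = 2)
  fold_cols <- grep("^fold_", names(de), value = TRUE)
  max_l2 <- apply(as.matrix(de[fold_cols]), 1, function(r)
    max(abs(log2(r)), na.rm = TRUE))
  details <- data.frame(gene = de$gene, max_abs_log2fc = max_l2,
                        anova_q = de$q, similar = max_l2 < max_log2fc,
                        stringsAsFactors = FALSE)
  structure(details$gene[details$similar], details = details)
}
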