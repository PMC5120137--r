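#' Fit the internal-standard recovery relationship
#'
#' Ordinary least squares of `log10(reads recovered)` on `log10(copies
#' added)` across the non-excluded standards of one library quantifies how
#' faithfully the spike-ins were recovered: a slope near 1 with high r^2
#' indicates log-linear recovery across the spiked range. The conversion
#' factor is the pooled ratio estimator `k = sum(reads) / sum(copies)` over
#' retained standards (reads per molecule; in length-weighted mode reads per
#' molecule-nt, `sum(reads) / sum(copies * length)`), which is robust to
#' per-standard noise; the regression itself serves as quality control.
#'
#' Standards with zero reads cannot enter the log-log regression and are
#' dropped from it with a warning, but they keep a per-standard ratio of 0
#' so outlier flagging still sees them.
#'
#' @param std_counts named numeric vector of standard read counts for one
#'   sample (names are standard ids), or a one-sample matrix of standard
#'   rows.
#' @param specs a [standard_specs()] data frame.
#' @param exclude standard ids to leave out of both the regression and `k`
#'   (e.g. standards known to be badly recovered).
#' @param mode `"per-copy"` or `"length-weighted"`; must match how the
#'   library was generated/sequenced.
#' @return `calibration_fit`: list with `slope`, `intercept` (log10 reads at
#'   1 copy), `r_squared`, `per_standard_ratio` (reads per copy, all
#'   non-excluded standards), `reads_per_copy` (pooled k), `excluded`,
#'   `mode`, `n_regression`.
#' @export
fit_recovery <- function(std_counts, specs, exclude = character(),
                         mode = c("per-copy", "length-weighted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(specs, "standard_spec"))
  if (is.matrix(std_counts)) {
    if (ncol(std_counts) != 1)
      stop("`std_counts` must be a single sample; fit each sample separately",
           call. = FALSE)
    std_counts <- stats::setNames(as.numeric(std_counts), rownames(std_counts))
  }
  if (is.null(names(std_counts)))
    stop("`std_counts` must be named by standard id", call. = FALSE)
  unknown <- setdiff(names(std_counts), specs$std_id)
  if (length(unknown))
    stop(sprintf("counts for unknown standard(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  bad_excl <- setdiff(exclude, specs$std_id)
  if (length(bad_excl))
    stop(sprintf("excluded id(s) not in spec: %s", paste(bad_excl, collapse = ", ")),
         call. = FALSE)

  keep <- setdiff(specs$std_id, exclude)
  reads <- std_counts[match(keep, names(std_counts))]
  reads[is.na(reads)] <- 0
  sp <- specs[match(keep, specs$std_id), ]
  denom <- if (mode == "length-weighted") sp$copies_added * sp$length else sp$copies_added

  if (all(reads == 0))
    stop("calibration failed: all retained standards have zero reads", call. = FALSE)

  nz <- reads > 0
  if (any(!nz)) {
    warning(sprintf("standard(s) with zero reads dropped from regression: %s",
                    paste(keep[!nz], collapse = ", ")), call. = FALSE)
  }
  x <- log10(sp$copies_added[nz])
  y <- log10(reads[nz])
  if (length(unique(x)) < 2)
    stop("degenerate design: need >= 2 distinct copies_added levels with nonzero reads",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  coefs <- fit$coefficients
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot

  structure(
    list(
      slope = unname(coefs[2]),
      intercept = unname(coefs[1]),
      r_squared = r2,
      per_standard_ratio = stats::setNames(reads / denom, keep),
      reads_per_copy = sum(reads) / sum(denom),
      excluded = as.character(exclude),
      mode = mode,
      n_regression = sum(nz)
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> slope %.3f, r2 %.4f, k = %.4g reads/%s (%d standards; %d excluded)\n",
    x$slope, x$r_squared, x$reads_per_copy,
    if (x$mode == "per-copy") "copy" else "copy-nt",
    length(x$per_standard_ratio), length(x$excluded)
  ))
  invisible(x)
}

#' Flag standards recovered off-ratio
#'
#' A standard is flagged when its per-copy recovery ratio deviates from the
#' geometric mean ratio by strictly more than `threshold_fold` in either
#' direction. Because grossly corrupted standards drag the geometric mean
#' itself, the rule is iterated to a fixed point: flagged standards are
#' removed, the geometric mean is recomputed over the remainder, and
#' deviations are re-evaluated until the flagged set stabilises. On clean
#' data this reduces to the one-pass rule. Standards with a zero ratio (no
#' reads recovered) are always flagged.
#'
#' Flagged standards are reported; whether to exclude them (by refitting
#' with `exclude =`) is the caller's decision.
#'
#' @param fit a [fit_recovery()] result with ratios for >= 3 standards.
#' @param threshold_fold fold-deviation threshold (default 2), strict
#'   inequality: a standard at exactly the threshold is not flagged.
#' @return character vector of flagged standard ids (possibly empty).
#' @export
flag_outlier_standards <- function(fit, threshold_fold = 2) {
  stopifnot(inherits(fit, "calibration_fit"))
  stop_if_not_scalar_number(threshold_fold, "threshold_fold", lower = 1)
  ratios <- fit$per_standard_ratio
  if (length(ratios) < 3)
    stop("insufficient data: need per-standard ratios for >= 3 standards", call. = FALSE)
  tol <- threshold_fold * (1 + 1e-9) # strict inequality, robust to rounding
  flagged <- names(ratios)[ratios == 0]
  # greedy peeling: remove the single worst deviator, recompute the
  # geometric mean over the remainder, repeat until nothing exceeds the
  # threshold -- prevents corrupted standards from dragging the reference
  repeat {
    ref <- ratios[setdiff(names(ratios), flagged)]
    ref <- ref[ref > 0]
    if (length(ref) < 2) break
    gm <- exp(mean(log(ref)))
    dev_ref <- pmax(ref / gm, gm / ref)
    worst <- which.max(dev_ref)
    if (dev_ref[worst] > tol) flagged <- c(flagged, names(ref)[worst]) else break
  }
  # re-evaluate every standard against the retained reference
  ref <- ratios[setdiff(names(ratios), flagged)]
  ref <- ref[ref > 0]
  if (length(ref)) {
    gm <- exp(mean(log(ref)))
    dev <- pmax(ratios / gm, gm / ratios) # Inf for zero ratios
    flagged <- names(ratios)[dev > tol | ratios == 0]
  }
  sort(flagged)
}
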