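#' Simulate logistic batch growth
#'
#' Cell densities follow the closed-form logistic trajectory
#' `N(t) = K n0 e^{mu t} / (K + n0 (e^{mu t} - 1))`, the standard model for
#' batch culture growth up to a carrying capacity, with optional
#' multiplicative lognormal replicate noise of coefficient of variation
#' `cv_noise`. Exponential-phase growth rates of methanol-grown OM43-clade
#' cultures fall in 0.06--0.09 h^-1; regime presets (see [regime_preset()])
#' use that range.
#'
#' @param mu_max maximum specific growth rate, h^-1 (>= 0).
#' @param capacity carrying capacity K, cells ml^-1 (>= n0).
#' @param n0 inoculum density, cells ml^-1 (> 0).
#' @param times sampling times in h, strictly increasing.
#' @param cv_noise replicate coefficient of variation (fraction, >= 0).
#' @param n_replicates number of replicate trajectories.
#' @param regime_label free-text label carried along.
#' @param seed integer seed.
#' @return `growth_curve`: list with `times` (h), `densities` (times x
#'   replicates matrix, cells ml^-1) and `regime_label`.
#' @export
simulate_growth <- function(mu_max, capacity, n0, times, cv_noise = 0,
                            n_replicates = 3L, regime_label = "regime",
                            seed = NULL) {
  stop_if_not_scalar_number(mu_max, "mu_max", lower = 0)
  stop_if_not_scalar_number(n0, "n0", lower = 0, strict = TRUE)
  stop_if_not_scalar_number(capacity, "capacity", lower = 0, strict = TRUE)
  if (capacity < n0) stop("`capacity` must be >= `n0`", call. = FALSE)
  stop_if_not_scalar_number(cv_noise, "cv_noise", lower = 0)
  if (length(times) < 1 || any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  mean_curve <- logistic_density(times, mu_max, capacity, n0)
  dens <- with_seed(seed, {
    m <- matrix(rep(mean_curve, n_replicates), ncol = n_replicates)
    if (cv_noise > 0) {
      sdlog <- sqrt(log(1 + cv_noise^2))
      noise <- matrix(
        stats::rlnorm(length(m), meanlog = -sdlog^2 / 2, sdlog = sdlog),
        ncol = n_replicates
      )
      m <- m * noise
    }
    m
  })
  dimnames(dens) <- list(NULL, sprintf("rep%d", seq_len(n_replicates)))
  structure(
    list(times = as.numeric(times), densities = dens, regime_label = regime_label),
    class = "growth_curve"
  )
}

# closed-form logistic; mu = 0 degenerates to constant n0
logistic_density <- function(t, mu, K, n0) {
  if (mu == 0) return(rep(n0, length(t)))
  K * n0 * exp(mu * t) / (K + n0 * (exp(mu * t) - 1))
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf(
    "<growth_curve> '%s': %d timepoints, %d replicates, %.3g -> %.3g cells/ml\n",
    x$regime_label, length(x$times), ncol(x$densities),
    mean(x$densities[1, ]), mean(x$densities[nrow(x$densities), ])
  ))
  invisible(x)
}

#' Specific growth rate and generation time between two density observations
#'
#' `mu = ln(n2/n1) / (t2 - t1)`; the generation (doubling) time is
#' `ln(2)/mu`. A non-positive growth rate has no finite doubling time and the
#' generation time is reported as `NA`.
#'
#' @param n1,n2 cell densities (cells ml^-1, > 0) at times `t1 < t2` (h).
#' @return list with `mu` (h^-1) and `generation_time` (h, `NA` if `mu <= 0`).
#' @examples
#' growth_rate(1e5, 2e5, 0, 10) # mu = 0.0693, generation time 10 h
#' @export
growth_rate <- function(n1, n2, t1, t2) {
  stop_if_not_scalar_number(n1, "n1", lower = 0, strict = TRUE)
  stop_if_not_scalar_number(n2, "n2", lower = 0, strict = TRUE)
  if (t2 <= t1) stop("`t2` must be > `t1`", call. = FALSE)
  mu <- log(n2 / n1) / (t2 - t1)
  list(mu = mu, generation_time = if (mu > 0) log(2) / mu else NA_real_)
}

#' Classify growth phase at each sampled timepoint
#'
#' Interval growth rates are computed between consecutive timepoints on the
#' replicate-mean densities and compared with the curve's maximum rate
#' `mu_max`: `exponential` when `mu >= 0.8 mu_max`, `late-exponential` when
#' `0.2 mu_max <= mu < 0.8 mu_max`, `stationary` when `|mu| < 0.2 mu_max`,
#' and `decline` when `mu <= -0.2 mu_max`. A stationary stretch that has
#' lasted longer than `deep_stationary_after` hours is relabelled
#' `deep-stationary`, and stationary points preceding the first exponential
#' point are labelled `lag`. The first timepoint inherits the first
#' interval's label.
#'
#' @param curve a [simulate_growth()] object (or compatible list).
#' @param deep_stationary_after hours of continuous stationary phase after
#'   which the label becomes `deep-stationary` (default 100 h).
#' @return character vector of labels, one per timepoint.
#' @export
classify_phase <- function(curve, deep_stationary_after = 100) {
  stopifnot(inherits(curve, "growth_curve"))
  t <- curve$times
  if (length(t) < 3) stop("need >= 3 timepoints to classify phases", call. = FALSE)
  dens <- rowMeans(curve$densities)
  if (any(dens <= 0)) stop("densities must be positive to compute rates", call. = FALSE)
  mu <- diff(log(dens)) / diff(t)
  mu_max <- max(mu)
  interval_label <- function(m) {
    if (mu_max <= 0) {
      if (m < 0) "decline" else "stationary"
    } else if (m >= 0.8 * mu_max) "exponential"
    else if (m >= 0.2 * mu_max) "late-exponential"
    else if (m <= -0.2 * mu_max) "decline"
    else "stationary"
  }
  lab <- vapply(mu, interval_label, character(1))
  lab <- c(lab[1], lab)   # first timepoint takes the first interval's label
  # lag: stationary before any exponential growth has occurred
  first_exp <- match("exponential", lab)
  if (!is.na(first_exp) && first_exp > 1) {
    pre <- seq_len(first_exp - 1)
    lab[pre][lab[pre] == "stationary"] <- "lag"
  }
  # deep stationary: continuous stationary residence longer than the cutoff
  entered <- NA_real_
  for (i in seq_along(lab)) {
    if (lab[i] == "stationary") {
      if (is.na(entered)) entered <- t[i]
      if (t[i] - entered > deep_stationary_after) lab[i] <- "deep-stationary"
    } else if (lab[i] != "deep-stationary") {
      entered <- NA_real_
    }
  }
  lab
}
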