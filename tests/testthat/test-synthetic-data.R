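test_that("genome construction honours size, lengths and determinism", {
  g1 <- make_genome(n_genes = 1, mean_length = 900, seed = 1)
  expect_equal(g1$n_genes, 1L)
  expect_length(g1$gene_ids, 1L)

  g <- make_genome(seed = 5)
  expect_equal(g$n_genes, 1377L)
  expect_false(anyDuplicated(g$gene_ids) > 0)
  expect_true(all(g$gene_lengths >= 50))

  expect_identical(make_genome(seed = 9), make_genome(seed = 9))
  expect_error(make_genome(n_genes = 0), "n_genes")
  expect_error(make_genome(n_genes = 10, mean_length = 10), "mean_length")
})

test_that("default genome totals ~1.3 Mbp across seeds", {
  totals <- vapply(1:20, function(s)
    sum(as.numeric(make_genome(n_genes = 1377, mean_length = 944,
                               seed = s)$gene_lengths)),
    numeric(1))
  expect_true(all(abs(totals - 1.3e6) / 1.3e6 < 0.05))
})

test_that("expression profiles are lognormal draws rescaled to the exact total", {
  g <- tiny_genome(n = 1377)
  p0 <- sample_expression(g, total_per_cell = 1377, sigma_log10 = 0, seed = 1)
  expect_equal(unname(p0$abundances), rep(1, 1377))

  for (s in 1:5) {
    for (sig in c(0.2, 0.7, 1.5)) {
      p <- sample_expression(g, total_per_cell = 1859, sigma_log10 = sig, seed = s)
      expect_equal(sum(p$abundances), 1859, tolerance = 1e-9)
      expect_true(all(p$abundances >= 0))
    }
  }
  expect_error(sample_expression(g, 100, sigma_log10 = -1), "sigma")
  expect_error(sample_expression(g, 0), "total_per_cell")
})

test_that("default spread yields a ~4.6-order abundance span", {
  g <- make_genome(seed = 2)
  spans <- vapply(1:20, function(s) {
    a <- sample_expression(g, 1859, seed = s)$abundances
    log10(max(a) / min(a))
  }, numeric(1))
  expect_equal(mean(spans), 4.6, tolerance = 0.4 / 4.6)
})

test_that("noise-free logistic curves match the closed form", {
  times <- seq(0, 150, by = 5)
  mu <- 0.08; n0 <- 1e3; K <- 3e6
  curve <- simulate_growth(mu, K, n0, times, cv_noise = 0, seed = 1)
  expected <- K * n0 * exp(mu * times) / (K + n0 * (exp(mu * times) - 1))
  for (j in seq_len(ncol(curve$densities)))
    expect_equal(curve$densities[, j], expected, tolerance = 1e-9)

  flat <- simulate_growth(0, K, n0, times, cv_noise = 0, seed = 1)
  expect_true(all(flat$densities == n0))
  expect_error(simulate_growth(0.1, capacity = 10, n0 = 100, times = times),
               "capacity")
})

test_that("library sampling is multinomial with exact read conservation", {
  g <- tiny_genome()
  p <- sample_expression(g, 500, seed = 3)
  std <- default_standards()

  cfg0 <- library_sim_config(0, 1e9, seed = 1)
  expect_true(all(simulate_library(p, std, cfg0) == 0L))

  for (s in 1:5) {
    cfg <- library_sim_config(12345, 1e9, seed = s)
    ct <- simulate_library(p, std, cfg)
    expect_identical(sum(ct), 12345L)
  }
  expect_identical(
    unclass(simulate_library(p, std, library_sim_config(1e4, 1e9, seed = 7))),
    unclass(simulate_library(p, std, library_sim_config(1e4, 1e9, seed = 7))))

  bad <- standard_specs("STD:01", 500, 1e8, "G1")[0, ]
  expect_error(simulate_library(p, bad, cfg0), "standard")
})

test_that("a dominant gene captures its expected read fraction", {
  # one gene holding 9x the standards' total molecules -> 90% of reads
  g <- make_genome(n_genes = 1, mean_length = 900, seed = 1)
  std <- default_standards()
  s_total <- sum(std$copies_added)
  n_cells <- 1e9
  prof <- structure(
    list(abundances = c(gene_0001 = 9 * s_total / n_cells),
         total_per_cell = 9 * s_total / n_cells, sigma_log10 = 0),
    class = "expression_profile")
  R <- 1e6
  ct <- simulate_library(prof, std, library_sim_config(R, n_cells, seed = 11))
  frac <- ct["gene_0001", 1] / R
  expect_equal(frac, 0.9, tolerance = 3 * sqrt(0.9 * 0.1 / R) / 0.9)
})

test_that("drawdown follows the carbon budget and inverts against the yield", {
  times <- seq(0, 100, 10)
  flat <- simulate_growth(0, 1e6, 1e5, times, cv_noise = 0)
  ms <- simulate_drawdown(flat, c0 = 20)
  expect_true(all(ms$concentrations == 20))

  curve <- simulate_growth(0.08, 3e6, 1e3, times, cv_noise = 0)
  ms2 <- simulate_drawdown(curve, c0 = 50)
  expect_true(all(diff(ms2$concentrations) <= 1e-12))
  produced <- max(rowMeans(curve$densities)) - rowMeans(curve$densities)[1]
  drawdown <- ms2$concentrations[1] - ms2$concentrations[length(times)]
  expect_equal(theoretical_yield(drawdown), produced, tolerance = 1e-6)

  # carbon exhausted -> clipped at zero with a warning
  big <- simulate_growth(0.1, 1e8, 1e3, seq(0, 300, 20), cv_noise = 0)
  expect_warning(ms3 <- simulate_drawdown(big, c0 = 10), "clipped")
  expect_true(all(ms3$concentrations >= 0))
})
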