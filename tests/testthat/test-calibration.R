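test_that("standards load from config, with FASTA lengths taking precedence", {
  cfg_path <- withr::local_tempfile(fileext = ".yml")
  write_standards_config(default_standards(), cfg_path)
  specs <- load_standards(cfg_path)
  expect_s3_class(specs, "standard_spec")
  expect_equal(nrow(specs), 14)
  expect_equal(length(unique(specs$group)), 4)

  # length from FASTA when config omits it
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", strrep("ACGU", 125), ">s2", strrep("AC", 150)), fa)
  cfg2 <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(standards = list(
    list(id = "s1", copies_added = 1e8, group = "G1"),
    list(id = "s2", copies_added = 1e9, group = "G1", length = 310)
  )), cfg2)
  expect_message(specs2 <- load_standards(cfg2, fa), "override")
  expect_equal(specs2$length[specs2$std_id == "s1"], 500)
  expect_equal(specs2$length[specs2$std_id == "s2"], 300)

  # missing copies_added is a format error naming the standard
  cfg3 <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(standards = list(
    list(id = "sA", copies_added = 1e8, group = "G1", length = 500),
    list(id = "sB", group = "G1", length = 500)
  )), cfg3)
  expect_error(load_standards(cfg3), "sB")

  cfg4 <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(standards = list()), cfg4)
  expect_error(load_standards(cfg4), "empty")
})

test_that("exact proportionality gives a perfect unit-slope fit", {
  specs <- default_standards()
  reads <- 0.01 * specs$copies_added
  names(reads) <- specs$std_id
  fit <- fit_recovery(reads, specs)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$reads_per_copy, 0.01, tolerance = 1e-9)
})

test_that("three collinear points reproduce the hand-computed regression", {
  specs <- standard_specs(c("a", "b", "c"), c(500, 500, 500),
                          c(1e4, 1e5, 1e6), "G1")
  fit <- fit_recovery(c(a = 50, b = 500, c = 5000), specs)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, log10(5e-3), tolerance = 1e-12)
})

test_that("scaling all counts shifts the intercept and k, not slope or r2", {
  specs <- default_standards()
  set.seed(4)
  reads <- stats::setNames(
    round(0.005 * specs$copies_added * runif(14, 0.7, 1.4)), specs$std_id)
  f1 <- fit_recovery(reads, specs)
  f2 <- fit_recovery(reads * 8, specs)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(f2$intercept, f1$intercept + log10(8), tolerance = 1e-12)
  expect_equal(f2$reads_per_copy, 8 * f1$reads_per_copy, tolerance = 1e-12)
})

test_that("excluding a standard removes it everywhere; re-inclusion restores the fit", {
  specs <- default_standards()
  set.seed(5)
  reads <- stats::setNames(
    round(0.005 * specs$copies_added * runif(14, 0.7, 1.4)), specs$std_id)
  f_all <- fit_recovery(reads, specs)
  f_exc <- fit_recovery(reads, specs, exclude = "STD:07")
  expect_false("STD:07" %in% names(f_exc$per_standard_ratio))
  keep <- setdiff(specs$std_id, "STD:07")
  expect_equal(f_exc$reads_per_copy,
               sum(reads[keep]) / sum(specs$copies_added[specs$std_id %in% keep]))
  f_back <- fit_recovery(reads, specs)
  expect_identical(f_back, f_all)
})

test_that("zero-count standards drop from the regression but stay flaggable", {
  specs <- default_standards()
  reads <- stats::setNames(0.005 * specs$copies_added, specs$std_id)
  reads["STD:03"] <- 0
  expect_warning(fit <- fit_recovery(reads, specs), "STD:03")
  expect_equal(fit$n_regression, 13)
  expect_equal(unname(fit$per_standard_ratio["STD:03"]), 0)
  expect_true("STD:03" %in% flag_outlier_standards(fit))

  all_zero <- stats::setNames(rep(0, 14), specs$std_id)
  expect_error(suppressWarnings(fit_recovery(all_zero, specs)),
               "calibration failed")
  one_level <- standard_specs(c("a", "b"), c(500, 500), c(1e5, 1e5), "G1")
  expect_error(suppressWarnings(fit_recovery(c(a = 10, b = 12), one_level)),
               "degenerate")
})

test_that("outlier flagging: clean data empty, boundary deviation not flagged", {
  specs <- default_standards()
  clean <- stats::setNames(0.005 * specs$copies_added, specs$std_id)
  expect_identical(flag_outlier_standards(fit_recovery(clean, specs)),
                   character(0))

  # ratios (0.5, 1, 2) x k: geometric mean k, both extremes at exactly 2-fold
  sp3 <- standard_specs(c("a", "b", "c"), 500, c(1e4, 1e5, 1e6), "G1")
  fit3 <- fit_recovery(c(a = 0.5 * 1e2, b = 1e3, c = 2 * 1e4), sp3)
  expect_identical(flag_outlier_standards(fit3, threshold_fold = 2),
                   character(0))

  two <- standard_specs(c("a", "b"), 500, c(1e4, 1e5), "G1")
  expect_error(
    flag_outlier_standards(fit_recovery(c(a = 100, b = 1000), two)),
    "insufficient")
})

test_that("planted 20-fold corrupted standards are exactly the flagged set", {
  g <- make_genome(seed = 1)
  prof <- sample_expression(g, 720, seed = 1)
  std <- default_standards()
  planted <- c("STD:02" = 0.05, "STD:04" = 0.05, "STD:05" = 0.05)
  for (s in 1:6) {
    cfg <- library_sim_config(3e6, 3e9, seed = s, corrupted_standards = planted)
    ct <- simulate_library(prof, std, cfg)
    fit <- suppressWarnings(fit_recovery(standard_counts(ct)[, 1], std))
    expect_identical(flag_outlier_standards(fit), sort(names(planted)))
  }
})

test_that("pooled k is an unbiased estimator of reads per molecule", {
  g <- tiny_genome(n = 300, seed = 8)
  prof <- sample_expression(g, 1000, seed = 8)
  std <- default_standards()
  n_cells <- 1e9
  R <- 1e6
  w_total <- sum(prof$abundances) * n_cells + sum(std$copies_added)
  k_true <- R / w_total
  rel_err <- vapply(1:100, function(s) {
    ct <- simulate_library(prof, std, library_sim_config(R, n_cells, seed = s))
    fit <- suppressWarnings(fit_recovery(standard_counts(ct)[, 1], std))
    (fit$reads_per_copy - k_true) / k_true
  }, numeric(1))
  expect_lt(abs(mean(rel_err)), 0.01)
})
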