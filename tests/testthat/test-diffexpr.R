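test_that("one-way ANOVA matches hand computation and stats::aov", {
  res <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$F, 3)
  expect_equal(res$p, 0.125, tolerance = 1e-3)

  expect_equal(anova_oneway(list(c(2, 2), c(2, 2), c(2, 2))), list(F = 0, p = 1))

  set.seed(10)
  for (i in 1:5) {
    groups <- lapply(1:4, function(g) rnorm(3, mean = g / 2))
    mine <- anova_oneway(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(seq_along(groups), lengths(groups))))
    ref <- summary(stats::aov(y ~ g, data = df))[[1]]
    expect_equal(mine$F, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(mine$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
  expect_error(anova_oneway(list(1, c(1, 2))), "replicates")
})

test_that("ANOVA p agrees with a permutation-test oracle", {
  groups <- list(c(1.2, 2.1, 3.0, 2.2), c(2.4, 4.1, 3.8, 5.0), c(1.0, 1.4, 2.3, 0.8))
  obs <- anova_oneway(groups)
  y <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n_perm <- 20000
  set.seed(99)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    gp <- split(y[sample.int(length(y))], g)
    if (anova_oneway(gp)$F >= obs$F) exceed <- exceed + 1L
  }
  p_perm <- (exceed + 1) / (n_perm + 1)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(obs$p - p_perm), 4 * mc_sd + 0.005)
})

test_that("BH step-up: identities, hand example, and exact brute-force agreement", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:1000) {
    p <- runif(sample(2:25, 1))
    q <- bh_adjust(p)
    expect_identical(q, bh_brute(p))
    expect_true(all(q >= p))
  }
  # second independent oracle
  set.seed(8)
  p <- runif(200)
  expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"))
})

test_that("pairwise t tests match closed forms and pairwise.t.test", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(pairwise_t(same)["a", "b"], 1)

  two <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  p <- pairwise_t(two, pooled_sd = FALSE)["a", "b"]
  expect_equal(p, stats::t.test(two$a, two$b, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(p, 0.02131, tolerance = 1e-3) # t = -3.674, df = 4

  set.seed(11)
  groups <- lapply(1:4, function(g) rnorm(3, g / 3))
  names(groups) <- paste0("r", 1:4)
  mine <- pairwise_t(groups, pooled_sd = TRUE)
  ref <- stats::pairwise.t.test(
    unlist(groups), rep(names(groups), lengths(groups)),
    p.adjust.method = "none", pool.sd = TRUE)$p.value
  for (i in rownames(ref)) for (j in colnames(ref))
    if (!is.na(ref[i, j]))
      expect_equal(mine[i, j], ref[i, j], tolerance = 1e-10)
})

test_that("fold-change conventions reproduce the published marker arithmetic", {
  m <- nb0046_marker_abundances()
  ntrb <- m[m$locus == "NB46_00304", ]
  expect_equal(round(fold_change(ntrb$deplete, ntrb$replete)$ratio), 5)

  pii <- m[m$locus == "NB46_00250", ]
  expect_gt(fold_change(pii$deplete, pii$replete)$ratio, 1000)

  expect_equal(fold_change(3, 3)$ratio, 1)
  expect_true(is.na(fold_change(0, 0)$ratio))
  expect_warning(fc <- fold_change(1, 0), "denominator")
  expect_identical(fc$ratio, Inf)

  rho <- m[m$locus == "NB46_00176", ]
  means <- c(deplete = rho$deplete, replete = rho$replete,
             vitamin = rho$vitamin, dom = rho$dom)
  out <- fold_vs_others(means, "deplete")
  expect_equal(round(out$fold), 18)
  expect_identical(out$direction, "down")

  hyp <- m[m$locus == "NB46_00251", ]
  means2 <- c(deplete = hyp$deplete, replete = hyp$replete,
              vitamin = hyp$vitamin, dom = hyp$dom)
  out2 <- fold_vs_others(means2, "deplete")
  expect_equal(round(out2$fold, -2), 1900)
  expect_identical(out2$direction, "up")

  expect_equal(fold_vs_others(c(a = 2, b = 2, c = 2, d = 2), "a")$ratio, 1)
})

test_that("regulation calls: planted effect, rule conjunction, label symmetry", {
  g <- tiny_genome(n = 120, seed = 21)
  regimes <- c("deplete", "replete", "vitamin", "dom")
  base <- sample_expression(g, 720, seed = 21)$abundances
  means <- stats::setNames(rep(list(base), 4), regimes)
  means$deplete[1:4] <- means$deplete[1:4] * 20 # planted 20-fold up genes
  tab <- regime_table(means, cv = 0.10, seed = 3)

  de <- call_regulation(tab, regimes)
  planted <- de$calls[match(g$gene_ids[1:4], de$gene)]
  expect_true(all(planted == "+++, -nn, -nn, -nn"))

  # 3-fold difference that is not significant stays 'n'
  noisy <- matrix(c(1, 9, 2,   3, 12, 3,  2, 10, 2.5, 2.4, 11, 2.2),
                  nrow = 1) # wide within-group spread
  set.seed(55)
  ab <- matrix(rep(noisy, 30) + abs(rnorm(12 * 30, 0, 0.1)), ncol = 12,
               byrow = TRUE)
  dimnames(ab) <- list(sprintf("g%02d", 1:30),
                       sprintf("%s_rep%d", rep(regimes, each = 3), 1:3))
  tab2 <- wrap_table(ab, regimes)
  de2 <- call_regulation(tab2, regimes)
  high_p <- de2[de2$q >= 0.05, ]
  expect_true(all(high_p$calls == "nnn, nnn, nnn, nnn"))

  # swapping two regime labels swaps their + and - calls
  regimes_sw <- c("replete", "deplete", "vitamin", "dom")
  de_sw <- call_regulation(tab, regimes_sw)
  row <- de[de$gene == g$gene_ids[1], ]
  row_sw <- de_sw[de_sw$gene == g$gene_ids[1], ]
  expect_identical(row$calls, "+++, -nn, -nn, -nn")
  expect_identical(row_sw$calls, "-nn, +++, n-n, n-n")

  expect_error(call_regulation(tab, regimes[1:3]), "4 regime")
})

test_that("BH-gated calling controls the false discovery rate under the null", {
  g <- tiny_genome(n = 400, seed = 31)
  regimes <- c("deplete", "replete", "vitamin", "dom")
  base <- sample_expression(g, 720, seed = 31)$abundances
  means <- stats::setNames(rep(list(base), 4), regimes)
  frac <- vapply(1:5, function(s) {
    tab <- regime_table(means, cv = 0.10, seed = 100 + s)
    de <- call_regulation(tab, regimes)
    mean(de$q < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("similar-across-regimes flag keys on max pairwise log2 fold change", {
  regimes <- c("deplete", "replete", "vitamin", "dom")
  ab <- rbind(
    g_same = c(1.0, 1.0, 1.1, 1.1, 1.1, 1.0, 0.9, 0.9, 1.0, 1.05, 1.05, 1.0),
    g_diff = c(1, 1, 1,  4, 4, 4,  1, 1, 1,  1, 1, 1)
  )
  colnames(ab) <- sprintf("%s_rep%d", rep(regimes, each = 3), 1:3)
  tab <- wrap_table(ab, regimes)
  similar <- flag_similar_genes(tab, regimes)
  expect_true("g_same" %in% similar)
  expect_false("g_diff" %in% similar)
  details <- attr(similar, "details")
  expect_true(all(c("max_abs_log2fc", "anova_q") %in% names(details)))

  # planted growth markers with small spread are flagged in >= 95% of seeds
  g <- tiny_genome(n = 40, seed = 41)
  base <- sample_expression(g, 100, seed = 41)$abundances
  means <- stats::setNames(rep(list(base), 4), regimes)
  hit <- vapply(1:10, function(s) {
    tab_s <- regime_table(means, cv = 0.08, seed = 200 + s)
    mean(g$gene_ids %in% flag_similar_genes(tab_s, regimes))
  }, numeric(1))
  expect_gte(mean(hit), 0.95)
})
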