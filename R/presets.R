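#' Cultivation-regime presets
#'
#' Parameter bundles emulating the six batch-culture regimes of a
#' methanol-grown OM43-clade methylotroph: logistic growth with
#' exponential-phase rates in 0.06--0.09 h^-1, carrying capacities of
#' ~3e6 cells ml^-1 for methanol + inorganic nutrients, >1e7 with vitamins,
#' and ~5e5 for DOM-grown cultures in UV-oxidized medium, with a 50 uM
#' methanol amendment where methanol is the carbon source.
#'
#' @param regime one of `"I"` to `"VI"`.
#' @return list with `mu_max` (h^-1), `capacity` (cells ml^-1), `n0`,
#'   `c0_methanol` (uM), `regime_label`.
#' @export
regime_preset <- function(regime = c("I", "II", "III", "IV", "V", "VI")) {
  regime <- match.arg(regime)
  p <- switch(regime,
    I   = list(mu_max = 0.060, capacity = 3e6, c0_methanol = 50),
    II  = list(mu_max = 0.075, capacity = 3e6, c0_methanol = 50),
    III = list(mu_max = 0.090, capacity = 1.4e7, c0_methanol = 50),
    IV  = list(mu_max = 0.080, capacity = 1.4e7, c0_methanol = 50),
    V   = list(mu_max = 0.065, capacity = 5.4e5, c0_methanol = 0.67),
    VI  = list(mu_max = 0.070, capacity = 5.4e5, c0_methanol = 0.67)
  )
  c(p, list(n0 = 1e3, regime_label = paste0("regime ", regime)))
}

#' Total mRNA content presets by growth phase
#'
#' Transcripts per cell for a streamlined methylotroph by growth phase:
#' 1,859 (exponential), 720 (late-exponential), 387 (stationary) and 17
#' (deep stationary).
#'
#' @param phase growth-phase name.
#' @return total transcripts per cell (numeric).
#' @export
phase_total_preset <- function(phase = c("exponential", "late-exponential",
                                         "stationary", "deep-stationary")) {
  phase <- match.arg(phase)
  switch(phase,
         "exponential" = 1859,
         "late-exponential" = 720,
         "stationary" = 387,
         "deep-stationary" = 17)
}

#' Published per-1,000-cell abundances of selected NB0046 marker genes
#'
#' Mean transcript abundances (transcripts per 1,000 cells, triplicate
#' means) of marker genes of OM43 strain NB0046 across four late-exponential
#' nutrient regimes: methanol without nutrients (`deplete`), methanol plus
#' inorganic nutrients (`replete`), methanol plus nutrients and vitamins
#' (`vitamin`), and HMW DOM plus nutrients in UV-oxidized medium (`dom`).
#' Used for the package's fold-change worked examples.
#'
#' @return data frame: `gene`, `locus`, `deplete`, `replete`, `vitamin`,
#'   `dom`.
#' @examples
#' m <- nb0046_marker_abundances()
#' row <- m[m$locus == "NB46_00304", ]
#' fold_change(row$deplete, row$replete)$ratio # ~4.9-fold NtrB increase
#' @export
nb0046_marker_abundances <- function() {
  data.frame(
    gene = c("Conserved hypothetical protein", "Nitrogen regulatory protein PII",
             "Ammonium transporter (amtB-2)", "Nitrogen regulation protein NtrB",
             "Bacteriorhodopsin"),
    locus = c("NB46_00251", "NB46_00250", "NB46_00249", "NB46_00304", "NB46_00176"),
    deplete = c(17897, 3093, 4952, 869, 1455),
    replete = c(10, 3, 18, 177, 16208),
    vitamin = c(10, 3, 19, 184, 36814),
    dom = c(8, 3, 23, 173, 27421),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete four-regime late-exponential dataset
#'
#' Generates everything the downstream pipeline consumes: a genome, a set of
#' spiked internal standards (with the three low-copy standards corrupted
#' 20-fold by default, emulating badly recovered spike-ins), triplicate
#' late-exponential expression profiles for four regimes with planted
#' differential effects, multinomially sampled libraries, sample metadata,
#' and growth/methanol series for one regime.
#'
#' Planted truth: `n_up` genes share a common baseline across regimes and
#' are elevated `effect_fold`-fold in the first regime (a
#' nutrient-deplete-like response); the fourth regime's mean profile equals
#' the third's (DOM mimicking the vitamin response), while regimes 1 and 2
#' otherwise get independent mean profiles. Replicate noise is
#' multiplicative lognormal with CV `cv_rep` on each gene's abundance.
#'
#' @param seed integer seed for everything.
#' @param regimes four regime labels.
#' @param n_genes,mean_length genome size parameters.
#' @param total_per_cell late-exponential total mRNA (transcripts/cell).
#' @param library_size reads per sample.
#' @param cells_collected cells per filter.
#' @param n_up number of planted upregulated genes in regime 1.
#' @param effect_fold planted fold change.
#' @param cv_rep replicate coefficient of variation.
#' @param corrupt ids and biases for corrupted standards; `NULL` for none.
#' @return list with `genome`, `standards`, `counts` (a [count_table()]),
#'   `meta`, `profiles` (list of per-sample true abundance vectors),
#'   `truth` (planted effect description), `growth` and `methanol` series,
#'   and `settings`.
#' @export
simulate_dataset <- function(seed = 1,
                             regimes = c("deplete", "replete", "vitamin", "dom"),
                             n_genes = 1377, mean_length = 944,
                             total_per_cell = phase_total_preset("late-exponential"),
                             library_size = 1e6, cells_collected = 3e9,
                             n_up = 10, effect_fold = 20, cv_rep = 0.10,
                             corrupt = c("STD:02" = 0.05, "STD:04" = 0.05,
                                         "STD:05" = 0.05)) {
  stopifnot(length(regimes) == 4)
  seed <- as.integer(abs(seed) %% 10000L) # keep derived sub-seeds < 2^31
  genome <- make_genome(n_genes = n_genes, mean_length = mean_length, seed = seed)
  standards <- default_standards()

  # regime mean profiles: 1 and 2 independent; 4 copies 3 (DOM ~ vitamin)
  base_seeds <- seed * 1000L + 1:3
  means <- list(
    sample_expression(genome, total_per_cell, seed = base_seeds[1])$abundances,
    sample_expression(genome, total_per_cell, seed = base_seeds[2])$abundances,
    sample_expression(genome, total_per_cell, seed = base_seeds[3])$abundances
  )
  up_genes <- genome$gene_ids[seq_len(n_up)]
  # planted genes share a common baseline across regimes so the planted
  # fold change is the regime contrast, not a draw-to-draw difference
  means[[2]][up_genes] <- means[[1]][up_genes]
  means[[3]][up_genes] <- means[[1]][up_genes]
  means[[4]] <- means[[3]]
  means[[1]][up_genes] <- means[[1]][up_genes] * effect_fold

  sdlog <- sqrt(log(1 + cv_rep^2))
  tables <- list()
  profiles <- list()
  ids <- character()
  k <- 0L
  for (r in 1:4) for (rep_i in 1:3) {
    k <- k + 1L
    sid <- sprintf("%s_rep%d", regimes[r], rep_i)
    ids[k] <- sid
    ab <- with_seed(seed * 100000L + k, {
      means[[r]] * stats::rlnorm(length(means[[r]]), -sdlog^2 / 2, sdlog)
    })
    prof <- structure(list(abundances = ab, total_per_cell = sum(ab),
                           sigma_log10 = NA_real_), class = "expression_profile")
    profiles[[sid]] <- ab
    cfg <- library_sim_config(library_size, cells_collected,
                              seed = seed * 200000L + k,
                              corrupted_standards = corrupt %||% numeric())
    tables[[sid]] <- simulate_library(prof, standards, cfg, sample_id = sid)
  }
  counts <- bind_count_tables(tables)
  meta <- sample_meta(
    sample_id = ids,
    regime = rep(regimes, each = 3),
    timepoint = "late-exponential",
    replicate = rep(1:3, times = 4),
    cells_collected = cells_collected,
    library_size = library_size
  )
  pre <- regime_preset("II")
  growth <- simulate_growth(pre$mu_max, pre$capacity, pre$n0,
                            times = seq(0, 240, by = 12), cv_noise = 0.05,
                            regime_label = pre$regime_label, seed = seed + 7L)
  methanol <- simulate_drawdown(growth, carbon_budget_params(),
                                c0 = pre$c0_methanol)
  list(genome = genome, standards = standards, counts = counts, meta = meta,
       profiles = profiles,
       truth = list(up_genes = up_genes, up_regime = regimes[1],
                    effect_fold = effect_fold, dom_mimics = regimes[3],
                    regime_means = stats::setNames(means, regimes)),
       growth = growth, methanol = methanol,
       settings = list(seed = seed, regimes = regimes, n_genes = n_genes,
                       total_per_cell = total_per_cell,
                       library_size = library_size,
                       cells_collected = cells_collected, n_up = n_up,
                       effect_fold = effect_fold, cv_rep = cv_rep,
                       corrupted = as.list(corrupt %||% numeric())))
}

#' Write a simulated dataset to a directory
#'
#' Emits counts (TSV), standards config (YAML), metadata (TSV), growth and
#' methanol series (tidy TSV) and a JSON sidecar echoing every generator
#' setting for provenance.
#'
#' @param ds a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    standards = file.path(dir, "standards.yml"),
    meta = file.path(dir, "metadata.tsv"),
    growth = file.path(dir, "growth.tsv"),
    methanol = file.path(dir, "methanol.tsv"),
    settings = file.path(dir, "settings.json")
  )
  write_count_table(ds$counts, paths["counts"])
  write_standards_config(ds$standards, paths["standards"])
  write_meta_tsv(ds$meta, paths["meta"])
  write_growth_tsv(ds$growth, paths["growth"])
  write_methanol_tsv(ds$methanol, paths["methanol"])
  jsonlite::write_json(ds$settings, paths["settings"], auto_unbox = TRUE, digits = NA)
  paths
}
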