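#' Pipeline configuration
#'
#' Collects the file paths and thresholds the end-to-end driver needs.
#' `read_pipeline_config()` loads the same structure from YAML/JSON; paths
#' in the file are resolved relative to the config's directory.
#'
#' @param counts path to the count-table TSV (genes + standards).
#' @param standards path to the standards config (YAML/JSON).
#' @param metadata path to the sample-metadata TSV.
#' @param growth,methanol optional series TSVs.
#' @param out_dir output directory.
#' @param mode calibration/conversion mode.
#' @param regimes regime labels (reporting order) for differential calls;
#'   `NULL` skips the stats stage.
#' @param alpha,min_fold,outlier_fold decision thresholds.
#' @param deep_stationary_after hours before stationary becomes deep.
#' @param seed integer seed recorded in the run log.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(counts, standards, metadata, out_dir,
                            growth = NULL, methanol = NULL,
                            mode = c("per-copy", "length-weighted"),
                            regimes = NULL, alpha = 0.05, min_fold = 2,
                            outlier_fold = 2, deep_stationary_after = 100,
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, min_fold >= 1, outlier_fold >= 1)
  structure(
    list(counts = counts, standards = standards, metadata = metadata,
         growth = growth, methanol = methanol, out_dir = out_dir, mode = mode,
         regimes = regimes, alpha = alpha, min_fold = min_fold,
         outlier_fold = outlier_fold,
         deep_stationary_after = deep_stationary_after, seed = seed),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML or JSON config file.
#' @export
read_pipeline_config <- function(path) {
  cfg <- read_config_file(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  pipeline_config(
    counts = resolve(cfg$counts), standards = resolve(cfg$standards),
    metadata = resolve(cfg$metadata), out_dir = cfg$out_dir %||% "txcell_out",
    growth = resolve(cfg$growth), methanol = resolve(cfg$methanol),
    mode = cfg$mode %||% "per-copy",
    regimes = if (is.null(cfg$regimes)) NULL else unlist(cfg$regimes),
    alpha = cfg$alpha %||% 0.05, min_fold = cfg$min_fold %||% 2,
    outlier_fold = cfg$outlier_fold %||% 2,
    deep_stationary_after = cfg$deep_stationary_after %||% 100,
    seed = cfg$seed %||% 1L
  )
}

#' Run the full calibrate -> quantify -> stats pipeline
#'
#' Stages: (1) read inputs; (2) per-sample recovery fits, outlier flagging
#' and exclusion, pooled conversion factor; (3) transcripts per cell and
#' per-1,000-cells tables with distribution summaries; (4) growth-phase and
#' methanol-budget report when series are provided; (5) differential calls
#' and sample clustering when `regimes` is set. All artifacts are written
#' under `config$out_dir` together with a MANIFEST listing completed stages
#' and a run log recording seed and thresholds. Stage errors are propagated
#' with the stage name; already-written artifacts are kept and the MANIFEST
#' marks the run incomplete.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory results of each stage and
#'   `manifest` of written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  note <- function(path) manifest <<- c(manifest, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(manifest, sprintf("INCOMPLETE at stage: %s", name)),
                 file.path(out, "MANIFEST"))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  res <- list()
  stage("read", {
    res$standards <- load_standards(config$standards)
    res$counts <- read_count_table(config$counts, standards = res$standards)
    res$meta <- read_meta_tsv(config$metadata)
  })

  stage("calibrate", {
    std <- standard_counts(res$counts)
    fits <- lapply(colnames(std), function(s) {
      f0 <- suppressWarnings(
        fit_recovery(std[, s], res$standards, mode = config$mode))
      flagged <- flag_outlier_standards(f0, threshold_fold = config$outlier_fold)
      if (length(flagged))
        suppressWarnings(fit_recovery(std[, s], res$standards,
                                      exclude = flagged, mode = config$mode))
      else f0
    })
    names(fits) <- colnames(std)
    res$fits <- fits
    for (s in names(fits)) {
      p <- file.path(out, sprintf("calibration_%s.json", s))
      write_calibration_json(fits[[s]], p)
      note(p)
    }
  })

  stage("quantify", {
    gc <- gene_counts(res$counts)
    copies <- vapply(colnames(gc), function(s)
      transcripts_per_sample(gc[, s, drop = FALSE], res$fits[[s]])[, 1],
      numeric(nrow(gc)))
    rownames(copies) <- rownames(gc)
    res$table <- per_cell(copies, res$meta)
    p1 <- file.path(out, "abundance_per_cell.tsv")
    p2 <- file.path(out, "abundance_per_1000_cells.tsv")
    write_abundance_tsv(res$table, p1)
    write_abundance_tsv(res$table, p2, per_1000 = TRUE)
    note(p1); note(p2)
    res$summary <- distribution_summary(res$table)
    res$totals <- total_mrna(res$table)
    p3 <- file.path(out, "sample_summary.json")
    jsonlite::write_json(
      list(distribution = res$summary, totals = res$totals$summary),
      p3, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    note(p3)
  })

  if (!is.null(config$growth)) stage("growth_budget", {
    curve <- read_growth_tsv(config$growth)
    phases <- classify_phase(curve, config$deep_stationary_after)
    rates <- c(NA_real_, diff(log(rowMeans(curve$densities))) / diff(curve$times))
    budget <- NULL
    if (!is.null(config$methanol)) {
      meoh <- read_methanol_tsv(config$methanol)
      drawdown <- meoh$concentrations[1] -
        meoh$concentrations[length(meoh$concentrations)]
      budget <- list(
        drawdown_uM = drawdown,
        theoretical_yield = theoretical_yield(drawdown),
        observed_yield = max(rowMeans(curve$densities)) -
          rowMeans(curve$densities)[1]
      )
    }
    p <- file.path(out, "growth_budget.json")
    jsonlite::write_json(
      list(times = curve$times, mu = rates, phase = phases, budget = budget),
      p, auto_unbox = TRUE, digits = NA)
    note(p)
    res$growth <- list(curve = curve, phases = phases, budget = budget)
  })

  if (!is.null(config$regimes)) stage("stats", {
    res$diffexpr <- call_regulation(res$table, config$regimes,
                                    alpha = config$alpha,
                                    min_fold = config$min_fold)
    p <- file.path(out, "diffexpr.tsv")
    utils::write.table(as.data.frame(res$diffexpr), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note(p)
    res$tree <- cluster_samples(res$table)
    p2 <- file.path(out, "clustering.nwk")
    write_newick(res$tree, p2)
    note(p2)
  })

  stage("report", {
    log_path <- file.path(out, "run_log.json")
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("txcell")),
           r_version = R.version.string,
           seed = config$seed, mode = config$mode,
           thresholds = list(alpha = config$alpha, min_fold = config$min_fold,
                             outlier_fold = config$outlier_fold,
                             deep_stationary_after = config$deep_stationary_after)),
      log_path, auto_unbox = TRUE, digits = NA)
    note(log_path)
    writeLines(c(manifest, "COMPLETE"), file.path(out, "MANIFEST"))
  })

  res$manifest <- manifest
  invisible(res)
}
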