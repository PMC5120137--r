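#' Internal RNA standard specifications
#'
#' An internal RNA standard is an in-vitro-transcribed RNA of known sequence,
#' length and copy number spiked into each sample before extraction; its
#' recovery in the sequenced library calibrates reads to absolute molecule
#' counts. `standard_specs()` validates a set of specifications;
#' `default_standards()` returns the package's reference design: 14
#' standards assembled into 4 groups whose per-sample copy numbers are
#' log-spaced over 4 orders of magnitude (1e8 to 1e12 molecules).
#'
#' @param std_id unique standard identifiers.
#' @param length standard lengths, nt (> 0).
#' @param copies_added molecules added per sample (> 0).
#' @param group group (pool) label.
#' @return A `standard_spec` data frame with columns `std_id`, `length`,
#'   `copies_added`, `group`.
#' @export
standard_specs <- function(std_id, length, copies_added, group) {
  std_id <- as.character(std_id)
  if (anyDuplicated(std_id)) stop("standard ids must be unique", call. = FALSE)
  if (length(std_id) == 0) stop("empty standard set", call. = FALSE)
  if (any(!is.finite(length)) || any(length <= 0))
    stop("standard lengths must be positive", call. = FALSE)
  if (any(!is.finite(copies_added)) || any(copies_added <= 0))
    stop("copies_added must be positive", call. = FALSE)
  structure(
    data.frame(std_id = std_id, length = as.numeric(length),
               copies_added = as.numeric(copies_added),
               group = as.character(group), stringsAsFactors = FALSE),
    class = c("standard_spec", "data.frame")
  )
}

#' @rdname standard_specs
#' @export
default_standards <- function() {
  n <- 14L
  standard_specs(
    std_id = sprintf("STD:%02d", seq_len(n)),
    length = round(seq(500, 1500, length.out = n)),
    copies_added = 10^seq(8, 12, length.out = n),
    group = rep(c("G1", "G2", "G3", "G4"), times = c(4L, 4L, 3L, 3L))
  )
}

#' Load standard specifications from a config file (plus optional FASTA)
#'
#' The config (YAML or JSON, chosen by extension) must contain a list
#' `standards` of records with fields `id`, `copies_added`, `group` and
#' optionally `length`. If `fasta_path` is given, sequence lengths are taken
#' from the FASTA records (matched by id) and override config lengths, with
#' a message when they disagree.
#'
#' @param config_path path to a YAML (`.yml`/`.yaml`) or JSON config.
#' @param fasta_path optional FASTA file of standard sequences.
#' @return A `standard_spec` data frame.
#' @examples
#' cfg <- system.file("extdata", "standards_demo.yml", package = "txcell")
#' load_standards(cfg)
#' @export
load_standards <- function(config_path, fasta_path = NULL) {
  cfg <- read_config_file(config_path)
  recs <- cfg$standards %||% cfg
  if (length(recs) == 0) stop("standards config is empty", call. = FALSE)
  get_field <- function(rec, field) rec[[field]] %||% NA
  ids <- vapply(recs, function(r) as.character(get_field(r, "id")), character(1))
  copies <- vapply(recs, function(r) {
    v <- get_field(r, "copies_added")
    if (is.null(v) || length(v) == 0 || is.na(suppressWarnings(as.numeric(v)))) NA_real_
    else as.numeric(v)
  }, numeric(1))
  if (anyNA(copies)) {
    stop(sprintf("standard(s) missing copies_added: %s",
                 paste(ids[is.na(copies)], collapse = ", ")), call. = FALSE)
  }
  groups <- vapply(recs, function(r) as.character(get_field(r, "group")), character(1))
  lens <- vapply(recs, function(r) {
    v <- r[["length"]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (!is.null(fasta_path)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA standard sequences requires the Biostrings package",
           call. = FALSE)
    fa <- Biostrings::fasta.seqlengths(fasta_path)
    names(fa) <- sub("\\s.*$", "", names(fa))
    hit <- match(ids, names(fa))
    mismatch <- !is.na(hit) & !is.na(lens) & lens != fa[hit]
    if (any(mismatch)) {
      message(sprintf("FASTA lengths override config for: %s",
                      paste(ids[mismatch], collapse = ", ")))
    }
    lens[!is.na(hit)] <- fa[hit[!is.na(hit)]]
  }
  if (anyNA(lens)) {
    stop(sprintf("standard(s) missing length (no config value, no FASTA record): %s",
                 paste(ids[is.na(lens)], collapse = ", ")), call. = FALSE)
  }
  standard_specs(ids, lens, copies, groups)
}

#' Write standard specifications as a YAML config
#'
#' @param specs a `standard_spec` data frame.
#' @param path output path (`.yml`/`.yaml` or `.json`).
#' @export
write_standards_config <- function(specs, path) {
  stopifnot(inherits(specs, "standard_spec"))
  recs <- lapply(seq_len(nrow(specs)), function(i) {
    list(id = specs$std_id[i], length = specs$length[i],
         copies_added = specs$copies_added[i], group = specs$group[i])
  })
  obj <- list(standards = recs)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}
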