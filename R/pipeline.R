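# Pipeline stages ------------------------------------------------------------
#
# Thin orchestration over the package's functions, used by the numbered
# scripts under analysis/: simulate a cohort, evaluate panels, run the
# cost-effectiveness stage (or replay it from the shipped published ladder),
# with a flat key-value config and per-run manifests for provenance.

#' Pipeline configuration
#'
#' @param seed Master seed; every random stage derives its own seed from it.
#' @param models Models to evaluate.
#' @param k Outer cross-validation folds.
#' @param w_grid C-score weight grid.
#' @param personas Named persona weights for [recommend()].
#' @param prices A [price_table()].
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, models = "stacking", k = 3,
                            w_grid = default_w_grid(),
                            personas = c(budget = 0.5, balanced = 0.95,
                                         accuracy_first = 0.99),
                            prices = price_table(), out_dir = "results") {
  stopifnot(is.numeric(seed), seed >= 0, all(models %in% MODEL_NAMES))
  structure(list(seed = as.integer(seed), models = models, k = k,
                 w_grid = w_grid, personas = personas, prices = prices,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a flat key-value config file
#'
#' One `key = value` pair per line; vectors comma-separated, persona and
#' price entries name-prefixed.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  lines <- c(
    paste("seed =", config$seed),
    paste("models =", paste(config$models, collapse = ",")),
    paste("k =", config$k),
    paste("w_grid =", paste(format(config$w_grid, trim = TRUE), collapse = ",")),
    paste("personas =", paste(sprintf("%s:%g", names(config$personas),
                                      config$personas), collapse = ",")),
    paste("price_cea =", unname(config$prices["CEA"])),
    paste("price_ca =", unname(config$prices["CA125"])),
    paste("out_dir =", config$out_dir))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  kv <- read_key_values(path)
  personas <- strsplit(kv$personas, ",")[[1]]
  pv <- as.numeric(sub(".*:", "", personas))
  names(pv) <- sub(":.*", "", personas)
  pipeline_config(
    seed = as.integer(kv$seed),
    models = strsplit(kv$models, ",")[[1]],
    k = as.integer(kv$k),
    w_grid = as.numeric(strsplit(kv$w_grid, ",")[[1]]),
    personas = pv,
    prices = price_table(cea = as.numeric(kv$price_cea),
                         ca = as.numeric(kv$price_ca)),
    out_dir = kv$out_dir)
}

read_key_values <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  keys <- trimws(sub("=.*", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(as.list(vals), keys)
}

write_manifest <- function(path, fields) {
  writeLines(sprintf("%s = %s", names(fields),
                     vapply(fields, as.character, character(1))), path)
  invisible(path)
}

#' Simulation stage: write a cohort CSV and its manifest
#'
#' @param config A [pipeline_config()].
#' @param spec Cohort spec (default [default_cohort_spec()]).
#' @param path Output CSV path (default `<out_dir>/cohort.csv`).
#' @return The cohort data frame, invisibly; writes `path` and
#'   `<path>.manifest`.
#' @export
run_simulate <- function(config, spec = default_cohort_spec(),
                         path = file.path(config$out_dir, "cohort.csv")) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(spec, seed = config$seed)
  write_cohort_csv(cohort, path)
  write_manifest(paste0(path, ".manifest"), list(
    stage = "simulate", seed = config$seed,
    n_mpe = spec$mpe$n, n_bpe = spec$bpe$n,
    cohort_md5 = unname(tools::md5sum(path)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  invisible(cohort)
}

#' Evaluation stage: performance records for every panel
#'
#' Evaluates all 255 panels under the configured models with resumable
#' incremental output (`panel,model,auc,sensitivity,specificity,threshold,k,seed`
#' plus a cost column added at read time).
#'
#' @param config A [pipeline_config()].
#' @param cohort Cohort data frame or path to a cohort CSV.
#' @param path Output records CSV.
#' @param quiet Suppress progress messages.
#' @return Records data frame, invisibly.
#' @export
run_evaluate <- function(config, cohort,
                         path = file.path(config$out_dir, "records.csv"),
                         quiet = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  records <- evaluate_panels(cohort, models = config$models, k = config$k,
                             seed = config$seed, out_csv = path,
                             quiet = quiet)
  write_manifest(paste0(path, ".manifest"), list(
    stage = "evaluate", seed = config$seed,
    models = paste(config$models, collapse = ","), k = config$k,
    n_records = nrow(records),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  invisible(records)
}

#' Cost-effectiveness stage
#'
#' Builds the best-per-cost ladder (or replays the shipped published
#' ladder), runs the C-score sweep, the quadrant segmentation, the anchor
#' flags and the persona recommendations, and writes them all under the
#' config's output directory.
#'
#' @param config A [pipeline_config()].
#' @param records Performance records data frame or CSV path; ignored in
#'   replay mode.
#' @param replay If `TRUE`, use the shipped published ladder
#'   ([load_table2()]) — deterministic, touches no model code.
#' @param anchor Anchor marker for outlier flagging.
#' @return List with `ladder`, `sweep`, `extremes`, `quadrants`, `flags`,
#'   `recommendations`, invisibly; all written as CSV/text files.
#' @export
run_ce <- function(config, records = NULL, replay = is.null(records),
                   anchor = "PE.CEA") {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (replay) {
    ladder <- load_table2()
  } else {
    if (is.character(records)) {
      records <- utils::read.csv(records, stringsAsFactors = FALSE)
    }
    model <- if ("stacking" %in% records$model) "stacking" else records$model[1]
    ladder <- build_ladder(records[records$model == model, ],
                           prices = config$prices,
                           panels = enumerate_panels())
  }
  sweep <- sweep_w(ladder, config$w_grid)
  extremes <- sweep_extremes(sweep)
  quadrants <- quadrant_segmentation(ladder)
  flags <- flag_missing_anchor(ladder, anchor)
  recs <- recommend(sweep, config$personas)

  utils::write.csv(ladder, file.path(config$out_dir, "ladder.csv"),
                   row.names = FALSE)
  write_sweep_csv(sweep, file.path(config$out_dir, "sweep.csv"))
  utils::write.csv(quadrants, file.path(config$out_dir, "quadrants.csv"),
                   row.names = FALSE)
  utils::write.csv(extremes, file.path(config$out_dir, "sweep_extremes.csv"),
                   row.names = FALSE)
  write_manifest(file.path(config$out_dir, "recommendations.txt"),
                 stats::setNames(
                   as.list(sprintf("%s (cost %g, AUC %.3f, C-score %.3f at w=%g)",
                                   recs$rung, recs$cost, recs$auc,
                                   round_half_away(recs$c_score, 3), recs$w)),
                   recs$persona))
  write_manifest(file.path(config$out_dir, "ce.manifest"), list(
    stage = "ce", replay = replay, anchor = anchor,
    median_cost = attr(quadrants, "median_cost"),
    median_auc = attr(quadrants, "median_auc"),
    anchor_flags = paste(flags, collapse = ","),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  invisible(list(ladder = ladder, sweep = sweep, extremes = extremes,
                 quadrants = quadrants, flags = flags,
                 recommendations = recs))
}
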