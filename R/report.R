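#' Write a benchmarking report as TSV and JSON
#'
#' Long-format report: one row per caller x tau x bin combination, with
#' the columns `caller, tau, bin, n_tp, n_fp, n_fn, sensitivity,
#' precision, fscore`. The same rows are written to both formats; the
#' JSON is an array of row objects that re-parses to the TSV content.
#'
#' @param rows A metrics `data.frame` (rows from [compute_metrics()],
#'   [threshold_sweep()] and/or [stratified_metrics()]).
#' @param out_tsv,out_json Output paths; either may be `NULL` to skip.
#' @return The rows, sorted as written, invisibly.
#' @export
render_report <- function(rows, out_tsv = NULL, out_json = NULL) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1)
  cols <- c("caller", "tau", "bin", "n_tp", "n_fp", "n_fn",
            "sensitivity", "precision", "fscore")
  rows <- rows[, cols]
  rows$bin[is.na(rows$bin)] <- -1L   # -1 = unstratified ("all lengths")
  rows <- rows[order(rows$caller, rows$tau, rows$bin, method = "radix"), ]
  rownames(rows) <- NULL
  if (!is.null(out_tsv))
    write.table(rows, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out_json))
    jsonlite::write_json(rows, out_json, dataframe = "rows", digits = NA,
                         na = "null")
  invisible(rows)
}

read_callsets_cfg <- function(calls, bed = NULL, min_len = 50) {
  regions <- if (!is.null(bed)) read_region_bed(bed)
  out <- lapply(names(calls), function(nm) {
    cs <- filter_min_length(parse_vcf(calls[[nm]], caller_id = nm), min_len)
    if (!is.null(regions)) cs <- filter_regions(cs, regions)
    cs
  })
  names(out) <- names(calls)
  out
}

cfg_get <- function(config, key, default = NULL) {
  if (is.null(config[[key]])) default else config[[key]]
}

cfg_require <- function(config, keys, mode) {
  miss <- keys[vapply(keys, function(k) is.null(config[[k]]), logical(1))]
  if (length(miss))
    stop("config for mode '", mode, "' is missing: ",
         paste(miss, collapse = ", "))
}

#' Run a configured pipeline stage
#'
#' Config-driven driver tying the stages together. The config (a YAML
#' file or an equivalent named list) names a `mode` --
#' `simulate`, `train`, `merge`, `evaluate`, `downsample` or `run`
#' (simulate, then train, merge and evaluate on the simulated data) --
#' plus the stage's inputs. A run log with the package version, seed
#' and a config digest goes to stderr; machine-readable outputs go only
#' to the configured paths, and nothing is written until the inputs
#' have been validated.
#'
#' Config keys by mode (paths relative to the working directory):
#' \itemize{
#'   \item simulate: `out_dir`, `n_per_bin`, `callers` (list of
#'     `name`, `sensitivity`, `fp_rate`, `jitter_sd`), optional
#'     `genome` (name: length map), `bin_edges`, `svtype`, `seed`.
#'   \item train: `calls` (name: path map), `truth`, optional `bed`,
#'     `organism`, `coverage`, `tau`, `bin_edges`, `metric`; `out`.
#'   \item merge: `profile`, `calls`, optional `merge_mode`,
#'     `min_support`, `dedupe_tau`; `out`.
#'   \item evaluate: `calls`, `truth`, optional `bed`, `taus`,
#'     `bin_edges`; `out_tsv`, optional `out_json`.
#'   \item downsample: `input`, `output`, `fraction` (or
#'     `current_coverage` + `target_coverage`), `seed`.
#' }
#'
#' @param config Path to a YAML config file, or a named list.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  mode <- config$mode
  if (is.null(mode) ||
      !mode %in% c("simulate", "train", "merge", "evaluate", "downsample",
                   "run"))
    stop("config must name a mode: simulate, train, merge, evaluate, ",
         "downsample or run")
  digest <- sprintf("%013.0f",
                    hash_unit(paste(deparse(config), collapse = ""), 0) * 2^45)
  message(sprintf("svconsensus %s | mode %s | seed %s | config %s",
                  as.character(packageVersion("svconsensus")), mode,
                  format(cfg_get(config, "seed", "-")), digest))
  switch(mode,
         simulate = pipeline_simulate(config),
         train = pipeline_train(config),
         merge = pipeline_merge(config),
         evaluate = pipeline_evaluate(config),
         downsample = pipeline_downsample(config),
         run = pipeline_run(config))
}

pipeline_bins <- function(config)
  length_bins(cfg_get(config, "bin_edges", c(50, 100, 500, 1000)))

pipeline_genome <- function(config) {
  g <- cfg_get(config, "genome")
  if (is.null(g)) genome_model() else genome_model(unlist(g))
}

pipeline_simulate <- function(config) {
  cfg_require(config, c("out_dir", "n_per_bin", "callers"), "simulate")
  bins <- pipeline_bins(config)
  genome <- pipeline_genome(config)
  seed <- cfg_get(config, "seed", 1L)
  svtype <- cfg_get(config, "svtype", "DEL")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(genome, config$n_per_bin, bins, svtype, seed)
  paths <- list(truth = file.path(config$out_dir, "truth.vcf"))
  write_vcf(truth, paths$truth)
  for (i in seq_along(config$callers)) {
    cal <- config$callers[[i]]
    model <- error_model(unlist(cal$sensitivity),
                         fp_rate = cfg_get(cal, "fp_rate", 0),
                         jitter_sd = cfg_get(cal, "jitter_sd", 0),
                         bins = bins, seed = seed + i)
    cs <- corrupt(truth, model, genome, caller_id = cal$name)
    paths[[cal$name]] <- file.path(config$out_dir,
                                   paste0(cal$name, ".vcf"))
    write_vcf(cs, paths[[cal$name]])
  }
  invisible(paths)
}

pipeline_train <- function(config) {
  cfg_require(config, c("calls", "truth", "out"), "train")
  bins <- pipeline_bins(config)
  callsets <- read_callsets_cfg(config$calls, cfg_get(config, "bed"))
  truth <- filter_min_length(parse_vcf(config$truth, caller_id = "truth"))
  if (!is.null(config$bed))
    truth <- filter_regions(truth, read_region_bed(config$bed))
  truth$organism <- cfg_get(config, "organism", NA_character_)
  truth$coverage <- cfg_get(config, "coverage", NA_real_)
  prof <- train_profile(callsets, truth, bins = bins,
                        tau = cfg_get(config, "tau", 100),
                        metric = cfg_get(config, "metric", "fscore"),
                        dataset = cfg_get(config, "dataset", config$truth))
  save_profile(prof, config$out)
  invisible(list(profile = config$out))
}

pipeline_merge <- function(config) {
  cfg_require(config, c("profile", "calls", "out"), "merge")
  prof <- load_profile(config$profile)
  callsets <- read_callsets_cfg(config$calls, cfg_get(config, "bed"))
  cfg <- merge_config(mode = cfg_get(config, "merge_mode", "standard"),
                      dedupe_tau = cfg_get(config, "dedupe_tau", 100),
                      min_support = cfg_get(config, "min_support", 2))
  write_vcf(merge_by_profile(prof, callsets, cfg), config$out)
  invisible(list(consensus = config$out))
}

pipeline_evaluate <- function(config) {
  cfg_require(config, c("calls", "truth", "out_tsv"), "evaluate")
  bins <- pipeline_bins(config)
  taus <- cfg_get(config, "taus", DEFAULT_TAUS)
  callsets <- read_callsets_cfg(config$calls, cfg_get(config, "bed"))
  truth <- filter_min_length(parse_vcf(config$truth, caller_id = "truth"))
  if (!is.null(config$bed))
    truth <- filter_regions(truth, read_region_bed(config$bed))
  rows <- do.call(rbind, lapply(callsets, function(cs) {
    rbind(threshold_sweep(cs, truth, taus),
          do.call(rbind, lapply(taus, function(tau)
            stratified_metrics(cs, truth, tau, bins))))
  }))
  render_report(rows, out_tsv = config$out_tsv,
                out_json = cfg_get(config, "out_json"))
  invisible(list(tsv = config$out_tsv, json = cfg_get(config, "out_json")))
}

pipeline_downsample <- function(config) {
  cfg_require(config, c("input", "output"), "downsample")
  frac <- cfg_get(config, "fraction")
  if (is.null(frac)) {
    cfg_require(config, c("current_coverage", "target_coverage"),
                "downsample")
    frac <- fraction_for_target(config$current_coverage,
                                config$target_coverage)
  }
  downsample_pairs(config$input, config$output, frac,
                   seed = cfg_get(config, "seed", 1L))
  invisible(list(alignment = config$output))
}

pipeline_run <- function(config) {
  cfg_require(config, c("out_dir", "n_per_bin", "callers"), "run")
  out <- config$out_dir
  sim <- pipeline_simulate(config)
  call_paths <- sim[setdiff(names(sim), "truth")]
  train_cfg <- c(config, list(calls = call_paths, truth = sim$truth,
                              out = file.path(out, "profile.yaml")))
  pipeline_train(train_cfg)
  merge_cfg <- list(profile = file.path(out, "profile.yaml"),
                    calls = call_paths,
                    merge_mode = cfg_get(config, "merge_mode", "standard"),
                    out = file.path(out, "consensus.vcf"))
  pipeline_merge(merge_cfg)
  eval_calls <- c(call_paths,
                  list(consensus = file.path(out, "consensus.vcf")))
  eval_cfg <- list(calls = eval_calls, truth = sim$truth,
                   taus = cfg_get(config, "taus", DEFAULT_TAUS),
                   bin_edges = cfg_get(config, "bin_edges",
                                       c(50, 100, 500, 1000)),
                   out_tsv = file.path(out, "metrics.tsv"),
                   out_json = file.path(out, "metrics.json"))
  pipeline_evaluate(eval_cfg)
  invisible(list(truth = sim$truth, calls = call_paths,
                 profile = file.path(out, "profile.yaml"),
                 consensus = file.path(out, "consensus.vcf"),
                 tsv = file.path(out, "metrics.tsv"),
                 json = file.path(out, "metrics.json")))
}
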