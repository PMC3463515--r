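# End-to-end orchestration: configuration (YAML), the `call` pipeline
# (quantification -> calibration -> hit calling -> length analysis -> report
# tree) and the simulate/evaluate harness. The command-line wrapper in
# inst/cli/ciliascreen.R is a thin shell over these functions.

#' Pipeline configuration
#'
#' All tunables of the calling pipeline with their defaults: threshold
#' multiplier `k_sd = 4`, knockdown cutoff 0.60 (fraction of transcript
#' remaining), minimum 150 cells per condition (QC warning below),
#' significance level 0.05 for length tests. Round-trips losslessly through
#' YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param counts,layout,qpcr,lengths input table paths (`qpcr`/`lengths`
#'   optional)
#' @param out_dir output directory for the results tree
#' @param anchor_reagent positive-control anchor reagent id
#' @param k_sd,knockdown_cutoff,min_cells,alpha numeric tunables
#' @param length_control reagent id of the control length sample (`NULL`:
#'   first scrambled control with lengths)
#' @param seed integer seed (used by simulation subcommands)
#' @return `pipeline_config` list
#' @export
pipeline_config <- function(counts = NULL, layout = NULL, qpcr = NULL,
                            lengths = NULL, out_dir = "results",
                            anchor_reagent = "siPCM1-1", k_sd = 4,
                            knockdown_cutoff = 0.60, min_cells = 150,
                            alpha = 0.05, length_control = NULL, seed = 1L) {
  stopifnot(k_sd > 0, knockdown_cutoff > 0, knockdown_cutoff <= 1,
            min_cells >= 1, alpha > 0, alpha < 1)
  structure(list(counts = counts, layout = layout, qpcr = qpcr,
                 lengths = lengths, out_dir = out_dir,
                 anchor_reagent = anchor_reagent, k_sd = k_sd,
                 knockdown_cutoff = knockdown_cutoff,
                 min_cells = as.integer(min_cells), alpha = alpha,
                 length_control = length_control, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}

#' Run the full calling pipeline
#'
#' Reads the screen, computes normalized effects and knockdown, calibrates
#' thresholds, applies the two-round automaton, runs length comparisons when
#' a lengths table is present, and writes the results tree (results.json,
#' summary.tsv, tallies.tsv, lengths_report.tsv, qc_log.txt) under
#' `config$out_dir`. Every excluded experiment, QC warning and threshold
#' fallback appears in the QC log. All thresholds are reported in the output
#' even when defaulted.
#'
#' @param config a `pipeline_config` or path to its YAML file
#' @return invisibly, a list with `calls` (a `screen_calls`) and
#'   `lengths_report` (or `NULL`)
#' @export
run_call <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$counts) || is.null(config$layout))
    stop("config must name counts and layout files", call. = FALSE)
  screen <- read_screen(config$counts, config$layout, qpcr = config$qpcr,
                        lengths = config$lengths, min_cells = config$min_cells)
  cc <- screen_call_config(anchor_reagent = config$anchor_reagent,
                           k_sd = config$k_sd,
                           knockdown_cutoff = config$knockdown_cutoff)
  calls <- call_screen(screen, cc)
  lr <- NULL
  if (!is.null(screen$lengths) && nrow(screen$lengths) > 0L)
    lr <- lengths_report(screen, control_reagent = config$length_control,
                         alpha = config$alpha)
  write_results(calls, config$out_dir, lengths_report = lr)
  invisible(list(calls = calls, lengths_report = lr))
}

#' Simulate replicate screens and report operating characteristics
#'
#' Thin orchestration of [simulate_screen()] and [evaluate_design()]:
#' writes `operating_characteristics.tsv` (per-class hit rates with binomial
#' SEs) and `effect_recovery.tsv` (bias/RMSE) under `out_dir`. Reruns with
#' the same seed produce identical reports.
#'
#' @param sim_config a [simulation_config()]
#' @param n_replicate_screens replicate screens to simulate
#' @param call_config pipeline parameters for the simulated screens
#' @param out_dir output directory
#' @return invisibly, the `design_eval` object
#' @export
run_simulate_and_evaluate <- function(sim_config = simulation_config(),
                                      n_replicate_screens = 50,
                                      call_config = screen_call_config(),
                                      out_dir = "sim_results") {
  ev <- evaluate_design(sim_config, n_replicate_screens, call_config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(ev$by_class, file.path(out_dir, "operating_characteristics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(ev$effect_recovery, file.path(out_dir, "effect_recovery.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(ev)
}
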