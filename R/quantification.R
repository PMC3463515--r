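# Percent-ciliation quantification, per-experiment normalization to the
# scrambled control, cross-experiment aggregation, and qRT-PCR knockdown
# quantification.

#' Percent ciliation of a condition
#'
#' Fraction of DAPI-identified cells bearing an acetylated-tubulin-positive
#' primary cilium: `ciliated_count / total_count`. Vectorized.
#'
#' @param ciliated_count,total_count non-negative integer vectors
#' @return numeric vector of fractions in \[0, 1\]
#' @export
percent_ciliation <- function(ciliated_count, total_count) {
  if (any(total_count <= 0, na.rm = TRUE) || any(is.na(total_count)))
    stop("percent_ciliation undefined for total_count <= 0", call. = FALSE)
  if (any(ciliated_count < 0 | ciliated_count > total_count))
    stop("ciliated_count must lie in [0, total_count]", call. = FALSE)
  ciliated_count / total_count
}

#' Normalize percent ciliation to the same-experiment scrambled control
#'
#' For each experiment the control reference is the mean percent ciliation
#' over that experiment's scrambled-control observations. Every reagent's
#' observation is divided by the same-experiment reference (per-experiment
#' ratio first), and the ratios are then averaged unweighted across
#' experiments, so 1.0 means control-level ciliation. Experiments lacking a
#' scrambled observation, or whose control percent ciliation is zero, are
#' excluded for all reagents and logged. Scrambled reagents themselves are
#' included in the output: their per-experiment ratios (scattered around 1)
#' are the negative-control dispersion consumed by [calibrate_thresholds()].
#'
#' @param screen a `cilia_screen`
#' @return `normalized_effects` object: list with `summary` (one row per
#'   reagent: `mean_normalized`, `sd_across_experiments`, `sem`,
#'   `n_experiments`, `reduction = 1 - mean_normalized`), `per_experiment`
#'   (long table of per-experiment ratios) and `qc`.
#' @export
normalize_to_control <- function(screen) {
  stopifnot(inherits(screen, "cilia_screen"))
  counts <- screen$counts
  layout <- screen$layout
  qc <- character(0)

  counts$pc <- percent_ciliation(counts$ciliated_count, counts$total_count)
  scram_ids <- layout$reagent_id[layout$reagent_class == "SCRAMBLED_CONTROL"]
  if (length(scram_ids) == 0L)
    stop("screen has no scrambled-control reagent; cannot normalize", call. = FALSE)

  scram_obs <- counts[counts$reagent_id %in% scram_ids, , drop = FALSE]
  experiments <- unique(counts$experiment_id)
  ctrl <- tapply(scram_obs$pc, scram_obs$experiment_id, mean)

  missing <- setdiff(experiments, names(ctrl))
  if (length(missing) > 0L)
    qc <- c(qc, sprintf("experiment %s excluded: no scrambled-control observation", missing))
  zero <- names(ctrl)[ctrl == 0]
  if (length(zero) > 0L)
    qc <- c(qc, sprintf("experiment %s excluded: control percent ciliation is zero", zero))
  keep <- setdiff(names(ctrl)[ctrl > 0], missing)
  if (length(keep) == 0L)
    stop("no experiment has usable scrambled-control data", call. = FALSE)

  obs <- counts[counts$experiment_id %in% keep, , drop = FALSE]
  obs$normalized <- obs$pc / as.numeric(ctrl[obs$experiment_id])

  dropped <- setdiff(unique(counts$reagent_id), unique(obs$reagent_id))
  if (length(dropped) > 0L)
    stop(sprintf("reagent %s: no experiment with both condition and control data",
                 dropped[1]), call. = FALSE)

  split_norm <- split(obs$normalized, obs$reagent_id)
  ids <- names(split_norm)
  n <- vapply(split_norm, length, integer(1))
  mean_norm <- vapply(split_norm, mean, numeric(1))
  sd_norm <- vapply(split_norm, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_, numeric(1))
  summary <- data.frame(
    reagent_id = ids,
    gene = layout$gene[match(ids, layout$reagent_id)],
    reagent_class = layout$reagent_class[match(ids, layout$reagent_id)],
    round = layout$round[match(ids, layout$reagent_id)],
    n_experiments = n,
    mean_normalized = mean_norm,
    sd_across_experiments = sd_norm,
    sem = sd_norm / sqrt(n),
    reduction = 1 - mean_norm,
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  per_experiment <- data.frame(reagent_id = obs$reagent_id,
                               experiment_id = obs$experiment_id,
                               normalized = obs$normalized,
                               stringsAsFactors = FALSE)
  structure(list(summary = summary, per_experiment = per_experiment, qc = qc),
            class = "normalized_effects")
}

#' @export
print.normalized_effects <- function(x, ...) {
  cat(sprintf("<normalized_effects> %d reagents over up to %d experiments\n",
              nrow(x$summary), max(x$summary$n_experiments)))
  print(utils::head(x$summary, 10))
  if (nrow(x$summary) > 10) cat("...\n")
  invisible(x)
}

#' Quantify knockdown for one reagent
#'
#' Three measurement modes:
#' \describe{
#'   \item{CT}{textbook single-reference 2^(-ddCt). Per replicate,
#'     dCt = target Ct - reference-gene Ct; the calibrator is the mean dCt of
#'     the scrambled control named in `control_link`; relative quantity
#'     2^-(dCt - calibrator) is computed per replicate and summarized.}
#'   \item{PERCENT_REMAINING}{precomputed percent-RNA-remaining replicates
#'     (percent scale in the file) are summarized directly.}
#'   \item{ACTIVITY}{binary reagent-activity flag for miRNA mimics, which
#'     raise rather than lower their target: positive iff the mean flag is
#'     at least 0.5; no percent remaining is defined.}
#' }
#' Internally fractions of control transcript are carried in \[0, 1\];
#' `knockdown_positive` is true iff the mean fraction remaining is at or
#' below `cutoff`.
#'
#' @param qpcr qPCR table of a `cilia_screen` (or a compatible data.frame)
#' @param reagent_id reagent to quantify
#' @param cutoff maximum mean fraction remaining scored as knockdown
#'   (default 0.60; the threshold is a screen tunable, not a measured value)
#' @return one-row data.frame: `reagent_id`, `mode`, `n_replicates`,
#'   `percent_remaining_mean`, `percent_remaining_sd` (fractions),
#'   `knockdown_positive`
#' @export
quantify_knockdown <- function(qpcr, reagent_id, cutoff = 0.60) {
  rows <- qpcr[qpcr$reagent_id == reagent_id, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("no qPCR data for reagent '%s'", reagent_id), call. = FALSE)
  mode <- unique(rows$mode)
  if (length(mode) != 1L)
    stop(sprintf("reagent '%s' has mixed qPCR modes", reagent_id), call. = FALSE)

  if (mode == "ACTIVITY") {
    res <- data.frame(reagent_id = reagent_id, mode = mode,
                      n_replicates = nrow(rows),
                      percent_remaining_mean = NA_real_,
                      percent_remaining_sd = NA_real_,
                      knockdown_positive = mean(rows$value) >= 0.5,
                      stringsAsFactors = FALSE)
    return(res)
  }
  if (nrow(rows) < 3L)
    stop(sprintf("reagent '%s': %d qPCR replicate(s), need >= 3", reagent_id, nrow(rows)),
         call. = FALSE)

  if (mode == "CT") {
    if (any(is.na(rows$reference_value)))
      stop(sprintf("reagent '%s': CT mode requires reference Ct values", reagent_id), call. = FALSE)
    link <- unique(rows$control_link)
    if (length(link) != 1L || is.na(link))
      stop(sprintf("reagent '%s': CT mode requires a single control_link", reagent_id), call. = FALSE)
    ctrl <- qpcr[qpcr$reagent_id == link & qpcr$mode == "CT", , drop = FALSE]
    if (nrow(ctrl) < 3L || any(is.na(ctrl$reference_value)))
      stop(sprintf("reagent '%s': linked control '%s' lacks triplicate CT data", reagent_id, link),
           call. = FALSE)
    dct <- rows$value - rows$reference_value
    dct_ctrl <- mean(ctrl$value - ctrl$reference_value)
    rq <- 2^(-(dct - dct_ctrl))          # fraction of control transcript
  } else {                               # PERCENT_REMAINING, percent scale
    rq <- rows$value / 100
  }
  m <- mean(rq)
  data.frame(reagent_id = reagent_id, mode = mode, n_replicates = length(rq),
             percent_remaining_mean = m, percent_remaining_sd = stats::sd(rq),
             knockdown_positive = m <= cutoff, stringsAsFactors = FALSE)
}

#' Quantify knockdown for every reagent with qPCR data
#'
#' @param screen a `cilia_screen`
#' @param cutoff see [quantify_knockdown()]
#' @return data.frame, one row per measured reagent
#' @export
quantify_all_knockdown <- function(screen, cutoff = 0.60) {
  stopifnot(inherits(screen, "cilia_screen"))
  if (is.null(screen$qpcr) || nrow(screen$qpcr) == 0L)
    return(data.frame(reagent_id = character(0), mode = character(0),
                      n_replicates = integer(0), percent_remaining_mean = numeric(0),
                      percent_remaining_sd = numeric(0), knockdown_positive = logical(0),
                      stringsAsFactors = FALSE))
  ids <- unique(screen$qpcr$reagent_id)
  out <- do.call(rbind, lapply(ids, function(id)
    quantify_knockdown(screen$qpcr, id, cutoff = cutoff)))
  rownames(out) <- NULL
  out
}
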