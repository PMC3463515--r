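# Seeded generator for complete synthetic screens with the statistical
# structure the analysis assumes, plus the operating-characteristics harness
# (false-positive rate, power, effect recovery).
#
# Generative model, in draw order (a single seeded RNG; the order is part of
# the reproducibility contract):
#   1. per-experiment baseline ciliation p0_e ~ Normal(baseline_mean,
#      baseline_sd) truncated to (0, 1), one draw per experiment;
#   2. per candidate/positive-control reagent (layout order): true fraction
#      of transcript remaining ~ Uniform over the active or silent range;
#   3. per reagent x experiment (layout order, experiments within):
#      ciliated_count ~ Binomial(cells_per_condition, clamp(p0_e * effect)),
#      where a candidate's realized effect maps its sampled knockdown through
#      the dose-response link and a positive control realizes its nominal
#      factor directly (it models a pre-validated reagent);
#   4. qPCR replicates per measured reagent: remaining * exp(N(0, sd));
#   5. cilium lengths (Gamma) for the scrambled control and gain-arm
#      duplexes.

#' Configuration of a synthetic screen
#'
#' Defaults state the screening conditions the pipeline was designed for:
#' 5 experiments, 160 cells per condition, control ciliation 55 +/- 5%
#' between experiments, a strong-loss positive control at 0.25x control
#' ciliation and a moderate anchor at 0.65x, active duplexes leaving 20-50%
#' of transcript and silent duplexes 80-110%, and a linear dose-response
#' reaching the full effect once 40% or less of the transcript remains.
#'
#' @param n_genes named integer vector: genes per simulated class; names
#'   must appear in `true_effects`. Default mirrors a 41-candidate screen.
#' @param true_effects named multiplicative effects on ciliation probability
#'   (1 = null).
#' @param n_experiments,cells_per_condition replication structure.
#' @param baseline_mean,baseline_sd between-experiment control ciliation.
#' @param kd_active_range,kd_silent_range Uniform ranges for the true
#'   fraction remaining of active and silent duplexes.
#' @param dose_response `"linear"` (default), `"step"` or `"hill"` link from
#'   fraction remaining to realized effect.
#' @param full_effect_at fraction remaining at or below which the full
#'   effect is realized.
#' @param qpcr_noise_sd log-scale multiplicative noise of qPCR replicates.
#' @param qpcr_replicates replicates per reagent (>= 3).
#' @param n_scrambled scrambled-control duplexes (>= 2 so negative-control
#'   dispersion is estimable).
#' @param positive_controls named vector of nominal effects; the last entry
#'   is used as the calibration anchor by downstream defaults.
#' @param length_mean,length_sd control cilium length Gamma moments (um).
#' @param length_gain_shift added mean length in gain conditions (um);
#'   default 4 pooled SDs.
#' @param n_length_control,n_length_condition cilia measured per arm.
#' @param simulate_lengths generate the length table for gain-class duplexes.
#' @param seed integer; fully determines the simulated screen.
#' @return validated `sim_config` list
#' @export
simulation_config <- function(n_genes = c(NULL_EFFECT = 18L, STRONG_LOSS = 10L,
                                          ANCHOR_LOSS = 10L, GAIN = 3L),
                              true_effects = c(NULL_EFFECT = 1.0, STRONG_LOSS = 0.25,
                                               ANCHOR_LOSS = 0.65, GAIN = 1.3),
                              n_experiments = 5L, cells_per_condition = 160L,
                              baseline_mean = 0.55, baseline_sd = 0.05,
                              kd_active_range = c(0.2, 0.5),
                              kd_silent_range = c(0.8, 1.1),
                              dose_response = c("linear", "step", "hill"),
                              full_effect_at = 0.4,
                              qpcr_noise_sd = 0.1, qpcr_replicates = 3L,
                              n_scrambled = 2L,
                              positive_controls = c(siIFT88 = 0.25, siPCM1 = 0.65),
                              length_mean = 2.4, length_sd = 0.35,
                              length_gain_shift = 1.4,
                              n_length_control = 45L, n_length_condition = 43L,
                              simulate_lengths = TRUE, seed = 1L) {
  dose_response <- match.arg(dose_response)
  if (is.null(names(n_genes)) || !all(names(n_genes) %in% names(true_effects)))
    stop("every class in n_genes must have an entry in true_effects", call. = FALSE)
  if (baseline_mean <= 0 || baseline_mean >= 1 || baseline_sd < 0)
    stop("baseline ciliation parameters out of range", call. = FALSE)
  if (any(true_effects < 0)) stop("true effects must be non-negative", call. = FALSE)
  if (n_scrambled < 2L) stop("need >= 2 scrambled duplexes for dispersion", call. = FALSE)
  if (qpcr_replicates < 3L) stop("qPCR requires >= 3 replicates", call. = FALSE)
  if (cells_per_condition < 1L || n_experiments < 1L)
    stop("invalid replication structure", call. = FALSE)
  structure(list(n_genes = n_genes, true_effects = true_effects,
                 n_experiments = as.integer(n_experiments),
                 cells_per_condition = as.integer(cells_per_condition),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 kd_active_range = kd_active_range, kd_silent_range = kd_silent_range,
                 dose_response = dose_response, full_effect_at = full_effect_at,
                 qpcr_noise_sd = qpcr_noise_sd, qpcr_replicates = as.integer(qpcr_replicates),
                 n_scrambled = as.integer(n_scrambled),
                 positive_controls = positive_controls,
                 length_mean = length_mean, length_sd = length_sd,
                 length_gain_shift = length_gain_shift,
                 n_length_control = as.integer(n_length_control),
                 n_length_condition = as.integer(n_length_condition),
                 simulate_lengths = isTRUE(simulate_lengths),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# monotone link from true fraction remaining to realized effect factor
dose_response_effect <- function(remaining, full, link = "linear", full_at = 0.4) {
  w <- switch(link,
    linear = pmin(1, pmax(0, (1 - remaining) / (1 - full_at))),
    step = as.numeric(remaining <= full_at),
    hill = 1 / (1 + (remaining / 0.7)^4))
  1 + (full - 1) * w
}

rtruncnorm01 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0 | x >= 1))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

rgamma_ms <- function(n, mean, sd) {
  stats::rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Simulate a complete synthetic screen
#'
#' Draws a screen under the hierarchical binomial model described in
#' [simulation_config()] and returns it together with the ground truth
#' (per-duplex nominal effect, true fraction remaining, and realized effect
#' after the dose-response link). With `dir` set, writes the four screen
#' CSVs plus `ground_truth.csv`; identical seeds give byte-identical files.
#'
#' @param config a `sim_config`
#' @param dir optional output directory
#' @return list with `screen` (a `cilia_screen`), `truth` (data.frame) and
#'   `config`
#' @export
simulate_screen <- function(config = simulation_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_exp <- config$n_experiments
  cells <- config$cells_per_condition
  experiments <- sprintf("exp%d", seq_len(n_exp))

  scram_ids <- sprintf("siScr-%d", seq_len(config$n_scrambled))
  layout <- data.frame(reagent_id = scram_ids, gene = NA_character_,
                       reagent_class = "SCRAMBLED_CONTROL", round = 1L,
                       category = "CONTROL", stringsAsFactors = FALSE)
  if (length(config$positive_controls) > 0L) {
    pos_ids <- paste0(names(config$positive_controls), "-1")
    layout <- rbind(layout, data.frame(
      reagent_id = pos_ids,
      gene = sub("^si", "", names(config$positive_controls)),
      reagent_class = "POSITIVE_CONTROL", round = 1L, category = "CONTROL",
      stringsAsFactors = FALSE))
  }
  gene_tab <- do.call(rbind, lapply(names(config$n_genes), function(cls) {
    k <- config$n_genes[[cls]]
    if (k == 0L) return(NULL)
    data.frame(gene = sprintf("%s_g%02d", cls, seq_len(k)), class = cls,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(gene_tab)) {
    duplexes <- data.frame(
      reagent_id = as.vector(t(outer(gene_tab$gene, 1:2, function(g, d) sprintf("si%s-%d", g, d)))),
      gene = rep(gene_tab$gene, each = 2L),
      reagent_class = "SIRNA", round = 1L,
      category = rep(gene_tab$class, each = 2L), stringsAsFactors = FALSE)
    layout <- rbind(layout, duplexes)
  }

  # 1. experiment baselines
  p0 <- rtruncnorm01(n_exp, config$baseline_mean, config$baseline_sd)

  # 2. per-reagent true knockdown (layout order; scrambled have none)
  is_meas <- layout$reagent_class %in% c("POSITIVE_CONTROL", "SIRNA", "MIRNA_MIMIC")
  remaining <- rep(NA_real_, nrow(layout))
  remaining[is_meas] <- stats::runif(sum(is_meas),
                                     config$kd_active_range[1], config$kd_active_range[2])
  nominal <- rep(1, nrow(layout))
  pos <- layout$reagent_class == "POSITIVE_CONTROL"
  nominal[pos] <- config$positive_controls[sub("-1$", "", layout$reagent_id[pos])]
  cand <- layout$reagent_class %in% c("SIRNA", "MIRNA_MIMIC")
  nominal[cand] <- config$true_effects[layout$category[cand]]
  realized <- rep(1, nrow(layout))
  realized[pos] <- nominal[pos]              # validated reagents: full effect
  realized[cand] <- dose_response_effect(remaining[cand], nominal[cand],
                                         config$dose_response, config$full_effect_at)

  # 3. binomial counts
  # reagent x experiment; pmax/pmin keep the matrix first so dims survive
  p_mat <- pmin(pmax(outer(realized, p0), 0), 1)
  ciliated <- matrix(stats::rbinom(length(p_mat), cells, as.vector(t(p_mat))),
                     nrow = nrow(layout), byrow = TRUE)
  counts <- data.frame(
    experiment_id = rep(experiments, times = nrow(layout)),
    reagent_id = rep(layout$reagent_id, each = n_exp),
    ciliated_count = as.vector(t(ciliated)),
    total_count = cells, stringsAsFactors = FALSE)

  # 4. qPCR replicates (percent scale)
  qpcr <- do.call(rbind, lapply(which(is_meas), function(i) {
    vals <- 100 * remaining[i] * exp(stats::rnorm(config$qpcr_replicates, 0, config$qpcr_noise_sd))
    data.frame(reagent_id = layout$reagent_id[i], mode = "PERCENT_REMAINING",
               replicate = seq_len(config$qpcr_replicates), value = vals,
               reference_value = NA_real_, control_link = NA_character_,
               stringsAsFactors = FALSE)
  }))

  # 5. lengths for the gain arm
  lengths <- NULL
  gain_rows <- which(cand & nominal > 1)
  if (config$simulate_lengths && length(gain_rows) > 0L) {
    ctrl_len <- rgamma_ms(config$n_length_control, config$length_mean, config$length_sd)
    lengths <- data.frame(reagent_id = scram_ids[1], length_um = ctrl_len,
                          stringsAsFactors = FALSE)
    for (i in gain_rows) {
      cond_len <- rgamma_ms(config$n_length_condition,
                            config$length_mean + config$length_gain_shift, config$length_sd)
      lengths <- rbind(lengths, data.frame(reagent_id = layout$reagent_id[i],
                                           length_um = cond_len, stringsAsFactors = FALSE))
    }
  }

  truth <- data.frame(reagent_id = layout$reagent_id, gene = layout$gene,
                      class = ifelse(cand, layout$category,
                                     layout$reagent_class),
                      nominal_effect = nominal, true_remaining = remaining,
                      realized_effect = realized, stringsAsFactors = FALSE)

  screen <- build_screen(layout, counts, qpcr, lengths,
                         min_cells = min(150L, cells))
  if (!is.null(dir)) {
    write_screen(screen, dir)
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(screen = screen, truth = truth, config = config)
}

#' Simulate one control/condition cilium-length pair
#'
#' Control lengths from the configured Gamma; condition lengths with the
#' gain-arm mean shift. Used by the length-test power analysis.
#'
#' @param config a `sim_config`
#' @param seed optional seed; when `NULL` the current RNG state is used
#' @return list with numeric vectors `control` and `condition`
#' @export
simulate_length_pair <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  list(control = rgamma_ms(config$n_length_control, config$length_mean, config$length_sd),
       condition = rgamma_ms(config$n_length_condition,
                             config$length_mean + config$length_gain_shift,
                             config$length_sd))
}

#' Operating characteristics of the screen design
#'
#' Simulates `n_replicate_screens` independent screens (seeds
#' `config$seed + 0:(n-1)`), runs the full pipeline on each, and reports
#' per-class empirical hit rates with binomial standard errors plus
#' effect-estimate bias and RMSE of `mean_normalized` against the realized
#' per-duplex effect from the ground truth.
#'
#' @param config a `sim_config`
#' @param n_replicate_screens number of replicate screens (>= 1)
#' @param call_config pipeline parameters, see [screen_call_config()]
#' @return `design_eval` object: `by_class` (gene-level hit rates),
#'   `effect_recovery` (per-class bias/RMSE), `n_screens`
#' @export
evaluate_design <- function(config = simulation_config(), n_replicate_screens = 50,
                            call_config = screen_call_config()) {
  stopifnot(inherits(config, "sim_config"), n_replicate_screens >= 1)
  classes <- names(config$n_genes)[config$n_genes > 0L]
  tall <- stats::setNames(rep(0, length(classes)), classes)
  acc <- list(n = tall, loss = tall, gain = tall,
              err_n = tall, err_sum = tall, err_sq = tall)

  for (i in seq_len(n_replicate_screens)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    sim <- suppressWarnings(simulate_screen(cfg_i))
    res <- suppressWarnings(call_screen(sim$screen, call_config))
    dec <- res$decisions
    for (cls in classes) {
      d <- dec[dec$category == cls, , drop = FALSE]
      acc$n[cls] <- acc$n[cls] + nrow(d)
      acc$loss[cls] <- acc$loss[cls] + sum(d$status == "HIT_LOSS")
      acc$gain[cls] <- acc$gain[cls] + sum(d$status == "HIT_GAIN")
    }
    eff <- res$effects$summary
    eff <- eff[eff$reagent_class == "SIRNA", , drop = FALSE]
    err <- eff$mean_normalized -
      sim$truth$realized_effect[match(eff$reagent_id, sim$truth$reagent_id)]
    cls_of <- sim$screen$layout$category[match(eff$reagent_id, sim$screen$layout$reagent_id)]
    for (cls in classes) {
      e <- err[cls_of == cls]
      acc$err_n[cls] <- acc$err_n[cls] + length(e)
      acc$err_sum[cls] <- acc$err_sum[cls] + sum(e)
      acc$err_sq[cls] <- acc$err_sq[cls] + sum(e^2)
    }
  }
  p_loss <- acc$loss / acc$n
  p_gain <- acc$gain / acc$n
  by_class <- data.frame(
    class = classes,
    nominal_effect = as.numeric(config$true_effects[classes]),
    n_gene_decisions = as.integer(acc$n),
    hit_loss_rate = p_loss,
    hit_loss_se = sqrt(p_loss * (1 - p_loss) / acc$n),
    hit_gain_rate = p_gain,
    hit_gain_se = sqrt(p_gain * (1 - p_gain) / acc$n),
    stringsAsFactors = FALSE)
  bias <- acc$err_sum / acc$err_n
  effect_recovery <- data.frame(
    class = classes,
    nominal_effect = as.numeric(config$true_effects[classes]),
    n_reagents = as.integer(acc$err_n),
    bias = bias,
    rmse = sqrt(acc$err_sq / acc$err_n),
    stringsAsFactors = FALSE)
  rownames(by_class) <- rownames(effect_recovery) <- NULL
  structure(list(by_class = by_class, effect_recovery = effect_recovery,
                 n_screens = n_replicate_screens),
            class = "design_eval")
}

#' @export
print.design_eval <- function(x, ...) {
  cat(sprintf("<design_eval> %d replicate screens\n", x$n_screens))
  print(x$by_class, digits = 4)
  cat("effect recovery:\n")
  print(x$effect_recovery, digits = 4)
  invisible(x)
}
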