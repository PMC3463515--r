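# Cilium-length statistics for the gain-of-ciliation arm: classic pooled
# (equal-variance) unpaired two-tailed t-test per condition vs the scrambled
# control, each measured cilium one observation.

#' Two-sample cilium-length comparison
#'
#' Classic Student's (pooled-variance) unpaired two-tailed t-test with
#' n1 + n2 - 2 degrees of freedom; means and SEMs (sd/sqrt(n)) are reported
#' in micrometres. Welch's unequal-variance form is available behind
#' `welch = TRUE`. Degenerate inputs: zero pooled variance with equal means
#' gives t = 0, p = 1; zero pooled variance with unequal means is an error.
#'
#' @param condition,control numeric vectors of per-cilium lengths (um),
#'   each of length >= 2
#' @param alpha significance level for the `significant` flag (default 0.05)
#' @param reagent_id optional label carried into the output
#' @param welch use the Welch (unequal-variance) statistic instead
#' @return one-row data.frame: `reagent_id`, `n_condition`, `n_control`,
#'   `mean_condition`, `mean_control`, `sem_condition`, `sem_control`,
#'   `t_statistic`, `df`, `p_value`, `significant`
#' @export
compare_lengths <- function(condition, control, alpha = 0.05,
                            reagent_id = NA_character_, welch = FALSE) {
  condition <- as.numeric(condition)
  control <- as.numeric(control)
  n1 <- length(condition); n2 <- length(control)
  if (n1 < 2L || n2 < 2L)
    stop("both samples need >= 2 observations", call. = FALSE)
  if (any(is.na(condition)) || any(is.na(control)))
    stop("length samples must not contain missing values", call. = FALSE)
  m1 <- mean(condition); m2 <- mean(control)
  v1 <- stats::var(condition); v2 <- stats::var(control)

  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      if (m1 == m2) { t <- 0; df <- n1 + n2 - 2 }
      else stop("zero variance with unequal means: degenerate comparison", call. = FALSE)
    } else {
      t <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    if (sp2 == 0) {
      if (m1 == m2) t <- 0
      else stop("zero pooled variance with unequal means: degenerate comparison", call. = FALSE)
    } else {
      t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    }
  }
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(reagent_id = reagent_id, n_condition = n1, n_control = n2,
             mean_condition = m1, mean_control = m2,
             sem_condition = stats::sd(condition) / sqrt(n1),
             sem_control = stats::sd(control) / sqrt(n2),
             t_statistic = t, df = df, p_value = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Length report for every measured reagent vs the scrambled control
#'
#' @param screen a `cilia_screen` with a lengths table
#' @param control_reagent reagent_id supplying the control length sample;
#'   defaults to the first scrambled control present in the lengths table
#' @param alpha,welch see [compare_lengths()]
#' @return data.frame, one [compare_lengths()] row per non-control reagent
#' @export
lengths_report <- function(screen, control_reagent = NULL, alpha = 0.05, welch = FALSE) {
  stopifnot(inherits(screen, "cilia_screen"))
  len <- screen$lengths
  if (is.null(len) || nrow(len) == 0L)
    stop("screen has no length measurements", call. = FALSE)
  if (is.null(control_reagent)) {
    scram <- screen$layout$reagent_id[screen$layout$reagent_class == "SCRAMBLED_CONTROL"]
    control_reagent <- intersect(scram, unique(len$reagent_id))[1]
    if (is.na(control_reagent))
      stop("no scrambled control in the lengths table; supply control_reagent", call. = FALSE)
  }
  ctrl <- len$length_um[len$reagent_id == control_reagent]
  if (length(ctrl) < 2L)
    stop(sprintf("control reagent '%s' has < 2 length observations", control_reagent), call. = FALSE)
  ids <- setdiff(unique(len$reagent_id), control_reagent)
  out <- do.call(rbind, lapply(ids, function(id)
    compare_lengths(len$length_um[len$reagent_id == id], ctrl,
                    alpha = alpha, reagent_id = id, welch = welch)))
  rownames(out) <- NULL
  out
}
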