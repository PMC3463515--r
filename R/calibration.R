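# Loss/gain threshold calibration from negative-control dispersion and the
# positive-control anchor.

#' Calibrate loss and gain thresholds
#'
#' The loss threshold is anchored at the normalized ciliation of a
#' positive-control reagent of known moderate effect (PCM1-level depletion),
#' accepted only if it exceeds `k_sd` standard deviations of the pooled
#' negative-control dispersion — the conservative rule that the anchor effect
#' must lie beyond anything any scrambled duplex produced. If the anchor does
#' not clear that bound, the threshold falls back to
#' `neg_mean - k_sd * neg_sd` with a warning. The gain threshold mirrors the
#' control-derived rule on the other side: `neg_mean + k_sd * neg_sd`.
#'
#' @param neg_values per-experiment normalized ciliation values of all
#'   scrambled-control duplexes, pooled (length >= 2, non-degenerate)
#' @param anchor mean normalized ciliation of the anchor reagent
#' @param k_sd number of negative-control standard deviations (default 4)
#' @return `threshold_set` object: `loss_threshold`, `gain_threshold`,
#'   `k_sd`, `neg_mean`, `neg_sd`, `anchor_value`, `validated`, `n_neg`
#' @examples
#' calibrate_thresholds(c(0.95, 1.00, 1.05), anchor = 0.65)
#' @export
calibrate_thresholds <- function(neg_values, anchor, k_sd = 4) {
  neg_values <- as.numeric(neg_values)
  if (length(neg_values) < 2L || any(is.na(neg_values)))
    stop("need >= 2 non-missing negative-control normalized values", call. = FALSE)
  if (length(anchor) != 1L || is.na(anchor))
    stop("anchor effect is missing", call. = FALSE)
  if (!is.numeric(k_sd) || k_sd <= 0) stop("k_sd must be positive", call. = FALSE)
  neg_mean <- mean(neg_values)
  neg_sd <- stats::sd(neg_values)
  if (neg_sd == 0)
    stop("negative-control dispersion is zero (degenerate controls)", call. = FALSE)
  bound <- neg_mean - k_sd * neg_sd
  validated <- anchor <= bound
  loss <- if (validated) as.numeric(anchor) else bound
  if (!validated)
    warning(sprintf(
      "anchor %.4f does not exceed %g SD below negative controls (bound %.4f); loss threshold falls back to the %g-SD bound",
      anchor, k_sd, bound, k_sd), call. = FALSE)
  gain <- neg_mean + k_sd * neg_sd
  stopifnot(loss < neg_mean, neg_mean < gain)
  structure(list(loss_threshold = loss, gain_threshold = gain, k_sd = k_sd,
                 neg_mean = neg_mean, neg_sd = neg_sd,
                 anchor_value = as.numeric(anchor), validated = validated,
                 n_neg = length(neg_values)),
            class = "threshold_set")
}

#' Calibrate thresholds from computed screen effects
#'
#' Pools the per-experiment normalized values of every scrambled duplex and
#' takes the anchor reagent's cross-experiment mean, then calls
#' [calibrate_thresholds()].
#'
#' @param effects `normalized_effects` from [normalize_to_control()]
#' @param screen the `cilia_screen` the effects came from
#' @param anchor_reagent reagent_id of the positive-control anchor
#' @param k_sd see [calibrate_thresholds()]
#' @export
calibrate_from_screen <- function(effects, screen, anchor_reagent, k_sd = 4) {
  stopifnot(inherits(effects, "normalized_effects"), inherits(screen, "cilia_screen"))
  scram_ids <- screen$layout$reagent_id[screen$layout$reagent_class == "SCRAMBLED_CONTROL"]
  neg <- effects$per_experiment$normalized[effects$per_experiment$reagent_id %in% scram_ids]
  i <- match(anchor_reagent, effects$summary$reagent_id)
  if (is.na(i))
    stop(sprintf("anchor reagent '%s' has no computed effect", anchor_reagent), call. = FALSE)
  calibrate_thresholds(neg, anchor = effects$summary$mean_normalized[i], k_sd = k_sd)
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> loss <= %.4f, gain >= %.4f (k = %g SD)\n",
              x$loss_threshold, x$gain_threshold, x$k_sd))
  cat(sprintf("  negative controls: mean %.4f, sd %.4f (n = %d per-experiment values)\n",
              x$neg_mean, x$neg_sd, x$n_neg))
  cat(sprintf("  anchor %.4f, %svalidated against the %g-SD bound\n",
              x$anchor_value, if (x$validated) "" else "NOT ", x$k_sd))
  invisible(x)
}
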