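# The two-round decision automaton: per-duplex classification against the
# calibrated thresholds, knockdown concordance, split rescue into round 2,
# gene-level verdicts and tallies.
#
# Round-1 rules for a two-duplex gene:
#   * both duplexes effective (phenotype crosses a threshold AND knockdown
#     confirmed) in the same direction        -> HIT
#   * exactly one effective, the other duplex silent (NONE) AND failing to
#     knock down expression                   -> ROUND2_PENDING ("split")
#   * anything else                           -> NEGATIVE
# Round 2 retests a pending gene with two fresh duplexes; both must be
# effective in the pending direction, otherwise the gene is negative.

PHENOTYPES <- c("LOSS", "GAIN", "NONE")
DECISION_STATUSES <- c("HIT_LOSS", "HIT_GAIN", "ROUND2_PENDING", "NEGATIVE")

#' Classify one duplex against the calibrated thresholds
#'
#' Phenotype is `LOSS` iff `mean_normalized <= loss_threshold`, `GAIN` iff
#' `>= gain_threshold`, otherwise `NONE`; a value exactly at a threshold
#' counts as crossing it, so the anchor duplex scores positive against
#' itself. A duplex is `effective` iff its phenotype is not `NONE` and its
#' knockdown (or mimic activity) is confirmed. A phenotype-positive duplex
#' with no knockdown measurement is carried with `knockdown_positive = NA`;
#' the automaton routes its gene to NEGATIVE with rationale
#' "unverified knockdown".
#'
#' @param effect one-row data.frame (or list) with `reagent_id` and
#'   `mean_normalized`
#' @param kd one-row data.frame from [quantify_knockdown()], or `NULL` if
#'   unmeasured
#' @param thresholds a `threshold_set`
#' @return one-row data.frame: `reagent_id`, `mean_normalized`, `phenotype`,
#'   `knockdown_positive`, `effective`
#' @export
classify_duplex <- function(effect, kd, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  mn <- as.numeric(effect$mean_normalized)
  if (length(mn) != 1L || is.na(mn)) stop("effect must carry one mean_normalized", call. = FALSE)
  if (!is.null(kd) && !identical(kd$reagent_id, effect$reagent_id))
    stop("effect and knockdown rows refer to different reagents", call. = FALSE)
  phenotype <- if (mn <= thresholds$loss_threshold) "LOSS"
               else if (mn >= thresholds$gain_threshold) "GAIN"
               else "NONE"
  kd_pos <- if (is.null(kd)) NA else kd$knockdown_positive
  data.frame(reagent_id = effect$reagent_id,
             mean_normalized = mn,
             phenotype = phenotype,
             knockdown_positive = kd_pos,
             effective = phenotype != "NONE" & !is.na(kd_pos) & kd_pos,
             stringsAsFactors = FALSE)
}

decision_row <- function(gene, category, status, round, rule, rationale,
                         direction = NA_character_) {
  data.frame(gene = gene, category = category, status = status,
             decided_in_round = round, direction = direction,
             rule = rule, rationale = rationale, stringsAsFactors = FALSE)
}

#' Round-1 gene decision from two duplex calls
#'
#' @param calls data.frame of exactly two [classify_duplex()] rows for the
#'   gene's round-1 duplexes
#' @param gene,category carried into the decision for reporting
#' @return one-row decision data.frame: `gene`, `category`, `status`
#'   (`HIT_LOSS`/`HIT_GAIN`/`ROUND2_PENDING`/`NEGATIVE`), `decided_in_round`,
#'   `direction` (pending or hit direction), `rule` (machine-readable id of
#'   the rule that fired) and a human-readable `rationale`
#' @export
decide_gene_round1 <- function(calls, gene = "gene", category = NA_character_) {
  calls <- as.data.frame(calls)
  if (nrow(calls) != 2L)
    stop(sprintf("gene %s: round 1 requires exactly 2 duplex calls, got %d", gene, nrow(calls)),
         call. = FALSE)
  unverified <- calls$phenotype != "NONE" & is.na(calls$knockdown_positive)
  eff <- calls$effective

  if (all(eff)) {
    if (calls$phenotype[1] == calls$phenotype[2]) {
      status <- if (calls$phenotype[1] == "LOSS") "HIT_LOSS" else "HIT_GAIN"
      return(decision_row(gene, category, status, 1L, "r1_both_effective",
                          sprintf("round 1: both duplexes effective (%s with confirmed knockdown)",
                                  calls$phenotype[1]),
                          direction = calls$phenotype[1]))
    }
    return(decision_row(gene, category, "NEGATIVE", 1L, "r1_opposite_directions",
                        "round 1: both duplexes effective but in opposite directions"))
  }
  if (sum(eff) == 1L) {
    other <- calls[!eff, , drop = FALSE]
    if (other$phenotype == "NONE" && identical(other$knockdown_positive, FALSE))
      return(decision_row(gene, category, "ROUND2_PENDING", 1L, "r1_split",
                          sprintf("round 1 split: one duplex effective (%s), the silent duplex also failed to knock down expression",
                                  calls$phenotype[eff]),
                          direction = calls$phenotype[eff]))
  }
  rationale <- if (any(unverified))
    "round 1: phenotype-positive duplex with unverified knockdown"
  else "round 1: criteria not met (all other outcomes are negative)"
  rule <- if (any(unverified)) "r1_unverified_knockdown" else "r1_other"
  decision_row(gene, category, "NEGATIVE", 1L, rule, rationale)
}

#' Round-2 gene decision
#'
#' A gene enters round 2 only as a round-1 split; two fresh duplexes are
#' tested and both must be effective in the pending direction for the gene
#' to be scored a hit. Any other round-2 outcome is negative.
#'
#' @param pending the gene's round-1 decision row (status `ROUND2_PENDING`)
#' @param calls data.frame of exactly two round-2 [classify_duplex()] rows
#' @return one-row decision data.frame (see [decide_gene_round1()])
#' @export
decide_gene_round2 <- function(pending, calls) {
  pending <- as.data.frame(pending)
  if (!identical(pending$status, "ROUND2_PENDING"))
    stop(sprintf("gene %s: round-2 calls present but gene is not pending (status %s)",
                 pending$gene, pending$status), call. = FALSE)
  calls <- as.data.frame(calls)
  if (nrow(calls) != 2L)
    stop(sprintf("gene %s: round 2 requires exactly 2 duplex calls, got %d",
                 pending$gene, nrow(calls)), call. = FALSE)
  dir <- pending$direction
  ok <- calls$effective & calls$phenotype == dir
  if (all(ok)) {
    status <- if (dir == "LOSS") "HIT_LOSS" else "HIT_GAIN"
    return(decision_row(pending$gene, pending$category, status, 2L, "r2_confirmed",
                        sprintf("round 2: both independent duplexes effective (%s); split confirmed", dir),
                        direction = dir))
  }
  decision_row(pending$gene, pending$category, "NEGATIVE", 2L, "r2_failed",
               sprintf("round 2: %d of 2 duplexes effective in the pending %s direction; not scored as a hit",
                       sum(ok), dir),
               direction = dir)
}

# generalized round-1 rule for genes probed by > 2 round-1 duplexes:
# >= min_effective duplexes effective in one direction, and no discordant
# silent-but-knocked-down duplex; no split rescue in this design.
decide_gene_multi <- function(calls, gene, category, min_effective = 2L) {
  eff <- calls[calls$effective, , drop = FALSE]
  dirs <- unique(eff$phenotype)
  discordant <- any(calls$phenotype == "NONE" & !is.na(calls$knockdown_positive) &
                      calls$knockdown_positive)
  if (nrow(eff) >= min_effective && length(dirs) == 1L && !discordant) {
    status <- if (dirs == "LOSS") "HIT_LOSS" else "HIT_GAIN"
    return(decision_row(gene, category, status, 1L, "r1_multi_effective",
                        sprintf("round 1 (%d duplexes): %d effective (%s), no discordant silent knockdown",
                                nrow(calls), nrow(eff), dirs),
                        direction = dirs))
  }
  decision_row(gene, category, "NEGATIVE", 1L, "r1_multi_other",
               sprintf("round 1 (%d duplexes): criteria not met", nrow(calls)))
}

#' Run the full decision automaton over a screen
#'
#' Computes normalized effects and knockdown for every reagent, calibrates
#' thresholds (unless supplied), classifies every candidate duplex, applies
#' the round-1 rules per gene and the round-2 rules for genes with round-2
#' reagents, and tallies outcomes by gene category. Round-2 data for a gene
#' that is not a round-1 split is an error; a pending gene without round-2
#' data remains `ROUND2_PENDING`.
#'
#' @param screen a `cilia_screen`
#' @param config a [screen_call_config()] list (anchor reagent, k_sd,
#'   knockdown cutoff, min_effective for >2-duplex designs)
#' @param thresholds optional precomputed `threshold_set`; when `NULL`,
#'   calibrated from the screen via [calibrate_from_screen()]
#' @return `screen_calls` object: `decisions` (one row per gene), `tallies`
#'   (category x status counts), `duplex_calls`, `effects`, `knockdown`,
#'   `thresholds`, `qc`
#' @export
call_screen <- function(screen, config = screen_call_config(), thresholds = NULL) {
  stopifnot(inherits(screen, "cilia_screen"))
  effects <- normalize_to_control(screen)
  kd <- quantify_all_knockdown(screen, cutoff = config$knockdown_cutoff)
  if (is.null(thresholds))
    thresholds <- calibrate_from_screen(effects, screen, config$anchor_reagent,
                                        k_sd = config$k_sd)
  qc <- c(screen$qc, effects$qc)
  if (!thresholds$validated)
    qc <- c(qc, sprintf("threshold fallback: anchor %.4f not beyond the %g-SD bound",
                        thresholds$anchor_value, thresholds$k_sd))

  layout <- screen$layout
  cand <- layout[layout$reagent_class %in% c("SIRNA", "MIRNA_MIMIC"), , drop = FALSE]
  calls <- do.call(rbind, lapply(cand$reagent_id, function(id) {
    eff_row <- effects$summary[effects$summary$reagent_id == id, , drop = FALSE]
    if (nrow(eff_row) == 0L)
      stop(sprintf("reagent '%s' has no count data", id), call. = FALSE)
    kd_row <- kd[kd$reagent_id == id, , drop = FALSE]
    classify_duplex(eff_row, if (nrow(kd_row) == 1L) kd_row else NULL, thresholds)
  }))
  calls$gene <- cand$gene[match(calls$reagent_id, cand$reagent_id)]
  calls$round <- cand$round[match(calls$reagent_id, cand$reagent_id)]

  if (is.null(calls))
    calls <- data.frame(reagent_id = character(0), mean_normalized = numeric(0),
                        phenotype = character(0), knockdown_positive = logical(0),
                        effective = logical(0), gene = character(0),
                        round = integer(0), stringsAsFactors = FALSE)

  keys <- gene_key(screen$genes$gene)
  decisions <- do.call(rbind, lapply(seq_along(keys), function(i) {
    g <- screen$genes$gene[i]
    cat_g <- screen$genes$category[i]
    gc <- calls[gene_key(calls$gene) == keys[i], , drop = FALSE]
    r1 <- gc[gc$round == 1L, , drop = FALSE]
    r2 <- gc[gc$round == 2L, , drop = FALSE]
    dec <- if (nrow(r1) == 2L) decide_gene_round1(r1, gene = g, category = cat_g)
           else decide_gene_multi(r1, gene = g, category = cat_g,
                                  min_effective = config$min_effective)
    if (nrow(r2) > 0L) dec <- decide_gene_round2(dec, r2)
    dec
  }))
  if (is.null(decisions))
    decisions <- decision_row(character(0), character(0), character(0),
                              integer(0), character(0), character(0), character(0))
  rownames(decisions) <- NULL
  if (any(decisions$status == "ROUND2_PENDING"))
    qc <- c(qc, sprintf("gene %s pending: round-1 split with no round-2 data",
                        decisions$gene[decisions$status == "ROUND2_PENDING"]))

  if (nrow(decisions) > 0L) {
    tallies <- as.data.frame(table(category = decisions$category,
                                   status = factor(decisions$status, DECISION_STATUSES)),
                             responseName = "n", stringsAsFactors = FALSE)
    tallies <- tallies[order(tallies$category, tallies$status), ]
  } else {
    tallies <- data.frame(category = character(0), status = character(0),
                          n = integer(0), stringsAsFactors = FALSE)
  }
  rownames(tallies) <- NULL

  structure(list(decisions = decisions, tallies = tallies, duplex_calls = calls,
                 effects = effects, knockdown = kd, thresholds = thresholds, qc = qc),
            class = "screen_calls")
}

#' Pipeline parameters for [call_screen()]
#'
#' @param anchor_reagent reagent_id of the positive-control anchor
#'   (default `"siPCM1-1"`, the id used by the packaged fixture and the
#'   simulator)
#' @param k_sd negative-control SD multiple for threshold calibration
#' @param knockdown_cutoff maximum mean fraction of transcript remaining
#'   scored as knockdown (default 0.60)
#' @param min_effective minimum effective duplexes for genes probed by more
#'   than two round-1 duplexes
#' @export
screen_call_config <- function(anchor_reagent = "siPCM1-1", k_sd = 4,
                               knockdown_cutoff = 0.60, min_effective = 2L) {
  stopifnot(k_sd > 0, knockdown_cutoff > 0, min_effective >= 1)
  list(anchor_reagent = anchor_reagent, k_sd = k_sd,
       knockdown_cutoff = knockdown_cutoff, min_effective = as.integer(min_effective))
}

#' @export
print.screen_calls <- function(x, ...) {
  n <- table(factor(x$decisions$status, DECISION_STATUSES))
  cat(sprintf("<screen_calls> %d genes: %d HIT_LOSS, %d HIT_GAIN, %d pending, %d negative\n",
              nrow(x$decisions), n[["HIT_LOSS"]], n[["HIT_GAIN"]],
              n[["ROUND2_PENDING"]], n[["NEGATIVE"]]))
  print(x$thresholds)
  if (length(x$qc) > 0L) cat(sprintf("  QC notes: %d\n", length(x$qc)))
  invisible(x)
}
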