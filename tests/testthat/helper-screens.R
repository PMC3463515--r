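# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except the packaged outcome table.

# minimal deterministic screen: 2 scrambled duplexes with slightly different
# fixed counts (nonzero negative-control dispersion), an anchor positive
# control at ~0.65x, and candidate genes supplied as a list:
#   genes = list(GENE = list(category=, ratios=c(d1, d2), kd=c(TRUE, FALSE)))
# kd NA means "no qPCR measurement for that duplex"
make_screen <- function(genes = list(), n_exp = 5L, cells = 160L) {
  scr1 <- c(88L, 90L, 86L, 89L, 87L)[seq_len(n_exp)]
  scr2 <- c(86L, 88L, 90L, 85L, 91L)[seq_len(n_exp)]
  base <- (scr1 + scr2) / 2
  experiments <- sprintf("exp%d", seq_len(n_exp))
  layout <- data.frame(reagent_id = c("siScr-1", "siScr-2", "siPCM1-1"),
                       gene = c(NA, NA, "PCM1"),
                       reagent_class = c("SCRAMBLED_CONTROL", "SCRAMBLED_CONTROL",
                                         "POSITIVE_CONTROL"),
                       round = 1L, category = "CONTROL", stringsAsFactors = FALSE)
  counts <- data.frame(
    experiment_id = rep(experiments, 3),
    reagent_id = rep(c("siScr-1", "siScr-2", "siPCM1-1"), each = n_exp),
    ciliated_count = c(scr1, scr2, as.integer(round(0.65 * base))),
    total_count = cells, stringsAsFactors = FALSE)
  qpcr <- data.frame(reagent_id = "siPCM1-1", mode = "PERCENT_REMAINING",
                     replicate = 1:3, value = c(28, 30, 32),
                     reference_value = NA_real_, control_link = NA_character_,
                     stringsAsFactors = FALSE)
  for (g in names(genes)) {
    spec <- genes[[g]]
    rnd <- if (is.null(spec$round)) rep(1L, length(spec$ratios)) else spec$round
    for (d in seq_along(spec$ratios)) {
      id <- sprintf("si%s-%d", g, d)
      layout <- rbind(layout, data.frame(reagent_id = id, gene = g,
                                         reagent_class = "SIRNA", round = rnd[d],
                                         category = spec$category %||% "COMMON_VARIANT",
                                         stringsAsFactors = FALSE))
      counts <- rbind(counts, data.frame(
        experiment_id = experiments, reagent_id = id,
        ciliated_count = as.integer(round(spec$ratios[d] * base)),
        total_count = cells, stringsAsFactors = FALSE))
      if (!is.na(spec$kd[d])) {
        vals <- if (spec$kd[d]) c(28, 30, 32) else c(92, 95, 98)
        qpcr <- rbind(qpcr, data.frame(reagent_id = id, mode = "PERCENT_REMAINING",
                                       replicate = 1:3, value = vals,
                                       reference_value = NA_real_,
                                       control_link = NA_character_,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  build_screen(layout, counts, qpcr, min_cells = 150L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a duplex-call row directly (for automaton unit/property tests)
make_call <- function(phenotype, kd, reagent_id = "siX-1") {
  data.frame(reagent_id = reagent_id, mean_normalized = NA_real_,
             phenotype = phenotype, knockdown_positive = kd,
             effective = phenotype != "NONE" & !is.na(kd) & kd,
             stringsAsFactors = FALSE)
}

# hand-written round-1 truth table: every combination of
# (phenotype in {L, G, N}) x (knockdown in {T, F}) for two duplexes,
# enumerated independently of the implementation from the published
# decision rules ("both duplexes ... hit; only one effective and only this
# duplex knocked down ... second round; all other outcomes negative").
round1_truth_table <- function() {
  txt <- "
L T L T HIT_LOSS
L T L F NEGATIVE
L T G T NEGATIVE
L T G F NEGATIVE
L T N T NEGATIVE
L T N F ROUND2_PENDING
L F L T NEGATIVE
L F L F NEGATIVE
L F G T NEGATIVE
L F G F NEGATIVE
L F N T NEGATIVE
L F N F NEGATIVE
G T L T NEGATIVE
G T L F NEGATIVE
G T G T HIT_GAIN
G T G F NEGATIVE
G T N T NEGATIVE
G T N F ROUND2_PENDING
G F L T NEGATIVE
G F L F NEGATIVE
G F G T NEGATIVE
G F G F NEGATIVE
G F N T NEGATIVE
G F N F NEGATIVE
N T L T NEGATIVE
N T L F NEGATIVE
N T G T NEGATIVE
N T G F NEGATIVE
N T N T NEGATIVE
N T N F NEGATIVE
N F L T ROUND2_PENDING
N F L F NEGATIVE
N F G T ROUND2_PENDING
N F G F NEGATIVE
N F N T NEGATIVE
N F N F NEGATIVE"
  tab <- utils::read.table(text = txt, col.names = c("ph1", "kd1", "ph2", "kd2", "expected"),
                           colClasses = "character", stringsAsFactors = FALSE)
  ph <- c(L = "LOSS", G = "GAIN", N = "NONE")
  tab$ph1 <- ph[tab$ph1]; tab$ph2 <- ph[tab$ph2]
  tab$kd1 <- tab$kd1 == "T"; tab$kd2 <- tab$kd2 == "T"
  tab
}
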