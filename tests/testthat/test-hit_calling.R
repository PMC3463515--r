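thresholds_unit <- calibrate_thresholds(c(0.95, 1.00, 1.05), anchor = 0.65, k_sd = 4)

test_that("classify_duplex applies thresholds with the tie rule", {
  eff <- function(mn) data.frame(reagent_id = "siX-1", mean_normalized = mn)
  kd_pos <- data.frame(reagent_id = "siX-1", knockdown_positive = TRUE)
  kd_neg <- data.frame(reagent_id = "siX-1", knockdown_positive = FALSE)

  call <- classify_duplex(eff(0.25), kd_pos, thresholds_unit)
  expect_identical(call$phenotype, "LOSS")
  expect_true(call$effective)

  call <- classify_duplex(eff(1.00), kd_neg, thresholds_unit)
  expect_identical(call$phenotype, "NONE")
  expect_false(call$effective)

  # exactly at a threshold counts as crossing: the anchor scores against itself
  expect_identical(classify_duplex(eff(0.65), kd_pos, thresholds_unit)$phenotype, "LOSS")
  expect_identical(classify_duplex(eff(thresholds_unit$gain_threshold), kd_pos,
                                   thresholds_unit)$phenotype, "GAIN")
  expect_identical(classify_duplex(eff(0.6500001), kd_pos, thresholds_unit)$phenotype, "NONE")

  # unmeasured knockdown propagates as NA and never counts as effective
  call <- classify_duplex(eff(0.25), NULL, thresholds_unit)
  expect_true(is.na(call$knockdown_positive))
  expect_false(call$effective)
})

test_that("round-1 automaton matches the hand-written truth table on all 36 combinations", {
  tab <- round1_truth_table()
  for (i in seq_len(nrow(tab))) {
    calls <- rbind(make_call(tab$ph1[i], tab$kd1[i], "siX-1"),
                   make_call(tab$ph2[i], tab$kd2[i], "siX-2"))
    got <- decide_gene_round1(calls, gene = "X")
    expect_identical(got$status, tab$expected[i],
                     label = sprintf("combo %d (%s/%s %s/%s): %s", i,
                                     tab$ph1[i], tab$kd1[i], tab$ph2[i], tab$kd2[i],
                                     got$status))
    # order of the two duplexes never matters
    got_rev <- decide_gene_round1(calls[2:1, ], gene = "X")
    expect_identical(got_rev$status, got$status)
  }
})

test_that("unverified knockdown on a phenotype-positive duplex is a located negative", {
  calls <- rbind(make_call("LOSS", NA), make_call("LOSS", TRUE, "siX-2"))
  got <- decide_gene_round1(calls, gene = "X")
  expect_identical(got$status, "NEGATIVE")
  expect_match(got$rationale, "unverified knockdown")
  expect_error(decide_gene_round1(calls[1, , drop = FALSE]), "exactly 2")
})

test_that("round 2 requires both fresh duplexes effective in the pending direction", {
  pending <- decide_gene_round1(rbind(make_call("LOSS", TRUE),
                                      make_call("NONE", FALSE, "siX-2")), gene = "X")
  expect_identical(pending$status, "ROUND2_PENDING")
  expect_identical(pending$direction, "LOSS")

  ok <- rbind(make_call("LOSS", TRUE, "siX-3"), make_call("LOSS", TRUE, "siX-4"))
  dec <- decide_gene_round2(pending, ok)
  expect_identical(dec$status, "HIT_LOSS")
  expect_identical(dec$decided_in_round, 2L)

  partial <- rbind(make_call("LOSS", TRUE, "siX-3"), make_call("NONE", TRUE, "siX-4"))
  expect_identical(decide_gene_round2(pending, partial)$status, "NEGATIVE")
  none <- rbind(make_call("NONE", TRUE, "siX-3"), make_call("NONE", TRUE, "siX-4"))
  expect_identical(decide_gene_round2(pending, none)$status, "NEGATIVE")
  # gain-direction round 2 must confirm gain, not loss
  wrong_dir <- rbind(make_call("GAIN", TRUE, "siX-3"), make_call("GAIN", TRUE, "siX-4"))
  expect_identical(decide_gene_round2(pending, wrong_dir)$status, "NEGATIVE")

  decided <- decide_gene_round1(rbind(make_call("LOSS", TRUE),
                                      make_call("LOSS", TRUE, "siX-2")), gene = "X")
  expect_error(decide_gene_round2(decided, ok), "not pending")
})

test_that("call_screen wires rounds together and errors on stray round-2 data", {
  scr <- make_screen(genes = list(
    HITR1 = list(ratios = c(0.30, 0.30), kd = c(TRUE, TRUE)),
    SPLIT = list(ratios = c(0.30, 1.00, 0.30, 0.30), kd = c(TRUE, FALSE, TRUE, TRUE),
                 round = c(1L, 1L, 2L, 2L)),
    FAILR2 = list(ratios = c(0.30, 1.00, 0.85, 0.85), kd = c(TRUE, FALSE, TRUE, TRUE),
                  round = c(1L, 1L, 2L, 2L)),
    NEG = list(ratios = c(0.30, 1.00), kd = c(TRUE, TRUE))))
  res <- call_screen(scr)
  dec <- res$decisions
  expect_identical(dec$status[dec$gene == "HITR1"], "HIT_LOSS")
  expect_identical(dec$decided_in_round[dec$gene == "HITR1"], 1L)
  expect_identical(dec$status[dec$gene == "SPLIT"], "HIT_LOSS")
  expect_identical(dec$decided_in_round[dec$gene == "SPLIT"], 2L)
  expect_identical(dec$status[dec$gene == "FAILR2"], "NEGATIVE")
  expect_identical(dec$decided_in_round[dec$gene == "FAILR2"], 2L)
  expect_identical(dec$status[dec$gene == "NEG"], "NEGATIVE")

  # round-2 reagents for a gene that is not a round-1 split
  bad <- make_screen(genes = list(
    SOLID = list(ratios = c(0.30, 0.30, 0.30, 0.30), kd = c(TRUE, TRUE, TRUE, TRUE),
                 round = c(1L, 1L, 2L, 2L))))
  expect_error(call_screen(bad), "not pending")

  # a pending gene with no round-2 data stays pending and is logged
  open_split <- make_screen(genes = list(
    SPLIT = list(ratios = c(0.30, 1.00), kd = c(TRUE, FALSE))))
  res2 <- call_screen(open_split)
  expect_identical(res2$decisions$status, "ROUND2_PENDING")
  expect_match(res2$qc, "pending", all = FALSE)
})

test_that("genes with more than two round-1 duplexes use the generalized rule", {
  scr <- make_screen(genes = list(
    TRIO = list(ratios = c(0.30, 0.30, 1.00), kd = c(TRUE, TRUE, FALSE)),
    DISC = list(ratios = c(0.30, 0.30, 1.00), kd = c(TRUE, TRUE, TRUE))))
  res <- call_screen(scr)
  expect_identical(res$decisions$status[res$decisions$gene == "TRIO"], "HIT_LOSS")
  # a silent duplex that nevertheless knocked down expression is discordant
  expect_identical(res$decisions$status[res$decisions$gene == "DISC"], "NEGATIVE")
})

test_that("decisions and rationale traces are deterministic", {
  scr <- make_screen(genes = list(
    AAA = list(ratios = c(0.30, 0.30), kd = c(TRUE, TRUE)),
    BBB = list(ratios = c(0.30, 1.00), kd = c(TRUE, FALSE))))
  r1 <- suppressWarnings(call_screen(scr))
  r2 <- suppressWarnings(call_screen(scr))
  expect_identical(r1$decisions, r2$decisions)
  expect_identical(r1$tallies, r2$tallies)
})
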