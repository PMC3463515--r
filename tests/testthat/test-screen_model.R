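test_that("screen files round-trip through write_screen/read_screen", {
  scr <- make_screen(genes = list(AAA = list(ratios = c(0.3, 0.3), kd = c(TRUE, TRUE))))
  dir <- withr::local_tempdir()
  write_screen(scr, dir)
  back <- read_screen(file.path(dir, "counts.csv"), file.path(dir, "layout.csv"),
                      qpcr = file.path(dir, "qpcr.csv"))
  expect_identical(back$layout, scr$layout)
  expect_identical(back$counts, scr$counts)
  expect_equal(back$qpcr, scr$qpcr)
})

test_that("malformed rows produce located errors, never silent drops", {
  scr <- make_screen()
  bad <- scr$counts
  bad$ciliated_count[7] <- bad$total_count[7] + 40L
  expect_error(build_screen(scr$layout, bad, scr$qpcr), "counts row 7.*exceeds total_count")

  orphan <- rbind(scr$counts,
                  data.frame(experiment_id = "exp1", reagent_id = "siGhost-1",
                             ciliated_count = 10L, total_count = 160L))
  expect_error(build_screen(scr$layout, orphan), "row 16.*siGhost-1.*not present in layout")

  lay <- scr$layout
  lay$gene[lay$reagent_id == "siScr-1"] <- "OOPS"
  expect_error(build_screen(lay, scr$counts), "scrambled control must not carry a gene")

  qp <- scr$qpcr
  qp$mode[1] <- "MAGIC"
  expect_error(build_screen(scr$layout, scr$counts, qp), "unknown mode 'MAGIC'")
})

test_that("low cell counts raise a QC warning, not an error", {
  scr <- make_screen()
  low <- scr$counts
  low$total_count[low$reagent_id == "siScr-1"][1] <- 120L
  low$ciliated_count[low$reagent_id == "siScr-1"][1] <- 66L
  expect_warning(s2 <- build_screen(scr$layout, low, scr$qpcr), "QC warning")
  expect_length(s2$qc, 1L)
  expect_match(s2$qc, "counted 120 cells")
})

test_that("layout invariants: duplicates, round-1 coverage, gene categories", {
  scr <- make_screen(genes = list(AAA = list(ratios = c(0.3, 0.3), kd = c(TRUE, TRUE))))
  lay <- rbind(scr$layout, scr$layout[3, ])
  expect_error(build_screen(lay, scr$counts), "duplicate reagent_id")

  lay <- scr$layout
  lay$round[lay$reagent_id == "siAAA-2"] <- 2L
  expect_error(build_screen(lay, scr$counts), "fewer than 2 round-1 reagents")

  lay <- scr$layout
  lay2 <- rbind(lay, data.frame(reagent_id = "siBBB-3", gene = "BBB",
                                reagent_class = "SIRNA", round = 2L,
                                category = "RARE_VARIANT"))
  expect_error(build_screen(lay2, scr$counts), "round-2 reagents but no round-1")
})

test_that("gene names match case-insensitively but are case-preserving", {
  scr <- make_screen()
  lay <- rbind(scr$layout,
               data.frame(reagent_id = c("siSyne1-1", "siSYNE1-2"),
                          gene = c("Syne1", "SYNE1"), reagent_class = "SIRNA",
                          round = 1L, category = "DISC1_INTERACTOR"))
  cts <- rbind(scr$counts,
               data.frame(experiment_id = rep(sprintf("exp%d", 1:5), 2),
                          reagent_id = rep(c("siSyne1-1", "siSYNE1-2"), each = 5),
                          ciliated_count = 26L, total_count = 160L))
  s2 <- build_screen(lay, cts)
  expect_identical(nrow(s2$genes), 1L)
  expect_identical(s2$genes$gene, "Syne1")  # first-seen spelling kept
})

test_that("results tree round-trips the full decision set", {
  scr <- make_screen(genes = list(
    AAA = list(ratios = c(0.30, 0.30), kd = c(TRUE, TRUE)),
    BBB = list(ratios = c(1.00, 1.00), kd = c(TRUE, NA))))
  calls <- call_screen(scr)
  dir <- withr::local_tempdir()
  write_results(calls, dir)
  expect_true(all(file.exists(file.path(dir, c("results.json", "summary.tsv",
                                               "tallies.tsv", "qc_log.txt")))))
  back <- read_results(dir)
  expect_identical(back$decisions$gene, calls$decisions$gene)
  expect_identical(back$decisions$status, calls$decisions$status)
  expect_identical(back$decisions$rationale, calls$decisions$rationale)
  expect_equal(back$decisions$decided_in_round, calls$decisions$decided_in_round)
  expect_equal(back$thresholds$loss_threshold, calls$thresholds$loss_threshold)
  expect_equal(back$effects$mean_normalized, calls$effects$summary$mean_normalized)
})

test_that("a controls-only screen yields an empty but valid result", {
  scr <- make_screen()
  calls <- call_screen(scr)
  expect_identical(nrow(calls$decisions), 0L)
  dir <- withr::local_tempdir()
  write_results(calls, dir)
  expect_identical(nrow(read_results(dir)$decisions), 0L)
})
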