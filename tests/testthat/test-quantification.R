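test_that("percent_ciliation is the ciliated fraction with guarded domain", {
  expect_identical(percent_ciliation(0L, 150L), 0)
  expect_equal(percent_ciliation(83L, 150L), 83 / 150)
  expect_equal(percent_ciliation(c(10L, 20L), c(100L, 160L)), c(0.1, 0.125))
  expect_error(percent_ciliation(1L, 0L), "total_count <= 0")
  expect_error(percent_ciliation(5L, 4L), "ciliated_count")
})

test_that("a condition identical to its control normalizes to exactly 1", {
  # both scrambled duplexes share every count, and the candidate copies them
  experiments <- sprintf("exp%d", 1:5)
  base <- c(88L, 90L, 86L, 89L, 87L)
  lay <- data.frame(reagent_id = c("siScr-1", "siScr-2", "siAAA-1", "siAAA-2"),
                    gene = c(NA, NA, "AAA", "AAA"),
                    reagent_class = c("SCRAMBLED_CONTROL", "SCRAMBLED_CONTROL",
                                      "SIRNA", "SIRNA"),
                    round = 1L, category = c("CONTROL", "CONTROL", "RARE_VARIANT",
                                             "RARE_VARIANT"))
  cts <- data.frame(experiment_id = rep(experiments, 4),
                    reagent_id = rep(lay$reagent_id, each = 5),
                    ciliated_count = rep(base, 4), total_count = 160L)
  eff <- normalize_to_control(build_screen(lay, cts))
  expect_equal(eff$summary$mean_normalized, rep(1, 4))
  expect_equal(eff$per_experiment$normalized, rep(1, 20))
})

test_that("normalization is per-experiment first and scale-invariant", {
  scr <- make_screen(genes = list(AAA = list(ratios = c(0.4, 0.4), kd = c(TRUE, TRUE))))
  eff1 <- normalize_to_control(scr)
  # triple every count in experiment 3: ratios must not move
  cts <- scr$counts
  i <- cts$experiment_id == "exp3"
  cts$ciliated_count[i] <- cts$ciliated_count[i] * 3L
  cts$total_count[i] <- cts$total_count[i] * 3L
  eff2 <- normalize_to_control(suppressWarnings(build_screen(scr$layout, cts, scr$qpcr)))
  expect_equal(eff2$summary$mean_normalized, eff1$summary$mean_normalized)
  expect_equal(eff2$summary$sem, eff1$summary$sem)
  expect_equal(eff1$summary$reduction, 1 - eff1$summary$mean_normalized)
  expect_equal(eff1$summary$sem,
               eff1$summary$sd_across_experiments / sqrt(eff1$summary$n_experiments))
})

test_that("experiments without usable control data are excluded and logged", {
  scr <- make_screen(genes = list(AAA = list(ratios = c(0.4, 0.4), kd = c(TRUE, TRUE))))
  cts <- scr$counts[!(scr$counts$experiment_id == "exp5" &
                        grepl("^siScr", scr$counts$reagent_id)), ]
  eff <- normalize_to_control(build_screen(scr$layout, cts, scr$qpcr))
  expect_match(eff$qc, "exp5 excluded", all = FALSE)
  expect_true(all(eff$summary$n_experiments == 4L))

  zero <- scr$counts
  zero$ciliated_count[zero$experiment_id == "exp2" & grepl("^siScr", zero$reagent_id)] <- 0L
  eff0 <- normalize_to_control(build_screen(scr$layout, zero, scr$qpcr))
  expect_match(eff0$qc, "exp2 excluded: control percent ciliation is zero", all = FALSE)
  expect_true(all(eff0$summary$n_experiments == 4L))
})

test_that("delta-delta-Ct knockdown matches hand arithmetic", {
  ct_fixture <- function(tgt, ref) {
    rbind(
      data.frame(reagent_id = "siAAA-1", mode = "CT", replicate = 1:3, value = tgt,
                 reference_value = ref, control_link = "siScr-1"),
      data.frame(reagent_id = "siScr-1", mode = "CT", replicate = 1:3,
                 value = c(21.0, 21.2, 21.1), reference_value = c(17.9, 18.0, 17.8),
                 control_link = NA_character_))
  }
  # dCt identical to the scrambled calibrator -> 2^0 = 100% remaining
  q <- ct_fixture(c(21.1, 21.2, 21.3), c(17.9, 18.0, 18.1))
  res <- quantify_knockdown(q, "siAAA-1")
  expect_equal(res$percent_remaining_mean, 1.0)
  expect_false(res$knockdown_positive)
  # ddCt = +1 in every replicate -> 50% remaining
  q <- ct_fixture(c(22.1, 22.2, 22.3), c(17.9, 18.0, 18.1))
  expect_equal(quantify_knockdown(q, "siAAA-1")$percent_remaining_mean, 0.5)
  # spreadsheet oracle, frozen: dCt = (6.3, 6.4, 6.3), calibrator mean 3.2,
  # RQ = 2^-(3.1, 3.2, 3.1)
  q <- ct_fixture(c(24.1, 24.3, 24.0), c(17.8, 17.9, 17.7))
  res <- quantify_knockdown(q, "siAAA-1")
  expect_equal(res$percent_remaining_mean, 0.114025689432072, tolerance = 1e-12)
  expect_equal(res$percent_remaining_sd, 0.004509280845548, tolerance = 1e-12)
  expect_true(res$knockdown_positive)
})

test_that("knockdown modes: percent pass-through, activity flag, errors", {
  q <- data.frame(reagent_id = "siAAA-1", mode = "PERCENT_REMAINING",
                  replicate = 1:3, value = c(28, 30, 32),
                  reference_value = NA_real_, control_link = NA_character_)
  res <- quantify_knockdown(q, "siAAA-1")
  expect_equal(res$percent_remaining_mean, 0.30)
  expect_true(res$knockdown_positive)
  expect_false(quantify_knockdown(q, "siAAA-1", cutoff = 0.25)$knockdown_positive)

  act <- data.frame(reagent_id = "mimX-1", mode = "ACTIVITY", replicate = 1,
                    value = 1, reference_value = NA_real_, control_link = NA_character_)
  res <- quantify_knockdown(act, "mimX-1")
  expect_true(res$knockdown_positive)
  expect_true(is.na(res$percent_remaining_mean))

  expect_error(quantify_knockdown(q, "siMissing-1"), "no qPCR data")
  expect_error(quantify_knockdown(q[1:2, ], "siAAA-1"), "need >= 3")
  ct <- data.frame(reagent_id = "siAAA-1", mode = "CT", replicate = 1:3,
                   value = c(24, 24, 24), reference_value = NA_real_,
                   control_link = "siScr-1")
  expect_error(quantify_knockdown(ct, "siAAA-1"), "reference Ct")
})

test_that("mean_normalized is consistent for a known simulated effect", {
  # large cells-per-condition and many experiments: the ratio estimator
  # converges on the realized per-duplex effect
  cfg <- simulation_config(n_genes = c(EFF = 2L), true_effects = c(EFF = 0.6),
                           n_experiments = 25L, cells_per_condition = 5000L,
                           kd_active_range = c(0.2, 0.35),  # full effect region
                           simulate_lengths = FALSE, seed = 42)
  sim <- simulate_screen(cfg)
  eff <- normalize_to_control(sim$screen)
  duplexes <- eff$summary[eff$summary$reagent_class == "SIRNA", ]
  realized <- sim$truth$realized_effect[match(duplexes$reagent_id, sim$truth$reagent_id)]
  expect_equal(realized, rep(0.6, 4))
  expect_equal(duplexes$mean_normalized, realized, tolerance = 0.02)
})
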