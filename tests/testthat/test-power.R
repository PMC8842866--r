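truth2 <- data.frame(chromosome = c("1", "2"), position_cM = c(61.2, 20),
                     stringsAsFactors = FALSE)

test_that("interval truth labels follow the containment rule", {
  sc <- fake_scan(position = c(60, 61, 63.1, 40, 42, 45),
                  neglog10p = c(5, 5, 5, 5, 5, 5))
  iv <- call_intervals(sc, 3, l = 4)
  cls <- classify(iv, data.frame(chromosome = "1", position_cM = 61.2))
  expect_equal(cls$n_intervals, 2)
  tp_ranges <- vapply(iv$intervals[cls$interval_tp], `[[`, numeric(1), "start")
  expect_equal(tp_ranges, 60)       # [60, 63.1] contains 61.2; [40,45] not
  expect_equal(cls$n_tp_intervals, 1)
  expect_equal(length(cls$tp_markers), 3)
  expect_equal(length(cls$all_iv_markers), 6)
})

test_that("true-negative window arithmetic: 5 cM each side", {
  sc <- fake_scan(position = c(55, 61.2, 65.9, 66.3, 80),
                  neglog10p = c(0, 0, 0, 9, 9))
  iv <- call_intervals(sc, 3, l = 1)
  cls <- classify(iv, data.frame(chromosome = "1", position_cM = 61.2))
  # 65.9 (|d| = 4.7) is inside; 55, 66.3, 80 outside
  expect_equal(cls$n_true_negative, 3)
  expect_equal(cls$n_fp_rate, 2)    # significant markers at 66.3, 80
  expect_equal(false_positive_rate(cls), 2 / 3)
})

test_that("detection power counts each true QTL once", {
  sc <- fake_scan(position = c(60, 61, 62, 63), neglog10p = c(5, 5, 5, 5))
  truth3 <- data.frame(chromosome = "1", position_cM = c(61.2, 10, 40))
  # hand-built overlapping true-positive intervals: coverage counted once
  iv <- call_intervals(sc, 3, l = 2)
  iv$intervals <- list(
    list(chromosome = "1", members = 1:3, start = 60, end = 62, peak = 2),
    list(chromosome = "1", members = 2:4, start = 61, end = 63, peak = 3))
  cls <- classify(iv, truth3)
  expect_equal(sum(cls$interval_tp), 2)
  expect_equal(detection_power(cls), 1 / 3)
  # all QTLs covered -> 1; no intervals -> 0
  cls_all <- classify(call_intervals(sc, 3, 2),
                      data.frame(chromosome = "1", position_cM = 61.5))
  expect_equal(detection_power(cls_all), 1)
  iv0 <- call_intervals(sc, 30, 3)
  expect_equal(detection_power(classify(iv0, truth3)), 0)
})

test_that("precision formulas and undefined cases", {
  sc <- fake_scan(position = c(60, 61, 40, 41), neglog10p = rep(5, 4))
  iv <- call_intervals(sc, 3, l = 2)
  cls <- classify(iv, data.frame(chromosome = "1", position_cM = 60.5))
  pr <- precisions(cls)
  expect_equal(unname(pr["qtl_precision"]), 0.5)
  expect_equal(unname(pr["marker_precision"]), 0.5)
  # all significant markers inside true intervals
  cls2 <- classify(call_intervals(sc, 3, 2),
                   data.frame(chromosome = "1", position_cM = c(60.5, 40.5)))
  expect_equal(unname(precisions(cls2)["marker_precision"]), 1)
  # zero intervals: absent, not zero
  iv0 <- call_intervals(sc, 30, 2)
  expect_true(all(is.na(precisions(classify(iv0, truth2)))))
})

test_that("peak accuracy averages peak-to-truth distances over true positives", {
  sc <- fake_scan(position = c(60.2, 60.7, 61.5, 20.0, 20.5, 21),
                  chromosome = c("1", "1", "1", "2", "2", "2"),
                  neglog10p = c(4, 9, 4, 4, 9, 4))
  iv <- call_intervals(sc, 3, l = 2)
  cls <- classify(iv, truth2)
  expect_equal(peak_accuracy(iv, cls), 0.5 * (abs(60.7 - 61.2) +
                                                abs(20.5 - 20)))
  # exact peak contributes 0
  sc2 <- fake_scan(position = c(61, 61.2, 61.4), neglog10p = c(4, 9, 4))
  iv2 <- call_intervals(sc2, 3, 2)
  expect_equal(peak_accuracy(iv2, classify(iv2, truth2[1, ])), 0)
  # no true positives -> absent
  iv3 <- call_intervals(sc2, 30, 2)
  expect_true(is.na(peak_accuracy(iv3, classify(iv3, truth2))))
})

test_that("experiment driver bookkeeping and determinism", {
  cfg <- experiment_config(
    n_chrom = 2, chrom_length = 30, n_markers = 120, n_ag = 2,
    n_founders = 6, generations = 3, ag_size = 30,
    diversity_levels = 1, n_replicates = 1, models = "snp",
    l_grid = c(1, 3), n_perm = 20, n_polygenic = 4,
    offspring_per_cross = 5,
    qtl_major = data.frame(chromosome = c("1", "2"),
                           position_cM = c(15, 20)),
    seed = 99)
  ex1 <- run_experiment(cfg)
  expect_equal(nrow(ex1$results), length(cfg$l_grid))
  expect_true(all(ex1$results$model == "snp"))
  rng <- ex1$results[c("detection_power", "false_positive_rate",
                       "qtl_precision", "marker_precision")]
  expect_true(all(rng >= 0 & rng <= 1, na.rm = TRUE))
  ex2 <- run_experiment(cfg)
  expect_identical(ex1$results, ex2$results)
  expect_identical(ex1$thresholds, ex2$thresholds)
})
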