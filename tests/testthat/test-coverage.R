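test_that("FPKM follows the 3x-mean-length reference rule", {
  expect_equal(computeFPKM(0, 500, 1e6), 0)
  expect_equal(computeFPKM(10, 500, 1e6), 10 / 1.5 / 1)
  expect_equal(computeFPKM(100, 1000 / 3, 2e6), 50, tolerance = 1e-6)
  expect_error(computeFPKM(1, 500, 0), "empty library")
})

test_that("FPKM is linear in reads, inverse in length and depth", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(0:1000, 1); L <- runif(1, 50, 2000); Tt <- runif(1, 1e4, 1e7)
    f <- computeFPKM(n, L, Tt)
    expect_equal(computeFPKM(2 * n, L, Tt), 2 * f)
    expect_equal(computeFPKM(n, 2 * L, Tt), f / 2)
    expect_equal(computeFPKM(n, L, 2 * Tt), f / 2)
  }
})

test_that("panel screening counts each read once, in its best panel", {
  ps <- tinyPanelSet()
  hits <- rbind(
    mkHit("r1", "rbcL_1", "rubisco", score = 120),
    mkHit("r1", "gltA_1", "gltA", score = 80),   # suboptimal, must not count
    mkHit("r2", "rbcL_1", "rubisco", score = 100))
  best <- filterBestHits(hits)
  rep <- screenPanels(best, ps, 1e6)
  expect_equal(rep$n_reads[rep$panel_id == "rubisco"], 2L)
  expect_equal(rep$n_reads[rep$panel_id == "gltA"], 0L)
  expect_equal(rep$fpkm[rep$panel_id == "gltA"], 0)
  expect_error(screenPanels(hits, ps, 1e6), "not best-filtered")
  # zero hits: all panels zero
  rep0 <- screenPanels(filterBestHits(mkHit()[0, ]), ps, 1e6)
  expect_true(all(rep0$n_reads == 0L))
})

test_that("relative coverage normalizes by the reference median", {
  expect_equal(relativeCoverage(0, c(1, 2)), 0)
  expect_equal(relativeCoverage(1, c(1, 2, 3, 4)), 0.4)  # even-count median 2.5
  expect_equal(relativeCoverage(2, 2), 1)
  expect_error(relativeCoverage(1, c(0, 0)), "reference set not detected")
  expect_error(relativeCoverage(1, numeric(0)), "no reference")
})

test_that("absence calling applies the 50-fold rule then attribution", {
  rep <- data.frame(panel_id = c("t1", "t2", "t3", "t4", "ref"),
                    role = c("target", "target", "target", "target",
                             "reference"),
                    relative_coverage = c(0, 0.4, 1.1, 0.4, 1),
                    stringsAsFactors = FALSE)
  att <- data.frame(panel_id = c("t2", "t3"),
                    attributed_outside_fraction = c(0.9, 0.05),
                    stringsAsFactors = FALSE)
  out <- callAbsence(rep, foldThreshold = 50, attribution = att)
  expect_equal(out$call[out$panel_id == "t1"], "absent")     # <= 1/50
  expect_equal(out$call[out$panel_id == "t2"], "absent")     # majority outside
  expect_equal(out$call[out$panel_id == "t3"], "present")    # majority inside
  expect_equal(out$call[out$panel_id == "t4"], "ambiguous")  # no attribution
  expect_equal(out$call[out$panel_id == "ref"], "reference")
  # boundary: exactly 1/threshold is absent (at least 50-fold lower)
  rep$relative_coverage <- 1 / 50
  expect_equal(callAbsence(rep)$call[1], "absent")
})

test_that("expression percentiles use mid-rank percent rank", {
  mk <- function(fpkmish) data.frame(
    feature_id = paste0("f", seq_along(fpkmish)),
    mapped_fragments = fpkmish, feature_length_bp = 1000)
  p2 <- expressionPercentile(mk(c(1, 9)))
  expect_equal(p2$percentile, c(0, 100))
  p5 <- expressionPercentile(mk(c(5, 1, 9, 3, 7)))
  expect_equal(p5$percentile[p5$mapped_fragments == 5], 50)
  expect_equal(max(p5$percentile), 100)
  expect_equal(min(p5$percentile), 0)
  pt <- expressionPercentile(mk(c(4, 4, 4)))
  expect_equal(pt$percentile, c(50, 50, 50))
  expect_error(expressionPercentile(mk(1)), "at least two")
  # percentile is monotone in fpkm
  set.seed(8)
  pr <- expressionPercentile(mk(sample(100, 20)))
  expect_equal(order(pr$fpkm), order(pr$percentile))
})
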