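test_that("bead peak finding recovers generator truth within 2%", {
  lot <- bead_lot_spec()
  tab <- generate_bead_tube(lot, n_events = 20000, seed = 31)
  peaks <- find_bead_peaks(tab)
  expect_length(peaks, 4)
  expect_true(all(abs(peaks - lot$levels) / lot$levels < 0.02))
})

test_that("peak finding is invariant to event order and errors on 3 peaks", {
  lot <- bead_lot_spec()
  tab <- generate_bead_tube(lot, n_events = 4000, seed = 32)
  perm <- sample(n_events(tab))
  tab2 <- event_table(tab$exprs[perm, ], tab$keywords)
  expect_identical(find_bead_peaks(tab), find_bead_peaks(tab2))
  # 3-peak tube: drop the top-level events
  keep <- tab$labels != "Bead4"
  tab3 <- event_table(tab$exprs[keep, ], tab$keywords)
  expect_error(find_bead_peaks(tab3), "unresolvable")
})

test_that("a 400-event tube still resolves four ~100-event peaks", {
  tab <- generate_bead_tube(bead_lot_spec(), n_events = 400, seed = 33)
  peaks <- find_bead_peaks(tab)
  expect_length(peaks, 4)
  expect_true(all(diff(peaks) > 0))
})

test_that("calibration fit has closed-form solutions on exact lines", {
  lot <- bead_lot_spec(levels = c(500, 5e3, 5e4, 5e5))
  ident <- fit_calibration(lot$levels, lot)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  expect_equal(ident$r_squared, 1, tolerance = 1e-12)
  doubled <- fit_calibration(2 * lot$levels, lot)
  expect_equal(doubled$slope, 1, tolerance = 1e-12)
  expect_equal(doubled$intercept, -log10(2), tolerance = 1e-12)
})

test_that("calibration on noisy beads recovers the truth slope within 0.02", {
  lot <- bead_lot_spec()
  tab <- generate_bead_tube(lot, slope = 1.05, intercept = -0.2,
                            n_events = 20000, seed = 34)
  curve <- fit_calibration(find_bead_peaks(tab), lot)
  expect_lt(abs(curve$slope - 1.05), 0.02)
  expect_lt(abs(curve$intercept - (-0.2)), 0.1)
  expect_gt(curve$r_squared, 0.999)
})

test_that("calibration rejects invalid peak inputs and warns on poor fits", {
  lot <- bead_lot_spec()
  expect_error(fit_calibration(c(1, 2, 3), lot), "4 peak")
  expect_error(fit_calibration(c(-1, 10, 100, 1000), lot), "positive")
  expect_warning(fit_calibration(c(500, 600, 5e4, 5e5), lot), "R-squared")
})

test_that("ABC conversion is the identity on the identity curve and flags F <= 0", {
  curve <- fit_calibration(bead_lot_spec()$levels, bead_lot_spec())
  expect_equal(fluorescence_to_abc(396, curve), 396,
               ignore_attr = TRUE, tolerance = 1e-10)
  out <- fluorescence_to_abc(c(-50, 0, 100), curve)
  expect_equal(unname(out[1:2]), c(0, 0))
  expect_identical(attr(out, "below_detection"), c(TRUE, TRUE, FALSE))
})

test_that("ABC conversion is strictly monotone for positive fluorescence", {
  lot <- bead_lot_spec()
  tab <- generate_bead_tube(lot, slope = 0.97, intercept = 0.1,
                            n_events = 8000, seed = 35)
  curve <- fit_calibration(find_bead_peaks(tab), lot)
  set.seed(36)
  f <- sort(runif(500, 1e-3, 1e6))
  abc <- fluorescence_to_abc(f, curve)
  expect_true(all(diff(abc) > 0))
})

test_that("background cutoffs equal the sort-and-interpolate oracle", {
  set.seed(37)
  assignment <- rep(c("A", "B"), c(500, 100))
  abc <- c(rlnorm(500, log(50), 0.5), rlnorm(100, log(80), 0.3))
  gr <- structure(list(assignment = assignment,
                       counts = data.frame(), leaves = c("A", "B"),
                       tube_id = "t"), class = "gate_result")
  cuts <- background_cutoffs(gr, abc)
  expect_equal(cuts$cutoff_abc[cuts$code == "A"],
               oracle_quantile(abc[assignment == "A"], 0.90))
  expect_equal(cuts$cutoff_abc[cuts$code == "B"],
               oracle_quantile(abc[assignment == "B"], 0.90))
  # engineered spike vector: 90th percentile from the oracle exactly
  spike <- c(rep(0, 89), 999, rep(0, 10))
  gr2 <- structure(list(assignment = rep("S", 100), counts = data.frame(),
                        leaves = "S", tube_id = "t"),
                   class = "gate_result")
  expect_equal(background_cutoffs(gr2, spike)$cutoff_abc,
               oracle_quantile(spike, 0.90))
  # constant vector
  expect_equal(background_cutoffs(gr2, rep(100, 100))$cutoff_abc, 100)
})

test_that("the minimum-count rule omits 65-event subsets and keeps 66", {
  assignment <- rep(c("small", "ok"), c(65, 66))
  abc <- seq_along(assignment)
  gr <- structure(list(assignment = assignment, counts = data.frame(),
                       leaves = c("small", "ok"), tube_id = "t"),
                  class = "gate_result")
  cuts <- background_cutoffs(gr, abc)
  expect_identical(cuts$code, "ok")
  stats <- subset_statistics(gr, abc, abc, cuts)
  expect_identical(stats$code, "ok")
  stats_all <- subset_statistics(gr, abc, abc, cuts,
                                 drop_below_min = FALSE)
  expect_true(stats_all$below_min_count[stats_all$code == "small"])
})

test_that("subset statistics match hand-computed quantiles", {
  v <- c(1, 2, 3, 4)
  gr <- structure(list(assignment = rep("X", 4), counts = data.frame(),
                       leaves = "X", tube_id = "t"),
                  class = "gate_result")
  s <- subset_statistics(gr, v, v, min_events = 1)
  expect_equal(s$median_abc, 2.5)
  expect_equal(s$q1_abc, oracle_quantile(v, 0.25))
  expect_equal(s$q3_abc, oracle_quantile(v, 0.75))
  expect_equal(s$iqr_abc, oracle_quantile(v, 0.75) - oracle_quantile(v, 0.25))
})

test_that("percent positive responds to the cutoff and flags missing cutoffs", {
  gr <- structure(list(assignment = rep("X", 100), counts = data.frame(),
                       leaves = "X", tube_id = "t"),
                  class = "gate_result")
  abc <- seq(1, 100)
  cuts <- data.frame(code = "X", n = 100, cutoff_abc = 1000)
  s <- subset_statistics(gr, abc, abc, cuts)
  expect_equal(s$pct_positive, 0)   # all below cutoff
  cuts2 <- data.frame(code = "X", n = 100, cutoff_abc = 50)
  expect_equal(subset_statistics(gr, abc, abc, cuts2)$pct_positive, 50)
  s3 <- subset_statistics(gr, abc, abc, NULL)
  expect_true(is.na(s3$pct_positive))
})

test_that("percent positive is invariant under monotone recalibration", {
  gr <- structure(list(assignment = rep("X", 200), counts = data.frame(),
                       leaves = "X", tube_id = "t"),
                  class = "gate_result")
  set.seed(38)
  abc <- rlnorm(200, log(100), 1)
  cuts <- data.frame(code = "X", n = 200, cutoff_abc = 150)
  g <- function(x) 3 * x^1.2   # strictly monotone recalibration
  cuts_g <- transform(cuts, cutoff_abc = g(cutoff_abc))
  expect_equal(subset_statistics(gr, abc, abc, cuts)$pct_positive,
               subset_statistics(gr, abc, g(abc), cuts_g)$pct_positive)
})

test_that("resolution summary reproduces the reference panel statistics", {
  ref <- reference_background_cutoffs()
  expect_equal(nrow(ref), 27)
  res <- summarize_resolution(ref)
  expect_identical(res$median, 396)
  expect_identical(res$min, 229)
  expect_identical(res$max, 786)
  one <- summarize_resolution(data.frame(cutoff_abc = 42))
  expect_true(one$median == 42 && one$min == 42 && one$max == 42)
  set.seed(39)
  for (i in 1:20) {
    r <- summarize_resolution(data.frame(cutoff_abc = runif(sample(1:30, 1),
                                                            0, 1000)))
    expect_true(r$min <= r$median && r$median <= r$max)
  }
  expect_error(summarize_resolution(data.frame(cutoff_abc = numeric(0))),
               "empty")
})

test_that("calibration plus conversion recovers a known ABC end to end", {
  lot <- bead_lot_spec()
  beads <- generate_bead_tube(lot, n_events = 20000, seed = 40)
  curve <- fit_calibration(find_bead_peaks(beads), lot)
  tab <- generate_subset_tube("innate", 40000, seed = 41, true_abc = 10000)
  gr <- apply_template(tab, innate_template())
  abc <- fluorescence_to_abc(channel_values(tab, "PE"), curve)
  stats <- subset_statistics(gr, channel_values(tab, "PE"), abc)
  big <- stats[stats$code == "Neutrophils", ]
  expect_lt(abs(big$median_abc - 10000) / 10000, 0.05)
})
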