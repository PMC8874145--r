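test_that("demultiplexing recovers the hidden mixture labels", {
  ser <- generate_titration_series(default_titration_mixture(),
                                   dilutions = c(1 / 5), n_events = 20000,
                                   seed = 51, include_fmo = FALSE)
  tab <- ser[[1]]
  lab <- demultiplex(tab)
  ok <- !is.na(lab)
  expect_gt(mean(ok), 0.98)
  expect_gt(mean(lab[ok] == tab$labels[ok]), 0.99)
  # every mixture component is seen
  expect_setequal(unique(tab$labels), unique(lab[ok]))
})

test_that("an unstained-only tube demultiplexes entirely to Raji", {
  set.seed(52)
  m <- cbind(`FSC-A` = rep(1e5, 100), `SSC-A` = 2e4,
             TrackerBlue = rlnorm(100, log(100), 0.2),
             TrackerDeepRed = rlnorm(100, log(100), 0.2), PE = 60)
  tab <- event_table(m)
  lab <- demultiplex(tab)
  expect_true(all(lab == "Raji", na.rm = TRUE))
  expect_gt(mean(!is.na(lab)), 0.99)
})

test_that("events in the gaps between tracker regions stay unassigned", {
  # regions are [median/3, median*3): 300 falls outside both the negative
  # region [33,300) and the low region [1000,9000)
  m <- cbind(`FSC-A` = 1e5, `SSC-A` = 2e4,
             TrackerBlue = c(300, 100), TrackerDeepRed = c(100, 100),
             PE = 60)
  tab <- event_table(m)
  lab <- demultiplex(tab)
  expect_true(is.na(lab[1]))
  expect_equal(lab[2], "Raji")
})

test_that("missing tracker channel is an explicit error", {
  tab <- event_table(matrix(1, 1, 2,
                            dimnames = list(NULL, c("FSC-A", "PE"))))
  expect_error(demultiplex(tab), "TrackerBlue")
})

test_that("Stain Index is zero for identical distributions and scale-invariant", {
  set.seed(53)
  v <- rlnorm(5000, log(500), 0.4)
  expect_equal(stain_index(v, v), 0)
  pos <- rlnorm(5000, log(5000), 0.4)
  si <- stain_index(pos, v)
  expect_equal(stain_index(3.7 * pos, 3.7 * v), si, tolerance = 1e-12)
  expect_gt(si, 0)
})

test_that("Stain Index matches the hand-computed robust-SD example", {
  # 3-point vectors: quantile at 0.8413 interpolates between the 2nd and
  # 3rd order statistics with weight (n-1)*p + 1 - 2 = 0.6826
  w <- (3 - 1) * 0.8413 + 1 - 2
  neg <- c(50, 100, 100 + 100 / w)   # median 100, P84.13 = 200
  pos <- c(900, 1000, 1100)          # median 1000
  expect_equal(stain_index(pos, neg), 4.5, tolerance = 1e-10)
})

test_that("zero-spread negatives give an undefined Stain Index", {
  expect_warning(si <- stain_index(c(1, 2, 3), rep(5, 10)), "undefined")
  expect_true(is.na(si))
})

test_that("classical-SD variant is available", {
  set.seed(54)
  neg <- rnorm(2000, 100, 10)
  pos <- rnorm(2000, 300, 10)
  si_sd <- stain_index(pos, neg, method = "sd")
  expect_equal(si_sd, (median(pos) - median(neg)) / (2 * sd(neg)),
               tolerance = 1e-12)
})

test_that("titration curves follow the binding law at half-saturation", {
  kd <- 1 / 100
  mix <- default_titration_mixture(bmax_positive = 50000, kd = kd)
  ser <- generate_titration_series(mix, dilutions = c(1 / 50, kd, 1 / 200),
                                   n_events = 30000, seed = 55,
                                   include_fmo = FALSE)
  curve <- build_titration_curves(ser, dilutions = c(1 / 50, kd, 1 / 200))
  at_kd <- curve$points[curve$points$dilution == kd &
                          curve$points$cell_type == "Blood.Granulocytes", ]
  expected <- 100 + 50000 / 2   # autofluorescence + bmax/2
  expect_lt(abs(at_kd$median_pe - expected) / expected, 0.05)
})

test_that("positive-cell medians decrease with dilution; negatives stay flat", {
  mix <- default_titration_mixture()
  ser <- generate_titration_series(mix, n_events = 8000, seed = 56)
  curve <- build_titration_curves(ser)
  p <- curve$points[curve$points$cell_type == "Blood.Granulocytes", ]
  p <- p[order(-p$dilution), ]
  expect_true(all(diff(p$median_pe) < 0))
  n <- curve$points[curve$points$cell_type == "300.19", ]
  expect_lt(max(n$median_pe) / min(n$median_pe), 1.2)
  expect_false(is.null(curve$fmo))
})

test_that("curve building validates tube/dilution correspondence", {
  ser <- generate_titration_series(default_titration_mixture(),
                                   dilutions = c(1 / 5, 1 / 10),
                                   n_events = 500, seed = 57,
                                   include_fmo = FALSE)
  expect_error(build_titration_curves(ser, dilutions = c(1 / 5)),
               "2 tubes")
})

test_that("always-saturated curves recommend the most dilute titer", {
  # noiseless curve assembled directly: kd far below the weakest tested
  dil <- c(1 / 5, 1 / 10, 1 / 20, 1 / 40)
  pts <- rbind(
    data.frame(dilution = dil, cell_type = "pos",
               median_pe = c(10000, 9990, 9980, 9970),
               rsd_pe = 50, n = 1000),
    data.frame(dilution = dil, cell_type = "neg", median_pe = 100,
               rsd_pe = 20, n = 1000))
  curve <- structure(list(points = pts,
                          fmo = data.frame(cell_type = c("pos", "neg"),
                                           median_pe = c(100, 100),
                                           rsd_pe = 20, n = 1000),
                          dilutions = dil, reagent = "r"),
                     class = "titration_curve")
  rec <- select_titer(curve, "pos", "neg")
  expect_equal(rec$dilution, 1 / 40)
})

test_that("excess background steps the saturation pick one dilution lower", {
  dil <- c(1 / 5, 1 / 10, 1 / 20, 1 / 40)
  # saturated at 1/5 and 1/10 only; negative background high at 1/10
  pts <- rbind(
    data.frame(dilution = dil, cell_type = "pos",
               median_pe = c(10000, 9500, 6000, 3000),
               rsd_pe = 50, n = 1000),
    data.frame(dilution = dil, cell_type = "neg",
               median_pe = c(900, 500, 120, 100), rsd_pe = 20, n = 1000))
  curve <- structure(list(points = pts,
                          fmo = data.frame(cell_type = c("pos", "neg"),
                                           median_pe = c(100, 100),
                                           rsd_pe = 20, n = 1000),
                          dilutions = dil, reagent = "r"),
                     class = "titration_curve")
  rec <- select_titer(curve, "pos", "neg")
  expect_equal(rec$dilution, 1 / 20)
  expect_true("background_exceeded" %in% rec$flags)
})

test_that("max-SI and max-SI-minus-one differ by exactly one step", {
  ser <- generate_titration_series(default_titration_mixture(),
                                   n_events = 8000, seed = 58)
  curve <- build_titration_curves(ser)
  si <- stain_index_series(curve, "Blood.Granulocytes", "300.19")$si
  expect_equal(which.max(si), 1)  # unimodal with max at top concentration
  a <- select_titer(curve, "Blood.Granulocytes", "300.19",
                    policy = "max-SI")
  b <- select_titer(curve, "Blood.Granulocytes", "300.19",
                    policy = "max-SI-minus-one")
  ia <- match(a$dilution, curve$dilutions)
  ib <- match(b$dilution, curve$dilutions)
  expect_equal(ib - ia, 1)
})

test_that("titer selection is deterministic under event-order permutation", {
  ser <- generate_titration_series(default_titration_mixture(),
                                   dilutions = dilution_series()[1:4],
                                   n_events = 4000, seed = 59)
  perm_ser <- lapply(ser, function(tab) {
    p <- sample(n_events(tab))
    event_table(tab$exprs[p, ], tab$keywords, tab$labels[p])
  })
  c1 <- build_titration_curves(ser, dilutions = dilution_series()[1:4])
  c2 <- build_titration_curves(perm_ser,
                               dilutions = dilution_series()[1:4])
  r1 <- select_titer(c1, "Blood.Granulocytes", "300.19")
  r2 <- select_titer(c2, "Blood.Granulocytes", "300.19")
  expect_identical(r1$dilution, r2$dilution)
})

test_that("clone benchmarking flags a low clone on the affected subsets only", {
  codes_t <- c("Tgd", "CD4 naive", "CD8 naive")
  codes_b <- c("B naive")
  mk <- function(abc_t, abc_b) {
    data.frame(code = c(codes_t, codes_b),
               n = 1000, median_pe = 1,
               median_abc = c(rep(abc_t, 3), abc_b))
  }
  stats <- list(SK7 = mk(70000, 500), UCHT1 = mk(72000, 500),
                TB3 = mk(80000, 500), `MEM-57` = mk(70000 * 0.45, 500))
  out <- benchmark_clones(stats)
  flagged <- out$table[out$table$flagged, ]
  expect_setequal(unique(flagged$clone), "MEM-57")
  expect_setequal(flagged$code, codes_t)
  # pairwise ratios are reciprocal by construction
  pw <- out$pairwise
  i <- which(pw$code == "Tgd" & pw$clone_a == "SK7" & pw$clone_b == "TB3")
  expect_equal(pw$ratio[i], 70000 / 80000)
})

test_that("single-clone benchmarking yields no comparisons or flags", {
  one <- list(SK7 = data.frame(code = "Tgd", n = 10, median_pe = 1,
                               median_abc = 1000))
  out <- benchmark_clones(one)
  expect_equal(nrow(out$pairwise), 0)
  expect_false(any(out$table$flagged))
})

test_that("benchmarking requires overlapping subsets", {
  a <- data.frame(code = "Tgd", median_abc = 1)
  b <- data.frame(code = "B naive", median_abc = 1)
  expect_error(benchmark_clones(list(a = a, b = b)), "share no")
})
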