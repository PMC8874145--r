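test_that("empty tube has the channel header and no events", {
  chs <- c("FSC-A", "FSC-H", "SSC-A", "PE")
  tab <- generate_tube(
    list(population_spec("p", 1, c(`FSC-A` = 1e5, `SSC-A` = 2e4, PE = 500))),
    chs, n_events = 0, seed = 1)
  expect_equal(n_events(tab), 0)
  expect_identical(channels(tab), chs)
  expect_length(tab$labels, 0)
})

test_that("population mixing is multinomial in the given fractions", {
  n <- 100000
  tab <- generate_tube(
    list(population_spec("a", 0.3, c(`FSC-A` = 1e5, PE = 100)),
         population_spec("b", 0.7, c(`FSC-A` = 1e5, PE = 10000))),
    c("FSC-A", "PE"), n, seed = 42)
  n_a <- sum(tab$labels == "a")
  sd_binom <- sqrt(n * 0.3 * 0.7)
  expect_lt(abs(n_a - 0.3 * n), 3 * sd_binom)
})

test_that("log-normal fluorescence has median at the location parameter", {
  tab <- generate_tube(
    list(population_spec("p", 1, c(`FSC-A` = 1e5, PE = 10000),
                         channel_cvs = c(PE = 0.2))),
    c("FSC-A", "PE"), 50000, seed = 7)
  expect_lt(abs(median(tab$exprs[, "PE"]) - 10000) / 10000, 0.01)
})

test_that("per-population medians converge to spec locations", {
  pops <- list(
    population_spec("dim", 0.5, c(`FSC-A` = 1.2e5, `SSC-A` = 1.5e4,
                                  PE = 300)),
    population_spec("bright", 0.5, c(`FSC-A` = 1.6e5, `SSC-A` = 6e4,
                                     PE = 20000)))
  tab <- generate_tube(pops, c("FSC-A", "FSC-H", "SSC-A", "PE"), 50000,
                       seed = 11)
  for (p in pops) {
    sel <- tab$labels == p$name
    for (ch in names(p$channel_locations)) {
      expect_lt(abs(median(tab$exprs[sel, ch]) - p$channel_locations[[ch]]) /
                  p$channel_locations[[ch]], 0.01)
    }
  }
})

test_that("generation is deterministic in the seed and labels cover all events", {
  pops <- default_innate_populations()
  a <- generate_tube(pops, innate_panel_channels(), 5000, seed = 3)
  b <- generate_tube(pops, innate_panel_channels(), 5000, seed = 3)
  c <- generate_tube(pops, innate_panel_channels(), 5000, seed = 4)
  expect_identical(a$exprs, b$exprs)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$exprs, c$exprs))
  expect_false(any(is.na(a$labels)))
  expect_length(a$labels, n_events(a))
})

test_that("invalid specs are rejected", {
  expect_error(generate_tube(
    list(population_spec("p", 0.6, c(`FSC-A` = 1e5))),
    c("FSC-A"), 10, 1), "sum")
  expect_error(generate_tube(
    list(population_spec("p", 1, c(`FSC-A` = 1e5, Nope = 5))),
    c("FSC-A"), 10, 1), "unknown channel")
  expect_error(population_spec("p", 1, c(PE = 100), channel_cvs = -0.1),
               "CV")
  expect_error(population_spec("p", 1, c(PE = 100), true_abc = -5),
               "true_abc")
})

test_that("bead tube peaks sit on the truth line", {
  lot <- bead_lot_spec()
  tab <- generate_bead_tube(lot, slope = 1, intercept = 0,
                            n_events = 20000, seed = 5)
  for (i in 1:4) {
    med <- median(tab$exprs[tab$labels == paste0("Bead", i), "PE"])
    expect_lt(abs(med - lot$levels[i]) / lot$levels[i], 0.02)
  }
})

test_that("overlapping bead peaks warn but do not fail", {
  lot <- bead_lot_spec(levels = c(100, 150, 200, 300), peak_cv = 0.4)
  expect_warning(generate_bead_tube(lot, n_events = 1000, seed = 1),
                 "overlap")
})

test_that("bead lot requires 4 ascending levels", {
  expect_error(bead_lot_spec(levels = c(1, 2, 3)), "4 levels")
  expect_error(bead_lot_spec(levels = c(500, 400, 600, 700)),
               "increasing")
})

test_that("binding law: half-saturation and saturation limit", {
  m <- binding_model(bmax = 50000, kd = 0.01)
  expect_equal(bound_abc(m, 0.01), 25000)
  m2 <- binding_model(bmax = 50000, kd = 0.01, ns_slope = 1000)
  big <- 1e6
  expect_lt(abs((bound_abc(m2, big) - 1000 * big) - 50000), 1)
})

test_that("negative-control cell line stays at autofluorescence across dilutions", {
  mix <- default_titration_mixture()
  dil <- dilution_series()[c(1, 4, 8)]
  ser <- generate_titration_series(mix, dilutions = dil, n_events = 6000,
                                   seed = 9, include_fmo = FALSE)
  af <- 50  # 300.19 autofluorescence in the default mixture
  for (tab in ser) {
    med <- median(tab$exprs[tab$labels == "300.19", "PE"])
    expect_lt(abs(med - af) / af, 0.10)
  }
})

test_that("titration series validates inputs", {
  mix <- default_titration_mixture()
  bad <- barcode_scheme(cell_types = c("A", "B"),
                        blue = c("high", "low"),
                        deepred = c("negative", "negative"))
  expect_error(generate_titration_series(mix, scheme = bad,
                                         n_events = 10, seed = 1),
               "missing barcode")
  expect_error(generate_titration_series(mix, dilutions = c(0.1, 0.2),
                                         n_events = 10, seed = 1),
               "decreasing")
})

test_that("barcode scheme rejects duplicate tracker combinations", {
  expect_error(barcode_scheme(cell_types = c("A", "B"),
                              blue = c("high", "high"),
                              deepred = c("low", "low")),
               "not unique")
})

test_that("doublets get summed signals and fall outside the singlet band", {
  pops <- list(population_spec("p", 1, c(`FSC-A` = 1e5, PE = 500)))
  tab <- generate_tube(pops, c("FSC-A", "FSC-H", "PE"), 10000, seed = 2,
                       doublet_fraction = 0.05)
  doub <- tab$labels == "Doublet"
  expect_equal(sum(doub), 500)
  ratio <- tab$exprs[doub, "FSC-A"] / tab$exprs[doub, "FSC-H"]
  expect_gt(mean(ratio > 1.15), 0.99)
})

test_that("generator-applied spillover is an exact right-multiplication", {
  sp <- spillover_matrix(matrix(c(1, 0.1, 0.05, 1), 2, 2,
                                dimnames = list(c("PE", "FITC"),
                                                c("PE", "FITC"))))
  pops <- list(population_spec("p", 1, c(`FSC-A` = 1e5, PE = 1000,
                                         FITC = 2000)))
  chs <- c("FSC-A", "PE", "FITC")
  truth <- generate_tube(pops, chs, 500, seed = 6)
  obs <- generate_tube(pops, chs, 500, seed = 6, spillover = sp)
  expect_equal(obs$exprs[, c("PE", "FITC")],
               truth$exprs[, c("PE", "FITC")] %*% unclass(sp),
               tolerance = 1e-12)
})
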