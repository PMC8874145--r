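#' Panel channel lists and default gate cuts
#'
#' The two backbone panels identify 27 leukocyte subsets: an innate tube
#' (granulocytes, monocytes, dendritic cells, ILCs, NK cells; 12 leaf
#' subsets) and an adaptive tube (T and B cell compartments; 15 leaf
#' subsets). Channels are named by the marker they detect; `PE` is the
#' variable quantitation channel. The default gate cuts are the package's
#' single convention shared between the synthetic generator and the gating
#' templates, so the template defaults resolve the generated populations.
#'
#' @return Character vector of channel names.
#' @export
innate_panel_channels <- function() {
  c("FSC-A", "FSC-H", "SSC-A", "CD45", "CD3", "CD19", "CD16", "CD14",
    "CD11c", "CD123", "HLA-DR", "CD127", "CRTH2", "CD117", "CD56", "PE")
}

#' @rdname innate_panel_channels
#' @export
adaptive_panel_channels <- function() {
  c("FSC-A", "FSC-H", "SSC-A", "CD45", "CD3", "CD19", "TCRgd", "CD4",
    "CD8", "CD45RA", "CD27", "CD25", "CD127", "CXCR5", "IgD", "PE")
}

#' @rdname innate_panel_channels
#' @return `default_gate_cuts()`: named list of linear-unit cut values —
#'   `fsc_debris` (events below are debris), `singlet_min`/`singlet_max`
#'   (FSC-A/FSC-H ratio band), `fl_pos` (marker positive/negative cut),
#'   `hladr_high` (HLA-DR bright cut for mDC), and the SSC strata
#'   `ssc_vlow`, `ssc_high`, `ssc_vhigh`.
#' @export
default_gate_cuts <- function() {
  list(fsc_debris = 30000, singlet_min = 0.85, singlet_max = 1.15,
       fl_pos = 1000, hladr_high = 25000,
       ssc_vlow = 40000, ssc_high = 100000, ssc_vhigh = 180000)
}

# marker medians: well-resolved positive vs negative (100x separation),
# HLA-DR bright on mDC
.FL_NEG <- 100
.FL_POS <- 10000
.FL_BRIGHT <- 60000

# fluorescence location for a known ABC through the truth line
abc_to_fluorescence <- function(abc, slope = 1, intercept = 0) {
  ifelse(abc > 0, 10^((log10(abc) - intercept) / slope), 0)
}

# build a population_spec with every fluorescence channel defaulting to
# the negative median and scatter + overrides supplied
make_pop <- function(name, fraction, channels, fsc, ssc, overrides = c(),
                     pe = .FL_NEG, true_abc = NA_real_) {
  loc <- stats::setNames(rep(.FL_NEG, length(channels)), channels)
  loc["FSC-A"] <- fsc
  loc["SSC-A"] <- ssc
  loc <- loc[setdiff(names(loc), "FSC-H")]
  loc[names(overrides)] <- overrides
  loc["PE"] <- pe
  population_spec(name, fraction, loc, true_abc = true_abc)
}

#' Default synthetic populations for the innate tube
#'
#' Twelve leaf subsets plus non-leaf fillers (debris, CD45-negative
#' events, T and B lymphocytes that the innate tree excludes); fractions
#' reflect typical whole-blood leukocyte composition and sum to 1. Leaves
#' carry `true_abc` on the PE channel, mapped to fluorescence through the
#' truth calibration line on top of a small autofluorescence.
#'
#' @param true_abc known PE-reagent ABC given to every leaf subset (a
#'   single number or a named vector by leaf code); 0 simulates an FMO
#'   (empty-PE) tube.
#' @param autofluorescence PE median of unstained events.
#' @param slope,intercept truth calibration line (identity by default).
#' @return List of [population_spec()]s.
#' @export
default_innate_populations <- function(true_abc = 10000,
                                       autofluorescence = 50,
                                       slope = 1, intercept = 0) {
  ch <- innate_panel_channels()
  leaves <- c("Neutrophils", "Eosinophils", "Basophils", "class Mono",
              "inter Mono", "nonc Mono", "mDC", "pDC", "ILC-1", "ILC-2",
              "ILC-3", "NK cells")
  abc <- resolve_leaf_abc(true_abc, leaves)
  pe <- function(code) autofluorescence +
    abc_to_fluorescence(abc[[code]], slope, intercept)
  P <- .FL_POS; N <- .FL_NEG; B <- .FL_BRIGHT
  lymph_base <- c(CD45 = P, CD123 = N, `HLA-DR` = N, CD14 = N)
  pops <- list(
    make_pop("Neutrophils", 0.45, ch, 180000, 130000,
             c(CD45 = P, CD16 = P), pe("Neutrophils"), abc[["Neutrophils"]]),
    make_pop("Eosinophils", 0.03, ch, 180000, 250000,
             c(CD45 = P), pe("Eosinophils"), abc[["Eosinophils"]]),
    make_pop("Basophils", 0.01, ch, 130000, 60000,
             c(CD45 = P, CD123 = P), pe("Basophils"), abc[["Basophils"]]),
    make_pop("class Mono", 0.08, ch, 160000, 60000,
             c(CD45 = P, `HLA-DR` = P, CD11c = P, CD14 = P),
             pe("class Mono"), abc[["class Mono"]]),
    make_pop("inter Mono", 0.01, ch, 160000, 60000,
             c(CD45 = P, `HLA-DR` = P, CD11c = P, CD14 = P, CD16 = P),
             pe("inter Mono"), abc[["inter Mono"]]),
    make_pop("nonc Mono", 0.01, ch, 160000, 60000,
             c(CD45 = P, `HLA-DR` = P, CD11c = P, CD16 = P),
             pe("nonc Mono"), abc[["nonc Mono"]]),
    make_pop("mDC", 0.01, ch, 160000, 60000,
             c(CD45 = P, `HLA-DR` = B, CD11c = P),
             pe("mDC"), abc[["mDC"]]),
    make_pop("pDC", 0.005, ch, 150000, 60000,
             c(CD45 = P, CD123 = P, `HLA-DR` = P),
             pe("pDC"), abc[["pDC"]]),
    make_pop("ILC-1", 0.003, ch, 120000, 15000,
             c(lymph_base, CD127 = P), pe("ILC-1"), abc[["ILC-1"]]),
    make_pop("ILC-2", 0.002, ch, 120000, 15000,
             c(lymph_base, CD127 = P, CRTH2 = P),
             pe("ILC-2"), abc[["ILC-2"]]),
    make_pop("ILC-3", 0.002, ch, 120000, 15000,
             c(lymph_base, CD127 = P, CD117 = P),
             pe("ILC-3"), abc[["ILC-3"]]),
    make_pop("NK cells", 0.06, ch, 120000, 15000,
             c(lymph_base, CD56 = P, CD16 = P),
             pe("NK cells"), abc[["NK cells"]]),
    # non-leaf fillers
    make_pop("T cells (excluded)", 0.233, ch, 120000, 15000,
             c(CD45 = P, CD3 = P), autofluorescence),
    make_pop("B cells (excluded)", 0.06, ch, 120000, 15000,
             c(CD45 = P, CD19 = P), autofluorescence),
    make_pop("Debris", 0.03, ch, 10000, 5000, c(), autofluorescence),
    make_pop("CD45neg", 0.005, ch, 120000, 15000, c(), autofluorescence)
  )
  pops
}

#' Default synthetic populations for the adaptive tube
#'
#' Fifteen lymphocyte leaf subsets plus fillers the adaptive tree excludes
#' (monocytes, neutrophils, NK cells, debris).
#'
#' @inheritParams default_innate_populations
#' @return List of [population_spec()]s.
#' @export
default_adaptive_populations <- function(true_abc = 10000,
                                         autofluorescence = 50,
                                         slope = 1, intercept = 0) {
  ch <- adaptive_panel_channels()
  leaves <- c("Tgd", "CD4 naive", "CD4 CM", "CD4 EM", "CD4 TEMRA", "Treg",
              "Tfh", "CD8 naive", "CD8 CM", "CD8 EM", "CD8 TEMRA",
              "B naive", "B dn", "B nat Eff", "B sw Mem")
  abc <- resolve_leaf_abc(true_abc, leaves)
  pe <- function(code) autofluorescence +
    abc_to_fluorescence(abc[[code]], slope, intercept)
  P <- .FL_POS; N <- .FL_NEG
  t4 <- c(CD45 = P, CD3 = P, CD4 = P, CD127 = P)
  t8 <- c(CD45 = P, CD3 = P, CD8 = P, CD127 = P)
  bc <- c(CD45 = P, CD19 = P)
  lp <- function(name, fraction, overrides, code = name) {
    make_pop(name, fraction, ch, 120000, 15000, overrides, pe(code),
             abc[[code]])
  }
  list(
    lp("Tgd", 0.03, c(CD45 = P, CD3 = P, TCRgd = P, CD27 = P)),
    lp("CD4 naive", 0.15, c(t4, CD45RA = P, CD27 = P)),
    lp("CD4 CM", 0.10, c(t4, CD27 = P)),
    lp("CD4 EM", 0.06, t4),
    lp("CD4 TEMRA", 0.02, c(t4, CD45RA = P)),
    lp("Treg", 0.03, c(CD45 = P, CD3 = P, CD4 = P, CD25 = P, CD27 = P)),
    lp("Tfh", 0.04, c(t4, CXCR5 = P, CD27 = P)),
    lp("CD8 naive", 0.08, c(t8, CD45RA = P, CD27 = P)),
    lp("CD8 CM", 0.04, c(t8, CD27 = P)),
    lp("CD8 EM", 0.05, t8),
    lp("CD8 TEMRA", 0.03, c(t8, CD45RA = P)),
    lp("B naive", 0.06, c(bc, IgD = P)),
    lp("B dn", 0.01, bc),
    lp("B nat Eff", 0.02, c(bc, IgD = P, CD27 = P)),
    lp("B sw Mem", 0.02, c(bc, CD27 = P)),
    # non-leaf fillers
    make_pop("NK (excluded)", 0.07, ch, 120000, 15000,
             c(CD45 = P), autofluorescence),
    make_pop("Monocytes (excluded)", 0.12, ch, 160000, 60000,
             c(CD45 = P), autofluorescence),
    make_pop("Neutrophils (excluded)", 0.03, ch, 180000, 130000,
             c(CD45 = P), autofluorescence),
    make_pop("Debris", 0.04, ch, 10000, 5000, c(), autofluorescence)
  )
}

# a single ABC for all leaves, or a named per-leaf vector
resolve_leaf_abc <- function(true_abc, leaves) {
  if (length(true_abc) == 1 && is.null(names(true_abc))) {
    return(stats::setNames(rep(true_abc, length(leaves)), leaves))
  }
  out <- stats::setNames(rep(0, length(leaves)), leaves)
  hit <- intersect(names(true_abc), leaves)
  out[hit] <- true_abc[hit]
  out
}

#' Generate a complete synthetic profiling tube
#'
#' Convenience wrapper: default populations of the requested tube,
#' generated at `n_events` with the given seed. `fmo = TRUE` sets every
#' leaf ABC to 0 (autofluorescence only), simulating the empty-PE control.
#'
#' @param tube `"innate"` or `"adaptive"`.
#' @param n_events,seed passed to [generate_tube()].
#' @param true_abc leaf ABC (ignored when `fmo = TRUE`).
#' @param fmo generate the fluorescence-minus-one control tube.
#' @param ... further arguments to [generate_tube()] (e.g. `spillover`,
#'   `doublet_fraction`).
#' @return An [event_table] with ground-truth labels.
#' @export
generate_subset_tube <- function(tube = c("innate", "adaptive"),
                                 n_events = 100000, seed = 1,
                                 true_abc = 10000, fmo = FALSE, ...) {
  tube <- match.arg(tube)
  if (fmo) true_abc <- 0
  if (tube == "innate") {
    pops <- default_innate_populations(true_abc = true_abc)
    chs <- innate_panel_channels()
  } else {
    pops <- default_adaptive_populations(true_abc = true_abc)
    chs <- adaptive_panel_channels()
  }
  id <- paste0(tube, if (fmo) "_FMO" else "")
  generate_tube(pops, chs, n_events, seed, tube_id = id, ...)
}
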