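#' Synthetic leukocyte tube generation
#'
#' The generator produces list-mode event data with the statistical
#' structure the downstream pipeline assumes: mixtures of cell populations
#' with log-normal fluorescence marginals (location parameter = median, so
#' sample medians are directly comparable to the spec), truncated-normal
#' scatter, four-peak calibration bead tubes, and barcoded titration
#' mixtures whose PE signal follows a saturation-binding law. Every table
#' carries a hidden ground-truth label per event for validation.
#'
#' @name synthetic
NULL

# run code under a seed without disturbing the session RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(code)
}

#' Population specification for the synthetic generator
#'
#' @param name population label (a leaf subset code, a cell-line name, or a
#'   filler such as `"Debris"`).
#' @param fraction expected proportion of tube events (0-1).
#' @param channel_locations named numeric vector: per-channel location
#'   parameter, in linear fluorescence or scatter units. For fluorescence
#'   channels the location is the population median.
#' @param channel_cvs named numeric vector or single number: per-channel
#'   coefficient of variation; defaults to 0.20 for fluorescence and 0.05
#'   for scatter channels.
#' @param true_abc optional known antibody binding capacity (molecules per
#'   cell) driving the PE channel location through the truth calibration
#'   line; `NA` when the PE location is given directly.
#' @return A `population_spec`.
#' @export
population_spec <- function(name, fraction, channel_locations,
                            channel_cvs = NULL, true_abc = NA_real_) {
  stopifnot(is.character(name), length(name) == 1)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]",
                                         call. = FALSE)
  if (is.null(names(channel_locations)) || any(names(channel_locations) == "")) {
    stop("channel_locations must be a named vector", call. = FALSE)
  }
  if (!is.na(true_abc) && true_abc < 0) stop("true_abc must be >= 0",
                                             call. = FALSE)
  if (!is.null(channel_cvs) && any(channel_cvs <= 0)) {
    stop("all CVs must be > 0", call. = FALSE)
  }
  structure(list(name = name, fraction = fraction,
                 channel_locations = channel_locations,
                 channel_cvs = channel_cvs, true_abc = true_abc),
            class = "population_spec")
}

# per-channel cv for a population: explicit entry, scalar, or class default
resolve_cv <- function(spec, channel) {
  cvs <- spec$channel_cvs
  if (!is.null(cvs)) {
    if (!is.null(names(cvs)) && channel %in% names(cvs)) return(cvs[[channel]])
    if (is.null(names(cvs)) && length(cvs) == 1) return(cvs[[1]])
  }
  if (is_scatter_channel(channel)) 0.05 else 0.20
}

#' Generate one synthetic tube
#'
#' Event counts per population are multinomial in the specified fractions.
#' Fluorescence channels are log-normal in linear space with median equal
#' to the location parameter; scatter channels are normal, truncated at 0.
#' `FSC-H` (when requested but not given a location) is derived from
#' `FSC-A` times a tight ratio noise so true single cells sit inside the
#' singlet ratio band; optional doublets get summed signals with a shared
#' `FSC-H`. An optional spillover matrix is applied to the fluorescence
#' block as a right-multiplication so that compensation inverts it exactly.
#'
#' @param populations list of [population_spec()]s; fractions must sum to 1
#'   (tolerance 1e-9).
#' @param channels ordered channel names of the tube.
#' @param n_events number of events (>= 0).
#' @param seed integer seed; identical seeds give bit-identical tables.
#' @param spillover optional [spillover_matrix()] applied to the true
#'   fluorescence signals.
#' @param doublet_fraction fraction of events replaced by synthetic
#'   doublets (summed channels, shared `FSC-H`); default 0.
#' @param singlet_ratio_cv CV of the FSC-H/FSC-A ratio for true singlets.
#' @param tube_id string recorded in the `$SRC` keyword.
#' @return An [event_table] with ground-truth `labels` (doublets labeled
#'   `"Doublet"`).
#' @export
generate_tube <- function(populations, channels, n_events, seed,
                          spillover = NULL, doublet_fraction = 0,
                          singlet_ratio_cv = 0.02, tube_id = "tube") {
  stopifnot(n_events >= 0)
  fr <- vapply(populations, function(p) p$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) {
    stop(sprintf("population fractions sum to %.12f, not 1", sum(fr)),
         call. = FALSE)
  }
  for (p in populations) {
    unknown <- setdiff(names(p$channel_locations), channels)
    if (length(unknown)) {
      stop(sprintf("unknown channel name in population '%s': %s", p$name,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  kw <- c(`$SRC` = tube_id, ABCF_SEED = as.character(seed))
  if (n_events == 0) {
    m <- matrix(numeric(0), ncol = length(channels),
                dimnames = list(NULL, channels))
    return(event_table(m, keywords = kw, labels = character(0)))
  }
  with_seed(seed, {
    n_doub <- round(doublet_fraction * n_events)
    n_single <- n_events - n_doub
    counts <- as.vector(stats::rmultinom(1, n_single, fr))
    blocks <- vector("list", length(populations))
    for (k in seq_along(populations)) {
      p <- populations[[k]]
      nk <- counts[k]
      m <- matrix(0, nrow = nk, ncol = length(channels),
                  dimnames = list(NULL, channels))
      for (ch in channels) {
        if (ch == "FSC-H" && !"FSC-H" %in% names(p$channel_locations)) next
        loc <- p$channel_locations[[ch]]
        if (is.null(loc)) {
          stop(sprintf("population '%s' has no location for channel '%s'",
                       p$name, ch), call. = FALSE)
        }
        cv <- resolve_cv(p, ch)
        if (is_scatter_channel(ch)) {
          m[, ch] <- pmax(0, stats::rnorm(nk, mean = loc, sd = cv * loc))
        } else if (loc > 0) {
          sigma <- sqrt(log(1 + cv^2))
          m[, ch] <- loc * exp(sigma * stats::rnorm(nk))
        } # loc == 0 stays exactly 0
      }
      if ("FSC-H" %in% channels &&
          !"FSC-H" %in% names(p$channel_locations)) {
        m[, "FSC-H"] <- m[, "FSC-A"] *
          stats::rnorm(nk, mean = 1, sd = singlet_ratio_cv)
      }
      blocks[[k]] <- m
    }
    exprs <- do.call(rbind, blocks)
    labels <- rep(vapply(populations, `[[`, character(1), "name"), counts)
    if (n_doub > 0) {
      i <- sample.int(nrow(exprs), n_doub, replace = TRUE)
      j <- sample.int(nrow(exprs), n_doub, replace = TRUE)
      doub <- exprs[i, , drop = FALSE] + exprs[j, , drop = FALSE]
      if ("FSC-H" %in% channels) doub[, "FSC-H"] <- exprs[i, "FSC-H"]
      exprs <- rbind(exprs, doub)
      labels <- c(labels, rep("Doublet", n_doub))
    }
    if (!is.null(spillover)) {
      ch <- rownames(spillover)
      missing <- setdiff(ch, channels)
      if (length(missing)) {
        stop(sprintf("spillover channels not in tube: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
      }
      exprs[, ch] <- exprs[, ch, drop = FALSE] %*% unclass(spillover)
    }
    event_table(exprs, keywords = kw, labels = labels)
  })
}

#' Bead lot specification (four-peak PE quantitation beads)
#'
#' @param levels exactly 4 strictly increasing positive PE-molecules-per-bead
#'   values, as printed on the bead lot sheet.
#' @param peak_cv coefficient of variation of each bead peak's fluorescence.
#' @return A `bead_lot_spec`.
#' @export
bead_lot_spec <- function(levels = c(500, 5e3, 5e4, 5e5), peak_cv = 0.10) {
  if (length(levels) != 4) stop("a bead lot has exactly 4 levels",
                                call. = FALSE)
  if (any(levels <= 0) || any(diff(levels) <= 0)) {
    stop("bead levels must be strictly increasing and positive",
         call. = FALSE)
  }
  if (peak_cv <= 0) stop("peak_cv must be > 0", call. = FALSE)
  structure(list(levels = levels, peak_cv = peak_cv),
            class = "bead_lot_spec")
}

#' Generate a calibration bead tube
#'
#' Produces four equally weighted PE peaks whose median fluorescences obey
#' the stated truth line `log10(ABC level) = slope * log10(F) + intercept`,
#' i.e. peak medians are placed at `F = 10^((log10(level) - intercept) /
#' slope)` so a downstream log-log fit recovers `slope` and `intercept`.
#'
#' @param lot a [bead_lot_spec()].
#' @param slope,intercept truth calibration line (identity line by default).
#' @param n_events number of bead events.
#' @param seed integer seed.
#' @param channels tube channels; must contain `"PE"`.
#' @return An [event_table] labeled `Bead1`..`Bead4`. Warns (does not fail)
#'   when `peak_cv` is large enough for adjacent peaks to overlap.
#' @export
generate_bead_tube <- function(lot, slope = 1, intercept = 0,
                               n_events = 20000, seed = 1,
                               channels = c("FSC-A", "FSC-H", "SSC-A", "PE")) {
  stopifnot(inherits(lot, "bead_lot_spec"), "PE" %in% channels)
  peak_f <- 10^((log10(lot$levels) - intercept) / slope)
  sigma10 <- sqrt(log(1 + lot$peak_cv^2)) / log(10)
  if (any(diff(log10(peak_f)) < 4 * sigma10)) {
    warning("bead peaks may overlap: peak_cv is large relative to peak spacing",
            call. = FALSE)
  }
  pops <- lapply(seq_along(peak_f), function(i) {
    population_spec(
      name = paste0("Bead", i), fraction = 0.25,
      channel_locations = c(`FSC-A` = 80000, `SSC-A` = 30000,
                            PE = peak_f[i]),
      channel_cvs = c(`FSC-A` = 0.05, `SSC-A` = 0.05, PE = lot$peak_cv),
      true_abc = lot$levels[i])
  })
  generate_tube(pops, channels, n_events, seed, tube_id = "beads")
}

#' Saturation-binding model for titration simulation
#'
#' Bound antibody per cell at stock fraction `c` follows
#' `bound(c) = bmax * c / (kd + c) + ns_slope * c`: a one-site binding
#' isotherm plus a linear nonspecific term.
#'
#' @param bmax saturating bound-antibody level (ABC units); 0 for a true
#'   negative cell type.
#' @param kd half-saturation concentration, in stock-fraction units (> 0).
#' @param ns_slope nonspecific linear binding coefficient (ABC per unit
#'   stock fraction).
#' @return A `binding_model`.
#' @export
binding_model <- function(bmax, kd, ns_slope = 0) {
  if (bmax < 0 || kd <= 0 || ns_slope < 0) {
    stop("need bmax >= 0, kd > 0, ns_slope >= 0", call. = FALSE)
  }
  structure(list(bmax = bmax, kd = kd, ns_slope = ns_slope),
            class = "binding_model")
}

#' @rdname binding_model
#' @param model a `binding_model`.
#' @param conc stock fraction(s) at which to evaluate the law.
#' @return `bound_abc()`: expected bound antibody (ABC units).
#' @export
bound_abc <- function(model, conc) {
  stopifnot(inherits(model, "binding_model"))
  model$bmax * conc / (model$kd + conc) + model$ns_slope * conc
}

#' Two-fold dilution series expressed as fractions of stock
#'
#' @param from starting (highest) stock fraction.
#' @param to lowest stock fraction to cover; the series stops at the last
#'   step `>= to`.
#' @param factor fold change per step.
#' @return Strictly decreasing numeric vector of stock fractions.
#' @export
#' @examples
#' dilution_series()  # 1/5 down to 1/2560
dilution_series <- function(from = 1 / 5, to = 1 / 3200, factor = 2) {
  stopifnot(from > to, factor > 1)
  out <- from
  while (out[length(out)] / factor >= to) {
    out <- c(out, out[length(out)] / factor)
  }
  out
}

#' Barcode scheme for the titration cell mixture
#'
#' Each cell type is assigned one of three intensities (`negative`, `low`,
#' `high`) on the two tracking-dye channels. The default reproduces the
#' standard mixture: mouse 300.19 Blue-high, U266 Blue-low, THP-1
#' DeepRed-high, Jurkat DeepRed-low, peripheral blood both high, Raji
#' unstained.
#'
#' @param cell_types character vector of barcode cell names.
#' @param blue,deepred per cell type level on the CellTracker Blue / Deep
#'   Red channel: `"negative"`, `"low"` or `"high"`.
#' @return A data frame of class `barcode_scheme`; the (blue, deepred)
#'   pairs must be pairwise distinct.
#' @export
barcode_scheme <- function(
    cell_types = c("300.19", "U266", "THP-1", "Jurkat", "Blood", "Raji"),
    blue = c("high", "low", "negative", "negative", "high", "negative"),
    deepred = c("negative", "negative", "high", "low", "high", "negative")) {
  lv <- c("negative", "low", "high")
  stopifnot(length(cell_types) == length(blue),
            length(blue) == length(deepred))
  if (!all(blue %in% lv) || !all(deepred %in% lv)) {
    stop("tracker levels must be 'negative', 'low' or 'high'", call. = FALSE)
  }
  key <- paste(blue, deepred)
  if (anyDuplicated(key)) {
    stop("barcode scheme is not unique in the (Blue, DeepRed) plane",
         call. = FALSE)
  }
  structure(data.frame(cell_type = cell_types, blue = blue,
                       deepred = deepred, stringsAsFactors = FALSE),
            class = c("barcode_scheme", "data.frame"))
}

#' Default linear medians for the three tracker intensities
#'
#' Separated >= 10x so demultiplexing is near-perfect by construction.
#' @return Named numeric vector (`negative`, `low`, `high`).
#' @export
tracker_levels <- function() {
  c(negative = 100, low = 3000, high = 60000)
}

#' Titration mixture cell type
#'
#' @param name component name (e.g. `"Jurkat"`, `"Blood.Granulocytes"`).
#' @param barcode_cell name of the barcode-scheme row this component
#'   belongs to (the three blood scatter types share `"Blood"`).
#' @param fraction expected fraction of tube events.
#' @param fsc,ssc scatter locations.
#' @param autofluorescence PE median with no antibody bound.
#' @param model a [binding_model()] for the profiled reagent.
#' @return A `titration_cell_type`.
#' @export
titration_cell_type <- function(name, barcode_cell, fraction, fsc, ssc,
                                autofluorescence, model) {
  stopifnot(inherits(model, "binding_model"))
  structure(list(name = name, barcode_cell = barcode_cell,
                 fraction = fraction, fsc = fsc, ssc = ssc,
                 autofluorescence = autofluorescence, model = model),
            class = "titration_cell_type")
}

#' Default titration mixture for a myeloid-type reagent
#'
#' Five cell lines plus peripheral blood mixed at equal rates (1/6 each);
#' the blood share splits into granulocytes, lymphocytes and monocytes at
#' typical proportions. By default granulocytes are the positive cell type
#' (one-site binding, `bmax` 50,000 ABC) and the mouse line 300.19 the
#' universal negative (`bmax` 0).
#'
#' @param bmax_positive saturating ABC of the positive cell type.
#' @param kd half-saturation stock fraction of the specific binding.
#' @param ns_slope nonspecific slope applied to every human cell type.
#' @return List of [titration_cell_type()]s (fractions sum to 1).
#' @export
default_titration_mixture <- function(bmax_positive = 50000, kd = 1 / 100,
                                      ns_slope = 0) {
  neg <- binding_model(0, kd = kd, ns_slope = 0)
  dim_model <- function(bmax) binding_model(bmax, kd = kd,
                                            ns_slope = ns_slope)
  b <- 1 / 6
  list(
    titration_cell_type("Raji",   "Raji",   b, 110000, 20000, 60, dim_model(0)),
    titration_cell_type("Jurkat", "Jurkat", b, 120000, 20000, 60, dim_model(0)),
    titration_cell_type("THP-1",  "THP-1",  b, 150000, 50000, 80, dim_model(8000)),
    titration_cell_type("U266",   "U266",   b, 140000, 30000, 70, dim_model(0)),
    titration_cell_type("300.19", "300.19", b, 100000, 20000, 50, neg),
    titration_cell_type("Blood.Granulocytes", "Blood", 0.6 * b, 180000,
                        130000, 100, dim_model(bmax_positive)),
    titration_cell_type("Blood.Lymphocytes", "Blood", 0.3 * b, 120000,
                        15000, 50, dim_model(0)),
    titration_cell_type("Blood.Monocytes", "Blood", 0.1 * b, 160000,
                        60000, 90, dim_model(15000))
  )
}

#' Generate a barcoded titration series
#'
#' One tube per dilution: all mixture components at their expected
#' fractions, tracker channels at the scheme's intensity medians, and the
#' PE median of each component following its binding model at the tube's
#' stock fraction (on top of autofluorescence), mapped through the truth
#' calibration line. An unstained FMO tube (stock fraction 0) is appended
#' when requested.
#'
#' @param cell_types list of [titration_cell_type()]s; their
#'   `barcode_cell`s must all appear in `scheme`.
#' @param scheme a [barcode_scheme()].
#' @param dilutions strictly decreasing stock fractions, e.g.
#'   [dilution_series()].
#' @param n_events events per tube.
#' @param seed integer seed (per-tube seeds are derived from it).
#' @param levels tracker intensity medians, see [tracker_levels()].
#' @param slope,intercept truth calibration line mapping fluorescence to
#'   ABC (identity by default, so PE location equals ABC).
#' @param include_fmo append an unstained control tube named `"FMO"`.
#' @return Named list of [event_table]s, one per dilution (names are the
#'   stock fractions), plus optionally `"FMO"`.
#' @export
generate_titration_series <- function(cell_types, scheme = barcode_scheme(),
                                      dilutions = dilution_series(),
                                      n_events = 20000, seed = 1,
                                      levels = tracker_levels(),
                                      slope = 1, intercept = 0,
                                      include_fmo = TRUE) {
  stopifnot(length(dilutions) >= 1)
  if (any(diff(dilutions) >= 0)) {
    stop("dilutions must be strictly decreasing stock fractions",
         call. = FALSE)
  }
  bc <- vapply(cell_types, `[[`, character(1), "barcode_cell")
  missing <- setdiff(bc, scheme$cell_type)
  if (length(missing)) {
    stop(sprintf("missing barcode for cell type(s): %s",
                 paste(unique(missing), collapse = ", ")), call. = FALSE)
  }
  channels <- c("FSC-A", "FSC-H", "SSC-A", "TrackerBlue", "TrackerDeepRed",
                "PE")
  abc_to_f <- function(abc) {
    ifelse(abc > 0, 10^((log10(abc) - intercept) / slope), 0)
  }
  make_tube <- function(conc, sub_seed, id) {
    pops <- lapply(cell_types, function(ct) {
      row <- scheme[scheme$cell_type == ct$barcode_cell, ]
      pe <- ct$autofluorescence +
        abc_to_f(if (conc > 0) bound_abc(ct$model, conc) else 0)
      population_spec(
        name = ct$name, fraction = ct$fraction,
        channel_locations = c(
          `FSC-A` = ct$fsc, `SSC-A` = ct$ssc,
          TrackerBlue = unname(levels[[row$blue]]),
          TrackerDeepRed = unname(levels[[row$deepred]]),
          PE = pe))
    })
    generate_tube(pops, channels, n_events, sub_seed, tube_id = id)
  }
  out <- list()
  for (i in seq_along(dilutions)) {
    nm <- format(dilutions[i], digits = 8)
    out[[nm]] <- make_tube(dilutions[i], seed + i,
                           sprintf("titration_%s", nm))
  }
  if (include_fmo) out[["FMO"]] <- make_tube(0, seed + length(dilutions) + 1,
                                             "titration_FMO")
  out
}
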