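#' Demultiplex a barcoded titration mixture
#'
#' Each event's two tracker channels are classified into rectangular
#' intensity regions derived from the scheme's negative/low/high medians:
#' region `[median/width, median*width)` around each level, half-open and
#' non-overlapping, so events falling in the gaps between regions stay
#' unassigned rather than being pulled to the nearest region. The (Blue,
#' DeepRed) level pair is then matched against the scheme; peripheral
#' blood events are further split into lymphocytes, monocytes and
#' granulocytes by side-scatter strata.
#'
#' @param table an [event_table] with the tracker channels.
#' @param scheme a [barcode_scheme()].
#' @param levels tracker level medians ([tracker_levels()]).
#' @param width half-open region half-width factor (region is
#'   `[median/width, median*width)`).
#' @param blue,deepred tracker channel names.
#' @param blood_name scheme cell type to split by scatter (`NULL` to skip).
#' @param ssc_cuts two SSC cuts separating lymphocytes / monocytes /
#'   granulocytes.
#' @return Character vector of per-event labels (`NA` = unassigned); blood
#'   events become `"Blood.Lymphocytes"`, `"Blood.Monocytes"`,
#'   `"Blood.Granulocytes"`.
#' @export
demultiplex <- function(table, scheme = barcode_scheme(),
                        levels = tracker_levels(), width = 3,
                        blue = "TrackerBlue", deepred = "TrackerDeepRed",
                        blood_name = "Blood",
                        ssc_cuts = c(40000, 100000)) {
  stopifnot(inherits(scheme, "barcode_scheme"), width > 1)
  classify <- function(x) {
    lev <- rep(NA_character_, length(x))
    for (nm in names(levels)) {
      lo <- levels[[nm]] / width
      hi <- levels[[nm]] * width
      lev[x >= lo & x < hi] <- nm
    }
    lev
  }
  bl <- classify(channel_values(table, blue))
  dr <- classify(channel_values(table, deepred))
  key <- paste(bl, dr)
  scheme_key <- paste(scheme$blue, scheme$deepred)
  label <- scheme$cell_type[match(key, scheme_key)]
  label[is.na(bl) | is.na(dr)] <- NA_character_
  if (!is.null(blood_name) && blood_name %in% scheme$cell_type) {
    ssc <- channel_values(table, "SSC-A")
    is_blood <- !is.na(label) & label == blood_name
    label[is_blood & ssc < ssc_cuts[1]] <- paste0(blood_name, ".Lymphocytes")
    label[is_blood & ssc >= ssc_cuts[1] & ssc < ssc_cuts[2]] <-
      paste0(blood_name, ".Monocytes")
    label[is_blood & ssc >= ssc_cuts[2]] <- paste0(blood_name,
                                                   ".Granulocytes")
  }
  label
}

#' Build titration curves from a dilution series of tubes
#'
#' Per cell type and dilution: median PE, robust SD (84.13th percentile
#' minus median — one "SD" above the median of a normal distribution) and
#' event count; the FMO (unstained) tube supplies each cell type's
#' background reference level.
#'
#' @param series named list of [event_table]s, one per dilution, e.g. from
#'   [generate_titration_series()] (an element named `"FMO"` is used as the
#'   FMO tube when `fmo` is not given).
#' @param dilutions strictly decreasing stock fractions, one per non-FMO
#'   table.
#' @param scheme,levels,... passed to [demultiplex()].
#' @param fmo optional FMO [event_table].
#' @param pe_channel PE channel name.
#' @param reagent reagent identifier recorded in the result.
#' @return A `titration_curve`: list with `points` (data frame: dilution,
#'   cell_type, median_pe, rsd_pe, n), `fmo` (data frame: cell_type,
#'   median_pe, rsd_pe, n), `dilutions`, `reagent`.
#' @export
build_titration_curves <- function(series, dilutions = NULL,
                                   scheme = barcode_scheme(),
                                   levels = tracker_levels(),
                                   fmo = NULL, pe_channel = "PE",
                                   reagent = "reagent", ...) {
  if (is.null(fmo) && "FMO" %in% names(series)) {
    fmo <- series[["FMO"]]
    series <- series[names(series) != "FMO"]
  }
  if (is.null(dilutions)) {
    dilutions <- suppressWarnings(as.numeric(names(series)))
    if (any(is.na(dilutions))) {
      stop("dilutions not supplied and series names are not numeric",
           call. = FALSE)
    }
  }
  if (length(series) != length(dilutions)) {
    stop(sprintf("got %d tubes for %d dilutions", length(series),
                 length(dilutions)), call. = FALSE)
  }
  if (length(dilutions) > 1 && any(diff(dilutions) >= 0)) {
    stop("dilutions must be strictly decreasing", call. = FALSE)
  }
  summarize_tube <- function(tab, dilution) {
    lab <- demultiplex(tab, scheme = scheme, levels = levels, ...)
    pe <- channel_values(tab, pe_channel)
    keep <- !is.na(lab)
    if (!any(keep)) return(NULL)
    agg <- lapply(split(pe[keep], lab[keep]), function(v) {
      c(median_pe = stats::median(v),
        rsd_pe = unname(stats::quantile(v, 0.8413, type = 7)) -
          stats::median(v),
        n = length(v))
    })
    data.frame(dilution = dilution, cell_type = names(agg),
               do.call(rbind, agg), row.names = NULL)
  }
  points <- do.call(rbind, Map(summarize_tube, series, dilutions))
  fmo_df <- if (!is.null(fmo)) {
    f <- summarize_tube(fmo, NA_real_)
    f$dilution <- NULL
    f
  } else NULL
  structure(list(points = points, fmo = fmo_df, dilutions = dilutions,
                 reagent = reagent),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("titration_curve '%s': %d dilutions x %d cell types\n",
              x$reagent, length(x$dilutions),
              length(unique(x$points$cell_type))))
  invisible(x)
}

#' Stain Index of a positive versus a negative population
#'
#' `SI = (median(pos) - median(neg)) / (2 * spread(neg))` where the spread
#' is, by default, the robust SD (84.13th percentile minus median) of the
#' negative — the Telford-style robust variant; `method = "sd"` uses the
#' classical standard deviation.
#'
#' @param pos,neg PE fluorescence vectors of the positive and negative
#'   population.
#' @param method `"rsd"` (robust, default) or `"sd"`.
#' @return The Stain Index (scalar); `NA` with a warning when the negative
#'   spread is zero (undefined SI).
#' @export
stain_index <- function(pos, neg, method = c("rsd", "sd")) {
  method <- match.arg(method)
  stopifnot(length(pos) > 0, length(neg) > 0)
  spread <- if (method == "rsd") {
    unname(stats::quantile(neg, 0.8413, type = 7)) - stats::median(neg)
  } else {
    stats::sd(neg)
  }
  if (!is.finite(spread) || spread <= 0) {
    warning("zero-spread negative population: Stain Index undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (stats::median(pos) - stats::median(neg)) / (2 * spread)
}

#' Stain Index series along a titration curve
#'
#' Computed from the curve's summary statistics: per dilution,
#' `(median_pos - median_neg) / (2 * rsd_neg)`.
#'
#' @param curve a [build_titration_curves()] result.
#' @param positive,negative cell-type labels to compare.
#' @return Data frame: `dilution`, `si`.
#' @export
stain_index_series <- function(curve, positive, negative) {
  stopifnot(inherits(curve, "titration_curve"))
  p <- curve$points
  out <- lapply(curve$dilutions, function(d) {
    rp <- p[p$dilution == d & p$cell_type == positive, ]
    rn <- p[p$dilution == d & p$cell_type == negative, ]
    si <- if (nrow(rp) == 0 || nrow(rn) == 0 || rn$rsd_pe <= 0) NA_real_
      else (rp$median_pe - rn$median_pe) / (2 * rn$rsd_pe)
    data.frame(dilution = d, si = si)
  })
  do.call(rbind, out)
}

#' Select the optimal titer from a titration curve
#'
#' Policies: `"saturation"` (default) picks the largest dilution (lowest
#' concentration) whose positive-cell median is at least
#' `saturation_fraction` of the maximum across dilutions; if the negative
#' cell type's median at that dilution exceeds `background_multiple` times
#' its FMO level, the recommendation steps one dilution further.
#' `"max-SI"` picks the Stain Index maximum; `"max-SI-minus-one"` picks
#' one step more dilute than the SI maximum (trading a little resolution
#' for fewer false positives).
#'
#' @param curve a [build_titration_curves()] result.
#' @param positive,negative cell-type labels.
#' @param policy titer policy.
#' @param saturation_fraction fraction of the maximal positive median that
#'   still counts as saturated (default 0.90).
#' @param background_multiple tolerated negative-to-FMO ratio (default 2).
#' @return A `titer_recommendation`: list with `dilution`, `policy`,
#'   `flags` (character vector, e.g. `background_exceeded`,
#'   `at_series_end`).
#' @export
select_titer <- function(curve, positive, negative,
                         policy = c("saturation", "max-SI",
                                    "max-SI-minus-one"),
                         saturation_fraction = 0.90,
                         background_multiple = 2) {
  policy <- match.arg(policy)
  stopifnot(inherits(curve, "titration_curve"))
  dil <- curve$dilutions               # decreasing concentration
  if (length(dil) < 3) stop("need at least 3 dilutions", call. = FALSE)
  p <- curve$points
  flags <- character(0)
  pick <- function(i) {
    structure(list(dilution = dil[i], policy = policy, flags = flags),
              class = "titer_recommendation")
  }
  if (policy == "saturation") {
    pos_med <- vapply(dil, function(d) {
      r <- p[p$dilution == d & p$cell_type == positive, ]
      if (nrow(r)) r$median_pe else NA_real_
    }, numeric(1))
    if (all(is.na(pos_med))) {
      stop(sprintf("positive cell type '%s' absent from curve", positive),
           call. = FALSE)
    }
    ok <- !is.na(pos_med) & pos_med >= saturation_fraction *
      max(pos_med, na.rm = TRUE)
    if (!any(ok)) {
      stop("no dilution satisfies the saturation criterion; retest at higher concentration",
           call. = FALSE)
    }
    i <- max(which(ok))                # most dilute still-saturated step
    flags <- c(flags, "plateau_reached")
    neg_row <- p[p$dilution == dil[i] & p$cell_type == negative, ]
    fmo_row <- curve$fmo[curve$fmo$cell_type == negative, ]
    if (nrow(neg_row) && nrow(fmo_row) &&
        neg_row$median_pe > background_multiple * fmo_row$median_pe) {
      flags <- c(flags, "background_exceeded")
      if (i < length(dil)) i <- i + 1 else flags <- c(flags,
                                                      "at_series_end")
    }
    return(pick(i))
  }
  si <- stain_index_series(curve, positive, negative)$si
  if (all(is.na(si))) stop("Stain Index undefined at every dilution",
                           call. = FALSE)
  i <- which.max(si)
  if (policy == "max-SI-minus-one") {
    if (i < length(dil)) i <- i + 1 else flags <- c(flags, "at_series_end")
  }
  pick(i)
}

#' @export
print.titer_recommendation <- function(x, ...) {
  cat(sprintf("recommended titer: 1/%s (policy %s)%s\n",
              format(1 / x$dilution, digits = 6), x$policy,
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Benchmark antibody clones sharing a target
#'
#' Compares per-subset median ABC across clones profiled on the same tube
#' and template: each clone's value is set against the per-subset
#' across-clone median, and clones deviating by more than `threshold`-fold
#' (either direction) are flagged — the pattern by which an epitope-
#' shifted clone stands out on a subset group while agreeing elsewhere.
#'
#' @param stats_by_clone named list (clone -> [subset_statistics()] table).
#' @param value column compared (default `median_abc`).
#' @param threshold fold-deviation from the clone median that triggers a
#'   flag (default 1.5).
#' @return List with `table` (data frame: code, clone, value,
#'   ratio_to_clone_median, flagged) and `pairwise` (data frame: code,
#'   clone_a, clone_b, ratio). With a single clone both are comparison-free.
#' @export
benchmark_clones <- function(stats_by_clone, value = "median_abc",
                             threshold = 1.5) {
  stopifnot(is.list(stats_by_clone), length(stats_by_clone) >= 1,
            !is.null(names(stats_by_clone)))
  codes <- Reduce(intersect, lapply(stats_by_clone,
                                    function(s) s$code))
  if (length(codes) == 0) stop("clones share no gated subsets",
                               call. = FALSE)
  clones <- names(stats_by_clone)
  m <- sapply(stats_by_clone, function(s) s[[value]][match(codes, s$code)])
  m <- matrix(m, nrow = length(codes),
              dimnames = list(codes, clones))
  rows <- list(); pw <- list()
  for (code in codes) {
    med <- stats::median(m[code, ])
    for (cl in clones) {
      ratio <- if (length(clones) > 1 && med > 0) m[code, cl] / med
        else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        code = code, clone = cl, value = m[code, cl],
        ratio_to_clone_median = ratio,
        flagged = !is.na(ratio) &&
          (ratio > threshold | ratio < 1 / threshold))
    }
    if (length(clones) > 1) {
      for (a in seq_along(clones)) for (b in seq_along(clones)) {
        if (a < b) {
          pw[[length(pw) + 1]] <- data.frame(
            code = code, clone_a = clones[a], clone_b = clones[b],
            ratio = m[code, a] / m[code, b])
        }
      }
    }
  }
  list(table = do.call(rbind, rows),
       pairwise = if (length(pw)) do.call(rbind, pw) else
         data.frame(code = character(0), clone_a = character(0),
                    clone_b = character(0), ratio = numeric(0)))
}
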