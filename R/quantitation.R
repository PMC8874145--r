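#' Locate the four bead peaks of a quantitation bead tube
#'
#' One-dimensional k-means (k = 4, Lloyd's algorithm) on log10 PE
#' fluorescence with quantile-based initial centers, which makes the
#' result deterministic and invariant to event order. Cluster medians are
#' returned on the linear scale, ascending.
#'
#' @param bead_table an [event_table] of the bead tube.
#' @param pe_channel PE channel name.
#' @param min_events minimum usable (positive-fluorescence) events.
#' @param min_log10_gap minimum separation between adjacent peak medians in
#'   log10 units; closer peaks are reported unresolvable.
#' @return Numeric vector of 4 ascending peak median fluorescences.
#' @export
find_bead_peaks <- function(bead_table, pe_channel = "PE",
                            min_events = 200, min_log10_gap = 0.3) {
  v <- channel_values(bead_table, pe_channel)
  v <- v[v > 0]
  if (length(v) < min_events) {
    stop(sprintf("bead tube has only %d positive events (need >= %d)",
                 length(v), min_events), call. = FALSE)
  }
  lx <- log10(v)
  centers <- matrix(stats::quantile(lx, c(0.125, 0.375, 0.625, 0.875),
                                    names = FALSE, type = 7))
  km <- stats::kmeans(matrix(lx), centers = centers, iter.max = 100,
                      algorithm = "Lloyd")
  med <- vapply(1:4, function(k) {
    if (!any(km$cluster == k)) return(NA_real_)
    stats::median(v[km$cluster == k])
  }, numeric(1))
  med <- sort(med)
  if (any(is.na(med)) || any(diff(log10(med)) < min_log10_gap)) {
    stop("unresolvable peaks: fewer than 4 well-separated bead clusters",
         call. = FALSE)
  }
  med
}

#' Fit the PE calibration curve
#'
#' Ordinary least squares of `log10(lot level)` on `log10(peak median
#' fluorescence)` over the four bead peaks; regressing ABC on fluorescence
#' means conversion needs no inversion.
#'
#' @param peak_medians 4 positive ascending peak median fluorescences.
#' @param lot a [bead_lot_spec()].
#' @param r_squared_warn warn when the fit's R-squared drops below this.
#' @return A `calibration_curve`: slope, intercept, `peak_medians`,
#'   `levels`, `r_squared`.
#' @export
fit_calibration <- function(peak_medians, lot, r_squared_warn = 0.99) {
  stopifnot(inherits(lot, "bead_lot_spec"))
  if (length(peak_medians) != 4) {
    stop("need exactly 4 peak medians", call. = FALSE)
  }
  if (any(peak_medians <= 0)) {
    stop("bead peak medians must be positive", call. = FALSE)
  }
  lx <- log10(peak_medians)
  ly <- log10(lot$levels)
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  if (r2 < r_squared_warn) {
    warning(sprintf("calibration R-squared %.4f below %.2f", r2,
                    r_squared_warn), call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 peak_medians = peak_medians, levels = lot$levels,
                 r_squared = r2),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: log10(ABC) = %.4f * log10(F) + %.4f  (R^2 = %.5f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Convert PE fluorescence to antibody binding capacity
#'
#' `ABC = 10^(slope * log10(F) + intercept)` for `F > 0`; non-positive
#' (compensated) fluorescence maps to ABC 0 and is flagged below
#' detection rather than dropped, so subset event counts are preserved.
#'
#' @param values PE fluorescence vector (linear, compensated).
#' @param curve a `calibration_curve` from [fit_calibration()].
#' @return Numeric ABC vector with a logical attribute `below_detection`.
#' @export
fluorescence_to_abc <- function(values, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  below <- values <= 0
  abc <- numeric(length(values))
  abc[!below] <- 10^(curve$slope * log10(values[!below]) + curve$intercept)
  attr(abc, "below_detection") <- below
  abc
}

#' Subset-specific background cutoffs from an FMO tube
#'
#' For each leaf with at least `min_events` events in the gated FMO
#' (empty-PE) tube, the cutoff is the 90th percentile of the subset's ABC
#' values (linear-interpolation quantile); leaves below the count are
#' omitted.
#'
#' @param fmo_result a `gate_result` of the FMO tube.
#' @param fmo_abc ABC vector for the same tube's events.
#' @param probs cutoff percentile (default 0.90).
#' @param min_events minimum subset event count (default 66).
#' @return Data frame of class `background_cutoff_table`: `code`, `n`,
#'   `cutoff_abc`.
#' @export
background_cutoffs <- function(fmo_result, fmo_abc, probs = 0.90,
                               min_events = 66) {
  stopifnot(inherits(fmo_result, "gate_result"),
            length(fmo_abc) == length(fmo_result$assignment))
  rows <- lapply(fmo_result$leaves, function(code) {
    v <- fmo_abc[!is.na(fmo_result$assignment) &
                   fmo_result$assignment == code]
    if (length(v) < min_events) return(NULL)
    data.frame(code = code, n = length(v),
               cutoff_abc = unname(stats::quantile(v, probs, type = 7)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(code = character(0), n = integer(0),
                      cutoff_abc = numeric(0))
  }
  rownames(out) <- NULL
  class(out) <- c("background_cutoff_table", "data.frame")
  out
}

#' Per-subset statistics of a stained tube
#'
#' For every gated leaf: event count, median PE fluorescence, median ABC,
#' quartiles and IQR of ABC (linear-interpolation quantiles), the
#' subset's background cutoff, and percent positive = share of events with
#' ABC above the cutoff. Subsets below the minimum count are omitted by
#' default (`drop_below_min = FALSE` keeps them, flagged). A leaf missing
#' from the cutoff table gets its statistics but no percent positive.
#'
#' @param result a `gate_result` of the stained tube.
#' @param pe PE fluorescence vector (linear) of the tube's events.
#' @param abc ABC vector of the tube's events.
#' @param cutoffs optional [background_cutoffs()] table.
#' @param min_events minimum subset event count (default 66).
#' @param drop_below_min omit subsets below the count (default `TRUE`).
#' @return Data frame of class `subset_stats`: `code`, `n`, `median_pe`,
#'   `median_abc`, `q1_abc`, `q3_abc`, `iqr_abc`, `cutoff_abc`,
#'   `pct_positive`, `below_min_count`.
#' @export
subset_statistics <- function(result, pe, abc, cutoffs = NULL,
                              min_events = 66, drop_below_min = TRUE) {
  stopifnot(inherits(result, "gate_result"),
            length(pe) == length(result$assignment),
            length(abc) == length(result$assignment))
  q <- function(v, p) unname(stats::quantile(v, p, type = 7))
  rows <- lapply(result$leaves, function(code) {
    sel <- !is.na(result$assignment) & result$assignment == code
    n <- sum(sel)
    if (n == 0 || (drop_below_min && n < min_events)) return(NULL)
    v_abc <- abc[sel]
    cutoff <- NA_real_
    if (!is.null(cutoffs) && code %in% cutoffs$code) {
      cutoff <- cutoffs$cutoff_abc[match(code, cutoffs$code)]
    }
    q1 <- q(v_abc, 0.25); q3 <- q(v_abc, 0.75)
    data.frame(
      code = code, n = n,
      median_pe = stats::median(pe[sel]),
      median_abc = stats::median(v_abc),
      q1_abc = q1, q3_abc = q3, iqr_abc = q3 - q1,
      cutoff_abc = cutoff,
      pct_positive = if (is.na(cutoff)) NA_real_ else
        100 * sum(v_abc > cutoff) / n,
      below_min_count = n < min_events)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(code = character(0), n = integer(0),
                      median_pe = numeric(0), median_abc = numeric(0),
                      q1_abc = numeric(0), q3_abc = numeric(0),
                      iqr_abc = numeric(0), cutoff_abc = numeric(0),
                      pct_positive = numeric(0),
                      below_min_count = logical(0))
  }
  rownames(out) <- NULL
  class(out) <- c("subset_stats", "data.frame")
  out
}

#' Summarize the minimal ABC resolution across subsets
#'
#' Median, minimum and maximum of the per-subset background cutoffs — the
#' headline sensitivity statistic of a panel (an odd subset count makes
#' the median the middle order statistic).
#'
#' @param cutoffs a [background_cutoffs()] table, or any data frame with a
#'   `cutoff_abc` column (e.g. [reference_background_cutoffs()]).
#' @return List with `median`, `min`, `max`, `n_subsets`.
#' @export
summarize_resolution <- function(cutoffs) {
  v <- cutoffs$cutoff_abc
  if (is.null(v) || length(v) == 0) {
    stop("empty cutoff table", call. = FALSE)
  }
  list(median = stats::median(v), min = min(v), max = max(v),
       n_subsets = length(v))
}
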