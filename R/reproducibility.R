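#' Cross-site coefficient-of-variation summary
#'
#' Aggregates median-ABC records over donors and laboratories per marker
#' and population: the intra-lab CV is the CV across donors within each
#' lab (labs with at least two donors), averaged over labs; the inter-lab
#' CV pools all donor-lab medians. CVs use the sample (n-1) SD and are
#' reported in percent; groupings with fewer than two values are reported
#' undefined (`NA`) and counted in `n_undefined_labs`.
#'
#' @param records data frame with columns `marker`, `population`, `donor`,
#'   `lab`, `median_abc`; (marker, population, donor, lab) must be unique.
#' @return Data frame of class `cv_summary`: `marker`, `population`,
#'   `intra_lab_cv`, `inter_lab_cv`, `n_values`, `n_labs`,
#'   `n_undefined_labs`. Empty input gives an empty summary.
#' @export
cv_summary <- function(records) {
  need <- c("marker", "population", "donor", "lab", "median_abc")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop(sprintf("records are missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(records) == 0) {
    out <- data.frame(marker = character(0), population = character(0),
                      intra_lab_cv = numeric(0), inter_lab_cv = numeric(0),
                      n_values = integer(0), n_labs = integer(0),
                      n_undefined_labs = integer(0))
    class(out) <- c("cv_summary", "data.frame")
    return(out)
  }
  key <- paste(records$marker, records$population, records$donor,
               records$lab, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (marker, population, donor, lab) record", call. = FALSE)
  }
  cv <- function(v) if (length(v) >= 2) 100 * stats::sd(v) / mean(v)
    else NA_real_
  grp <- split(records, paste(records$marker, records$population,
                              sep = "\r"))
  rows <- lapply(grp, function(g) {
    lab_cvs <- vapply(split(g$median_abc, g$lab), cv, numeric(1))
    defined <- lab_cvs[!is.na(lab_cvs)]
    data.frame(
      marker = g$marker[1], population = g$population[1],
      intra_lab_cv = if (length(defined)) mean(defined) else NA_real_,
      inter_lab_cv = cv(g$median_abc),
      n_values = nrow(g),
      n_labs = length(unique(g$lab)),
      n_undefined_labs = sum(is.na(lab_cvs)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cv_summary", "data.frame")
  out
}

#' Fold change of median ABC between two subset-statistics tables
#'
#' @param a,b [subset_statistics()] tables (or any data frames with `code`
#'   and `median_abc`) sharing at least one subset.
#' @return Data frame: `code`, `median_abc_a`, `median_abc_b`, `ratio`
#'   (a over b), `direction` (`"higher"`, `"lower"`, `"equal"` or
#'   `"undefined"` on a zero denominator, which is flagged `NA` ratio).
#' @export
fold_change <- function(a, b) {
  codes <- intersect(a$code, b$code)
  if (length(codes) == 0) stop("no overlapping subsets", call. = FALSE)
  va <- a$median_abc[match(codes, a$code)]
  vb <- b$median_abc[match(codes, b$code)]
  ratio <- ifelse(vb == 0, NA_real_, va / vb)
  data.frame(
    code = codes, median_abc_a = va, median_abc_b = vb, ratio = ratio,
    direction = ifelse(is.na(ratio), "undefined",
                       ifelse(ratio > 1, "higher",
                              ifelse(ratio < 1, "lower", "equal"))))
}
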