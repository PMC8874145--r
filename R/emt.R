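#' Load and validate an Experiment Master Table (EMT)
#'
#' The EMT maps plate wells to PE reagents and carries the experiment
#' metadata that drives protocol generation and FCS annotation. Required
#' columns: `plate`, `well`, `cd`, `clone`, `vendor`, `titer_volume_ul`
#' (microlitres of PE reagent per well at the chosen titer); optional:
#' `gene`, `panel`. An FMO (empty PE) well is marked by `cd == "FMO"` and
#' may have a zero reagent volume; all other wells need a positive volume.
#'
#' @param path CSV or TSV file (delimiter chosen by extension, `.tsv`/`.txt`
#'   read as tab-separated).
#' @param experiment,operator,lab,date experiment-level metadata recorded in
#'   protocols and annotations.
#' @return An object of class `experiment_master_table` with elements
#'   `table` (validated rows), `meta`, and `violations` (character vector,
#'   empty when the table is valid). With violations present the object is
#'   still returned, flagged invalid; [generate_protocol()] and
#'   [annotate_batch()] refuse flagged tables.
#' @export
load_and_validate_emt <- function(path, experiment = "EXP", operator = "NA",
                                  lab = "NA", date = "1970-01-01") {
  if (!file.exists(path)) stop(sprintf("EMT file '%s' not found", path),
                               call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  validate_emt(df, experiment = experiment, operator = operator, lab = lab,
               date = date)
}

#' @rdname load_and_validate_emt
#' @param df a data frame with the EMT columns (in-memory entry point).
#' @export
validate_emt <- function(df, experiment = "EXP", operator = "NA",
                         lab = "NA", date = "1970-01-01") {
  required <- c("plate", "well", "cd", "clone", "vendor", "titer_volume_ul")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("EMT is missing mandatory columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  violations <- character(0)
  add <- function(v) violations <<- c(violations, v)

  well_ok <- grepl("^[A-H](1[0-2]|[1-9])$", df$well)
  if (any(!well_ok)) {
    add(sprintf("invalid well position: %s",
                paste(unique(df$well[!well_ok]), collapse = ", ")))
  }
  key <- paste(df$plate, df$well)
  dup <- unique(df$well[duplicated(key) | duplicated(key, fromLast = TRUE)])
  if (length(dup)) {
    add(sprintf("duplicate well within a plate: %s",
                paste(sort(dup), collapse = ", ")))
  }
  vol <- suppressWarnings(as.numeric(df$titer_volume_ul))
  is_fmo <- toupper(df$cd) == "FMO"
  bad_vol <- is.na(vol) | (!is_fmo & vol <= 0) | (is_fmo & vol < 0)
  if (any(bad_vol)) {
    add(sprintf("nonpositive volume in well(s): %s",
                paste(df$well[bad_vol], collapse = ", ")))
  }
  no_id <- !is_fmo & (is.na(df$cd) | df$cd == "" | is.na(df$clone) |
                        df$clone == "")
  if (any(no_id)) {
    add(sprintf("missing reagent identifiers in well(s): %s",
                paste(df$well[no_id], collapse = ", ")))
  }
  for (p in unique(df$plate)) {
    if (!any(is_fmo[df$plate == p])) {
      add(sprintf("plate %s has no FMO (empty-PE) well", p))
    }
  }
  df$titer_volume_ul <- vol
  structure(list(table = df,
                 meta = list(experiment = experiment, operator = operator,
                             lab = lab, date = date),
                 violations = violations),
            class = "experiment_master_table")
}

#' @export
print.experiment_master_table <- function(x, ...) {
  cat(sprintf("experiment_master_table: %d wells, %d plate(s)\n",
              nrow(x$table), length(unique(x$table$plate))))
  if (length(x$violations)) {
    cat("violations:\n")
    for (v in x$violations) cat(" -", v, "\n")
  } else {
    cat("valid\n")
  }
  invisible(x)
}

#' Generate the experimental protocol from a validated EMT
#'
#' Reproduces the staining arithmetic of the plate SOP: each well receives
#' the PE reagent topped up with diluent to 10 ul, then 40 ul of cell
#' suspension (2e6 cells) for a 50 ul staining volume, then 25 ul of
#' backbone antibody mix for 75 ul total. Master-mix totals are scaled by
#' well count plus a pipetting overage.
#'
#' @param emt a valid `experiment_master_table`.
#' @param overage_fraction extra fraction of master mixes prepared beyond
#'   the per-well sum (default 0.10).
#' @param timestamp protocol time stamp; injectable so regeneration from the
#'   same EMT is byte-identical.
#' @return A `protocol_document`: list with `wells` (per-well pipetting
#'   table), `totals`, `meta`, `timestamp`.
#' @export
generate_protocol <- function(emt, overage_fraction = 0.10,
                              timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")) {
  stopifnot(inherits(emt, "experiment_master_table"))
  if (length(emt$violations)) {
    stop("EMT has validation violations; fix them before protocol generation",
         call. = FALSE)
  }
  df <- emt$table
  if (any(df$titer_volume_ul > 10)) {
    stop(sprintf("PE reagent volume exceeds the 10 ul PE+diluent budget in well(s): %s",
                 paste(df$well[df$titer_volume_ul > 10], collapse = ", ")),
         call. = FALSE)
  }
  wells <- data.frame(
    plate = df$plate,
    well = df$well,
    reagent = ifelse(toupper(df$cd) == "FMO", "FMO (diluent only)",
                     paste0(df$cd, " (", df$clone, ")")),
    pe_volume_ul = df$titer_volume_ul,
    diluent_volume_ul = 10 - df$titer_volume_ul,
    cell_suspension_ul = 40,
    backbone_mix_ul = 25,
    total_ul = 75,
    stringsAsFactors = FALSE
  )
  n <- nrow(df)
  f <- 1 + overage_fraction
  totals <- list(
    n_wells = n,
    backbone_mix_ul = 25 * n * f,
    diluent_ul = sum(wells$diluent_volume_ul) * f,
    cell_suspension_ul = 40 * n * f,
    cells_needed = 2e6 * n * f,
    overage_fraction = overage_fraction
  )
  structure(list(wells = wells, totals = totals, meta = emt$meta,
                 timestamp = timestamp),
            class = "protocol_document")
}

#' @export
print.protocol_document <- function(x, ...) {
  writeLines(format_protocol(x))
  invisible(x)
}

#' Render a protocol document as printable text
#'
#' @param x a `protocol_document`.
#' @return Character vector of lines.
#' @export
format_protocol <- function(x) {
  stopifnot(inherits(x, "protocol_document"))
  t <- x$totals
  c(sprintf("Staining protocol - experiment %s (%s)", x$meta$experiment,
            x$timestamp),
    sprintf("Operator: %s   Lab: %s   Date: %s", x$meta$operator, x$meta$lab,
            x$meta$date),
    "",
    sprintf("Wells: %d   Overage: %.0f%%", t$n_wells,
            100 * t$overage_fraction),
    sprintf("Backbone mAb mix to prepare: %.1f ul", t$backbone_mix_ul),
    sprintf("Staining diluent to prepare: %.1f ul", t$diluent_ul),
    sprintf("Cell suspension: %.1f ul (%.3g cells at 5e7/ml stock)",
            t$cell_suspension_ul, t$cells_needed),
    "",
    "Per-well pipetting (ul): PE reagent + diluent = 10; + 40 cells = 50; + 25 backbone = 75",
    utils::capture.output(print(x$wells, row.names = FALSE)))
}
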