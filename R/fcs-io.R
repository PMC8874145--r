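#' Read an FCS file
#'
#' Parses FCS 2.0/3.0/3.1 list-mode files: header segment offsets, the
#' delimited TEXT segment (with doubled-delimiter escaping), and the DATA
#' segment for `$DATATYPE` F (float32), D (float64) or I (unsigned integer).
#' Channel names are taken from `$PnN`; `$PnS` display aliases, when present,
#' stay available through the returned keywords.
#'
#' @param path path to an FCS file.
#' @return An [event_table] carrying all TEXT-segment keywords.
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 58) stop("file too short to be FCS", call. = FALSE)
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1")) {
    stop(sprintf("unsupported FCS version '%s'", version), call. = FALSE)
  }
  off <- function(i) {
    s <- trimws(rawToChar(raw[(11 + 8 * (i - 1)):(10 + 8 * i)]))
    if (s == "") 0 else suppressWarnings(as.numeric(s))
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)
  if (is.na(text_beg) || is.na(text_end) || text_end <= text_beg) {
    stop("malformed header: bad TEXT segment offsets", call. = FALSE)
  }
  kw <- parse_fcs_text(raw[(text_beg + 1):(text_end + 1)])

  getkw <- function(name, default = NULL) {
    if (name %in% names(kw)) kw[[name]] else default
  }
  # FCS 3.0 allows 0 in the header with the true offsets in TEXT
  if (is.na(data_beg) || data_beg == 0) {
    data_beg <- as.numeric(getkw("$BEGINDATA", 0))
  }
  if (is.na(data_end) || data_end == 0) {
    data_end <- as.numeric(getkw("$ENDDATA", 0))
  }
  n_par <- as.integer(getkw("$PAR", 0))
  n_tot <- as.integer(getkw("$TOT", 0))
  datatype <- getkw("$DATATYPE", "F")
  byteord <- getkw("$BYTEORD", "1,2,3,4")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little" else "big"
  ch <- vapply(seq_len(n_par), function(i) {
    v <- getkw(sprintf("$P%dN", i))
    if (is.null(v)) sprintf("P%d", i) else v
  }, character(1))

  n_values <- n_par * n_tot
  if (n_values > 0) {
    seg <- raw[(data_beg + 1):(data_end + 1)]
    if (datatype == "F") {
      vals <- readBin(seg, what = "numeric", n = n_values, size = 4,
                      endian = endian)
    } else if (datatype == "D") {
      vals <- readBin(seg, what = "numeric", n = n_values, size = 8,
                      endian = endian)
    } else if (datatype == "I") {
      widths <- vapply(seq_len(n_par), function(i) {
        as.integer(getkw(sprintf("$P%dB", i), "32"))
      }, integer(1))
      if (length(unique(widths)) != 1L) {
        stop("mixed-width integer data not supported", call. = FALSE)
      }
      size <- widths[1] / 8
      vals <- readBin(seg, what = "integer", n = n_values, size = size,
                      signed = FALSE, endian = endian)
      vals <- as.numeric(vals)
    } else {
      stop(sprintf("unsupported $DATATYPE '%s'", datatype), call. = FALSE)
    }
    if (length(vals) != n_values) {
      stop("DATA segment shorter than $PAR x $TOT", call. = FALSE)
    }
    m <- matrix(vals, ncol = n_par, byrow = TRUE, dimnames = list(NULL, ch))
  } else {
    m <- matrix(numeric(0), ncol = n_par, dimnames = list(NULL, ch))
  }
  event_table(m, keywords = kw)
}

# TEXT segment -> named character vector; first byte is the delimiter,
# a doubled delimiter inside a value is an escaped literal
parse_fcs_text <- function(bytes) {
  s <- rawToChar(bytes)
  delim <- substr(s, 1, 1)
  body <- substring(s, 2)
  if (endsWith(body, delim)) body <- substring(body, 1, nchar(body) - 1)
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # merge empty tokens produced by escaped (doubled) delimiters
  tokens <- character(0)
  i <- 1
  while (i <= length(parts)) {
    tok <- parts[i]
    while (i + 1 <= length(parts) && parts[i + 1] == "" ) {
      # "a", "", "b" came from "a<d><d>b": rejoin with a literal delimiter
      nxt <- if (i + 2 <= length(parts)) parts[i + 2] else ""
      tok <- paste0(tok, delim, nxt)
      i <- i + 2
    }
    tokens <- c(tokens, tok)
    i <- i + 1
  }
  if (length(tokens) %% 2 != 0) {
    stop("malformed TEXT segment: odd number of tokens", call. = FALSE)
  }
  keys <- tokens[seq(1, length(tokens), by = 2)]
  vals <- tokens[seq(2, length(tokens), by = 2)]
  stats::setNames(vals, keys)
}

#' Write an FCS 3.0 file
#'
#' Emits FCS 3.0 with `$DATATYPE` F (little-endian float32, `$PnB` 32,
#' `$PnE` 0,0), correct `$BEGINDATA`/`$ENDDATA` offsets and all user
#' keywords embedded in the TEXT segment. Delimiters occurring inside
#' keyword values are escaped by doubling; a channel name containing the
#' delimiter is rejected.
#'
#' @param table an [event_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  delim <- "/"
  ch <- channels(table)
  if (any(grepl(delim, ch, fixed = TRUE))) {
    stop("channel name contains the keyword delimiter '/'", call. = FALSE)
  }
  n_par <- ncol(table$exprs)
  n_tot <- nrow(table$exprs)

  esc <- function(v) gsub(delim, paste0(delim, delim), v, fixed = TRUE)
  required <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot)
  )
  per_channel <- character(0)
  for (i in seq_len(n_par)) {
    per_channel[sprintf("$P%dN", i)] <- ch[i]
    per_channel[sprintf("$P%dB", i)] <- "32"
    per_channel[sprintf("$P%dE", i)] <- "0,0"
    per_channel[sprintf("$P%dR", i)] <- "262144"
  }
  user <- table$keywords
  # computed keywords always win over stale copies from a previous read
  user <- user[!names(user) %in% c(names(required), names(per_channel),
                                   "$BEGINDATA", "$ENDDATA")]
  # offsets use fixed-width fields so TEXT length is known before they are
  data_beg_s <- "%12d"; data_end_s <- "%12d"
  build_text <- function(beg, end) {
    kv <- c(required,
            "$BEGINDATA" = sprintf(data_beg_s, as.integer(beg)),
            "$ENDDATA" = sprintf(data_end_s, as.integer(end)),
            per_channel,
            stats::setNames(esc(unname(user)), esc(names(user))))
    paste0(delim,
           paste0(names(kv), delim, unname(kv), delim, collapse = ""))
  }
  probe <- build_text(0, 0)
  text_beg <- 58
  text_end <- text_beg + nchar(probe, type = "bytes") - 1
  data_beg <- text_end + 1
  data_end <- if (n_tot * n_par > 0) data_beg + 4 * n_tot * n_par - 1 else 0
  text <- build_text(data_beg, data_end)
  stopifnot(nchar(text, type = "bytes") == nchar(probe, type = "bytes"))

  hdr_off <- function(x) formatC(as.integer(x), width = 8, format = "d")
  header <- paste0("FCS3.0    ",
                   hdr_off(text_beg), hdr_off(text_end),
                   hdr_off(if (data_end > 0) data_beg else 0),
                   hdr_off(data_end),
                   hdr_off(0), hdr_off(0))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, text)), con)
  if (n_tot * n_par > 0) {
    writeBin(as.numeric(t(table$exprs)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Extract the well position from a default cytometer file name
#'
#' Acquisition software labels exported files like
#' `Specimen_001_A1_A01_001.fcs`; the third underscore-delimited token is
#' the plate well.
#'
#' @param name a file name (path components are ignored).
#' @return The well token, e.g. `"A1"`.
#' @export
#' @examples
#' parse_default_filename("Specimen_001_A1_A01_001.fcs")
parse_default_filename <- function(name) {
  base <- basename(name)
  pat <- "^[^_]+_[0-9]+_([A-H](1[0-2]|[1-9]))_[A-H][0-9]{2}_[0-9]{3}\\.fcs$"
  m <- regmatches(base, regexec(pat, base))[[1]]
  if (length(m) < 2) {
    stop(sprintf("file name '%s' does not match the default cytometer pattern",
                 base), call. = FALSE)
  }
  m[2]
}

#' Annotate and rename a batch of FCS files from the experiment master table
#'
#' For every file whose name parses to a well, the matching EMT row supplies
#' reagent identifiers (CD name, gene, clone, vendor, titer) and experiment
#' metadata, written into the FCS TEXT segment under `ABCF_`-prefixed
#' keywords. Annotated copies are written to `out_dir` under the
#' deterministic scheme `<experiment>_<plate>_<well>_<CD>_<clone>.fcs`;
#' originals are never touched. Re-annotating an already annotated file
#' overwrites (never duplicates) the keywords, and the DATA segment is
#' carried over unchanged.
#'
#' @param files character vector of FCS paths.
#' @param emt an `experiment_master_table` from [load_and_validate_emt()].
#' @param out_dir output directory (created if missing).
#' @return A list with `report` (a data frame: one row per input file and per
#'   unmatched EMT well, columns `file`, `well`, `status`, `output`) and
#'   `n_annotated`, `n_unmatched`. Status is one of `annotated`,
#'   `unparseable-name`, `no-emt-row`, `unused-emt-row`.
#' @export
annotate_batch <- function(files, emt, out_dir) {
  stopifnot(inherits(emt, "experiment_master_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- emt$table
  meta <- emt$meta
  report <- list()
  used_wells <- character(0)
  n_annotated <- 0L
  for (f in files) {
    well <- tryCatch(parse_default_filename(f), error = function(e) NA_character_)
    tab <- NULL
    if (is.na(well)) {
      # already-annotated files carry their well as a keyword
      tab <- tryCatch(read_fcs(f), error = function(e) NULL)
      if (!is.null(tab) && "ABCF_WELL" %in% names(tab$keywords)) {
        well <- tab$keywords[["ABCF_WELL"]]
      }
    }
    if (is.na(well)) {
      warning(sprintf("skipping '%s': unparseable file name", basename(f)),
              call. = FALSE)
      report[[length(report) + 1]] <- data.frame(
        file = basename(f), well = NA_character_,
        status = "unparseable-name", output = NA_character_)
      next
    }
    hit <- which(rows$well == well)
    if (length(hit) == 0) {
      report[[length(report) + 1]] <- data.frame(
        file = basename(f), well = well,
        status = "no-emt-row", output = NA_character_)
      next
    }
    r <- rows[hit[1], ]
    if (is.null(tab)) tab <- read_fcs(f)
    ann <- c(ABCF_CD = r$cd, ABCF_GENE = r$gene, ABCF_CLONE = r$clone,
             ABCF_VENDOR = r$vendor, ABCF_TITER = as.character(r$titer_volume_ul),
             ABCF_WELL = well, ABCF_PLATE = as.character(r$plate),
             ABCF_EXPERIMENT = meta$experiment, ABCF_OPERATOR = meta$operator,
             ABCF_LAB = meta$lab, ABCF_DATE = meta$date)
    tab$keywords[names(ann)] <- ann
    out_name <- sprintf("%s_%s_%s_%s_%s.fcs", meta$experiment, r$plate, well,
                        gsub("[^A-Za-z0-9.-]", "-", r$cd),
                        gsub("[^A-Za-z0-9.-]", "-", r$clone))
    out_path <- file.path(out_dir, out_name)
    write_fcs(tab, out_path)
    n_annotated <- n_annotated + 1L
    used_wells <- c(used_wells, well)
    report[[length(report) + 1]] <- data.frame(
      file = basename(f), well = well, status = "annotated",
      output = out_name)
  }
  unused <- setdiff(rows$well, used_wells)
  for (w in unused) {
    report[[length(report) + 1]] <- data.frame(
      file = NA_character_, well = w, status = "unused-emt-row",
      output = NA_character_)
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  n_unmatched <- sum(report$status %in% c("unparseable-name", "no-emt-row"))
  list(report = report, n_annotated = n_annotated, n_unmatched = n_unmatched)
}
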