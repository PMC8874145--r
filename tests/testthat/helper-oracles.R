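# independent oracles and fixture builders used across test files

# brute-force linear-interpolation quantile: sort, locate h = (n-1)p + 1,
# interpolate between the flanking order statistics
oracle_quantile <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# minimal raw-byte FCS reader, independent of the package's parser:
# header offsets per the format definition, naive TEXT split (no escape
# handling), float32 little-endian data
oracle_read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  off <- function(i) as.integer(trimws(rawToChar(
    raw[(11 + 8 * (i - 1)):(10 + 8 * i)])))
  tb <- off(1); te <- off(2)
  s <- rawToChar(raw[(tb + 1):(te + 1)])
  delim <- substr(s, 1, 1)
  parts <- strsplit(substring(s, 2), delim, fixed = TRUE)[[1]]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        parts[seq(1, length(parts), 2)])
  db <- as.integer(kw[["$BEGINDATA"]]); de <- as.integer(kw[["$ENDDATA"]])
  n_par <- as.integer(kw[["$PAR"]]); n_tot <- as.integer(kw[["$TOT"]])
  vals <- if (n_par * n_tot > 0) {
    readBin(raw[(db + 1):(de + 1)], "numeric", n = n_par * n_tot,
            size = 4, endian = "little")
  } else numeric(0)
  list(keywords = kw,
       exprs = matrix(vals, ncol = n_par, byrow = TRUE))
}

# small EMT data frame; wells get distinct reagents, last well is the FMO
make_emt_df <- function(wells = c("A1", "A2", "A3", "A4"), plate = "P1") {
  n <- length(wells)
  data.frame(
    plate = plate, well = wells,
    cd = c(paste0("CD", seq_len(n - 1)), "FMO"),
    clone = c(paste0("CL", seq_len(n - 1)), ""),
    gene = c(paste0("GENE", seq_len(n - 1)), ""),
    vendor = "VendorX",
    titer_volume_ul = c(rep(2.5, n - 1), 0),
    stringsAsFactors = FALSE)
}

# per-leaf recall and precision of a gate result against hidden labels
leaf_accuracy <- function(table, result) {
  leaves <- result$leaves
  truth <- table$labels
  out <- lapply(leaves, function(lf) {
    is_true <- truth == lf
    is_called <- !is.na(result$assignment) & result$assignment == lf
    data.frame(leaf = lf,
               n_true = sum(is_true),
               recall = sum(is_called & is_true) / max(1, sum(is_true)),
               precision = sum(is_called & is_true) / max(1, sum(is_called)))
  })
  do.call(rbind, out)
}

# tiny plate of default-named FCS files for annotation tests
write_plate_fcs <- function(dir, wells, n_events = 20, seed = 99) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(wells))
  for (i in seq_along(wells)) {
    tab <- generate_tube(
      list(population_spec("cells", 1,
                           c(`FSC-A` = 1e5, `SSC-A` = 2e4, PE = 500))),
      c("FSC-A", "FSC-H", "SSC-A", "PE"), n_events, seed + i)
    paths[i] <- file.path(dir, sprintf("Specimen_001_%s_%s%02d_%03d.fcs",
                                       wells[i], substr(wells[i], 1, 1),
                                       as.integer(substring(wells[i], 2)),
                                       i))
    write_fcs(tab, paths[i])
  }
  paths
}
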