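#' Spillover matrices and compensation
#'
#' A spillover matrix S has rows and columns named by fluorescence
#' channels, `S[i, j]` giving the fraction of channel i's true signal that
#' bleeds into detector j; the diagonal is exactly 1. Observed signals are
#' `true %*% S`, so compensation right-multiplies the observed fluorescence
#' block by `solve(S)` and inverts the generator's spillover exactly.
#'
#' @param mat square numeric matrix with identical row and column names.
#' @return A validated spillover matrix (class `spillover_matrix`).
#' @export
spillover_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("spillover matrix must be square",
                                   call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)) ||
      !identical(rownames(mat), colnames(mat))) {
    stop("spillover matrix needs identical row/column channel names",
         call. = FALSE)
  }
  if (any(abs(diag(mat) - 1) > 1e-12)) {
    stop("spillover matrix diagonal must be exactly 1", call. = FALSE)
  }
  d <- tryCatch(determinant(mat)$modulus, error = function(e) -Inf)
  if (!is.finite(d)) stop("spillover matrix is singular", call. = FALSE)
  structure(mat, class = c("spillover_matrix", "matrix"))
}

#' @rdname spillover_matrix
#' @param path CSV file: first column channel names, remaining columns the
#'   square matrix.
#' @export
read_spillover_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  spillover_matrix(m)
}

#' @rdname spillover_matrix
#' @param spill a `spillover_matrix`.
#' @export
write_spillover_csv <- function(spill, path) {
  df <- data.frame(channel = rownames(spill), as.data.frame(unclass(spill)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Apply spillover compensation to an event table
#'
#' Fluorescence columns named in the matrix are replaced by
#' `observed %*% solve(S)`; scatter and unlisted channels are untouched. A
#' keyword `ABCF_COMPENSATED` records the application. Negative compensated
#' values are retained (not clipped); the ABC conversion flags them
#' downstream.
#'
#' @param table an [event_table].
#' @param spill a [spillover_matrix()] whose channels are all present in
#'   `table`.
#' @return The compensated [event_table].
#' @export
compensate <- function(table, spill) {
  stopifnot(inherits(table, "event_table"))
  if (!inherits(spill, "spillover_matrix")) spill <- spillover_matrix(spill)
  ch <- rownames(spill)
  missing <- setdiff(ch, channels(table))
  if (length(missing)) {
    stop(sprintf("spillover channels absent from table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  inv <- solve(unclass(spill))
  out <- table
  out$exprs[, ch] <- table$exprs[, ch, drop = FALSE] %*% inv
  out$keywords["ABCF_COMPENSATED"] <- "1"
  out
}

#' Per-channel display transforms for gating
#'
#' Gate geometry is evaluated in a variance-stabilized space: fluorescence
#' channels get `asinh(x / cofactor)`, scatter channels the identity.
#' Quantitation (medians, ABC) always stays on the compensated linear
#' scale, so the transform affects gating only.
#'
#' @param channels channel names the spec covers.
#' @param transform `"arcsinh"` or `"identity"` per channel (recycled).
#' @param cofactor arcsinh cofactor (linear units), recycled; must be > 0.
#' @return A data frame of class `transform_spec`.
#' @export
transform_spec <- function(channels,
                           transform = ifelse(is_scatter_channel(channels),
                                              "identity", "arcsinh"),
                           cofactor = 150) {
  transform <- rep(transform, length.out = length(channels))
  cofactor <- rep(cofactor, length.out = length(channels))
  if (!all(transform %in% c("identity", "arcsinh"))) {
    stop("transform must be 'identity' or 'arcsinh'", call. = FALSE)
  }
  if (any(cofactor <= 0)) stop("cofactor must be > 0", call. = FALSE)
  structure(data.frame(channel = channels, transform = transform,
                       cofactor = cofactor, stringsAsFactors = FALSE),
            class = c("transform_spec", "data.frame"))
}

#' @rdname transform_spec
#' @param table an [event_table].
#' @param spec a `transform_spec` covering every channel to be transformed.
#' @return `apply_transform()`: a transformed copy of the table (keyword
#'   `ABCF_TRANSFORMED` set); untransformed channels pass through.
#' @export
apply_transform <- function(table, spec) {
  stopifnot(inherits(table, "event_table"), inherits(spec, "transform_spec"))
  missing <- setdiff(spec$channel, channels(table))
  if (length(missing)) {
    stop(sprintf("transform spec channels absent from table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- table
  for (i in seq_len(nrow(spec))) {
    if (spec$transform[i] == "arcsinh") {
      ch <- spec$channel[i]
      out$exprs[, ch] <- asinh(table$exprs[, ch] / spec$cofactor[i])
    }
  }
  out$keywords["ABCF_TRANSFORMED"] <- "1"
  out
}
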