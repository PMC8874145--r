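#' Event table: list-mode cytometry events plus keywords
#'
#' The central in-memory container of the package: a numeric matrix of
#' events (rows) by named channels (columns), a flat keyword map mirroring
#' the FCS TEXT segment, and an optional hidden ground-truth label vector
#' carried by synthetic data for validation.
#'
#' @param exprs numeric matrix, one row per event; must have column names
#'   (the short channel names, FCS `$PnN`).
#' @param keywords named character vector (or coercible list) of FCS-style
#'   keywords. May be empty.
#' @param labels optional character vector of per-event ground-truth
#'   population labels (synthetic data only); length must equal `nrow(exprs)`.
#'
#' @return An object of class `event_table` with elements `exprs`,
#'   `keywords` and (possibly `NULL`) `labels`.
#' @export
#' @examples
#' m <- matrix(rnorm(20, 100, 5), ncol = 2,
#'             dimnames = list(NULL, c("FSC-A", "PE")))
#' et <- event_table(m, keywords = c(`$SRC` = "example"))
#' n_events(et)
#' channels(et)
event_table <- function(exprs, keywords = character(), labels = NULL) {
  if (!is.matrix(exprs) || !is.numeric(exprs)) {
    stop("`exprs` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(colnames(exprs)) && ncol(exprs) > 0) {
    stop("`exprs` must have channel (column) names", call. = FALSE)
  }
  if (anyDuplicated(colnames(exprs))) {
    stop("duplicate channel names", call. = FALSE)
  }
  if (nrow(exprs) > 0 && any(!is.finite(exprs))) {
    stop("event values must be finite", call. = FALSE)
  }
  kw <- unlist(keywords)
  if (length(kw)) {
    kw <- stats::setNames(as.character(kw), names(keywords))
    if (is.null(names(kw)) || any(names(kw) == "")) {
      stop("all keywords must be named", call. = FALSE)
    }
  } else {
    kw <- stats::setNames(character(0), character(0))
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(exprs)) {
      stop("`labels` must have one entry per event", call. = FALSE)
    }
  }
  structure(list(exprs = exprs, keywords = kw, labels = labels),
            class = "event_table")
}

#' @rdname event_table
#' @param x an `event_table`.
#' @export
n_events <- function(x) {
  stopifnot(inherits(x, "event_table"))
  nrow(x$exprs)
}

#' @rdname event_table
#' @export
channels <- function(x) {
  stopifnot(inherits(x, "event_table"))
  colnames(x$exprs)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table: %d events x %d channels\n",
              nrow(x$exprs), ncol(x$exprs)))
  cat("channels:", paste(channels(x), collapse = ", "), "\n")
  if (length(x$keywords)) {
    cat(sprintf("keywords: %d\n", length(x$keywords)))
  }
  if (!is.null(x$labels)) {
    cat("ground-truth labels present\n")
  }
  invisible(x)
}

#' @rdname event_table
#' @param channel a channel name present in the table.
#' @return `channel_values()`: the channel's event values as a numeric
#'   vector (errors on an unknown name).
#' @export
channel_values <- function(x, channel) {
  stopifnot(inherits(x, "event_table"))
  if (!channel %in% channels(x)) {
    stop(sprintf("channel '%s' not present in event table", channel),
         call. = FALSE)
  }
  x$exprs[, channel]
}

# scatter channels are exempt from compensation/arcsinh by convention
is_scatter_channel <- function(nm) {
  grepl("^(FSC|SSC)", nm) | nm %in% c("Time", "TIME")
}
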