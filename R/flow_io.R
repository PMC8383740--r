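#' Flow-cytometry event table
#'
#' A thin container for per-cell measurements: a data frame with one numeric
#' column per channel, plus bookkeeping attributes (sample id and the
#' transform state of every channel).  Simulated tables additionally carry a
#' `true_generation` column (not a channel) so downstream estimates can be
#' checked against ground truth.
#'
#' @param data data.frame of numeric channel columns; may include the
#'   reserved columns `event_id` and `true_generation`.
#' @param sample_id character scalar identifying the sample.
#' @param transforms named character vector, one entry per channel, each one
#'   of `"linear"`, `"log10"` or `"arcsinh"`. Channels not named default to
#'   `"linear"`.
#' @return An object of class `event_table` (a data.frame subclass).
#' @examples
#' et <- event_table(data.frame(CellTrace = rnorm(5, 4)), sample_id = "s1",
#'                   transforms = c(CellTrace = "log10"))
#' channels(et)
#' @export
event_table <- function(data, sample_id = "sample", transforms = NULL) {
  stopifnot(is.data.frame(data))
  chans <- setdiff(names(data), c("event_id", "true_generation"))
  for (ch in chans) {
    if (!is.numeric(data[[ch]]))
      stop("channel '", ch, "' is not numeric", call. = FALSE)
  }
  tr <- rep("linear", length(chans))
  names(tr) <- chans
  if (!is.null(transforms)) {
    bad <- setdiff(names(transforms), chans)
    if (length(bad)) stop("transform given for unknown channel: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    ok <- transforms %in% c("linear", "log10", "arcsinh")
    if (!all(ok)) stop("unknown transform state: ",
                       paste(unique(transforms[!ok]), collapse = ", "),
                       call. = FALSE)
    tr[names(transforms)] <- transforms
  }
  structure(as.data.frame(data),
            sample_id = as.character(sample_id)[1],
            transforms = tr,
            class = c("event_table", "data.frame"))
}

#' @rdname event_table
#' @param x an `event_table`.
#' @export
channels <- function(x) {
  stopifnot(inherits(x, "event_table"))
  setdiff(names(x), c("event_id", "true_generation"))
}

#' @rdname event_table
#' @export
n_events <- function(x) nrow(x)

#' @rdname event_table
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' @rdname event_table
#' @export
transform_state <- function(x) attr(x, "transforms")

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> sample '%s': %d events, %d channel(s)\n",
              attr(x, "sample_id"), nrow(x), length(channels(x))))
  tr <- attr(x, "transforms")
  for (ch in channels(x))
    cat(sprintf("  %s [%s]\n", ch, tr[[ch]]))
  if ("true_generation" %in% names(x))
    cat("  + true_generation labels\n")
  invisible(x)
}

# rebuild attributes after row subsetting
restore_event_table <- function(df, template) {
  structure(as.data.frame(df),
            sample_id = attr(template, "sample_id"),
            transforms = attr(template, "transforms"),
            class = c("event_table", "data.frame"))
}

#' Transform a channel in place
#'
#' Applies `log10` (with a floor for non-positive values) or `arcsinh`
#' scaling to a linear channel.  The transform state is recorded per channel
#' and a second non-linear transform of the same channel is refused rather
#' than silently stacked.
#'
#' @param table an `event_table`.
#' @param channel channel name.
#' @param transform `"log10"` or `"arcsinh"`.
#' @param cofactor arcsinh cofactor (ignored for log10).
#' @param floor replacement for values `<= 0` before log10; default is the
#'   smallest positive measurement divided by 10.
#' @return the transformed `event_table`.
#' @export
transform_channel <- function(table, channel, transform = c("log10", "arcsinh"),
                              cofactor = 150, floor = NULL) {
  transform <- match.arg(transform)
  stopifnot(inherits(table, "event_table"))
  if (!channel %in% channels(table))
    stop("unknown channel '", channel, "'", call. = FALSE)
  tr <- attr(table, "transforms")
  if (tr[[channel]] != "linear")
    stop("channel '", channel, "' already carries transform '",
         tr[[channel]], "'; refusing to apply '", transform, "' on top",
         call. = FALSE)
  v <- table[[channel]]
  if (transform == "log10") {
    pos <- v[v > 0]
    if (is.null(floor)) {
      if (!length(pos)) stop("no positive values and no floor given",
                             call. = FALSE)
      floor <- min(pos) / 10
    }
    v[v <= 0] <- floor
    table[[channel]] <- log10(v)
  } else {
    table[[channel]] <- asinh(v / cofactor)
  }
  tr[[channel]] <- transform
  attr(table, "transforms") <- tr
  table
}

#' Rectangular gate
#'
#' @param ... named closed intervals, one per channel, e.g.
#'   `rect_gate(FSC = c(1e4, 2e5), SSC = c(0, 1e5))`.
#' @return object of class `rect_gate`.
#' @export
rect_gate <- function(...) {
  iv <- list(...)
  if (!length(iv) || is.null(names(iv)) || any(names(iv) == ""))
    stop("rect_gate() needs named channel intervals", call. = FALSE)
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2 || !is.numeric(v) || v[1] > v[2])
      stop("interval for '", nm, "' must be numeric c(lower, upper) with ",
           "lower <= upper", call. = FALSE)
  }
  structure(iv, class = "rect_gate")
}

#' Apply a rectangular gate
#'
#' Keeps events falling inside every interval; bounds are closed, so events
#' on a boundary are kept (FlowJo-compatible tie-break).
#'
#' @param table an `event_table`.
#' @param gate a [rect_gate()].
#' @return the gated `event_table`.
#' @export
apply_gate <- function(table, gate) {
  stopifnot(inherits(table, "event_table"), inherits(gate, "rect_gate"))
  missing <- setdiff(names(gate), channels(table))
  if (length(missing))
    stop("gate channel(s) not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- rep(TRUE, nrow(table))
  for (nm in names(gate)) {
    v <- table[[nm]]
    keep <- keep & v >= gate[[nm]][1] & v <= gate[[nm]][2]
  }
  restore_event_table(table[keep, , drop = FALSE], table)
}

#' Downsample several samples to an equal event count
#'
#' Mirrors the common practice of sampling an equal number of viable single
#' cells across all samples before pooled analyses: each table is subsampled
#' without replacement to exactly `n` events.
#'
#' @param tables list of `event_table`s.
#' @param n target event count; every table must have at least `n` events.
#' @param seed integer seed (selection is deterministic given the seed).
#' @return list of downsampled `event_table`s.
#' @export
downsample_equal <- function(tables, n, seed = NULL) {
  stopifnot(is.list(tables), n >= 1)
  for (t in tables) stopifnot(inherits(t, "event_table"))
  sizes <- vapply(tables, nrow, integer(1))
  if (any(sizes < n)) {
    bad <- vapply(tables[sizes < n], function(t) attr(t, "sample_id"),
                  character(1))
    stop("sample(s) with fewer than ", n, " events: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, lapply(tables, function(t) {
    idx <- sample.int(nrow(t), n)
    restore_event_table(t[idx, , drop = FALSE], t)
  }))
}

#' Read / write event tables as CSV
#'
#' CSV files use one header row of channel names; the reserved columns
#' `event_id` and `true_generation` round-trip when present.
#'
#' @param table an `event_table`.
#' @param path file path.
#' @param sample_id sample id to attach on read (defaults to file name).
#' @param transforms transform state to record on read.
#' @return `read_events_csv` returns an `event_table`; `write_events_csv`
#'   returns `path` invisibly.
#' @export
write_events_csv <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path, sample_id = NULL, transforms = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  event_table(df, sample_id = sample_id, transforms = transforms)
}
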