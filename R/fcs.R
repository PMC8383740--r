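# Minimal FCS support: list-mode, single dataset, datatypes F/D/I,
# little- or big-endian.  Anything else is rejected loudly -- the goal is
# bit-exact round-tripping of the files this package writes plus reading
# plain instrument exports, not dialect breadth.

FCS_HEADER_LEN <- 58L

fcs_pad_offset <- function(x) formatC(x, width = 8, flag = " ")

#' Read an FCS 3.0/3.1 file
#'
#' Parses the HEADER and TEXT segments, then decodes the DATA segment
#' according to `$DATATYPE`, `$PnB` and `$BYTEORD`.  Channel names come from
#' `$PnN`.  Only list-mode (`$MODE L`) single-dataset files with datatype
#' `F`, `D` or `I` are supported; unsupported files fail with an error naming
#' the offending keyword.
#'
#' @param path path to an FCS file.
#' @param sample_id sample id for the resulting table (default: `$FIL`
#'   keyword if present, else the file name).
#' @param transforms optional transform state to record (FCS itself stores
#'   raw values; the caller knows what scale they are on).
#' @return an [event_table()].
#' @export
read_fcs <- function(path, sample_id = NULL, transforms = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  fsize <- file.size(path)
  header <- readChar(con, FCS_HEADER_LEN, useBytes = TRUE)
  if (nchar(header) < FCS_HEADER_LEN)
    stop("not an FCS file: header shorter than ", FCS_HEADER_LEN, " bytes",
         call. = FALSE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", version, "'", call. = FALSE)
  off <- function(a, b) suppressWarnings(as.integer(trimws(substr(header, a, b))))
  text_beg <- off(11, 18); text_end <- off(19, 26)
  data_beg <- off(27, 34); data_end <- off(35, 42)
  if (is.na(text_beg) || is.na(text_end) || text_end < text_beg)
    stop("malformed HEADER: bad TEXT offsets", call. = FALSE)

  seek(con, text_beg)
  raw_text <- readChar(con, text_end - text_beg + 1, useBytes = TRUE)
  delim <- substr(raw_text, 1, 1)
  body <- substr(raw_text, 2, nchar(raw_text))
  # strip one trailing delimiter if present
  if (substr(body, nchar(body), nchar(body)) == delim)
    body <- substr(body, 1, nchar(body) - 1)
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 != 0)
    stop("malformed TEXT segment: odd number of tokens", call. = FALSE)
  keys <- toupper(trimws(parts[seq(1, length(parts), 2)]))
  vals <- parts[seq(2, length(parts), 2)]
  kw <- stats::setNames(vals, keys)

  need <- function(k) {
    if (!k %in% names(kw)) stop("missing required FCS keyword ", k,
                                call. = FALSE)
    kw[[k]]
  }
  if (toupper(need("$MODE")) != "L")
    stop("unsupported $MODE '", kw[["$MODE"]], "' (only list mode)",
         call. = FALSE)
  if ("$NEXTDATA" %in% names(kw) && as.integer(kw[["$NEXTDATA"]]) != 0)
    stop("multiple datasets per file are not supported ($NEXTDATA != 0)",
         call. = FALSE)
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D", "I"))
    stop("unsupported $DATATYPE '", dtype, "'", call. = FALSE)
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop("unsupported $BYTEORD '", byteord, "'", call. = FALSE)
  par <- as.integer(need("$PAR"))
  tot <- as.integer(need("$TOT"))

  ch_names <- character(par)
  bits <- integer(par)
  for (p in seq_len(par)) {
    ch_names[p] <- need(sprintf("$P%dN", p))
    bits[p] <- as.integer(need(sprintf("$P%dB", p)))
  }
  if (dtype == "F" && any(bits != 32))
    stop("$DATATYPE F requires $PnB 32", call. = FALSE)
  if (dtype == "D" && any(bits != 64))
    stop("$DATATYPE D requires $PnB 64", call. = FALSE)
  if (dtype == "I" && !all(bits %in% c(16L, 32L)))
    stop("$DATATYPE I supports only $PnB 16 or 32", call. = FALSE)
  if (dtype == "I" && length(unique(bits)) > 1)
    stop("mixed $PnB widths are not supported", call. = FALSE)

  if (is.na(data_beg) || data_beg == 0) {
    data_beg <- as.integer(need("$BEGINDATA"))
    data_end <- as.integer(need("$ENDDATA"))
  }
  bytes_per <- bits[1] %/% 8L
  expected <- as.numeric(tot) * par * bytes_per
  if (tot > 0) {
    avail <- min(data_end, fsize - 1) - data_beg + 1
    if (avail < expected)
      stop(sprintf("truncated DATA segment: need %d bytes, have %d",
                   expected, max(avail, 0)), call. = FALSE)
  }

  if (tot > 0) {
    seek(con, data_beg)
    n_vals <- tot * par
    vals <- switch(dtype,
      F = readBin(con, "numeric", n = n_vals, size = 4, endian = endian),
      D = readBin(con, "numeric", n = n_vals, size = 8, endian = endian),
      I = {
        if (bytes_per == 2)
          readBin(con, "integer", n = n_vals, size = 2, signed = FALSE,
                  endian = endian)
        else {
          # 32-bit unsigned: read as signed and fix the wrap
          v <- readBin(con, "integer", n = n_vals, size = 4, endian = endian)
          v <- as.numeric(v)
          v[v < 0] <- v[v < 0] + 2^32
          v
        }
      })
    mat <- matrix(as.numeric(vals), nrow = tot, ncol = par, byrow = TRUE)
  } else {
    mat <- matrix(numeric(0), nrow = 0, ncol = par)
  }
  colnames(mat) <- ch_names
  if (is.null(sample_id))
    sample_id <- if ("$FIL" %in% names(kw)) kw[["$FIL"]] else basename(path)
  event_table(as.data.frame(mat), sample_id = sample_id,
              transforms = transforms)
}

#' Write an FCS 3.1 file
#'
#' Writes list-mode, 32-bit float, little-endian data (one `$PnB 32` /
#' `$PnE 0,0` parameter per channel).  Values round-trip through [read_fcs()]
#' at float32 precision; the reserved `event_id`/`true_generation` columns
#' are not written (use CSV to preserve them).
#'
#' @param table an [event_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  chans <- channels(table)
  if (!length(chans)) stop("event table has no channels", call. = FALSE)
  mat <- as.matrix(as.data.frame(table)[, chans, drop = FALSE])
  if (nrow(mat) && !all(is.finite(mat)))
    stop("non-finite values cannot be written to FCS", call. = FALSE)
  par <- ncol(mat); tot <- nrow(mat)

  make_text <- function(data_beg, data_end) {
    kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
            "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
            "$BEGINDATA", as.character(data_beg),
            "$ENDDATA", as.character(data_end),
            "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
            "$NEXTDATA", "0",
            "$PAR", as.character(par), "$TOT", as.character(tot),
            "$FIL", attr(table, "sample_id"))
    for (p in seq_len(par)) {
      rng <- if (tot) max(abs(mat[, p])) * 2 + 1 else 262144
      kv <- c(kv,
              sprintf("$P%dN", p), chans[p],
              sprintf("$P%dB", p), "32",
              sprintf("$P%dE", p), "0,0",
              sprintf("$P%dR", p), format(ceiling(rng), scientific = FALSE))
    }
    paste0("/", paste(kv, collapse = "/"), "/")
  }

  # TEXT length depends on the data offsets it must contain; iterate to a
  # fixed point (converges in <= 3 rounds since digit counts stabilize).
  data_beg <- FCS_HEADER_LEN + 1L
  data_end <- data_beg
  text <- ""
  for (i in 1:5) {
    text <- make_text(data_beg, data_end)
    text_beg <- FCS_HEADER_LEN
    text_end <- text_beg + nchar(text) - 1L
    new_beg <- text_end + 1L
    new_end <- new_beg + max(tot * par * 4L - 1L, 0L)
    if (new_beg == data_beg && new_end == data_end) break
    data_beg <- new_beg; data_end <- new_end
  }
  text_beg <- FCS_HEADER_LEN
  text_end <- text_beg + nchar(text) - 1L

  header <- paste0("FCS3.1    ",
                   fcs_pad_offset(text_beg), fcs_pad_offset(text_end),
                   fcs_pad_offset(data_beg),
                   fcs_pad_offset(if (tot) data_end else 0L),
                   fcs_pad_offset(0L), fcs_pad_offset(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  if (tot)
    writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}
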