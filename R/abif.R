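#' @useDynLib glycge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ABIF element sizes by type code (only the types the reader decodes;
# anything else is kept as raw bytes).
.abif_elt_size <- c(`1` = 1L, `2` = 1L, `4` = 2L, `5` = 4L, `7` = 4L, `8` = 8L)

#' Parse an ABIF tag specification
#'
#' Tag specs are strings of the form `"NAME,number"`, e.g. `"DATA,1"`.
#'
#' @param spec character scalar `"NAME,number"`.
#' @return list with elements `name` (4 characters) and `number` (integer).
#' @export
abif_tag <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  if (length(parts) != 2L || nchar(parts[1]) != 4L || is.na(suppressWarnings(as.integer(parts[2]))))
    stop("invalid ABIF tag spec '", spec, "': expected 'NAME,number' with a 4-character name")
  list(name = parts[1], number = as.integer(parts[2]))
}

#' Read an ABIF (.fsa/.ab1) trace file
#'
#' Decodes the ABIF directory and all payloads it can interpret. All
#' multi-byte fields are big-endian per the ABIF specification. Numeric
#' arrays of element type 4 (16-bit) and 5 (32-bit signed integer) are
#' decoded to integer vectors; other element types are retained as raw
#' bytes so no payload is silently dropped.
#'
#' @param path path to an ABIF file.
#' @return an object of class `abif_record`: list with `version`,
#'   `directory` (list of entries with `name`, `number`, `type`,
#'   `n_elements`, `data`), and `provenance`.
#' @export
read_abif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "ABIF"))
    stop("not an ABIF file (bad magic '", magic, "'): ", path)
  version <- readBin(con, "integer", 1L, size = 2L, signed = TRUE, endian = "big")
  hdr <- .abif_read_dir_entry(con)
  if (!identical(hdr$name, "tdir"))
    stop("corrupt ABIF header: directory entry named '", hdr$name, "', expected 'tdir'")
  n_entries <- hdr$n_elements
  if (n_entries < 0L || hdr$offset + 28 * n_entries > size)
    stop("corrupt ABIF file: directory (", n_entries,
         " entries at offset ", hdr$offset, ") exceeds file size ", size)
  seek(con, hdr$offset)
  entries <- vector("list", n_entries)
  for (k in seq_len(n_entries)) entries[[k]] <- .abif_read_dir_entry(con)
  keys <- vapply(entries, function(e) paste0(e$name, ",", e$number), character(1))
  if (anyDuplicated(keys))
    stop("corrupt ABIF file: duplicate directory entry ", keys[duplicated(keys)][1])
  directory <- lapply(entries, function(e) {
    elt <- .abif_elt_size[as.character(e$type)]
    if (!is.na(elt) && e$data_size != elt * e$n_elements)
      stop("corrupt ABIF tag ", e$name, ",", e$number, ": payload size ",
           e$data_size, " != ", e$n_elements, " elements of ", elt, " bytes")
    if (e$data_size <= 4L) {
      payload_raw <- e$inline[seq_len(max(e$data_size, 0L))]
    } else {
      if (e$offset < 0L || e$offset + e$data_size > size)
        stop("corrupt ABIF tag ", e$name, ",", e$number,
             ": payload (", e$data_size, " bytes at ", e$offset,
             ") exceeds file size ", size)
      seek(con, e$offset)
      payload_raw <- readBin(con, "raw", e$data_size)
      if (length(payload_raw) < e$data_size)
        stop("corrupt ABIF tag ", e$name, ",", e$number, ": truncated payload")
    }
    data <- .abif_decode(payload_raw, e$type, e$n_elements)
    list(name = e$name, number = e$number, type = e$type,
         n_elements = e$n_elements, data = data)
  })
  names(directory) <- keys
  structure(list(version = version, directory = directory, provenance = path),
            class = "abif_record")
}

.abif_read_dir_entry <- function(con) {
  name <- readChar(con, 4L, useBytes = TRUE)
  number <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  type <- readBin(con, "integer", 1L, size = 2L, signed = TRUE, endian = "big")
  elt_size <- readBin(con, "integer", 1L, size = 2L, signed = TRUE, endian = "big")
  n_elements <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  data_size <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  inline <- readBin(con, "raw", 4L)
  offset <- sum(as.integer(inline) * c(16777216, 65536, 256, 1))
  if (offset > .Machine$integer.max) offset <- offset - 4294967296
  readBin(con, "raw", 4L)  # data handle, unused
  if (length(name) == 0L || any(is.na(c(number, type, elt_size, n_elements, data_size))))
    stop("corrupt ABIF file: truncated directory entry")
  list(name = name, number = number, type = type, elt_size = elt_size,
       n_elements = n_elements, data_size = data_size,
       inline = inline, offset = offset)
}

.abif_decode <- function(raw, type, n) {
  if (type == 4L) readBin(raw, "integer", n, size = 2L, signed = TRUE, endian = "big")
  else if (type == 5L) readBin(raw, "integer", n, size = 4L, endian = "big")
  else if (type == 1L) as.integer(raw)
  else if (type == 2L) rawToChar(raw)
  else if (type == 7L) readBin(raw, "numeric", n, size = 4L, endian = "big")
  else if (type == 8L) readBin(raw, "numeric", n, size = 8L, endian = "big")
  else raw
}

#' Write a minimal ABIF file
#'
#' Emits a spec-conformant ABIF container holding the supplied integer
#' channels, readable by [read_abif()] with bit-faithful payloads. Values
#' within 16-bit range are written as element type 4 (short); larger
#' magnitudes as type 5 (32-bit).
#'
#' @param channels named list of integer vectors; names are tag specs such
#'   as `"DATA,1"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abif <- function(channels, path) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list with tag-spec names like 'DATA,1'")
  tags <- lapply(names(channels), abif_tag)
  payloads <- lapply(seq_along(channels), function(k) {
    v <- channels[[k]]
    if (length(v) == 0L) stop("empty channel: ", names(channels)[k])
    if (any(!is.finite(v))) stop("non-finite values in channel ", names(channels)[k])
    if (any(v != round(v))) stop("non-integer values in channel ", names(channels)[k])
    if (any(abs(v) > 2147483647)) stop("values in channel ", names(channels)[k],
                                       " exceed 32-bit signed range")
    type <- if (all(abs(v) <= 32767)) 4L else 5L
    list(type = type, values = as.integer(v))
  })
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("ABIF", con, eos = NULL, useBytes = TRUE)
  writeBin(101L, con, size = 2L, endian = "big")
  # header directory entry written after payload offsets are known;
  # reserve the 28-byte slot plus the 47 reserved shorts now.
  header_at <- seek(con)
  writeBin(raw(28L + 94L), con)
  data_at <- seek(con)
  offsets <- integer(length(payloads))
  sizes <- integer(length(payloads))
  for (k in seq_along(payloads)) {
    p <- payloads[[k]]
    elt <- if (p$type == 4L) 2L else 4L
    sizes[k] <- elt * length(p$values)
    offsets[k] <- seek(con)
    writeBin(p$values, con, size = elt, endian = "big")
  }
  dir_at <- seek(con)
  for (k in seq_along(payloads)) {
    p <- payloads[[k]]
    elt <- if (p$type == 4L) 2L else 4L
    .abif_write_dir_entry(con, tags[[k]]$name, tags[[k]]$number, p$type, elt,
                          length(p$values), sizes[k], offsets[k],
                          inline = if (sizes[k] <= 4L) p$values else NULL)
  }
  seek(con, header_at)
  .abif_write_dir_entry(con, "tdir", 1L, 1023L, 28L, length(payloads),
                        28L * length(payloads), dir_at)
  invisible(path)
}

.abif_write_dir_entry <- function(con, name, number, type, elt_size,
                                  n_elements, data_size, offset, inline = NULL) {
  writeChar(name, con, eos = NULL, useBytes = TRUE)
  writeBin(as.integer(number), con, size = 4L, endian = "big")
  writeBin(as.integer(type), con, size = 2L, endian = "big")
  writeBin(as.integer(elt_size), con, size = 2L, endian = "big")
  writeBin(as.integer(n_elements), con, size = 4L, endian = "big")
  writeBin(as.integer(data_size), con, size = 4L, endian = "big")
  if (!is.null(inline) && data_size <= 4L) {
    buf <- raw(4L)
    enc <- writeBin(inline, raw(), size = if (type == 4L) 2L else 4L, endian = "big")
    buf[seq_along(enc)] <- enc
    writeBin(buf, con)
  } else {
    writeBin(as.integer(offset), con, size = 4L, endian = "big")
  }
  writeBin(0L, con, size = 4L, endian = "big")  # data handle
}

#' Construct a raw fluorescence trace
#'
#' @param values numeric vector of fluorescence intensities at uniform scan
#'   spacing.
#' @param channel_tag tag spec of origin (e.g. `"DATA,1"`), or `"synthetic"`.
#' @param sample_id free-text sample identifier.
#' @return object of class `raw_trace`.
#' @export
raw_trace <- function(values, channel_tag = "synthetic", sample_id = "") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a trace needs at least 2 samples")
  if (any(!is.finite(values))) stop("non-finite values in trace")
  structure(list(values = values, channel_tag = channel_tag,
                 sample_id = sample_id),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat("<raw_trace> ", length(x$values), " scans, channel ", x$channel_tag,
      if (nzchar(x$sample_id)) paste0(", sample ", x$sample_id), "\n", sep = "")
  invisible(x)
}

#' Extract glycan and size-standard channels from an ABIF record
#'
#' Defaults correspond to a 3130XL configuration where `DATA,1` holds the
#' APTS-labelled glycan fluorescence (522 nm) and `DATA,105` the LIZ-labelled
#' oligonucleotide standard (655 nm). Other instruments map dyes to other
#' DATA numbers, so both tags are configurable.
#'
#' @param record an `abif_record` from [read_abif()].
#' @param glycan_tag,ladder_tag tag specs of the two channels.
#' @param sample_id sample identifier attached to both traces.
#' @return list with elements `glycan` and `ladder`, both `raw_trace`.
#' @export
extract_channels <- function(record, glycan_tag = "DATA,1",
                             ladder_tag = "DATA,105", sample_id = "") {
  stopifnot(inherits(record, "abif_record"))
  get_ch <- function(tag) {
    if (!tag %in% names(record$directory)) {
      avail <- grep("^DATA,", names(record$directory), value = TRUE)
      stop("channel not found: ", tag, "; available DATA tags: ",
           if (length(avail)) paste(avail, collapse = ", ") else "(none)")
    }
    record$directory[[tag]]$data
  }
  g <- get_ch(glycan_tag)
  l <- get_ch(ladder_tag)
  if (length(g) != length(l))
    stop("channels do not co-migrate: ", glycan_tag, " has ", length(g),
         " scans but ", ladder_tag, " has ", length(l))
  list(glycan = raw_trace(g, glycan_tag, sample_id),
       ladder = raw_trace(l, ladder_tag, sample_id))
}

#' Read a plain-text two-column trace
#'
#' Fallback for users without binary files: a TSV with columns
#' `scan` and `intensity` (header optional).
#'
#' @param path file path.
#' @param channel_tag,sample_id provenance attached to the trace.
#' @return a `raw_trace`.
#' @export
read_trace_tsv <- function(path, channel_tag = "text", sample_id = "") {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = has_header, sep = "\t")
  if (ncol(df) < 2L) stop("expected two tab-separated columns in ", path)
  ord <- order(df[[1]])
  raw_trace(df[[2]][ord], channel_tag, sample_id)
}

#' Write a trace as two-column TSV
#' @param trace a `raw_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  utils::write.table(
    data.frame(scan = seq_along(trace$values), intensity = trace$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
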