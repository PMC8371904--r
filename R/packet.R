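#' Packet field layout
#'
#' Describes the on-the-wire structure of one encoded packet. In
#' `seed_based` mode a packet stores the RNG seed from which the decoder
#' re-derives the degree and chunk selection; in `explicit_list` mode it
#' stores the chunk indices themselves (required for unequal error
#' protection, where seeded reconstruction is impossible). Field widths are
#' freely configurable; a width of 0 omits the field, in which case the
#' information must travel out-of-band. All integers are big-endian.
#'
#' The serialized order is: total chunk count, seed (or degree + chunk id
#' list), payload, checksum. The checksum covers every serialized byte that
#' precedes it, so corruption of the seed or chunk-count fields — fatal for
#' decoding — is detected as well.
#'
#' @param mode `"seed_based"` or `"explicit_list"`.
#' @param num_chunks_width bytes for the total-chunk-count field (0 omits).
#' @param seed_width bytes for the seed (seed_based; commonly 2 or 4).
#' @param degree_width bytes for the degree field (explicit_list; 0 infers
#'   the degree from the record length).
#' @param chunk_id_width bytes per chunk index (explicit_list).
#' @param checksum one of `"nocode"`, `"crc8"`, `"crc32"`, `"reed_solomon"`.
#' @param rs_symbols Reed-Solomon parity byte count (reed_solomon only).
#' @return an object of class `packet_layout`.
#' @examples
#' packet_layout()  # 4-byte chunk count, 4-byte seed, CRC-32
#' packet_layout(seed_width = 2, checksum = "reed_solomon", rs_symbols = 4)
#' @export
packet_layout <- function(mode = c("seed_based", "explicit_list"),
                          num_chunks_width = 4L,
                          seed_width = 4L,
                          degree_width = 0L,
                          chunk_id_width = 2L,
                          checksum = c("crc32", "crc8", "nocode",
                                       "reed_solomon"),
                          rs_symbols = 2L) {
  mode <- match.arg(mode)
  checksum <- match.arg(checksum)
  for (w in list(num_chunks_width, seed_width, degree_width, chunk_id_width)) {
    if (!is_count(w)) stop_param("field widths must be non-negative integers")
  }
  if (mode == "seed_based" && seed_width < 1L) {
    stop_param("seed_based mode requires seed_width >= 1")
  }
  if (mode == "explicit_list" && chunk_id_width < 1L) {
    stop_param("explicit_list mode requires chunk_id_width >= 1")
  }
  if (checksum == "reed_solomon" && !is_count(rs_symbols, min = 1L)) {
    stop_param("rs_symbols must be a positive integer")
  }
  structure(list(mode = mode,
                 num_chunks_width = as.integer(num_chunks_width),
                 seed_width = as.integer(seed_width),
                 degree_width = as.integer(degree_width),
                 chunk_id_width = as.integer(chunk_id_width),
                 checksum = checksum,
                 rs_symbols = as.integer(rs_symbols)),
            class = "packet_layout")
}

checksum_width <- function(layout) {
  switch(layout$checksum,
         nocode = 0L, crc8 = 1L, crc32 = 4L,
         reed_solomon = layout$rs_symbols)
}

#' @rdname packet_layout
#' @param layout a `packet_layout`.
#' @param chunk_size payload length in bytes.
#' @param degree packet degree (needed for `explicit_list` layouts, whose
#'   length grows with the chunk id list).
#' @return `serialized_packet_length()`: the total serialized length in
#'   bytes. For `seed_based` layouts this depends on the layout and chunk
#'   size only, so all packets of one encoding share one length.
#' @export
serialized_packet_length <- function(layout, chunk_size, degree = NULL) {
  stopifnot(inherits(layout, "packet_layout"))
  base <- layout$num_chunks_width + chunk_size + checksum_width(layout)
  if (layout$mode == "seed_based") {
    as.integer(base + layout$seed_width)
  } else {
    if (is.null(degree)) stop_param("explicit_list length requires a degree")
    as.integer(base + layout$degree_width + degree * layout$chunk_id_width)
  }
}

#' Construct an encoded packet
#'
#' One packet is a single encoded symbol: the XOR of the selected chunks,
#' plus the metadata needed to re-derive (or read off) that selection.
#' Exactly one of `seed` / `chunk_ids` must be given, matching the layout
#' mode. Chunk indices are 0-based.
#'
#' @param payload raw vector (one chunk-size worth of XORed data).
#' @param seed unsigned integer seed (seed_based mode).
#' @param chunk_ids 0-based integer vector of distinct chunk indices
#'   (explicit_list mode).
#' @param total_chunks total number of chunks of the encoding, or `NULL`.
#' @param degree packet degree; defaults to `length(chunk_ids)` when ids are
#'   given.
#' @return an object of class `fountain_packet`.
#' @export
fountain_packet <- function(payload, seed = NULL, chunk_ids = NULL,
                            total_chunks = NULL, degree = NULL) {
  if (!is.raw(payload)) stop_param("payload must be a raw vector")
  if (is.null(seed) == is.null(chunk_ids)) {
    stop_param("exactly one of seed / chunk_ids must be supplied")
  }
  if (!is.null(chunk_ids)) {
    if (anyDuplicated(chunk_ids)) stop_param("chunk_ids must be distinct")
    chunk_ids <- as.integer(chunk_ids)
    if (is.null(degree)) degree <- length(chunk_ids)
  }
  structure(list(payload = payload, seed = seed, chunk_ids = chunk_ids,
                 total_chunks = if (!is.null(total_chunks))
                   as.integer(total_chunks),
                 degree = if (!is.null(degree)) as.integer(degree)),
            class = "fountain_packet")
}

#' @export
print.fountain_packet <- function(x, ...) {
  id <- if (!is.null(x$seed)) sprintf("seed=%.0f", x$seed)
        else sprintf("ids=[%s]", paste(x$chunk_ids, collapse = ","))
  cat(sprintf("<fountain_packet %s degree=%s payload=%dB>\n", id,
              x$degree %||% "?", length(x$payload)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / deserialize packets
#'
#' `serialize_packet()` concatenates the layout's fields (chunk count, seed
#' or degree + chunk id list, payload) big-endian in their configured widths
#' and appends the checksum computed over all preceding bytes.
#' `deserialize_packet()` inverts this; the checksum is verified (for
#' Reed-Solomon, up to `floor(rs_symbols/2)` byte errors are corrected
#' first) and a failure raises an integrity error so that the caller can
#' treat the packet as erased — mirroring the erasure channel.
#'
#' @param p a [fountain_packet()].
#' @param layout a [packet_layout()].
#' @return `serialize_packet()`: a raw vector.
#' @export
serialize_packet <- function(p, layout) {
  stopifnot(inherits(p, "fountain_packet"), inherits(layout, "packet_layout"))
  parts <- list()
  if (layout$num_chunks_width > 0L) {
    if (is.null(p$total_chunks)) {
      stop_param("layout stores the chunk count but packet has none")
    }
    parts$nc <- int_to_bytes(p$total_chunks, layout$num_chunks_width)
  }
  if (layout$mode == "seed_based") {
    if (is.null(p$seed)) stop_param("seed_based layout but packet has no seed")
    parts$seed <- int_to_bytes(p$seed, layout$seed_width)
  } else {
    if (is.null(p$chunk_ids)) {
      stop_param("explicit_list layout but packet has no chunk_ids")
    }
    if (layout$degree_width > 0L) {
      parts$deg <- int_to_bytes(length(p$chunk_ids), layout$degree_width)
    }
    parts$ids <- do.call(c, lapply(p$chunk_ids, int_to_bytes,
                                   width = layout$chunk_id_width))
  }
  parts$payload <- p$payload
  body <- do.call(c, unname(parts))
  c(body, compute_checksum(body, layout$checksum, layout$rs_symbols))
}

#' @rdname serialize_packet
#' @param raw_bytes serialized packet bytes.
#' @param chunk_size payload length in bytes.
#' @return `deserialize_packet()`: the parsed [fountain_packet()].
#' @export
deserialize_packet <- function(raw_bytes, layout, chunk_size) {
  stopifnot(inherits(layout, "packet_layout"))
  n <- length(raw_bytes)
  ckw <- checksum_width(layout)
  fixed <- layout$num_chunks_width + chunk_size + ckw
  if (layout$mode == "seed_based") {
    if (n != fixed + layout$seed_width) {
      stop_format(sprintf("packet length %d does not match layout (%d)",
                          n, fixed + layout$seed_width))
    }
  } else {
    rest <- n - fixed - layout$degree_width
    if (rest < 0L || rest %% layout$chunk_id_width != 0L) {
      stop_format("packet length inconsistent with explicit_list layout")
    }
  }

  if (layout$checksum == "reed_solomon") {
    corrected <- rs_correct(raw_bytes, layout$rs_symbols)
    raw_bytes <- corrected
  } else if (ckw > 0L) {
    body <- raw_bytes[seq_len(n - ckw)]
    want <- raw_bytes[(n - ckw + 1L):n]
    got <- compute_checksum(body, layout$checksum, layout$rs_symbols)
    if (!identical(as.raw(got), as.raw(want))) {
      stop_integrity("packet checksum mismatch")
    }
  }

  pos <- 1L
  take <- function(k) {
    out <- raw_bytes[seq.int(pos, length.out = k)]
    pos <<- pos + k
    out
  }
  total_chunks <- NULL
  if (layout$num_chunks_width > 0L) {
    total_chunks <- bytes_to_int(take(layout$num_chunks_width))
  }
  if (layout$mode == "seed_based") {
    seed <- bytes_to_int(take(layout$seed_width))
    payload <- take(chunk_size)
    fountain_packet(payload, seed = seed, total_chunks = total_chunks)
  } else {
    if (layout$degree_width > 0L) {
      degree <- bytes_to_int(take(layout$degree_width))
    } else {
      degree <- (n - fixed) %/% layout$chunk_id_width
    }
    ids <- vapply(seq_len(degree),
                  function(i) bytes_to_int(take(layout$chunk_id_width)), 0)
    payload <- take(chunk_size)
    fountain_packet(payload, chunk_ids = as.integer(ids),
                    total_chunks = total_chunks)
  }
}

#' Header chunk with file metadata
#'
#' The optional header chunk travels as chunk 0 and participates in the
#' encoding like any data chunk. It stores the number of zero bytes padded
#' onto the last chunk (2 bytes, big-endian) followed by the UTF-8 file
#' name, zero-padded to the chunk size, so the decoder can restore the file
#' byte-exactly under its original name. File names must not contain NUL.
#'
#' @param filename file name (UTF-8; may be empty).
#' @param last_chunk_padding number of zero bytes appended to the last data
#'   chunk during splitting.
#' @param chunk_size chunk size in bytes; the encoded header must fit.
#' @return `build_header_chunk()`: a raw vector of length `chunk_size`.
#' @export
build_header_chunk <- function(filename, last_chunk_padding, chunk_size) {
  if (!is_count(last_chunk_padding) || last_chunk_padding >= 65536) {
    stop_param("last_chunk_padding must be an integer in [0, 65536)")
  }
  fn <- charToRaw(enc2utf8(filename))
  if (any(fn == as.raw(0))) stop_param("filename must not contain NUL bytes")
  if (2L + length(fn) > chunk_size) {
    stop_param("filename does not fit into the chunk size")
  }
  c(int_to_bytes(last_chunk_padding, 2L), fn,
    raw(chunk_size - 2L - length(fn)))
}

#' @rdname build_header_chunk
#' @param chunk raw vector: the decoded header chunk.
#' @return `parse_header_chunk()`: list with `filename` and `padding`.
#' @export
parse_header_chunk <- function(chunk) {
  if (length(chunk) < 2L) stop_format("header chunk too short")
  padding <- bytes_to_int(chunk[1:2])
  rest <- chunk[-(1:2)]
  nz <- which(rest != as.raw(0))
  fn <- if (length(nz)) rawToChar(rest[seq_len(max(nz))]) else ""
  list(filename = fn, padding = padding)
}

## ---- binary packet container --------------------------------------------

CONTAINER_MAGIC <- charToRaw("NFC1")

layout_mode_code <- c(seed_based = 0L, explicit_list = 1L)
layout_checksum_code <- c(nocode = 0L, crc8 = 1L, crc32 = 2L,
                          reed_solomon = 3L)

#' Binary packet container file
#'
#' Stores serialized packets in one file with a small self-describing
#' preamble: magic `"NFC1"`, one layout descriptor (mode, field widths,
#' checksum kind, Reed-Solomon symbol count, 2-byte chunk size) and a 4-byte
#' packet count, followed by the concatenated packets. For `explicit_list`
#' layouts each packet record is preceded by its own 2-byte length.
#'
#' @param packets list of [fountain_packet()]s.
#' @param layout the [packet_layout()] used to serialize.
#' @param chunk_size payload size in bytes.
#' @param path file path.
#' @return `write_packet_container()`: `path`, invisibly.
#' @export
write_packet_container <- function(packets, layout, chunk_size, path) {
  hdr <- c(CONTAINER_MAGIC,
           as.raw(layout_mode_code[[layout$mode]]),
           as.raw(layout$num_chunks_width), as.raw(layout$seed_width),
           as.raw(layout$degree_width), as.raw(layout$chunk_id_width),
           as.raw(layout_checksum_code[[layout$checksum]]),
           as.raw(layout$rs_symbols),
           int_to_bytes(chunk_size, 2L),
           int_to_bytes(length(packets), 4L))
  body <- lapply(packets, function(p) {
    s <- serialize_packet(p, layout)
    if (layout$mode == "explicit_list") c(int_to_bytes(length(s), 2L), s)
    else s
  })
  writeBin(c(hdr, do.call(c, c(body, list(raw(0))))), path)
  invisible(path)
}

#' @rdname write_packet_container
#' @return `read_packet_container()`: list with `packets`, `layout`,
#'   `chunk_size`.
#' @export
read_packet_container <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 16L || !identical(bytes[1:4], CONTAINER_MAGIC)) {
    stop_format("not a packet container (bad magic)")
  }
  mode <- names(layout_mode_code)[as.integer(bytes[5]) + 1L]
  layout <- packet_layout(mode = mode,
                          num_chunks_width = as.integer(bytes[6]),
                          seed_width = max(1L, as.integer(bytes[7])),
                          degree_width = as.integer(bytes[8]),
                          chunk_id_width = max(1L, as.integer(bytes[9])),
                          checksum = names(layout_checksum_code)[
                            as.integer(bytes[10]) + 1L],
                          rs_symbols = max(1L, as.integer(bytes[11])))
  chunk_size <- bytes_to_int(bytes[12:13])
  n_packets <- bytes_to_int(bytes[14:17])
  pos <- 18L
  packets <- vector("list", n_packets)
  for (i in seq_len(n_packets)) {
    if (layout$mode == "explicit_list") {
      len <- bytes_to_int(bytes[pos:(pos + 1L)])
      pos <- pos + 2L
    } else {
      len <- serialized_packet_length(layout, chunk_size)
    }
    packets[[i]] <- deserialize_packet(bytes[seq.int(pos, length.out = len)],
                                       layout, chunk_size)
    pos <- pos + len
  }
  list(packets = packets, layout = layout, chunk_size = chunk_size)
}
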