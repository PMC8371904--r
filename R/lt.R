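#' Split a payload into equal-length chunks
#'
#' Divides binary data into `n` equally long chunks (the source symbols of
#' the fountain code), zero-padding the last chunk. Optionally prepends a
#' header chunk (chunk 0) carrying the file name and padding length so the
#' decoder can restore the input byte-exactly; the header chunk then
#' participates in the encoding like any data chunk.
#'
#' @param data raw vector (non-empty).
#' @param chunk_size chunk size in bytes (give exactly one of `chunk_size`
#'   / `num_chunks`).
#' @param num_chunks number of data chunks.
#' @param header if `TRUE`, prepend a header chunk.
#' @param filename file name stored in the header chunk.
#' @return an object of class `source_block`: fields `chunks` (list of raw
#'   vectors), `chunk_size`, `n` (chunk count including any header chunk),
#'   `padding`, `header_present`.
#' @examples
#' blk <- split_into_chunks(as.raw(1:10), chunk_size = 4)
#' blk$n        # 3
#' blk$padding  # 2
#' @export
split_into_chunks <- function(data, chunk_size = NULL, num_chunks = NULL,
                              header = FALSE, filename = "") {
  if (!is.raw(data) || !length(data)) {
    stop_param("data must be a non-empty raw vector")
  }
  if (is.null(chunk_size) == is.null(num_chunks)) {
    stop_param("give exactly one of chunk_size / num_chunks")
  }
  if (is.null(chunk_size)) {
    if (!is_count(num_chunks, min = 1L)) {
      stop_param("num_chunks must be a positive integer")
    }
    chunk_size <- as.integer(ceiling(length(data) / num_chunks))
  }
  if (!is_count(chunk_size, min = 1L)) {
    stop_param("chunk_size must be a positive integer")
  }
  chunk_size <- as.integer(chunk_size)
  n_data <- as.integer(ceiling(length(data) / chunk_size))
  padding <- n_data * chunk_size - length(data)
  padded <- c(data, raw(padding))
  chunks <- lapply(seq_len(n_data), function(i) {
    padded[((i - 1L) * chunk_size + 1L):(i * chunk_size)]
  })
  if (header) {
    chunks <- c(list(build_header_chunk(filename, padding, chunk_size)),
                chunks)
  }
  structure(list(chunks = chunks, chunk_size = chunk_size,
                 n = length(chunks), padding = padding,
                 header_present = header),
            class = "source_block")
}

#' @export
print.source_block <- function(x, ...) {
  cat(sprintf("<source_block %d chunk(s) x %d byte(s), padding=%d%s>\n",
              x$n, x$chunk_size, x$padding,
              if (x$header_present) ", header" else ""))
  invisible(x)
}

#' Select distinct chunk indices
#'
#' Draws `degree` distinct, uniformly distributed chunk indices in
#' `[0, n)` from the deterministic generator, by rejection sampling of
#' duplicates. Optional per-chunk weights bias the selection (used by the
#' unequal-error-protection mode); weights are applied by inverse-CDF over
#' the remaining candidates.
#'
#' @param rng an [rng_new()] generator, advanced in place.
#' @param degree number of indices, `1 <= degree <= n`.
#' @param n number of chunks.
#' @param weights optional positive weight per chunk.
#' @return integer vector of `degree` distinct 0-based indices.
#' @export
choose_chunk_indices <- function(rng, degree, n, weights = NULL) {
  if (!is_count(degree, min = 1L) || degree > n) {
    stop_param("degree must satisfy 1 <= degree <= n")
  }
  if (is.null(weights)) {
    picked <- integer(0)
    while (length(picked) < degree) {
      i <- rng_int(rng, n)
      if (!(i %in% picked)) picked <- c(picked, i)
    }
    return(as.integer(picked))
  }
  stopifnot(length(weights) == n, all(weights > 0))
  avail <- 0:(n - 1L)
  w <- as.numeric(weights)
  picked <- integer(0)
  for (k in seq_len(degree)) {
    cdf <- cumsum(w) / sum(w)
    j <- findInterval(rng_unif(rng), cdf) + 1L
    picked <- c(picked, avail[j])
    avail <- avail[-j]
    w <- w[-j]
  }
  as.integer(picked)
}

# Seed semantics shared by encoder and decoder: the packet seed initializes
# the RNG; the first draw yields the degree (capped at n), subsequent draws
# yield the distinct indices.
lt_selection <- function(seed, dist, n, weights = NULL) {
  rng <- rng_new(seed)
  d <- min(sample_degree(dist, rng), n)
  list(degree = d,
       indices = choose_chunk_indices(rng, d, n, weights = weights))
}

#' LT-encode one packet
#'
#' Runs the LT encoding steps for one seed: seed the generator, draw the
#' degree from the distribution, select that many distinct chunks, and XOR
#' them into the payload. The packet records the seed (seed-based layouts)
#' or the explicit index list (explicit-list layouts).
#'
#' @param block a [split_into_chunks()] source block.
#' @param seed unsigned integer seed; must fit `layout$seed_width`.
#' @param dist a degree distribution, e.g. [robust_soliton()].
#' @param layout a [packet_layout()].
#' @return a [fountain_packet()].
#' @examples
#' blk <- split_into_chunks(as.raw(1:12), chunk_size = 4)
#' p <- lt_encode(blk, seed = 7, dist = ideal_soliton(blk$n),
#'                layout = packet_layout())
#' @export
lt_encode <- function(block, seed, dist, layout = packet_layout()) {
  stopifnot(inherits(block, "source_block"))
  sel <- lt_selection(seed, dist, block$n)
  payload <- Reduce(xor, block$chunks[sel$indices + 1L])
  if (layout$mode == "seed_based") {
    fountain_packet(payload, seed = seed, total_chunks = block$n,
                    degree = sel$degree)
  } else {
    fountain_packet(payload, chunk_ids = sel$indices,
                    total_chunks = block$n)
  }
}

#' Build the LT decoding system
#'
#' One row per verified packet: seed-based packets re-run the seeded
#' degree/index selection (encoder/decoder symmetry), explicit-list packets
#' use their stored ids; the right-hand side is the payload. Duplicate
#' packets simply contribute duplicate rows.
#'
#' @param packets list of [fountain_packet()]s (already checksum-verified).
#' @param n chunk count.
#' @param dist the degree distribution used at encode time (required for
#'   seed-based packets; without it the chunk selection cannot be re-derived
#'   and an explicit index list would be needed).
#' @return a [gf2_system()] over `n` unknowns.
#' @export
lt_rows <- function(packets, n, dist = NULL) {
  sets <- lapply(packets, function(p) packet_index_set(p, n, dist))
  gf2_system(sets, rhs = lapply(packets, `[[`, "payload"), U = n)
}

packet_index_set <- function(p, n, dist) {
  if (!is.null(p$chunk_ids)) return(p$chunk_ids)
  if (is.null(dist)) {
    stop_param(paste("seed-based packet but no degree distribution given;",
                     "an explicit chunk list would be required"))
  }
  lt_selection(p$seed, dist, n)$indices
}

#' LT-encode a run of packets, optionally with unequal error protection
#'
#' Generates one packet per seed. When `priority_chunks` is given
#' (0-based indices), the encoder first emits one degree-1 packet per
#' priority chunk and then doubles those chunks' selection weight in every
#' packet of degree `<= priority_max_degree`, so important chunks are
#' over-represented in low-degree packets. Unequal error protection
#' requires an `explicit_list` layout, since the biased selection can no
#' longer be reproduced from a seed alone.
#'
#' @param block a source block.
#' @param seeds integer vector of seeds.
#' @param dist degree distribution.
#' @param layout packet layout.
#' @param priority_chunks optional 0-based chunk indices to protect.
#' @param priority_max_degree degree bound below which priority weighting
#'   applies (default 4).
#' @return list of [fountain_packet()]s (the degree-1 priority packets
#'   first, then one packet per seed).
#' @export
lt_encode_packets <- function(block, seeds, dist, layout = packet_layout(),
                              priority_chunks = NULL,
                              priority_max_degree = 4L) {
  if (is.null(priority_chunks)) {
    return(lapply(seeds, function(s) lt_encode(block, s, dist, layout)))
  }
  if (layout$mode != "explicit_list") {
    stop_param("unequal error protection requires an explicit_list layout")
  }
  stopifnot(all(priority_chunks >= 0), all(priority_chunks < block$n))
  forced <- lapply(priority_chunks, function(i) {
    fountain_packet(block$chunks[[i + 1L]], chunk_ids = i,
                    total_chunks = block$n)
  })
  weights <- rep(1, block$n)
  weights[priority_chunks + 1L] <- 2
  rest <- lapply(seeds, function(s) {
    rng <- rng_new(s)
    d <- min(sample_degree(dist, rng), block$n)
    idx <- if (d <= priority_max_degree) {
      choose_chunk_indices(rng, d, block$n, weights = weights)
    } else {
      choose_chunk_indices(rng, d, block$n)
    }
    payload <- Reduce(xor, block$chunks[idx + 1L])
    fountain_packet(payload, chunk_ids = idx, total_chunks = block$n)
  })
  c(forced, rest)
}
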