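#' Codec configuration
#'
#' Bundles everything encoder and decoder must agree on out-of-band: the
#' code family, the chunk geometry, the degree distribution, the packet
#' layout and — for Online codes — the outer-code parameters. The same
#' object drives [fountain_encode()], [fountain_decode()] and the driver
#' routines.
#'
#' When `dist` is omitted, LT and Online default to a Robust Soliton
#' distribution over the symbol count with the spike position placed by
#' Luby's heuristic `K = N / (c ln(N/delta) sqrt(N))` (`c = 0.1`,
#' `delta = 0.05`); Raptor always uses its fixed degree table.
#'
#' @param kind `"lt"`, `"online"` or `"raptor"`.
#' @param chunk_size chunk size in bytes (give exactly one of `chunk_size`
#'   / `num_chunks`).
#' @param num_chunks number of data chunks.
#' @param dist optional degree distribution (LT/Online inner code).
#' @param layout a [packet_layout()].
#' @param header store a header chunk (file name + padding) as chunk 0.
#' @param filename file name recorded in the header chunk.
#' @param q,epsilon Online outer-code parameters.
#' @param aux_seed seed of the Online aux membership map (layout-level
#'   constant; must match between encoder and decoder).
#' @param mapping a [base_mapping()].
#' @return an object of class `codec_config`.
#' @examples
#' cfg <- codec_config("raptor", chunk_size = 16)
#' @export
codec_config <- function(kind = c("lt", "online", "raptor"),
                         chunk_size = NULL, num_chunks = NULL,
                         dist = NULL, layout = packet_layout(),
                         header = TRUE, filename = "",
                         q = 3L, epsilon = 0.05, aux_seed = 1,
                         mapping = base_mapping()) {
  kind <- match.arg(kind)
  structure(list(kind = kind, chunk_size = chunk_size,
                 num_chunks = num_chunks, dist = dist, layout = layout,
                 header = header, filename = filename,
                 q = as.integer(q), epsilon = epsilon, aux_seed = aux_seed,
                 mapping = mapping),
            class = "codec_config")
}

#' @export
print.codec_config <- function(x, ...) {
  cat(sprintf("<codec_config %s chunk_size=%s layout=%s/%s%s>\n", x$kind,
              x$chunk_size %||% sprintf("n=%s", x$num_chunks),
              x$layout$mode, x$layout$checksum,
              if (x$header) " +header" else ""))
  invisible(x)
}

# Robust Soliton with Luby's spike-position heuristic
robust_soliton_default <- function(n, delta = 0.05, c = 0.1) {
  if (n == 1L) return(custom_distribution(1))
  K <- round(n / (c * log(n / delta) * sqrt(n)))
  K <- max(1L, min(n - 1L, as.integer(K)))
  robust_soliton(n, K, delta)
}

# Encoder state: source block + code-specific symbols; `encode_one(seed)`
# yields one packet.
encoder_state <- function(data, codec) {
  stopifnot(inherits(codec, "codec_config"))
  block <- split_into_chunks(data, chunk_size = codec$chunk_size,
                             num_chunks = codec$num_chunks,
                             header = codec$header,
                             filename = codec$filename)
  st <- decode_state(codec, n = block$n, chunk_size = block$chunk_size)
  st$block <- block
  if (codec$kind == "online") {
    aux <- rep(list(raw(block$chunk_size)), st$params$M)
    for (i in seq_len(st$params$F)) {
      for (a in st$aux_membership[[i]]) {
        aux[[a + 1L]] <- xor(aux[[a + 1L]], block$chunks[[i]])
      }
    }
    st$aux <- aux
    st$symbols <- c(block$chunks, aux)
  } else if (codec$kind == "raptor") {
    st$symbols <- build_intermediates(block, st$params)
  } else {
    st$symbols <- block$chunks
  }
  st$encode_one <- function(seed) {
    idx <- st$index_set_for_seed(seed)
    payload <- Reduce(xor, st$symbols[idx + 1L])
    if (codec$layout$mode == "seed_based") {
      fountain_packet(payload, seed = seed, total_chunks = block$n,
                      degree = length(idx))
    } else {
      fountain_packet(payload, chunk_ids = idx, total_chunks = block$n)
    }
  }
  st
}

# Decoder-side state: everything derivable from the codec config plus the
# chunk count (and chunk size), without the payload data.
decode_state <- function(codec, n, chunk_size) {
  st <- list(codec = codec, n = as.integer(n),
             chunk_size = as.integer(chunk_size))
  if (codec$kind == "lt") {
    st$dist <- codec$dist %||% robust_soliton_default(n)
    st$U <- st$n
    st$constraints <- list()
    st$index_set_for_seed <- function(seed) {
      lt_selection(seed, st$dist, st$U)$indices
    }
  } else if (codec$kind == "online") {
    st$params <- online_params(codec$q, codec$epsilon, n)
    st$U <- st$params$F + st$params$M
    st$dist <- codec$dist %||% robust_soliton_default(st$U)
    # for very small files M may fall below q; cap the effective quality so
    # each chunk still joins q_eff distinct aux blocks (both sides derive
    # the same cap from the shared parameters)
    st$q_eff <- min(codec$q, st$params$M)
    membership <- online_aux_membership(st$params, codec$aux_seed,
                                        q = st$q_eff)
    st$aux_membership <- membership
    st$constraints <- lapply(seq_len(st$params$M) - 1L, function(a) {
      members <- which(vapply(membership, function(m) a %in% m, TRUE)) - 1L
      c(members, st$params$F + a)
    })
    st$index_set_for_seed <- function(seed) {
      lt_selection(seed, st$dist, st$U)$indices
    }
  } else {
    st$params <- precode_counts(n)
    st$U <- st$params$L
    st$dist <- raptor_distribution()
    st$constraints <- raptor_parity_sets(st$params)
    st$index_set_for_seed <- function(seed) {
      raptor_tuple(seed, st$params)$indices
    }
  }
  st$packet_index_set <- function(p) {
    if (!is.null(p$chunk_ids)) p$chunk_ids
    else st$index_set_for_seed(p$seed)
  }
  st$system <- function(packets) {
    zero <- raw(st$chunk_size)
    gf2_system(c(lapply(packets, st$packet_index_set), st$constraints),
               rhs = c(lapply(packets, `[[`, "payload"),
                       rep(list(zero), length(st$constraints))),
               U = st$U)
  }
  st
}

#' Encode a payload into packets
#'
#' Either generates a fixed number of packets (seeds `start_seed`,
#' `start_seed + 1`, ...) or — the default — generates packets until the
#' structure-only pseudo-decoder signals decodability, plus
#' `overhead_extra` more. The returned packet list is always
#' Gaussian-decodable in the default mode.
#'
#' @param data raw vector (or a character string, stored as UTF-8).
#' @param codec a [codec_config()].
#' @param n_packets fixed packet count, or `NULL` for
#'   generate-until-decodable.
#' @param overhead_extra extra packets beyond the decodability point.
#' @param start_seed first seed.
#' @return list of [fountain_packet()]s.
#' @examples
#' cfg <- codec_config("lt", chunk_size = 8, header = FALSE)
#' pkts <- fountain_encode(as.raw(1:32), cfg)
#' @export
fountain_encode <- function(data, codec, n_packets = NULL,
                            overhead_extra = 0L, start_seed = 0) {
  if (is.character(data)) data <- charToRaw(data)
  st <- encoder_state(data, codec)
  max_seed <- 256^codec$layout$seed_width
  if (!is.null(n_packets)) {
    seeds <- start_seed + seq_len(n_packets) - 1
    if (any(seeds >= max_seed)) stop_overflow("seed exceeds layout width")
    return(lapply(seeds, st$encode_one))
  }
  el <- gf2_eliminator(st$U)
  for (s in st$constraints) eliminator_add(el, idx = s)
  packets <- list()
  seed <- start_seed
  while (TRUE) {
    if (seed >= max_seed) stop_overflow("seed space exhausted before decodability")
    p <- st$encode_one(seed)
    packets[[length(packets) + 1L]] <- p
    eliminator_add(el, idx = st$packet_index_set(p))
    seed <- seed + 1
    if (eliminator_solved(el)) break
  }
  extra <- 0L
  while (extra < overhead_extra && seed < max_seed) {
    packets[[length(packets) + 1L]] <- st$encode_one(seed)
    seed <- seed + 1
    extra <- extra + 1L
  }
  packets
}

#' Decode packets back to the original payload
#'
#' Builds the code's GF(2) system (packet rows plus outer-code or precode
#' constraint rows), solves it, and reassembles the chunks. With a header
#' chunk, the file name and padding are restored and the output is
#' byte-exact; otherwise the zero-padded concatenation is returned with
#' the padding attached as an attribute. Decoding succeeds as soon as all
#' *chunk* unknowns are determined, even if auxiliary/parity unknowns are
#' not.
#'
#' @param packets list of verified [fountain_packet()]s.
#' @param codec the [codec_config()] used at encode time.
#' @param num_chunks chunk count override when the packets do not carry it
#'   (layouts with `num_chunks_width = 0`).
#' @param decoder `"gauss"` or `"bp"` (belief propagation).
#' @return list with `data` (raw vector) and `filename` (from the header
#'   chunk, or `NULL`).
#' @export
fountain_decode <- function(packets, codec, num_chunks = NULL,
                            decoder = c("gauss", "bp")) {
  decoder <- match.arg(decoder)
  if (!length(packets)) stop_param("no packets to decode")
  n <- num_chunks %||% packets[[1L]]$total_chunks
  if (is.null(n)) {
    stop_param("chunk count unavailable: packets carry none and no override given")
  }
  st <- decode_state(codec, n = n,
                     chunk_size = length(packets[[1L]]$payload))
  sys <- st$system(packets)
  res <- if (decoder == "gauss") gauss_solve(sys) else belief_propagate(sys)
  chunk_idx <- seq_len(st$n)
  if (res$solved) {
    chunks <- res$solution[chunk_idx]
  } else if (!is.null(res$determined) &&
             all((chunk_idx - 1L) %in% res$determined)) {
    chunks <- res$determined_values[match(chunk_idx - 1L, res$determined)]
  } else {
    stop_with("dnafountain_decode_error",
              sprintf("decoding failed: %d unknown(s) unresolved",
                      st$U - (res$rank %||% 0L)))
  }
  if (codec$header) {
    hdr <- parse_header_chunk(chunks[[1L]])
    body <- do.call(c, chunks[-1L])
    n_body <- length(body) - hdr$padding
    list(data = body[seq_len(n_body)], filename = hdr$filename)
  } else {
    body <- do.call(c, chunks)
    structure(list(data = body, filename = NULL),
              padding_unknown = TRUE)
  }
}
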