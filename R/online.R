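#' Online-code parameters
#'
#' The Online code wraps an inner LT code with an outer code of
#' `M = ceil(0.55 * q * epsilon * F)` auxiliary blocks, where `F` is the
#' chunk count, `q` the quality parameter and `epsilon` the target
#' overhead. Each chunk is XORed into exactly `q` distinct auxiliary
#' blocks; the aux blocks then take part in the inner encoding as regular
#' input symbols, which protects rarely-covered chunks against the coupon
#' collector's problem.
#'
#' @param q quality (positive integer).
#' @param epsilon positive real overhead parameter.
#' @param F chunk count.
#' @return an object of class `online_params` with fields `q`, `epsilon`,
#'   `F` and `M`.
#' @examples
#' online_params(q = 3, epsilon = 0.01, F = 1000)$M  # 17
#' @export
online_params <- function(q, epsilon, F) {
  if (!is_count(q, min = 1L)) stop_param("q must be a positive integer")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop_param("epsilon must be a positive real")
  }
  if (!is_count(F, min = 1L)) stop_param("F must be a positive integer")
  M <- as.integer(ceiling(0.55 * q * epsilon * F))
  M <- max(M, 1L)
  structure(list(q = as.integer(q), epsilon = epsilon, F = as.integer(F),
                 M = M),
            class = "online_params")
}

#' @export
print.online_params <- function(x, ...) {
  cat(sprintf("<online_params q=%d epsilon=%g F=%d M=%d>\n",
              x$q, x$epsilon, x$F, x$M))
  invisible(x)
}

#' Build the auxiliary blocks of the Online outer code
#'
#' Every chunk is XORed into exactly `q` distinct auxiliary blocks, chosen
#' uniformly by the deterministic generator seeded with `aux_seed`. The
#' membership map is therefore reproducible at the decoder from `aux_seed`
#' alone (a layout-level constant shared out-of-band).
#'
#' @param block a [split_into_chunks()] source block with `F` chunks.
#' @param params an [online_params()] with `M >= q`.
#' @param aux_seed seed of the membership map (default 1).
#' @return list with `aux` (list of `M` raw vectors) and `membership`
#'   (list: chunk -> 0-based aux indices).
#' @export
build_aux_blocks <- function(block, params, aux_seed = 1) {
  stopifnot(inherits(block, "source_block"),
            inherits(params, "online_params"))
  if (block$n != params$F) stop_param("block$n must equal params$F")
  if (params$M < params$q) {
    stop_param("M < q: not enough auxiliary blocks for q distinct targets")
  }
  membership <- online_aux_membership(params, aux_seed)
  aux <- rep(list(raw(block$chunk_size)), params$M)
  for (i in seq_len(params$F)) {
    for (a in membership[[i]]) {
      aux[[a + 1L]] <- xor(aux[[a + 1L]], block$chunks[[i]])
    }
  }
  list(aux = aux, membership = membership)
}

# chunk -> q distinct aux indices, reproducible from aux_seed alone.
# `q` can be overridden (the driver caps it at M for very small files).
online_aux_membership <- function(params, aux_seed = 1, q = params$q) {
  rng <- rng_new(aux_seed)
  lapply(seq_len(params$F), function(i) {
    choose_chunk_indices(rng, q, params$M)
  })
}

#' Online-encode one packet
#'
#' The inner encoding is an LT code over the union of the `F` chunks and
#' the `M` auxiliary blocks (aux symbols occupy indices `F..F+M-1`).
#'
#' @param block source block (`F` chunks).
#' @param aux the [build_aux_blocks()] result.
#' @param seed packet seed.
#' @param dist inner degree distribution over `N = F + M` symbols.
#' @param layout packet layout.
#' @return a [fountain_packet()]; `total_chunks` records `F` (the aux count
#'   is recomputed from the out-of-band `q`, `epsilon`).
#' @export
online_encode <- function(block, aux, seed, dist, layout = packet_layout()) {
  stopifnot(inherits(block, "source_block"))
  symbols <- c(block$chunks, aux$aux)
  sel <- lt_selection(seed, dist, length(symbols))
  payload <- Reduce(xor, symbols[sel$indices + 1L])
  if (layout$mode == "seed_based") {
    fountain_packet(payload, seed = seed, total_chunks = block$n,
                    degree = sel$degree)
  } else {
    fountain_packet(payload, chunk_ids = sel$indices,
                    total_chunks = block$n)
  }
}

#' Build the Online decoding system
#'
#' Unknowns are the `F` chunks followed by the `M` auxiliary symbols. Each
#' received packet contributes one row over that union; in addition, `M`
#' constraint rows with all-zero right-hand sides encode the outer code
#' (`aux_j XOR its member chunks = 0`), which is how the decoder "reduces"
#' the aux packets. Decoding succeeds when the chunk unknowns resolve (with
#' Gaussian elimination, full rank: every aux symbol is itself determined
#' by its constraint row once the chunks are known).
#'
#' @param packets verified packets.
#' @param params [online_params()].
#' @param dist inner degree distribution (for seed-based packets).
#' @param aux_seed membership seed used at encode time.
#' @param chunk_size payload size in bytes (for the zero right-hand sides;
#'   inferred from the packets when omitted).
#' @return a [gf2_system()] over `F + M` unknowns.
#' @export
online_system <- function(packets, params, dist = NULL, aux_seed = 1,
                          chunk_size = NULL) {
  stopifnot(inherits(params, "online_params"))
  U <- params$F + params$M
  if (is.null(chunk_size)) {
    if (!length(packets)) stop_param("need packets or chunk_size")
    chunk_size <- length(packets[[1L]]$payload)
  }
  membership <- online_aux_membership(params, aux_seed)
  aux_sets <- lapply(seq_len(params$M) - 1L, function(a) {
    members <- which(vapply(membership, function(m) a %in% m, TRUE)) - 1L
    c(members, params$F + a)
  })
  pkt_sets <- lapply(packets, function(p) packet_index_set(p, U, dist))
  gf2_system(c(pkt_sets, aux_sets),
             rhs = c(lapply(packets, `[[`, "payload"),
                     rep(list(raw(chunk_size)), params$M)),
             U = U)
}
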