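is_prime <- function(x) {
  if (x < 2) return(FALSE)
  if (x < 4) return(TRUE)
  if (x %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= x) {
    if (x %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

next_prime <- function(x) {
  while (!is_prime(x)) x <- x + 1
  as.integer(x)
}

#' Raptor precode sizing
#'
#' The Raptor precode extends the `k` chunks with `S` circulant (LDPC-style)
#' parity blocks and `H` dense Gray/Half parity blocks, giving
#' `L = k + S + H` intermediate symbols that the inner LT code then encodes.
#' The counts follow the smallest-integer conditions
#' \itemize{
#'   \item `f(k)`: smallest `x` with `x * (x - 1) >= 2k` (auxiliary value),
#'   \item `S`: smallest prime `>= ceiling(0.01 k + f(k))`,
#'   \item `H`: smallest `x` with `choose(x, ceiling(x/2)) >= f(k) + S`.
#' }
#' `L_prime` is the smallest prime `>= L`; the per-packet index walk works
#' modulo `L_prime`.
#'
#' @param k chunk count (positive integer).
#' @return an object of class `raptor_params` with fields `k`, `f_k`, `S`,
#'   `H`, `L`, `L_prime`.
#' @examples
#' p <- precode_counts(1000)
#' c(p$f_k, p$S, p$H)  # 46 59 9
#' @export
precode_counts <- function(k) {
  if (!is_count(k, min = 1L)) stop_param("k must be a positive integer")
  k <- as.integer(k)
  f_k <- 1L
  while (f_k * (f_k - 1) < 2 * k) f_k <- f_k + 1L
  S <- next_prime(as.integer(ceiling(0.01 * k + f_k)))
  H <- 1L
  while (choose(H, ceiling(H / 2)) < f_k + S) H <- H + 1L
  L <- k + S + H
  structure(list(k = k, f_k = f_k, S = S, H = as.integer(H),
                 L = as.integer(L), L_prime = next_prime(L)),
            class = "raptor_params")
}

#' @export
print.raptor_params <- function(x, ...) {
  cat(sprintf("<raptor_params k=%d S=%d H=%d L=%d L'=%d>\n",
              x$k, x$S, x$H, x$L, x$L_prime))
  invisible(x)
}

# 0-based member sets of the S + H parity constraints, shared by encoder
# and decoder. Each set lists the generator symbols plus the parity symbol
# itself, so XOR over the set is the zero vector (zero syndrome).
#
# Circulant stage (from the k chunks): chunk i joins parity blocks
# b, b+a, b+2a (mod S) with a = 1 + (i %/% S) %% (S - 1), b = i %% S —
# exactly 3 distinct blocks per chunk since S is prime.
# Gray/Half stage (from the k + S preceding symbols): symbol j joins parity
# i iff bit i of the j-th Gray codeword of Hamming weight ceiling(H/2) is
# set.
raptor_parity_sets <- function(params) {
  k <- params$k; S <- params$S; H <- params$H
  s_members <- vector("list", S)
  for (i in 0:(k - 1L)) {
    a <- 1L + (i %/% S) %% (S - 1L)
    b <- i %% S
    for (t in c(b, (b + a) %% S, (b + 2L * a) %% S)) {
      s_members[[t + 1L]] <- c(s_members[[t + 1L]], i)
    }
  }
  s_sets <- lapply(seq_len(S), function(j) {
    c(s_members[[j]], k + j - 1L)
  })

  codes <- gray_weight_codewords(ceiling(H / 2), k + S)
  h_sets <- lapply(seq_len(H), function(i) {
    members <- which(bitwAnd(codes %/% 2^(i - 1L), 1) == 1) - 1L
    c(members, k + S + i - 1L)
  })
  c(s_sets, h_sets)
}

# first `count` integers of the Gray-code sequence g(m) = m XOR (m >> 1)
# having Hamming weight `w`, in ascending m (as doubles; values stay small)
gray_weight_codewords <- function(w, count) {
  out <- numeric(count)
  found <- 0L
  m <- 0
  while (found < count) {
    g <- xor32(m, m %/% 2)
    v <- g
    pc <- 0L
    while (v > 0) {
      pc <- pc + v %% 2
      v <- v %/% 2
    }
    if (pc == w) {
      found <- found + 1L
      out[found] <- g
    }
    m <- m + 1
  }
  out
}

#' Build the Raptor intermediate symbols
#'
#' Intermediates `0..k-1` are the chunks; `k..k+S-1` the circulant parity
#' blocks; `k+S..L-1` the Gray/Half parity blocks computed over chunks and
#' circulant parities. Every parity block is the XOR of its generators, so
#' the syndrome of each precode constraint is zero.
#'
#' @param block source block with `params$k` chunks.
#' @param params a [precode_counts()] result.
#' @return list of `L` raw vectors.
#' @export
build_intermediates <- function(block, params) {
  stopifnot(inherits(block, "source_block"),
            inherits(params, "raptor_params"))
  if (block$n != params$k) stop_param("block$n must equal params$k")
  zero <- raw(block$chunk_size)
  inter <- c(block$chunks, rep(list(zero), params$S + params$H))
  sets <- raptor_parity_sets(params)
  for (j in seq_along(sets)) {
    s <- sets[[j]]
    gen <- s[-length(s)]          # last element is the parity symbol itself
    tgt <- s[length(s)] + 1L
    if (length(gen)) inter[[tgt]] <- Reduce(xor, inter[gen + 1L])
  }
  inter
}

#' Raptor per-packet tuple and index walk
#'
#' From the packet seed, draws the tuple `(d, a, b)`: `v` uniform in
#' `[0, 2^20)` gives the degree `d` through the fixed table (capped at
#' `L`), `a` is uniform in `[1, L')` and `b` uniform in `[0, L')`. The `d`
#' indices are collected by stepping `b <- (b + a) mod L'` and skipping
#' values `>= L`; since `L'` is prime the walk visits every residue, and
#' the emitted indices are distinct.
#'
#' @param seed packet seed.
#' @param params a [precode_counts()] result.
#' @return list with `d`, `a`, `b` (the drawn start value) and `indices`
#'   (0-based, length `d`).
#' @export
raptor_tuple <- function(seed, params) {
  stopifnot(inherits(params, "raptor_params"))
  rng <- rng_new(seed)
  v <- rng_int(rng, 1048576)
  d <- min(raptor_degree_lookup(v), params$L)
  a <- 1 + rng_int(rng, params$L_prime - 1L)
  b0 <- rng_int(rng, params$L_prime)
  b <- b0
  idx <- integer(d)
  for (j in seq_len(d)) {
    while (b >= params$L) b <- (b + a) %% params$L_prime
    idx[j] <- b
    b <- (b + a) %% params$L_prime
  }
  list(d = d, a = a, b = b0, indices = idx)
}

#' Raptor-encode one packet
#'
#' XORs the intermediate symbols selected by the packet's tuple walk. The
#' code operates non-systematically: chunks are never emitted verbatim.
#'
#' @param intermediates [build_intermediates()] output.
#' @param seed packet seed.
#' @param params [precode_counts()] result.
#' @param layout packet layout.
#' @return a [fountain_packet()]; `total_chunks` records `k`.
#' @export
raptor_encode <- function(intermediates, seed, params,
                          layout = packet_layout()) {
  tup <- raptor_tuple(seed, params)
  payload <- Reduce(xor, intermediates[tup$indices + 1L])
  if (layout$mode == "seed_based") {
    fountain_packet(payload, seed = seed, total_chunks = params$k,
                    degree = tup$d)
  } else {
    fountain_packet(payload, chunk_ids = tup$indices,
                    total_chunks = params$k)
  }
}

#' Build the Raptor decoding system
#'
#' Unknowns are the `L` intermediate symbols. Each received packet
#' contributes one row (indicator of its tuple indices, right-hand side =
#' payload); the `S + H` precode constraints contribute rows with all-zero
#' right-hand sides. The decoded chunks are the first `k` solved symbols.
#'
#' @param packets verified packets.
#' @param params [precode_counts()] result.
#' @param chunk_size payload size (inferred from packets when omitted).
#' @return a [gf2_system()] over `L` unknowns.
#' @export
raptor_system <- function(packets, params, chunk_size = NULL) {
  stopifnot(inherits(params, "raptor_params"))
  if (is.null(chunk_size)) {
    if (!length(packets)) stop_param("need packets or chunk_size")
    chunk_size <- length(packets[[1L]]$payload)
  }
  pkt_sets <- lapply(packets, function(p) {
    if (!is.null(p$chunk_ids)) p$chunk_ids
    else raptor_tuple(p$seed, params)$indices
  })
  parity <- raptor_parity_sets(params)
  gf2_system(c(pkt_sets, parity),
             rhs = c(lapply(packets, `[[`, "payload"),
                     rep(list(raw(chunk_size)), length(parity))),
             U = params$L)
}
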