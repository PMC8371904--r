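# Independent oracles used to cross-check the implementation. These are
# deliberately naive (dense 0/1 matrices, quadratic scans, bit-by-bit CRC)
# and share no code with the package internals.

# rank of a GF(2) indicator matrix by plain dense elimination
brute_gf2_rank <- function(index_sets, U) {
  if (!length(index_sets)) return(0L)
  M <- matrix(0L, length(index_sets), U)
  for (i in seq_along(index_sets)) M[i, index_sets[[i]] + 1L] <- 1L
  r <- 0L
  for (col in seq_len(U)) {
    piv <- which(M[, col] == 1L & seq_len(nrow(M)) > r)
    if (!length(piv)) next
    r <- r + 1L
    if (piv[1L] != r) M[c(r, piv[1L]), ] <- M[c(piv[1L], r), ]
    for (i in seq_len(nrow(M))) {
      if (i != r && M[i, col] == 1L) M[i, ] <- (M[i, ] + M[r, ]) %% 2L
    }
  }
  r
}

# longest tandem repeat count of any unit of length p: all-substring scan
brute_tandem_repeat <- function(seq, p) {
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  if (L < p) return(0L)
  best <- 1L
  for (start in seq_len(L - p + 1L)) {
    unit <- chars[start:(start + p - 1L)]
    reps <- 1L
    pos <- start + p
    while (pos + p - 1L <= L &&
           identical(chars[pos:(pos + p - 1L)], unit)) {
      reps <- reps + 1L
      pos <- pos + p
    }
    best <- max(best, reps)
  }
  best
}

# bit-by-bit reference CRCs (no tables)
ref_crc8 <- function(data) {
  crc <- 0L
  for (b in as.integer(data)) {
    crc <- bitwXor(crc, b)
    for (k in 1:8) {
      crc <- if (crc >= 128L) bitwXor(bitwAnd(crc * 2L, 255L), 0x07L)
             else bitwAnd(crc * 2L, 255L)
    }
  }
  crc
}

ref_crc32 <- function(data) {
  xor32 <- function(a, b) {
    bitwXor(a %/% 65536, b %/% 65536) * 65536 +
      bitwXor(a %% 65536, b %% 65536)
  }
  crc <- 4294967295
  for (b in as.integer(data)) {
    crc <- xor32(crc, b)
    for (k in 1:8) {
      crc <- if (crc %% 2 == 1) xor32(crc %/% 2, 3988292384) else crc %/% 2
    }
  }
  xor32(crc, 4294967295)
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_payload <- function(n) as.raw(sample(0:255, n, replace = TRUE))

# a random solvable-or-not GF(2) instance with known ground truth
random_gf2_instance <- function(U, m, payload_len = 3L) {
  sets <- lapply(seq_len(m), function(i) {
    sort(sample(0:(U - 1L), sample(seq_len(U), 1L)))
  })
  truth <- lapply(seq_len(U), function(i) random_payload(payload_len))
  rhs <- lapply(sets, function(s) Reduce(xor, truth[s + 1L]))
  list(sets = sets, rhs = rhs, truth = truth,
       system = gf2_system(sets, rhs, U))
}
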