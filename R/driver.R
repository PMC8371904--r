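#' Sweep the full seed space
#'
#' Generates one candidate packet per seed in the layout's seed range,
#' converts each to DNA and scores it with the rule engine. Sorting the
#' result by predicted error (ties broken by ascending seed) ranks every
#' sequence the code can produce for this payload, so the best candidates
#' can be selected for synthesis. A 2-byte seed field yields exactly
#' 65,536 candidates.
#'
#' @param data raw vector (or character string) to encode.
#' @param codec a [codec_config()].
#' @param rules a [rule_config()].
#' @param max_seed_width refuse seed fields wider than this many bytes
#'   (guard against runaway enumeration; default 3).
#' @return data.frame with columns `seed`, `dna`, `error`, sorted by
#'   `error` then `seed`.
#' @export
sweep_seed_space <- function(data, codec, rules = rule_config(),
                             max_seed_width = 3L) {
  if (is.character(data)) data <- charToRaw(data)
  if (codec$layout$seed_width > max_seed_width) {
    stop_param(sprintf(
      "seed space of %d-byte seeds too large to enumerate (raise max_seed_width to override)",
      codec$layout$seed_width))
  }
  st <- encoder_state(data, codec)
  n_seeds <- 256^codec$layout$seed_width
  seeds <- seq_len(n_seeds) - 1
  dna <- character(n_seeds)
  err <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    p <- st$encode_one(seeds[i])
    dna[i] <- bytes_to_dna(serialize_packet(p, codec$layout), codec$mapping)
    err[i] <- total_error(dna[i], rules)$total
  }
  out <- data.frame(seed = seeds, dna = dna, error = err,
                    stringsAsFactors = FALSE)
  out[order(out$error, out$seed), , drop = FALSE]
}

#' Error-bounded packet generation
#'
#' Walks the seed space in ascending order and accepts packets subject to
#' an upper bound on the predicted DNA error score. In `strict` mode a
#' packet is accepted iff its score is `<= bound`. In `weak` mode a
#' uniform number in `[0, 1)` is drawn per packet and the packet is
#' accepted iff the draw is `>=` its score — still usable when every
#' candidate scores above a strict bound, at the price of less optimal
#' packets.
#'
#' @param data payload (raw or character).
#' @param codec a [codec_config()].
#' @param rules a [rule_config()].
#' @param mode `"strict"` or `"weak"`.
#' @param bound strict-mode score bound (`>= 0`).
#' @param count number of packets to accept.
#' @param rng generator for the weak-mode draws (default `rng_new(1)`).
#' @param seed_budget how many seeds may be tried (default: the layout's
#'   full seed space); exhausting it raises an error.
#' @return list of accepted [fountain_packet()]s; attributes `seeds_tried`
#'   and `scores` report the search.
#' @export
encode_with_bound <- function(data, codec, rules = rule_config(),
                              mode = c("strict", "weak"), bound = 1,
                              count = 1L, rng = NULL,
                              seed_budget = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(bound) || bound < 0) stop_param("bound must be >= 0")
  if (is.character(data)) data <- charToRaw(data)
  if (is.null(rng)) rng <- rng_new(1)
  st <- encoder_state(data, codec)
  budget <- seed_budget %||% 256^codec$layout$seed_width
  accepted <- list()
  scores <- numeric(0)
  seed <- 0
  while (length(accepted) < count) {
    if (seed >= budget) {
      stop_with("dnafountain_progress_error",
                sprintf("seed budget (%g) exhausted with %d/%d packets accepted",
                        budget, length(accepted), count))
    }
    p <- st$encode_one(seed)
    dna <- bytes_to_dna(serialize_packet(p, codec$layout), codec$mapping)
    score <- total_error(dna, rules)$total
    take <- if (mode == "strict") score <= bound else rng_unif(rng) >= score
    if (take) {
      accepted[[length(accepted) + 1L]] <- p
      scores <- c(scores, score)
    }
    seed <- seed + 1
  }
  attr(accepted, "seeds_tried") <- seed
  attr(accepted, "scores") <- scores
  accepted
}

#' Generate packets until the pseudo-decoder reports decodability
#'
#' Feeds each new packet's index set into the structure-only decoder and
#' stops as soon as the accumulated system is solvable, then emits
#' `overhead_extra` additional packets (a static safety overhead against
#' channel losses). Equivalent to `fountain_encode(..., n_packets = NULL)`.
#'
#' @inheritParams fountain_encode
#' @return list of packets; attribute `packets_needed` records how many
#'   packets were required before the decoder signalled success.
#' @export
encode_until_decodable <- function(data, codec, overhead_extra = 0L,
                                   start_seed = 0) {
  pkts <- fountain_encode(data, codec, n_packets = NULL,
                          overhead_extra = overhead_extra,
                          start_seed = start_seed)
  attr(pkts, "packets_needed") <- length(pkts) - overhead_extra
  pkts
}

#' Simulate the DNA erasure channel
#'
#' Scores each sequence with the rule engine and erases it with
#' probability `min(score * generations, 1)` ([drop_decision()]);
#' survivors keep their order. Checksums downstream convert any residual
#' corruption into erasures, so loss is the only channel effect modelled.
#'
#' @param seqs character vector of DNA sequences (or a [read_fasta()]
#'   data.frame).
#' @param rules a [rule_config()].
#' @param generations storage/amplification generations (scales the drop
#'   probability).
#' @param rng an [rng_new()] generator.
#' @return the surviving subset of `seqs` (same type as the input);
#'   attribute `dropped` holds the erased indices.
#' @export
simulate_channel <- function(seqs, rules = rule_config(), generations = 1,
                             rng = rng_new(1)) {
  df <- is.data.frame(seqs)
  ss <- if (df) seqs$seq else seqs
  erased <- vapply(ss, function(s) {
    drop_decision(total_error(s, rules), generations, rng)
  }, TRUE, USE.NAMES = FALSE)
  out <- if (df) seqs[!erased, , drop = FALSE] else seqs[!erased]
  attr(out, "dropped") <- which(erased)
  out
}

#' Per-chunk coverage of a packet set
#'
#' Counts, for every data chunk, how many packets contain it. References
#' to auxiliary (Online) or precode (Raptor) symbols are expanded into
#' their constituent chunks first — a packet XORing a parity block
#' effectively carries every chunk inside that block, which is why the
#' precoded codes mix many more chunks per packet than plain LT. Chunks
#' cancelling out under XOR (referenced an even number of times through
#' different symbols) are not counted. Rarely covered chunks are the
#' code's exposure to the coupon collector's problem: losing the few
#' packets containing them makes the file undecodable.
#'
#' @param packets list of packets.
#' @param codec the [codec_config()] (needed to re-derive seed-based
#'   selections).
#' @param num_chunks chunk count override when packets carry none.
#' @return integer vector of per-chunk inclusion counts (length `n`), with
#'   a `summary` attribute (min/mean/max).
#' @export
chunk_coverage <- function(packets, codec, num_chunks = NULL) {
  if (!length(packets)) {
    n <- num_chunks %||% stop_param("need packets or num_chunks")
    out <- integer(n)
    attr(out, "summary") <- c(min = 0, mean = 0, max = 0)
    return(out)
  }
  n <- num_chunks %||% packets[[1L]]$total_chunks
  if (is.null(n)) stop_param("chunk count unavailable")
  st <- decode_state(codec, n = n,
                     chunk_size = length(packets[[1L]]$payload))
  rows <- symbol_chunk_rows(st)
  counts <- integer(n)
  for (p in packets) {
    idx <- st$packet_index_set(p)
    chunks <- row_to_indices(Reduce(xor, rows[idx + 1L]))
    counts[chunks + 1L] <- counts[chunks + 1L] + 1L
  }
  attr(counts, "summary") <- c(min = min(counts), mean = mean(counts),
                               max = max(counts))
  counts
}

# bit rows (over the n chunks) giving each symbol's chunk content: chunks
# map to themselves; aux/parity symbols to the XOR of their generators
symbol_chunk_rows <- function(st) {
  n <- st$n
  rows <- vector("list", st$U)
  for (i in seq_len(n)) rows[[i]] <- indices_to_row(i - 1L, n)
  if (st$codec$kind == "online") {
    for (a in seq_len(st$params$M) - 1L) {
      members <- which(vapply(st$aux_membership,
                              function(m) a %in% m, TRUE)) - 1L
      rows[[n + a + 1L]] <- indices_to_row(members, n)
    }
  } else if (st$codec$kind == "raptor") {
    for (s in st$constraints) {
      gen <- s[-length(s)]
      tgt <- s[length(s)]
      rows[[tgt + 1L]] <- if (length(gen)) Reduce(xor, rows[gen + 1L])
                          else indices_to_row(integer(0), n)
    }
  }
  rows
}

#' Write packets as DNA to FASTA / read them back
#'
#' `packets_to_fasta()` serializes each packet, converts it to DNA and
#' writes one FASTA record per packet with headers of the form
#' `pkt_<index> seed=<seed> err=<score>` (the error token is present when
#' a rule configuration is given). `fasta_to_packets()` reads a FASTA
#' file, converts each record back to bytes and deserializes it;
#' records failing the alphabet check, the length check or the packet
#' checksum are treated as erased and reported in the `dropped` element
#' rather than aborting the decode.
#'
#' @param packets list of packets.
#' @param codec a [codec_config()].
#' @param path FASTA file path.
#' @param rules optional [rule_config()] used to annotate error scores.
#' @return `packets_to_fasta()`: invisibly, the data.frame of `id`, `seq`
#'   written.
#' @export
packets_to_fasta <- function(packets, codec, path, rules = NULL) {
  dna <- vapply(packets, function(p) {
    bytes_to_dna(serialize_packet(p, codec$layout), codec$mapping)
  }, "")
  ids <- vapply(seq_along(packets), function(i) {
    p <- packets[[i]]
    id <- sprintf("pkt_%d", i - 1L)
    if (!is.null(p$seed)) id <- sprintf("%s seed=%.0f", id, p$seed)
    if (!is.null(rules)) {
      id <- sprintf("%s err=%.4f", id, total_error(dna[i], rules)$total)
    }
    id
  }, "")
  write_fasta(dna, path, ids = ids)
  invisible(data.frame(id = ids, seq = dna, stringsAsFactors = FALSE))
}

#' @rdname packets_to_fasta
#' @param chunk_size payload size in bytes (fixed per encoding).
#' @return `fasta_to_packets()`: list with `packets` (verified packets, in
#'   file order) and `dropped` (indices of erased records).
#' @export
fasta_to_packets <- function(path, codec, chunk_size) {
  recs <- read_fasta(path)
  packets <- list()
  dropped <- integer(0)
  for (i in seq_len(nrow(recs))) {
    p <- tryCatch({
      bytes <- dna_to_bytes(recs$seq[i], codec$mapping)
      deserialize_packet(bytes, codec$layout, chunk_size)
    }, dnafountain_integrity_error = function(e) NULL,
       dnafountain_format_error = function(e) NULL)
    if (is.null(p)) dropped <- c(dropped, i)
    else packets[[length(packets) + 1L]] <- p
  }
  list(packets = packets, dropped = dropped)
}
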