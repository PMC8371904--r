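test_that("serialized length follows the layout", {
  # 4-byte chunk count + 4-byte seed + 16-byte payload + 4-byte CRC-32
  lay <- packet_layout(num_chunks_width = 4, seed_width = 4,
                       checksum = "crc32")
  p <- fountain_packet(random_payload(16), seed = 123, total_chunks = 9)
  expect_length(serialize_packet(p, lay), 28)
  expect_identical(serialized_packet_length(lay, 16), 28L)
  # omitting the static chunk-count field saves its 4 bytes
  lay0 <- packet_layout(num_chunks_width = 0, seed_width = 4,
                        checksum = "crc32")
  expect_length(serialize_packet(fountain_packet(p$payload, seed = 123),
                                 lay0), 24)
})

test_that("serialization round-trips over random packets and layouts", {
  set.seed(8)
  for (trial in 1:40) {
    chunk_size <- sample(1:24, 1)
    mode <- sample(c("seed_based", "explicit_list"), 1)
    lay <- packet_layout(
      mode = mode,
      num_chunks_width = sample(c(0L, 1L, 2L, 4L), 1),
      seed_width = sample(1:4, 1),
      degree_width = sample(c(0L, 1L), 1),
      chunk_id_width = sample(1:2, 1),
      checksum = sample(c("nocode", "crc8", "crc32", "reed_solomon"), 1),
      rs_symbols = 4)
    n <- sample(2:200, 1)
    p <- if (mode == "seed_based") {
      fountain_packet(random_payload(chunk_size),
                      seed = sample(0:255, 1),
                      total_chunks = if (lay$num_chunks_width > 0) n,
                      degree = 3)
    } else {
      fountain_packet(random_payload(chunk_size),
                      chunk_ids = sample(0:(n - 1), sample(1:min(5, n), 1)),
                      total_chunks = if (lay$num_chunks_width > 0) n)
    }
    wire <- serialize_packet(p, lay)
    q <- deserialize_packet(wire, lay, chunk_size)
    expect_identical(q$payload, p$payload)
    expect_identical(q$chunk_ids, p$chunk_ids)
    if (!is.null(p$seed)) expect_equal(q$seed, p$seed)
    expect_identical(q$total_chunks, p$total_chunks)
  }
})

test_that("field overflow and length mismatches are reported", {
  lay <- packet_layout(seed_width = 1)
  p <- fountain_packet(random_payload(4), seed = 300, total_chunks = 2)
  expect_error(serialize_packet(p, lay),
               class = "dnafountain_overflow_error")
  lay2 <- packet_layout()
  wire <- serialize_packet(fountain_packet(random_payload(4), seed = 1,
                                           total_chunks = 2), lay2)
  expect_error(deserialize_packet(wire[-1], lay2, 4),
               class = "dnafountain_format_error")
})

test_that("corruption is detected, and repaired when Reed-Solomon allows", {
  payload <- random_payload(16)
  p <- fountain_packet(payload, seed = 77, total_chunks = 5)
  # CRC-32: a single corrupted payload byte is an integrity error
  lay <- packet_layout(checksum = "crc32")
  wire <- serialize_packet(p, lay)
  bad <- wire; bad[12] <- xor(bad[12], as.raw(1))
  expect_error(deserialize_packet(bad, lay, 16),
               class = "dnafountain_integrity_error")
  # Reed-Solomon with 4 parity bytes: 1 corrupted byte is repaired ...
  lay_rs <- packet_layout(checksum = "reed_solomon", rs_symbols = 4)
  wire <- serialize_packet(p, lay_rs)
  bad <- wire; bad[3] <- xor(bad[3], as.raw(0x5a))
  q <- deserialize_packet(bad, lay_rs, 16)
  expect_identical(q$payload, payload)
  expect_equal(q$seed, 77)
  # ... but 3 corrupted bytes exceed floor(4/2) and fail
  bad3 <- wire
  for (i in c(2, 9, 17)) bad3[i] <- xor(bad3[i], as.raw(0x21))
  expect_error(deserialize_packet(bad3, lay_rs, 16),
               class = "dnafountain_integrity_error")
})

test_that("header chunk stores and restores filename and padding", {
  h <- build_header_chunk("a.txt", 3, 32)
  expect_length(h, 32)
  parsed <- parse_header_chunk(h)
  expect_identical(parsed$filename, "a.txt")
  expect_identical(parsed$padding, 3)
  # empty filename, zero padding: all zero bytes
  expect_identical(build_header_chunk("", 0, 8), raw(8))
  expect_error(build_header_chunk("abcdef", 0, 4),
               class = "dnafountain_parameter_error")
})

test_that("packet container round-trips with its layout descriptor", {
  lay <- packet_layout(seed_width = 2, checksum = "crc8")
  pkts <- lapply(1:5, function(i) {
    fountain_packet(random_payload(8), seed = i * 11, total_chunks = 4)
  })
  path <- withr::local_tempfile(fileext = ".pkt")
  write_packet_container(pkts, lay, 8, path)
  back <- read_packet_container(path)
  expect_identical(back$chunk_size, 8)
  expect_identical(back$layout$checksum, "crc8")
  expect_equal(lapply(back$packets, `[[`, "seed"),
               lapply(pkts, `[[`, "seed"))
  expect_identical(lapply(back$packets, `[[`, "payload"),
                   lapply(pkts, `[[`, "payload"))
})
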