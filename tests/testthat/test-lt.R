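test_that("chunking computes counts and padding, with optional header", {
  blk <- split_into_chunks(as.raw(1:10), chunk_size = 4)
  expect_identical(blk$n, 3L)
  expect_identical(blk$padding, 2L)
  expect_identical(blk$chunks[[3]], as.raw(c(9, 10, 0, 0)))
  blk2 <- split_into_chunks(as.raw(1:12), chunk_size = 4)
  expect_identical(blk2$n, 3L)
  expect_identical(blk2$padding, 0L)
  blk3 <- split_into_chunks(as.raw(1:10), chunk_size = 4, header = TRUE)
  expect_identical(blk3$n, 4L)
  expect_identical(parse_header_chunk(blk3$chunks[[1]])$padding, 2)
  expect_error(split_into_chunks(raw(0), chunk_size = 4),
               class = "dnafountain_parameter_error")
  blk4 <- split_into_chunks(as.raw(1:10), num_chunks = 5)
  expect_identical(blk4$n, 5L)
})

test_that("index selection is distinct, complete at full degree, and uniform", {
  rng <- rng_new(3)
  for (i in 1:50) {
    idx <- choose_chunk_indices(rng, sample(1:8, 1), 8)
    expect_false(anyDuplicated(idx) > 0)
    expect_true(all(idx >= 0 & idx < 8))
  }
  expect_setequal(choose_chunk_indices(rng, 10, 10), 0:9)
  expect_error(choose_chunk_indices(rng, 11, 10),
               class = "dnafountain_parameter_error")
  # frequency of each index over degree-1 draws: within 4 SE of 1/10
  rng <- rng_new(17)
  n <- 1e5
  draws <- replicate(n, choose_chunk_indices(rng, 1, 10))
  freq <- tabulate(draws + 1L, 10) / n
  se <- sqrt(0.1 * 0.9 / n)
  expect_true(all(abs(freq - 0.1) < 4 * se))
})

test_that("packets XOR the selected chunks and are seed-reproducible", {
  blk <- split_into_chunks(random_payload(48), chunk_size = 8)
  dist <- ideal_soliton(blk$n)
  lay <- packet_layout()
  # the indicator (0,1,0,0,1,1) over 6 chunks means C1 xor C4 xor C5
  # (0-based): verified through an explicit-list packet
  p <- fountain_packet(Reduce(xor, blk$chunks[c(2, 5, 6)]),
                       chunk_ids = c(1L, 4L, 5L), total_chunks = 6)
  sys <- lt_rows(list(p), blk$n, dist)
  expect_identical(sys$index_sets[[1]], c(1L, 4L, 5L))
  expect_identical(sys$rhs[[1]],
                   xor(xor(blk$chunks[[2]], blk$chunks[[5]]),
                       blk$chunks[[6]]))
  # determinism: same (block, seed, dist) -> byte-identical packets
  p1 <- lt_encode(blk, 99, dist, lay)
  p2 <- lt_encode(blk, 99, dist, lay)
  expect_identical(serialize_packet(p1, lay), serialize_packet(p2, lay))
  # degree-1 packet payload equals the selected chunk
  d1 <- custom_distribution(1)
  q <- lt_encode(blk, 5, d1, lay)
  sel <- dnafountain:::lt_selection(5, d1, blk$n)
  expect_identical(q$payload, blk$chunks[[sel$indices + 1L]])
})

test_that("decoder rows mirror the encoder's seeded selection", {
  blk <- split_into_chunks(random_payload(60), chunk_size = 6)
  dist <- robust_soliton(blk$n, 4, 0.1)
  pkts <- lapply(0:30, function(s) lt_encode(blk, s, dist))
  sys <- lt_rows(pkts, blk$n, dist)
  for (i in seq_along(pkts)) {
    sel <- dnafountain:::lt_selection(pkts[[i]]$seed, dist, blk$n)
    expect_identical(sys$index_sets[[i]], sel$indices)
  }
  # seed-based rows require the distribution
  expect_error(lt_rows(pkts, blk$n, dist = NULL),
               class = "dnafountain_parameter_error")
})

test_that("the three-chunk textbook packet set decodes", {
  blk <- split_into_chunks(as.raw(1:12), chunk_size = 4)
  C <- blk$chunks
  pkts <- list(
    fountain_packet(C[[1]], chunk_ids = 0L, total_chunks = 3),
    fountain_packet(xor(C[[1]], C[[2]]), chunk_ids = c(0L, 1L),
                    total_chunks = 3),
    fountain_packet(xor(C[[2]], C[[3]]), chunk_ids = c(1L, 2L),
                    total_chunks = 3))
  res <- gauss_solve(lt_rows(pkts, 3))
  expect_true(res$solved)
  expect_identical(res$solution, C)
})

test_that("LT round-trips across payload sizes with the Gaussian decoder", {
  set.seed(9)
  for (size in c(1, 37, 400)) {
    data <- random_payload(size)
    cfg <- codec_config("lt", chunk_size = 8, header = TRUE,
                        filename = "x.bin")
    pkts <- fountain_encode(data, cfg)
    out <- fountain_decode(pkts, cfg)
    expect_identical(out$data, data)
    expect_identical(out$filename, "x.bin")
  }
})

test_that("priority chunks get degree-1 packets and boosted low-degree presence", {
  blk <- split_into_chunks(random_payload(80), chunk_size = 8)
  dist <- robust_soliton(blk$n, 4, 0.1)
  lay <- packet_layout(mode = "explicit_list", degree_width = 1)
  prio <- c(2L, 7L)
  pkts <- lt_encode_packets(blk, seeds = 0:49, dist, lay,
                            priority_chunks = prio)
  deg1 <- Filter(function(p) length(p$chunk_ids) == 1L, pkts)
  covered <- unlist(lapply(deg1, `[[`, "chunk_ids"))
  expect_true(all(prio %in% covered))
  # payloads of the forced packets are the chunks themselves
  expect_identical(pkts[[1]]$payload, blk$chunks[[prio[1] + 1L]])
  # seeded generation requires the explicit-list layout
  expect_error(lt_encode_packets(blk, 0:3, dist, packet_layout(),
                                 priority_chunks = prio),
               class = "dnafountain_parameter_error")
})
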