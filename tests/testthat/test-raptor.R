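# brute-force smallest-integer searches for the precode conditions,
# written independently of the package internals
brute_precode <- function(k) {
  f <- which(sapply(1:200, function(x) x * (x - 1) >= 2 * k))[1]
  seq2 <- function(a, b) if (b < a) integer(0) else a:b
  s <- ceiling(0.01 * k + f)
  while (!(s >= 2 && all(s %% seq2(2, floor(sqrt(s))) != 0))) s <- s + 1
  h <- 1
  while (choose(h, ceiling(h / 2)) < f + s) h <- h + 1
  c(f = f, S = s, H = h)
}

test_that("precode counts match the brute-force smallest-integer search", {
  p <- precode_counts(1000)
  expect_identical(c(p$f_k, p$S, p$H), c(46L, 59L, 9L))
  p1 <- precode_counts(1)
  expect_identical(c(p1$f_k, p1$S, p1$H), c(2L, 3L, 4L))
  expect_identical(p1$L, 8L)
  for (k in c(2, 7, 30, 163, 500, 1234, 2000)) {
    b <- brute_precode(k)
    p <- precode_counts(k)
    expect_identical(c(p$f_k, p$S, p$H),
                     as.integer(c(b["f"], b["S"], b["H"])))
    expect_identical(p$L, as.integer(k + b["S"] + b["H"]))
    expect_true(p$L_prime >= p$L)
  }
})

test_that("precode counts are monotone non-decreasing over k = 1..2000", {
  ks <- 1:2000
  S <- vapply(ks, function(k) precode_counts(k)$S, 0L)
  H <- vapply(ks, function(k) precode_counts(k)$H, 0L)
  expect_true(all(diff(S) >= 0))
  expect_true(all(diff(H) >= 0))
})

test_that("every chunk appears in exactly 3 circulant parity blocks", {
  for (k in c(10, 163, 1000)) {
    params <- precode_counts(k)
    sets <- dnafountain:::raptor_parity_sets(params)
    counts <- integer(k)
    for (j in seq_len(params$S)) {
      gen <- sets[[j]][-length(sets[[j]])]
      counts[gen + 1L] <- counts[gen + 1L] + 1L
    }
    expect_true(all(counts == 3L))
  }
})

test_that("intermediates have zero syndrome on every parity constraint", {
  for (k in c(1, 10, 40)) {
    blk <- split_into_chunks(random_payload(k * 4), chunk_size = 4)
    params <- precode_counts(blk$n)
    inter <- build_intermediates(blk, params)
    expect_length(inter, params$L)
    for (s in dnafountain:::raptor_parity_sets(params)) {
      expect_true(all(Reduce(xor, inter[s + 1L]) == as.raw(0)))
    }
  }
  # k = 1: L = 1 + 3 + 4 = 8 intermediates
  blk1 <- split_into_chunks(as.raw(1), chunk_size = 1)
  expect_length(build_intermediates(blk1, precode_counts(1)), 8)
})

test_that("the tuple walk skips out-of-range values and emits distinct indices", {
  # documented walk: d=4, a=5, b=1 over L = L' = 11 visits 1, 6, 0, 5
  fake <- structure(list(k = 11L, f_k = 0L, S = 0L, H = 0L, L = 11L,
                         L_prime = 11L), class = "raptor_params")
  walk <- function(d, a, b, L, Lp) {
    idx <- integer(d)
    for (j in seq_len(d)) {
      while (b >= L) b <- (b + a) %% Lp
      idx[j] <- b
      b <- (b + a) %% Lp
    }
    idx
  }
  expect_equal(walk(4, 5, 1, 11, 11), c(1, 6, 0, 5))
  params <- precode_counts(50)
  for (seed in 0:100) {
    tup <- raptor_tuple(seed, params)
    expect_true(all(tup$indices >= 0 & tup$indices < params$L))
    expect_false(anyDuplicated(tup$indices) > 0)
    expect_length(tup$indices, tup$d)
    expect_true(tup$a >= 1 && tup$a < params$L_prime)
  }
  # determinism
  expect_identical(raptor_tuple(7, params), raptor_tuple(7, params))
})

test_that("raptor packets XOR the walked intermediates deterministically", {
  blk <- split_into_chunks(random_payload(80), chunk_size = 8)
  params <- precode_counts(blk$n)
  inter <- build_intermediates(blk, params)
  p1 <- raptor_encode(inter, 13, params)
  p2 <- raptor_encode(inter, 13, params)
  expect_identical(p1$payload, p2$payload)
  tup <- raptor_tuple(13, params)
  expect_identical(p1$payload, Reduce(xor, inter[tup$indices + 1L]))
  # XOR self-inverse: adding a packet to itself gives the zero payload
  expect_true(all(xor(p1$payload, p2$payload) == as.raw(0)))
})

test_that("the decode system bundles packet rows and parity rows", {
  params <- precode_counts(12)
  sys <- raptor_system(list(), params, chunk_size = 4)
  expect_length(sys$index_sets, params$S + params$H)
  # feeding all L intermediates as degree-1 explicit packets solves trivially
  blk <- split_into_chunks(random_payload(48), chunk_size = 4)
  inter <- build_intermediates(blk, precode_counts(blk$n))
  params <- precode_counts(blk$n)
  pkts <- lapply(seq_len(params$L) - 1L, function(i) {
    fountain_packet(inter[[i + 1L]], chunk_ids = i, total_chunks = params$k)
  })
  res <- gauss_solve(raptor_system(pkts, params))
  expect_true(res$solved)
  expect_identical(res$solution[seq_len(params$k)], blk$chunks)
})

test_that("small-overhead decodability matches the simulation-derived rates", {
  params <- precode_counts(30)
  psets <- dnafountain:::raptor_parity_sets(params)
  rate <- function(m, trials = 60) {
    succ <- 0
    for (t in seq_len(trials)) {
      seeds <- sample(0:4294967295, m)
      sets <- lapply(seeds, function(s) raptor_tuple(s, params)$indices)
      if (pseudo_decode(c(sets, psets), params$L)) succ <- succ + 1
    }
    succ / trials
  }
  set.seed(5)
  expect_gt(rate(32), 0.60)
  expect_gt(rate(36), 0.90)
})

test_that("raptor round-trips for k in {1, 10, 163} with small overhead", {
  set.seed(12)
  for (k in c(1, 10, 163)) {
    data <- random_payload(k * 5)
    cfg <- codec_config("raptor", num_chunks = k, header = FALSE)
    pkts <- encode_until_decodable(data, cfg)
    out <- fountain_decode(pkts, cfg)
    expect_identical(out$data[seq_along(data)], data)
    # overhead beyond k stays modest (parity rows carry the precode)
    expect_lt(attr(pkts, "packets_needed"), k + 15 + 0.15 * k)
  }
})
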