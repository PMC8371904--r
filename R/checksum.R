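# Packet integrity codes: CRC-8 (poly 0x07, init 0x00, non-reflected),
# CRC-32 (IEEE 802.3 reflected, init/xorout 0xFFFFFFFF) and Reed-Solomon
# over GF(2^8) with primitive polynomial 0x11D (roots alpha^0..alpha^(nsym-1),
# generator element 2). CRCs detect corruption; Reed-Solomon with `nsym`
# parity bytes additionally corrects up to floor(nsym/2) byte errors.

crc_env <- new.env(parent = emptyenv())

crc8_table <- function() {
  if (is.null(crc_env$crc8)) {
    tab <- integer(256)
    for (i in 0:255) {
      c <- i
      for (k in 1:8) {
        c <- if (c >= 128L) bitwXor(bitwAnd(c * 2L, 255L), 0x07L)
             else bitwAnd(c * 2L, 255L)
      }
      tab[i + 1L] <- c
    }
    crc_env$crc8 <- tab
  }
  crc_env$crc8
}

crc32_table <- function() {
  if (is.null(crc_env$crc32)) {
    tab <- numeric(256)
    for (i in 0:255) {
      c <- as.numeric(i)
      for (k in 1:8) {
        c <- if (c %% 2 == 1) xor32(c %/% 2, 3988292384) else c %/% 2
      }
      tab[i + 1L] <- c
    }
    crc_env$crc32 <- tab
  }
  crc_env$crc32
}

crc8 <- function(data) {
  tab <- crc8_table()
  c <- 0L
  for (b in as.integer(data)) c <- tab[bitwXor(c, b) + 1L]
  as.raw(c)
}

crc32 <- function(data) {
  tab <- crc32_table()
  crc <- TWO32 - 1
  for (b in as.integer(data)) {
    crc <- xor32(crc %/% 256, tab[bitwXor(crc %% 256, b) + 1L])
  }
  int_to_bytes(xor32(crc, TWO32 - 1), 4L)
}

## ---- GF(2^8) arithmetic -------------------------------------------------

gf256_tables <- function() {
  if (is.null(crc_env$gf_exp)) {
    gf_exp <- integer(255)
    gf_log <- integer(256)
    x <- 1L
    for (i in 0:254) {
      gf_exp[i + 1L] <- x
      gf_log[x + 1L] <- i
      x <- x * 2L
      if (x >= 256L) x <- bitwXor(x, 285L) # reduce by 0x11D
    }
    crc_env$gf_exp <- gf_exp
    crc_env$gf_log <- gf_log
  }
  list(exp = crc_env$gf_exp, log = crc_env$gf_log)
}

gf_mul <- function(a, b) {
  if (a == 0L || b == 0L) return(0L)
  t <- gf256_tables()
  t$exp[(t$log[a + 1L] + t$log[b + 1L]) %% 255L + 1L]
}

gf_div <- function(a, b) {
  if (b == 0L) stop("division by zero in GF(256)")
  if (a == 0L) return(0L)
  t <- gf256_tables()
  t$exp[(t$log[a + 1L] - t$log[b + 1L] + 255L) %% 255L + 1L]
}

gf_pow <- function(i) gf256_tables()$exp[((i %% 255L) + 255L) %% 255L + 1L]

# polynomials over GF(2^8), LOW-order coefficient first
gf_poly_mul <- function(p, q) {
  out <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    for (j in seq_along(q)) {
      out[i + j - 1L] <- bitwXor(out[i + j - 1L], gf_mul(p[i], q[j]))
    }
  }
  out
}

# evaluate low-first polynomial at alpha^e_log
gf_poly_eval_explog <- function(p, e_log) {
  v <- 0L
  for (j in seq_along(p)) {
    if (p[j] != 0L) {
      v <- bitwXor(v, gf_mul(p[j], gf_pow((j - 1L) * e_log)))
    }
  }
  v
}

rs_generator_poly <- function(nsym) {
  g <- 1L
  for (i in 0:(nsym - 1L)) g <- gf_poly_mul(g, c(gf_pow(i), 1L))
  rev(g) # return HIGH-order first for the division in rs_parity
}

# parity bytes appended after the message (systematic encoding)
rs_parity <- function(msg, nsym) {
  gen <- rs_generator_poly(as.integer(nsym))
  rem <- c(as.integer(msg), integer(nsym))
  for (i in seq_along(msg)) {
    coef <- rem[i]
    if (coef != 0L) {
      for (j in 2:length(gen)) {
        rem[i + j - 1L] <- bitwXor(rem[i + j - 1L], gf_mul(gen[j], coef))
      }
    }
  }
  as.raw(rem[(length(msg) + 1L):(length(msg) + nsym)])
}

rs_syndromes <- function(cw, nsym) {
  n <- length(cw)
  vapply(0:(nsym - 1L), function(j) {
    # S_j = sum_i cw[i] * alpha^(j * (n-1-i)); cw[1] is the highest power
    v <- 0L
    for (i in seq_len(n)) {
      if (cw[i] != 0L) v <- bitwXor(v, gf_mul(cw[i], gf_pow(j * (n - i))))
    }
    v
  }, 0L)
}

# Decode a codeword (message + nsym parity bytes). Returns the corrected
# codeword, or signals an integrity error when more than floor(nsym/2)
# byte errors are present. Errors-only decoding:
# Berlekamp-Massey -> error locator Lambda; Chien search -> positions;
# Forney -> magnitudes (Y_k = X_k * Omega(X_k^-1) / Lambda'(X_k^-1)).
rs_correct <- function(codeword, nsym) {
  nsym <- as.integer(nsym)
  cw <- as.integer(codeword)
  n <- length(cw)
  if (n <= nsym) stop_format("Reed-Solomon codeword shorter than parity")
  S <- rs_syndromes(cw, nsym)
  if (all(S == 0L)) return(as.raw(cw))

  # Berlekamp-Massey (Lambda low-order first)
  Lambda <- 1L; B <- 1L; L <- 0L; m <- 1L; b <- 1L
  for (r in 0:(nsym - 1L)) {
    delta <- S[r + 1L]
    if (L >= 1L) {
      for (i in 1:L) {
        if (i + 1L <= length(Lambda) && r - i >= 0L) {
          delta <- bitwXor(delta, gf_mul(Lambda[i + 1L], S[r - i + 1L]))
        }
      }
    }
    if (delta == 0L) {
      m <- m + 1L
    } else {
      upd <- c(integer(m), vapply(B, function(z) gf_mul(z, gf_div(delta, b)), 0L))
      len <- max(length(Lambda), length(upd))
      newLambda <- bitwXor(c(Lambda, integer(len - length(Lambda))),
                           c(upd, integer(len - length(upd))))
      if (2L * L <= r) {
        B <- Lambda
        b <- delta
        L <- r + 1L - L
        m <- 1L
      } else {
        m <- m + 1L
      }
      Lambda <- newLambda
    }
  }
  while (length(Lambda) > 1L && Lambda[length(Lambda)] == 0L) {
    Lambda <- Lambda[-length(Lambda)]
  }
  nerr <- length(Lambda) - 1L
  if (nerr == 0L || nerr > nsym %/% 2L) {
    stop_integrity("Reed-Solomon: too many errors to correct")
  }

  # Chien search: error at byte i (0-based, left-most first) iff
  # Lambda(alpha^-(n-1-i)) == 0
  err_pos <- integer(0)
  for (i in 0:(n - 1L)) {
    xinv_log <- (255L - (n - 1L - i)) %% 255L
    if (gf_poly_eval_explog(Lambda, xinv_log) == 0L) err_pos <- c(err_pos, i)
  }
  if (length(err_pos) != nerr) {
    stop_integrity("Reed-Solomon: error locator root count mismatch")
  }

  # Forney
  Omega <- gf_poly_mul(S, Lambda)[seq_len(nsym)]
  for (i in err_pos) {
    p <- n - 1L - i
    xinv_log <- (255L - p) %% 255L
    num <- gf_mul(gf_pow(p), gf_poly_eval_explog(Omega, xinv_log))
    den <- 0L
    for (j in seq_along(Lambda)) {
      deg <- j - 1L
      if (deg %% 2L == 1L && Lambda[j] != 0L) {
        den <- bitwXor(den, gf_mul(Lambda[j], gf_pow((deg - 1L) * xinv_log)))
      }
    }
    if (den == 0L) stop_integrity("Reed-Solomon: Forney denominator zero")
    cw[i + 1L] <- bitwXor(cw[i + 1L], gf_div(num, den))
  }
  if (any(rs_syndromes(cw, nsym) != 0L)) {
    stop_integrity("Reed-Solomon: correction failed")
  }
  as.raw(cw)
}

#' Compute a packet checksum
#'
#' @param data raw vector to protect (must be non-empty for `crc8`, `crc32`
#'   and `reed_solomon`).
#' @param kind one of `"nocode"` (identity, no integrity check), `"crc8"`,
#'   `"crc32"`, `"reed_solomon"`.
#' @param rs_symbols number of Reed-Solomon parity bytes (`reed_solomon`
#'   only); up to `floor(rs_symbols/2)` byte errors can later be corrected.
#' @return raw vector: empty for `nocode`, 1 byte for `crc8`, 4 bytes for
#'   `crc32`, `rs_symbols` bytes for `reed_solomon`.
#' @examples
#' compute_checksum(charToRaw("123456789"), "crc32")  # cb f4 39 26
#' @export
compute_checksum <- function(data, kind = c("nocode", "crc8", "crc32",
                                            "reed_solomon"),
                             rs_symbols = 2L) {
  kind <- match.arg(kind)
  if (kind == "nocode") return(raw(0))
  if (!length(data)) stop_param("data must be non-empty for this checksum")
  switch(kind,
    crc8 = crc8(data),
    crc32 = crc32(data),
    reed_solomon = {
      if (!is_count(rs_symbols, min = 1L)) {
        stop_param("rs_symbols must be a positive integer")
      }
      rs_parity(data, as.integer(rs_symbols))
    })
}
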