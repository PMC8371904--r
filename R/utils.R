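# Low-level byte/word helpers shared across the package. All multi-byte
# integers on the wire are big-endian; 32-bit arithmetic is carried out on
# doubles (exact for values < 2^53) because R's native integer is signed.

TWO32 <- 4294967296

#' @noRd
xor32 <- function(a, b) {
  # bitwXor only accepts values < 2^31, so split into 16-bit halves
  hi <- bitwXor(a %/% 65536L, b %/% 65536L)
  lo <- bitwXor(a %% 65536L, b %% 65536L)
  hi * 65536 + lo
}

#' @noRd
mul32 <- function(a, b) {
  # exact 32-bit product via 16-bit limbs (doubles stay < 2^53)
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  (al * bl + ((ah * bl + al * bh) %% 65536) * 65536) %% TWO32
}

#' @noRd
int_to_bytes <- function(x, width) {
  if (width == 0L) return(raw(0))
  x <- as.numeric(x)
  if (is.na(x) || x < 0 || x >= 256^width) {
    stop_overflow(sprintf("value %s does not fit in %d byte(s)",
                          format(x), width))
  }
  out <- raw(width)
  for (i in width:1) {
    out[[i]] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

#' @noRd
bytes_to_int <- function(b) {
  if (!length(b)) return(0)
  sum(as.numeric(as.integer(b)) * 256^((length(b) - 1):0))
}

#' @noRd
xor_raw <- function(a, b) xor(a, b)

# classed conditions: callers distinguish format, integrity, overflow and
# corruption failures (the erasure channel treats integrity failures as drops)
stop_with <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "dnafountain_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
stop_format    <- function(msg) stop_with("dnafountain_format_error", msg)
stop_integrity <- function(msg) stop_with("dnafountain_integrity_error", msg)
stop_overflow  <- function(msg) stop_with("dnafountain_overflow_error", msg)
stop_corrupt   <- function(msg) stop_with("dnafountain_corruption_error", msg)
stop_param     <- function(msg) stop_with("dnafountain_parameter_error", msg)

#' @noRd
is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}
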