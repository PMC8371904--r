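# GF(2) linear systems A x = b. Rows are bit-packed into raw vectors
# (8 unknowns per byte, unknown j -> byte j %/% 8, bit j %% 8); right-hand
# sides are the packet payloads, one raw row per equation. Every row
# operation XORs rows of A and the matching rows of b together, so A and b
# stay consistent throughout elimination.

low_bit_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      t[1] <- NA_integer_
      for (v in 1:255) {
        b <- 0L
        while (bitwAnd(v, bitwShiftL(1L, b)) == 0L) b <- b + 1L
        t[v + 1L] <- b
      }
      tab <<- t
    }
    tab
  }
})

# pack a 0-based index set into a raw bit row of width U
indices_to_row <- function(idx, U) {
  W <- (U + 7L) %/% 8L
  bytes <- integer(W)
  if (length(idx)) {
    w <- idx %/% 8L + 1L
    b <- bitwShiftL(1L, idx %% 8L)
    for (k in seq_along(idx)) {
      bytes[w[k]] <- bitwOr(bytes[w[k]], b[k])
    }
  }
  as.raw(bytes)
}

row_to_indices <- function(row) {
  which(as.logical(rawToBits(row))) - 1L
}

#' GF(2) decoding system
#'
#' Bundles the binary constraint matrix `A` (one bit-row per received
#' packet or precode constraint) with the byte-vector right-hand sides `b`
#' (the packet payloads). Solving the system recovers the unknown symbols.
#'
#' @param index_sets list of 0-based integer vectors; element `i` lists the
#'   unknowns XORed into equation `i`.
#' @param rhs list of raw vectors (equal length), or `NULL` for
#'   structure-only systems.
#' @param U number of unknowns.
#' @return an object of class `gf2_system`.
#' @export
gf2_system <- function(index_sets, rhs = NULL, U) {
  if (!is_count(U, min = 1L)) stop_param("U must be a positive integer")
  U <- as.integer(U)
  if (!is.null(rhs) && length(rhs) != length(index_sets)) {
    stop_param("rows and rhs must have equal length")
  }
  if (length(index_sets)) {
    rng_ok <- vapply(index_sets,
                     function(s) !length(s) || (min(s) >= 0 && max(s) < U),
                     TRUE)
    if (!all(rng_ok)) stop_param("index sets must lie in [0, U)")
  }
  if (!is.null(rhs)) {
    lens <- lengths(rhs)
    if (length(lens) && any(lens != lens[1L])) {
      stop_param("all rhs payloads must have equal length")
    }
  }
  structure(list(index_sets = lapply(index_sets, as.integer),
                 rhs = rhs, U = U),
            class = "gf2_system")
}

#' @export
print.gf2_system <- function(x, ...) {
  cat(sprintf("<gf2_system %d equation(s), %d unknown(s)%s>\n",
              length(x$index_sets), x$U,
              if (is.null(x$rhs)) ", structure-only" else ""))
  invisible(x)
}

## ---- incremental eliminator ----------------------------------------------
# Maintains a reduced basis: one row per pivot column, each pivot bit
# cleared from every other basis row (RREF). Used by the Gaussian solver,
# the pseudo-decoder and generate-until-decodable loops. In GF(2), partial
# pivoting degenerates to "any row with a 1 in the pivot column"; rows are
# taken in arrival order, which makes elimination deterministic.

gf2_eliminator <- function(U, payload_len = 0L) {
  e <- new.env(parent = emptyenv())
  e$U <- as.integer(U)
  e$W <- (e$U + 7L) %/% 8L
  e$basis <- matrix(raw(0), nrow = 0L, ncol = e$W)
  e$brhs <- if (payload_len > 0L)
    matrix(raw(0), nrow = 0L, ncol = payload_len)
  e$pivot_row <- rep(NA_integer_, e$U)   # pivot column -> basis row index
  e$pivot_col <- integer(0)              # basis row index -> pivot column
  e$rank <- 0L
  class(e) <- "gf2_eliminator"
  e
}

leading_col <- function(row) {
  nz <- which(row != as.raw(0))
  if (!length(nz)) return(NA_integer_)
  w <- nz[1L]
  (w - 1L) * 8L + low_bit_table()[as.integer(row[w]) + 1L] + 1L
}

# Add one equation. Returns TRUE if it increased the rank. Signals a
# corruption error when the row reduces to 0 = nonzero (an undetected
# packet error slipped past the checksum).
#
# The basis is kept in reduced form: every basis row contains exactly one
# pivot column (its own). Reducing an incoming row therefore needs a single
# pass: XOR in the basis row of every pivot column the incoming row sets;
# those XORs only ever flip non-pivot columns, so no second pass is needed.
eliminator_add <- function(el, idx = NULL, row = NULL, rhs = NULL) {
  if (is.null(idx)) idx <- row_to_indices(row)
  if (is.null(row)) row <- indices_to_row(idx, el$U)
  track_rhs <- !is.null(el$brhs)
  if (track_rhs && is.null(rhs)) rhs <- raw(ncol(el$brhs))
  if (length(idx)) {
    pj <- el$pivot_row[idx + 1L]
    hit <- pj[!is.na(pj)]
    for (j in hit) {
      row <- xor(row, el$basis[j, ])
      if (track_rhs) rhs <- xor(rhs, el$brhs[j, ])
    }
  }
  col <- leading_col(row)
  if (is.na(col)) {
    if (track_rhs && any(rhs != as.raw(0))) {
      stop_corrupt("inconsistent system: 0 = nonzero payload")
    }
    return(FALSE)
  }
  # new pivot at `col`: clear that bit from existing basis rows (keep RREF)
  w <- (col - 1L) %/% 8L + 1L
  bit <- bitwShiftL(1L, (col - 1L) %% 8L)
  if (el$rank > 0L) {
    has <- which(bitwAnd(as.integer(el$basis[, w]), bit) != 0L)
    if (length(has)) {
      el$basis[has, ] <- xor(el$basis[has, , drop = FALSE],
                             matrix(row, nrow = length(has), ncol = el$W,
                                    byrow = TRUE))
      if (track_rhs) {
        el$brhs[has, ] <- xor(el$brhs[has, , drop = FALSE],
                              matrix(rhs, nrow = length(has),
                                     ncol = ncol(el$brhs), byrow = TRUE))
      }
    }
  }
  el$basis <- rbind(el$basis, row, deparse.level = 0)
  if (track_rhs) el$brhs <- rbind(el$brhs, rhs, deparse.level = 0)
  el$rank <- el$rank + 1L
  el$pivot_row[col] <- el$rank
  el$pivot_col <- c(el$pivot_col, col)
  TRUE
}

eliminator_solved <- function(el) el$rank == el$U

popcount8_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- vapply(0:255, function(v) {
        sum(bitwAnd(v, bitwShiftL(1L, 0:7)) != 0L)
      }, 0L)
    }
    tab
  }
})

# Unknowns already uniquely determined by the accumulated equations: in the
# reduced basis, unknown i is determined iff its pivot row is the singleton
# indicator e_i (then the row's rhs is its value).
eliminator_determined <- function(el) {
  if (el$rank == 0L) return(list(idx = integer(0), values = list()))
  pc <- popcount8_table()
  counts <- rowSums(matrix(pc[as.integer(el$basis) + 1L], nrow = el$rank))
  rows <- which(counts == 1L)
  cols <- el$pivot_col[rows]
  ord <- order(cols)
  rows <- rows[ord]
  list(idx = cols[ord] - 1L,
       values = if (!is.null(el$brhs)) lapply(rows, function(j) el$brhs[j, ]))
}

eliminator_solution <- function(el) {
  stopifnot(eliminator_solved(el))
  ord <- el$pivot_row[seq_len(el$U)]
  lapply(ord, function(j) el$brhs[j, ])
}

#' Solve a GF(2) system by Gaussian elimination
#'
#' Forward elimination and back substitution purely by row XOR (the RHS
#' payloads are XORed in lock-step with the bit rows). The input system is
#' not modified. Solvability is equivalent to `rank(A) = U`.
#'
#' @param system a [gf2_system()] with payloads.
#' @return if solvable, `list(solved = TRUE, solution = <list of U raw
#'   vectors>)`; otherwise `list(solved = FALSE, rank = <rank>, missing =
#'   <0-based unresolved unknown indices>)`.
#' @seealso [belief_propagate()], [pseudo_decode()]
#' @export
gauss_solve <- function(system) {
  stopifnot(inherits(system, "gf2_system"))
  if (is.null(system$rhs)) stop_param("gauss_solve needs payloads; see pseudo_decode")
  plen <- if (length(system$rhs)) length(system$rhs[[1L]]) else 1L
  el <- gf2_eliminator(system$U, payload_len = plen)
  for (i in seq_along(system$index_sets)) {
    eliminator_add(el, idx = system$index_sets[[i]], rhs = system$rhs[[i]])
  }
  if (eliminator_solved(el)) {
    list(solved = TRUE, solution = eliminator_solution(el))
  } else {
    det <- eliminator_determined(el)
    list(solved = FALSE, rank = el$rank,
         missing = which(is.na(el$pivot_row)) - 1L,
         determined = det$idx, determined_values = det$values)
  }
}

#' Belief-propagation (peeling) decoder
#'
#' Iteratively resolves unknowns from degree-1 equations: a resolved
#' unknown's payload is XORed out of every other equation containing it,
#' which may create new degree-1 equations; this propagates transitively
#' until a fixpoint. Belief propagation is a restricted elimination
#' strategy: its success implies Gaussian solvability, never the reverse.
#'
#' @param system a [gf2_system()] with payloads.
#' @param incremental if `TRUE`, equations are injected one at a time with
#'   peeling after each arrival (the final fixpoint is identical either
#'   way).
#' @return same contract as [gauss_solve()].
#' @export
belief_propagate <- function(system, incremental = FALSE) {
  stopifnot(inherits(system, "gf2_system"))
  if (is.null(system$rhs)) stop_param("belief_propagate needs payloads")
  U <- system$U
  plen <- if (length(system$rhs)) length(system$rhs[[1L]]) else 1L
  known <- vector("list", U)
  rows <- list()
  rhs <- list()
  member <- vector("list", U) # unknown -> row ids still containing it

  resolve_queue <- integer(0)
  add_row <- function(set, pay) {
    # reduce by already-known unknowns first
    known_mask <- !vapply(known[set + 1L], is.null, TRUE)
    for (u in set[known_mask]) pay <- xor(pay, known[[u + 1L]])
    set <- set[!known_mask]
    if (!length(set)) return(invisible())
    rid <- length(rows) + 1L
    rows[[rid]] <<- set
    rhs[[rid]] <<- pay
    for (u in set) member[[u + 1L]] <<- c(member[[u + 1L]], rid)
    if (length(set) == 1L) resolve_queue <<- c(resolve_queue, rid)
    invisible()
  }

  peel <- function() {
    while (length(resolve_queue)) {
      rid <- resolve_queue[1L]
      resolve_queue <<- resolve_queue[-1L]
      set <- rows[[rid]]
      if (length(set) != 1L) next
      u <- set[1L]
      if (!is.null(known[[u + 1L]])) { rows[[rid]] <<- integer(0); next }
      known[[u + 1L]] <<- rhs[[rid]]
      rows[[rid]] <<- integer(0)
      for (other in setdiff(member[[u + 1L]], rid)) {
        os <- rows[[other]]
        if (!(u %in% os)) next
        rows[[other]] <<- setdiff(os, u)
        rhs[[other]] <<- xor(rhs[[other]], known[[u + 1L]])
        if (length(rows[[other]]) == 1L) {
          resolve_queue <<- c(resolve_queue, other)
        }
      }
      member[[u + 1L]] <<- integer(0)
    }
  }

  for (i in seq_along(system$index_sets)) {
    add_row(system$index_sets[[i]], system$rhs[[i]])
    if (incremental) peel()
  }
  peel()

  unresolved <- which(vapply(known, is.null, TRUE)) - 1L
  if (!length(unresolved)) {
    list(solved = TRUE, solution = known)
  } else {
    det <- setdiff(seq_len(U) - 1L, unresolved)
    list(solved = FALSE, rank = U - length(unresolved),
         missing = unresolved,
         determined = det, determined_values = known[det + 1L])
  }
}

#' Structure-only decodability check
#'
#' The pseudo-decoder works only on the chunk-index sets and ignores the
#' payloads entirely: during encoding it is enough to know whether the
#' accumulated constraint matrix can be reduced to the identity. Its
#' verdict equals [gauss_solve()]'s solvability on the same indicator
#' matrix.
#'
#' @param index_sets list of 0-based integer index sets (one per packet).
#' @param U number of unknowns.
#' @return `TRUE` iff the system is decodable.
#' @export
pseudo_decode <- function(index_sets, U) {
  el <- gf2_eliminator(U)
  for (s in index_sets) eliminator_add(el, idx = s)
  eliminator_solved(el)
}
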