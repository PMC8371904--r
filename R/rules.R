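# DNA stability rules. Each rule maps a sequence to an error contribution
# in [0, 1]; enabled contributions are summed (and scaled), so the
# accumulated score of a sequence violating several rules may exceed 1.0.
# The score is read as the predicted probability that the sequence is lost
# over one full synthesis/storage/sequencing cycle; the erasure channel
# turns it into a drop decision.

seq_codes <- function(seq) as.integer(charToRaw(toupper(seq)))
BASE_CODES <- as.integer(charToRaw("ACGT"))

#' GC content of a sequence
#'
#' Percentage of G and C bases: `(|G|+|C|) / (|G|+|C|+|A|+|T|) * 100`.
#' A balanced GC content of 40-60% is the stability sweet spot for
#' synthesis and sequencing; AT-rich strands bond more weakly, GC-poor
#' sequences mutate and abort more often.
#'
#' @param seq a DNA string (non-empty).
#' @return GC percentage in `[0, 100]`.
#' @examples
#' gc_content("ACGT")  # 50
#' @export
gc_content <- function(seq) {
  y <- seq_codes(seq)
  if (!length(y)) stop_param("sequence must be non-empty")
  mean(y %in% as.integer(charToRaw("GC"))) * 100
}

#' GC-content error curve
#'
#' Clamped quartic mapping a GC percentage to an error contribution:
#' \deqn{f(x) = \frac{1}{100}\left(-\frac{x^4}{7200} + \frac{x^3}{36}
#'   - \frac{121 x^2}{72} + \frac{175 x}{6} + 100\right), \qquad
#'   \mathrm{err}_{gc} = \max(\min(f, 1), 0).}
#' The clamp makes the curve exactly 0 on \[40, 60\] and exactly 1 on
#' \[0, 30\] and \[70, 100\], with a near-linear ramp in between.
#'
#' @param gc_percent GC percentage(s) in `[0, 100]`.
#' @return error value(s) in `[0, 1]`.
#' @examples
#' gc_error(50)  # 0
#' gc_error(20)  # 1
#' @export
gc_error <- function(gc_percent) {
  x <- gc_percent
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 100)) {
    stop_param("gc_percent must lie in [0, 100]")
  }
  # same quartic over the common denominator 720000: every intermediate is
  # an exact integer for integer x, so the plateaus are exactly 0 and 1
  f <- (-x^4 + 200 * x^3 - 12100 * x^2 + 210000 * x + 720000) / 720000
  pmax(pmin(f, 1), 0)
}

# value of a run-length/repeat-count curve: curve[n], saturating at the end
curve_value <- function(curve, n) {
  if (n < 1L) return(0)
  curve[[min(n, length(curve))]]
}

longest_run <- function(seq) {
  y <- seq_codes(seq)
  if (!length(y)) return(0L)
  max(rle(y)$lengths)
}

#' Homopolymer rule
#'
#' Runs of one repeated base are unstable during synthesis, PCR and
#' sequencing (polymerase slippage, signal saturation); longer runs are
#' exponentially more error-prone. The rule maps the longest
#' single-base run through a monotone non-decreasing curve; the default
#' curve is 0 for runs up to 3, 0.3 at 4, 0.7 at 5 and 1.0 from 6 on.
#'
#' @param seq a DNA string.
#' @param curve numeric vector; `curve[n]` is the error for a longest run
#'   of `n`, saturating at the last entry.
#' @return error in `[0, 1]`.
#' @export
homopolymer_error <- function(seq, curve = rule_config()$homopolymer_curve) {
  curve_value(curve, longest_run(seq))
}

# longest tandem repeat count for units of exactly `p` bases: positions
# where s[i] == s[i+p] form runs; a match-run of length m implies
# floor(m/p) + 1 consecutive unit repeats
longest_tandem_repeat <- function(seq, unit_length) {
  y <- seq_codes(seq)
  L <- length(y)
  p <- as.integer(unit_length)
  if (L <= p) return(if (L == p) 1L else 0L)
  eq <- y[seq_len(L - p)] == y[(p + 1L):L]
  r <- rle(eq)
  m <- r$lengths[r$values]
  if (!length(m)) return(1L)
  max(m) %/% p + 1L
}

#' Micro-satellite (short tandem repeat) rule
#'
#' Di- and trinucleotide repeats slip during PCR, forming loops that
#' extend the strand and escape proof-reading. The rule finds the longest
#' tandem repeat of any unit of the given length and maps the repeat count
#' through a curve (default: dinucleotide repeats fire from 4 units,
#' trinucleotide from 3).
#'
#' @param seq a DNA string.
#' @param unit_length repeat unit length, 2 or 3.
#' @param curve numeric vector indexed by repeat count.
#' @return error in `[0, 1]`.
#' @examples
#' microsatellite_error("ACACACACAC", 2)  # fires: AC x 5
#' @export
microsatellite_error <- function(seq, unit_length,
                                 curve = NULL) {
  if (!unit_length %in% c(2L, 3L)) stop_param("unit_length must be 2 or 3")
  if (is.null(curve)) {
    cfg <- rule_config()
    curve <- if (unit_length == 2L) cfg$dinucleotide_curve
             else cfg$trinucleotide_curve
  }
  curve_value(curve, longest_tandem_repeat(seq, unit_length))
}

#' Windowed GC-content rule
#'
#' The GC sweet spot applies per window as well as to the whole strand: a
#' sequence can average 50% GC and still contain an AT-only stretch. This
#' rule evaluates [gc_error()] (or a custom curve) on every window and
#' returns the worst value; with `window = nchar(seq)` it equals the
#' overall GC rule.
#'
#' @param seq a DNA string.
#' @param window window length in bases.
#' @param gc_curve function mapping GC percentage to error.
#' @return error in `[0, 1]`.
#' @export
windowed_gc_error <- function(seq, window, gc_curve = gc_error) {
  y <- seq_codes(seq)
  L <- length(y)
  if (!is_count(window, min = 1L) || window > L) {
    stop_param("window must satisfy 1 <= window <= sequence length")
  }
  gcs <- c(0L, cumsum(y %in% as.integer(charToRaw("GC"))))
  starts <- seq_len(L - window + 1L)
  pct <- (gcs[starts + window] - gcs[starts]) / window * 100
  max(gc_curve(pct))
}

#' Rule configuration
#'
#' Bundles the enabled rules and their parameters. Two named presets ship
#' with the package: `"default"` (all rules, curves as documented in each
#' rule) and `"erlich_zielinski"` (the reference screening rule set:
#' homopolymers above 3 nt and overall GC outside 45-55% are rejected
#' outright, nothing else is scored). Any field can be overridden; the
#' `scale` knob rescales the accumulated score, since the default rules
#' deliberately overestimate to form a close upper bound on the real
#' mutation probability.
#'
#' @param preset `"default"`, `"erlich_zielinski"` or `"none"`.
#' @param ... named overrides of the fields listed below.
#' @return an object of class `rule_config` with fields: `rules`
#'   (character vector of enabled rules), `homopolymer_curve`,
#'   `dinucleotide_curve`, `trinucleotide_curve`, `gc_window`,
#'   `gc_curve`, `base_weights` (per-base per-occurrence mutation weight),
#'   `illegal_motifs`, `length_limits`, `scale`.
#' @examples
#' cfg <- rule_config()
#' total_error("ACGTACGTACGT", cfg)$total
#' @export
rule_config <- function(preset = c("default", "erlich_zielinski", "none"),
                        ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    rules = c("homopolymer", "gc_overall", "gc_window", "dinucleotide",
              "trinucleotide", "mutation", "illegal_symbol", "length",
              "illegal_motif"),
    homopolymer_curve = c(0, 0, 0, 0.3, 0.7, 1),
    dinucleotide_curve = c(0, 0, 0, 0.5, 0.8, 1),
    trinucleotide_curve = c(0, 0, 0.5, 0.8, 1),
    gc_window = 50L,
    gc_curve = gc_error,
    base_weights = c(A = 0.002, C = 0.002, G = 0.002, T = 0.002),
    illegal_motifs = character(0),
    length_limits = c(0, Inf),
    scale = 1
  )
  if (preset == "erlich_zielinski") {
    cfg$rules <- c("homopolymer", "gc_overall", "illegal_symbol")
    cfg$homopolymer_curve <- c(0, 0, 0, 1)
    cfg$gc_curve <- function(x) as.numeric(x < 45 | x > 55)
  } else if (preset == "none") {
    cfg$rules <- character(0)
  }
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop_param(paste("unknown rule_config field(s):",
                                      paste(bad, collapse = ", ")))
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "rule_config")
}

#' @export
print.rule_config <- function(x, ...) {
  cat(sprintf("<rule_config preset=%s rules=[%s] scale=%g>\n",
              x$preset, paste(x$rules, collapse = ","), x$scale))
  invisible(x)
}

#' Accumulated rule score of one sequence
#'
#' Evaluates every enabled rule independently, sums the contributions and
#' applies the global scale. Individual contributions lie in `[0, 1]`; the
#' accumulated total is unbounded above — a score above 1 means several
#' rules were violated. A sequence containing symbols outside `A/C/G/T`
#' receives an `illegal_symbol` contribution of 1 (it cannot be stored)
#' and no other rule is evaluated on it.
#'
#' @param seq a DNA string.
#' @param config a [rule_config()].
#' @return an object of class `rule_report`: list with `per_rule` (named
#'   contributions) and `total`.
#' @export
total_error <- function(seq, config = rule_config()) {
  stopifnot(inherits(config, "rule_config"))
  enabled <- config$rules
  per <- numeric(0)
  y <- seq_codes(seq)
  legal <- all(y %in% BASE_CODES) && length(y) > 0L
  if ("illegal_symbol" %in% enabled && !legal) {
    per["illegal_symbol"] <- 1
    total <- sum(per) * config$scale
    return(structure(list(per_rule = per, total = total),
                     class = "rule_report"))
  }
  L <- length(y)
  for (rule in enabled) {
    per[rule] <- switch(rule,
      homopolymer = homopolymer_error(seq, config$homopolymer_curve),
      gc_overall = config$gc_curve(gc_content(seq)),
      gc_window = windowed_gc_error(seq, min(config$gc_window, L),
                                    config$gc_curve),
      dinucleotide = microsatellite_error(seq, 2L,
                                          config$dinucleotide_curve),
      trinucleotide = microsatellite_error(seq, 3L,
                                           config$trinucleotide_curve),
      mutation = min(1, sum(config$base_weights[
        c("A", "C", "G", "T")[match(y, BASE_CODES)]])),
      illegal_symbol = 0,
      length = as.numeric(L < config$length_limits[1L] ||
                          L > config$length_limits[2L]),
      illegal_motif = if (length(config$illegal_motifs)) {
        as.numeric(any(vapply(config$illegal_motifs, grepl, TRUE,
                              x = toupper(seq), fixed = TRUE)))
      } else 0,
      stop_param(sprintf("unknown rule '%s'", rule)))
  }
  structure(list(per_rule = per, total = sum(per) * config$scale),
            class = "rule_report")
}

#' @export
print.rule_report <- function(x, ...) {
  cat(sprintf("<rule_report total=%.3f>\n", x$total))
  nz <- x$per_rule[x$per_rule > 0]
  if (length(nz)) {
    for (r in names(nz)) cat(sprintf("  %-15s %.3f\n", r, nz[[r]]))
  }
  invisible(x)
}

#' Erasure decision for one sequence
#'
#' Instead of simulating individual mutations over storage generations,
#' errors are reduced to deletions in the erasure channel: the sequence is
#' dropped with probability `min(total_error * generations, 1)`. More
#' generations (longer storage, more PCR cycles) scale the loss
#' probability linearly.
#'
#' @param total_error accumulated rule score (a number or a
#'   [total_error()] report).
#' @param generations number of storage/amplification generations (>= 1).
#' @param rng an [rng_new()] generator, advanced in place.
#' @return `TRUE` if the sequence is erased.
#' @export
drop_decision <- function(total_error, generations = 1, rng) {
  if (inherits(total_error, "rule_report")) total_error <- total_error$total
  if (!is_count(generations, min = 1L)) {
    stop_param("generations must be a positive integer")
  }
  p <- min(total_error * generations, 1)
  rng_unif(rng) < p
}
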