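#' Two-bit base mapping
#'
#' Binary data is stored in DNA by mapping each bit pair onto one of the
#' four bases, giving the ideal information density of 2 bits per
#' nucleotide. The default assignment is `00 -> A`, `01 -> C`, `10 -> G`,
#' `11 -> T`; any permutation of the four bases is a legal mapping (the
#' assignment is free as long as encoder and decoder agree).
#'
#' @param bases character vector: the bases assigned to bit pairs
#'   `00, 01, 10, 11`, a permutation of `c("A","C","G","T")`.
#' @return an object of class `base_mapping`.
#' @export
base_mapping <- function(bases = c("A", "C", "G", "T")) {
  if (length(bases) != 4L || !setequal(bases, c("A", "C", "G", "T"))) {
    stop_param("bases must be a permutation of A, C, G, T")
  }
  # precompute byte -> 4-base string (most-significant bit pair first)
  b <- 0:255
  quads <- cbind(b %/% 64L, (b %/% 16L) %% 4L, (b %/% 4L) %% 4L, b %% 4L)
  byte_str <- apply(quads, 1L, function(q) paste0(bases[q + 1L],
                                                  collapse = ""))
  structure(list(bases = bases, byte_str = byte_str),
            class = "base_mapping")
}

#' Convert bytes to a DNA sequence and back
#'
#' Each byte maps to 4 bases, most-significant bit pair first, so the DNA
#' length is exactly four times the byte length and the conversion is a
#' bijection. `dna_to_bytes()` signals an integrity error on any symbol
#' outside `A/C/G/T` (the sequence is then treated as erased) and a format
#' error when the length is not a multiple of 4.
#'
#' @param data raw vector.
#' @param mapping a [base_mapping()].
#' @return `bytes_to_dna()`: a single character string over `ACGT`.
#' @examples
#' bytes_to_dna(as.raw(0x1b))        # "ACGT"
#' dna_to_bytes("ACGT")              # 1b
#' @export
bytes_to_dna <- function(data, mapping = base_mapping()) {
  stopifnot(is.raw(data), inherits(mapping, "base_mapping"))
  if (!length(data)) return("")
  paste0(mapping$byte_str[as.integer(data) + 1L], collapse = "")
}

#' @rdname bytes_to_dna
#' @param seq character string of bases (lowercase accepted).
#' @export
dna_to_bytes <- function(seq, mapping = base_mapping()) {
  stopifnot(is.character(seq), length(seq) == 1L,
            inherits(mapping, "base_mapping"))
  if (!nchar(seq)) return(raw(0))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  vals <- match(chars, mapping$bases) - 1L
  if (anyNA(vals)) {
    stop_integrity(sprintf("illegal symbol '%s' in DNA sequence",
                           chars[which(is.na(vals))[1L]]))
  }
  if (length(vals) %% 4L != 0L) {
    stop_format("DNA length must be a multiple of 4")
  }
  m <- matrix(vals, nrow = 4L)
  as.raw(m[1L, ] * 64L + m[2L, ] * 16L + m[3L, ] * 4L + m[4L, ])
}

#' FASTA input and output
#'
#' Thin wrappers around `Biostrings` that preserve record order exactly as
#' in the file (abundance ordering of clustered reads is the caller's
#' concern) and normalize bases to uppercase. Headers written by the
#' encoder have the form `pkt_<index> seed=<seed> err=<score>`; parsers
#' ignore unknown header tokens.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a data.frame with columns `id` (full header
#'   line) and `seq`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop_format(sprintf("malformed FASTA '%s': %s",
                                        path, conditionMessage(e)))
                  })
  data.frame(id = if (is.null(names(set))) character(length(set))
                  else names(set),
             seq = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta
#' @param seqs character vector of sequences (or the data.frame returned by
#'   `read_fasta()`).
#' @param ids record identifiers; defaults to `pkt_<i>`.
#' @return `write_fasta()`: `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, ids = NULL) {
  if (is.data.frame(seqs)) {
    if (is.null(ids)) ids <- seqs$id
    seqs <- seqs$seq
  }
  if (is.null(ids)) ids <- sprintf("pkt_%d", seq_along(seqs) - 1L)
  set <- Biostrings::DNAStringSet(toupper(seqs))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Sliding-window base composition
#'
#' Relative frequency of the four bases in every window of the given
#' length, one row per window start; useful for inspecting the composition
#' profile of generated packets (e.g. 32-base windows along a sequence).
#'
#' @param seq a DNA string.
#' @param window window length in bases (`<= nchar(seq)`).
#' @return data.frame with columns `start` (1-based window start) and `A`,
#'   `C`, `G`, `T` frequencies; each row sums to 1.
#' @export
sliding_window_composition <- function(seq, window) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (!is_count(window, min = 1L) || window > L) {
    stop_param("window must satisfy 1 <= window <= sequence length")
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  starts <- seq_len(L - window + 1L)
  freq <- vapply(c("A", "C", "G", "T"), function(b) {
    cs <- c(0L, cumsum(chars == b))
    (cs[starts + window] - cs[starts]) / window
  }, numeric(length(starts)))
  freq <- matrix(freq, nrow = length(starts),
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  data.frame(start = starts, freq)
}
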