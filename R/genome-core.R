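# Sequence primitives and circular-coordinate arithmetic.
#
# Coordinates are 0-based with an explicit span (never an end), so features
# that wrap the origin of a circular genome are unambiguous: a feature at
# start s with span w covers positions (s, s+1, ..., s+w-1) mod L. 1-based
# inclusive coordinates appear only at I/O boundaries (GFF3, GenBank).

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a circular (or linear) genome
#'
#' A light container for a DNA sequence with explicit topology. All
#' downstream coordinates in this package are 0-based starts with spans;
#' intervals on circular genomes may wrap through the origin.
#'
#' @param sequence A single character string over `A,C,G,T,N` (case is
#'   normalised to upper).
#' @param id Sequence identifier.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `circular_genome` with fields `id`,
#'   `sequence`, `length`, `topology`.
#' @examples
#' g <- circular_genome("AACCGGTT", id = "toy")
#' extract_seq(g, start = 6, span = 4)  # wraps: "TTAA"
#' @export
circular_genome <- function(sequence, id = "genome",
                            topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    stop("genome sequence must be non-empty", call. = FALSE)
  }
  check_alphabet(sequence)
  structure(
    list(id = as.character(id), sequence = sequence,
         length = nchar(sequence), topology = topology),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

#' @export
length.circular_genome <- function(x) x$length

check_alphabet <- function(seq, alphabet = DNA_ALPHABET) {
  bad <- regexpr(sprintf("[^%s]", paste(alphabet, collapse = "")), seq)
  if (bad != -1L) {
    stop(sprintf("invalid character '%s' at position %d (alphabet %s)",
                 substr(seq, bad, bad), as.integer(bad),
                 paste(alphabet, collapse = "")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse complement of a DNA string
#'
#' N complements to N. An involution: applying it twice returns the input.
#'
#' @param seq A DNA string over `A,C,G,T,N` (upper case).
#' @return The reverse complement, same length.
#' @examples
#' reverse_complement("GGATCC")  # its own reverse complement
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  check_alphabet(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Integer encoding used by the scanners: A=1 C=2 G=3 T=4 N=5.
encode_dna <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_ALPHABET)
}

decode_dna <- function(code) paste(DNA_ALPHABET[code], collapse = "")

# complement in integer code; N (5) complements to a sixth state that can
# never match anything, implementing "windows containing N mismatch".
COMP_CODE <- c(4L, 3L, 2L, 1L, 6L)

#' Extract a (possibly wrapping) interval from a genome
#'
#' @param genome A [circular_genome()].
#' @param start 0-based start position, `0 <= start < length`.
#' @param span Number of bases, `1 <= span <= length`.
#' @param strand `"+"` (default) returns the top strand left to right;
#'   `"-"` returns the reverse complement of that stretch.
#' @return A DNA string of `span` bases. On circular genomes the interval
#'   may wrap through the origin (`start + span > length`); requesting a
#'   wrap on a linear genome is an error.
#' @export
extract_seq <- function(genome, start, span, strand = "+") {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  start <- as.integer(start); span <- as.integer(span)
  if (start < 0L || start >= L) {
    stop(sprintf("start %d outside [0, %d)", start, L), call. = FALSE)
  }
  if (span < 1L || span > L) {
    stop(sprintf("span %d outside [1, %d]", span, L), call. = FALSE)
  }
  if (start + span > L) {
    if (genome$topology != "circular") {
      stop("interval wraps the origin but genome is linear", call. = FALSE)
    }
    s <- paste0(substr(genome$sequence, start + 1L, L),
                substr(genome$sequence, 1L, start + span - L))
  } else {
    s <- substr(genome$sequence, start + 1L, start + span)
  }
  if (strand == "-") reverse_complement(s) else s
}

# circular overlap length between footprints (s1,w1) and (s2,w2), ignoring
# strand; footprints are position sets mod L.
circular_overlap <- function(s1, w1, s2, w2, L) {
  pieces <- function(s, w) {
    s <- s %% L
    if (s + w <= L) list(c(s, s + w)) else list(c(s, L), c(0, s + w - L))
  }
  a <- pieces(s1, w1); b <- pieces(s2, w2)
  tot <- 0L
  for (x in a) for (y in b) {
    tot <- tot + max(0, min(x[2], y[2]) - max(x[1], y[1]))
  }
  tot
}

# shortest circular distance between two positions
circular_dist <- function(a, b, L) {
  d <- abs((a %% L) - (b %% L))
  pmin(d, L - d)
}

GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  # first base slowest, third fastest (TTT, TTC, TTA, TTG, TCT, ...)
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), times = 4L),
                   rep(bases, times = 16L))
  # standard code in TCAG order
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

#' Translate a coding sequence
#'
#' Standard genetic code; the trailing stop codon (if present) is dropped
#' from the protein. An in-frame internal stop is an error, as is a length
#' not divisible by three or a codon containing `N`.
#'
#' @param cds A DNA string whose length is a multiple of 3.
#' @return The protein string.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop(sprintf("CDS length %d not divisible by 3", n), call. = FALSE)
  }
  if (n == 0L) return("")
  check_alphabet(cds)
  codons <- substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  aa <- GENETIC_CODE_TABLE[codons]
  if (anyNA(aa)) {
    stop(sprintf("ambiguous codon '%s' at codon %d",
                 codons[which(is.na(aa))[1]], which(is.na(aa))[1]),
         call. = FALSE)
  }
  k <- length(aa)
  if (aa[k] == "*") aa <- aa[-k]
  internal <- which(aa == "*")
  if (length(internal) > 0L) {
    stop(sprintf("internal stop codon at codon %d", internal[1]),
         call. = FALSE)
  }
  paste(aa, collapse = "")
}

#' Rotate the origin of a circular genome
#'
#' Moves the origin so that old position `k` becomes position 0. Feature
#' coordinates shift by `-k` mod length. Used by the rotation-invariance
#' checks and handy for putting a chosen anchor gene first.
#'
#' @param genome A circular [circular_genome()].
#' @param k 0-based position that becomes the new origin.
#' @return A new `circular_genome`.
#' @export
rotate_genome <- function(genome, k) {
  stopifnot(inherits(genome, "circular_genome"))
  if (genome$topology != "circular") {
    stop("only circular genomes can be rotated", call. = FALSE)
  }
  L <- genome$length
  k <- as.integer(k) %% L
  if (k == 0L) return(genome)
  circular_genome(
    paste0(substr(genome$sequence, k + 1L, L), substr(genome$sequence, 1L, k)),
    id = genome$id, topology = "circular"
  )
}

# new coordinates of a feature table after rotating origin to k
rotate_features <- function(features, k, L) {
  features$start <- (features$start - k) %% L
  features
}
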