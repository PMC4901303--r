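# Protein alignment and E-value machinery for orthology calls.
#
# Scores are optimal Smith-Waterman local alignments with affine gaps
# (BLOSUM62 by default), computed by Biostrings' dynamic programming.
# E-values come from the Karlin-Altschul formula with fixed, published
# gapped constants (config-exposed); external database searches are not
# reproduced offline, so these constants are the stated convention, not a
# fit.

AA_ALPHABET <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

default_matrix <- function() {
  # lazily fetch BLOSUM62 shipped with Biostrings
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

check_protein <- function(x, arg = "sequence") {
  bad <- regexpr("[^ARNDCQEGHILKMFPSTWYVX*]", x)
  if (bad != -1L) {
    stop(sprintf("%s has non-amino-acid character '%s' at position %d",
                 arg, substr(x, bad, bad), as.integer(bad)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Optimal local protein alignment
#'
#' Smith-Waterman with affine gap penalties: a gap of length `g` costs
#' `gap_open + g * gap_extend`. Identity is matches over aligned columns
#' (gap columns included). When no residue pair scores positively the
#' score floor is 0 with an empty alignment.
#'
#' @param a,b Protein strings.
#' @param matrix Substitution matrix (default BLOSUM62 from Biostrings).
#' @param gap_open,gap_extend Affine gap parameters (default 11/1, the
#'   BLAST convention).
#' @param K,lambda Karlin-Altschul constants for the bit-score/E-value
#'   conversion (defaults 0.041 and 0.267, published gapped BLOSUM62
#'   values).
#' @return A one-row tibble: `raw_score`, `bits`, `identity`,
#'   `aligned_length`, `evalue` (with `m * n` = `nchar(a) * nchar(b)` as
#'   search space; orthology search recomputes E-values over its own
#'   search space).
#' @export
align_proteins <- function(a, b, matrix = NULL, gap_open = 11L,
                           gap_extend = 1L, K = 0.041, lambda = 0.267) {
  stopifnot(is.character(a), is.character(b), nchar(a) > 0L, nchar(b) > 0L)
  a <- toupper(a); b <- toupper(b)
  check_protein(a, "a"); check_protein(b, "b")
  if (is.null(matrix)) matrix <- default_matrix()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  raw <- Biostrings::score(pa)
  if (raw <= 0) {
    return(tibble::tibble(raw_score = 0, bits = 0, identity = 0,
                          aligned_length = 0L,
                          evalue = estimate_evalue(0, nchar(a), nchar(b),
                                                   K, lambda)))
  }
  alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
  tibble::tibble(
    raw_score = raw,
    bits = (lambda * raw - log(K)) / log(2),
    identity = Biostrings::nmatch(pa) / alen,
    aligned_length = alen,
    evalue = estimate_evalue(raw, nchar(a), nchar(b), K, lambda)
  )
}

# score matrix for two proteomes (named character vectors); returns list
# of matrices raw, identity with rows = names(A), cols = names(B)
proteome_scores <- function(A, B, matrix = NULL, gap_open = 11L,
                            gap_extend = 1L) {
  if (is.null(matrix)) matrix <- default_matrix()
  raw <- matrix(0, length(A), length(B), dimnames = list(names(A), names(B)))
  idn <- raw
  Aset <- Biostrings::AAStringSet(A)
  for (j in seq_along(B)) {
    pa <- Biostrings::pairwiseAlignment(
      Aset, Biostrings::AAString(B[[j]]),
      substitutionMatrix = matrix, gapOpening = gap_open,
      gapExtension = gap_extend, type = "local")
    sc <- Biostrings::score(pa)
    alen <- Biostrings::nchar(pa)
    idn[, j] <- ifelse(sc > 0, Biostrings::nmatch(pa) / pmax(alen, 1L), 0)
    raw[, j] <- pmax(sc, 0)
  }
  list(raw = raw, identity = idn)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw score `S` and search-space
#' sizes `m` (query length) and `n` (summed subject length). Strictly
#' decreasing in `S`, linear in `m` and `n`.
#'
#' @param raw_score Raw alignment score.
#' @param m,n Query and subject search-space lengths (positive).
#' @param K,lambda Karlin-Altschul constants (positive).
#' @return The expected number of chance alignments with score >=
#'   `raw_score`.
#' @export
estimate_evalue <- function(raw_score, m, n, K = 0.041, lambda = 0.267) {
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive", call. = FALSE)
  if (K <= 0 || lambda <= 0) stop("K and lambda must be positive", call. = FALSE)
  K * m * n * exp(-lambda * raw_score)
}
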