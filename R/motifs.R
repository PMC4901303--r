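# Promoter-motif screening in fixed upstream windows.
#
# Baculovirus promoter logic: the late motif TAAG, early TATA-box and CAGT
# initiator, and GATA, searched as exact strings (IUPAC degenerate codes are
# supported for user-supplied motifs) on the coding strand only, within a
# fixed window immediately 5' of the start codon.

DEFAULT_MOTIFS <- c("TAAG", "TATA", "CAGT", "GATA")

IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Upstream window of an ORF
#'
#' The `window` bases immediately 5' of the start codon, read on the coding
#' strand, wrapping through the origin on circular genomes. On a linear
#' genome the window is truncated at the sequence end.
#'
#' @param genome A [circular_genome()].
#' @param start,span,strand ORF footprint (0-based top-strand start, span,
#'   strand), e.g. one row of [find_orfs()] output.
#' @param window Window size in bp (default 200).
#' @return A DNA string (coding-strand orientation, 3' end adjacent to the
#'   start codon).
#' @export
upstream_window <- function(genome, start, span, strand = "+", window = 200L) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  window <- as.integer(window)
  circ <- genome$topology == "circular"
  if (circ && window >= L) {
    stop("window must be smaller than the genome", call. = FALSE)
  }
  if (strand == "+") {
    ws <- start - window
    if (ws < 0L) {
      if (!circ) { window <- window + ws; ws <- 0L }
      else ws <- ws %% L
    }
    if (window <= 0L) return("")
    extract_seq(genome, ws, window, "+")
  } else {
    ws <- start + span          # bases 3' of the footprint in + coordinates
    w <- window
    if (!circ && ws + w > L) w <- L - ws
    if (w <= 0L) return("")
    extract_seq(genome, ws %% L, w, "-")
  }
}

#' Scan a window for promoter motifs
#'
#' Reports every exact occurrence of each motif on the given strand;
#' overlapping occurrences are all reported. IUPAC degenerate codes in the
#' motifs are honoured (`N` matches any base; genome `N` matches nothing
#' except motif `N`).
#'
#' @param window DNA string as returned by [upstream_window()].
#' @param motifs Character vector of motifs (default TAAG, TATA, CAGT,
#'   GATA).
#' @return A tibble: `motif`, `offset`, `window_pos` (1-based position of
#'   the motif's first base within the window, counting from its 5' end).
#' @details `offset` is the 1-based upstream distance of the motif's
#'   3'-most base from the start codon: `offset = 1` means the motif ends
#'   on the base immediately 5' of the ATG, and the largest possible value
#'   is `window - nchar(motif) + 1` (motif flush with the window's 5'
#'   edge).
#' @export
scan_motifs <- function(window, motifs = DEFAULT_MOTIFS) {
  stopifnot(is.character(window), length(window) == 1L)
  W <- nchar(window)
  hits <- list()
  if (W > 0L) {
    wchars <- strsplit(window, "", fixed = TRUE)[[1]]
    for (m in motifs) {
      mu <- toupper(m)
      k <- nchar(mu)
      if (k > W) next
      mchars <- strsplit(mu, "", fixed = TRUE)[[1]]
      ok <- rep(TRUE, W - k + 1L)
      for (j in seq_len(k)) {
        allowed <- IUPAC_CLASSES[[mchars[j]]]
        if (is.null(allowed)) {
          stop(sprintf("invalid IUPAC code '%s' in motif '%s'", mchars[j], m),
               call. = FALSE)
        }
        ok <- ok & (wchars[seq_len(W - k + 1L) + j - 1L] %in% allowed)
      }
      pos <- which(ok)
      if (length(pos) > 0L) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          motif = mu, offset = W - pos - k + 2L, window_pos = pos)
      }
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(motif = character(), offset = integer(),
                          window_pos = integer()))
  }
  dplyr::arrange(out, .data$window_pos, .data$motif)
}

#' Screen ORF upstream regions for promoter motifs
#'
#' Applies [upstream_window()] and [scan_motifs()] to every ORF in a
#' table; flags ORFs carrying the late promoter motif TAAG.
#'
#' @param genome A [circular_genome()].
#' @param orfs ORF tibble (needs `start`, `span`, `strand`, and `name` if
#'   present).
#' @param window Upstream window size (default 200 bp).
#' @param motifs Motifs to search (default TAAG, TATA, CAGT, GATA).
#' @return A tibble with one row per hit: `orf` (name or `orf<i>`),
#'   `motif`, `offset`, `window_pos`, plus attribute-free convenience
#'   column `late_promoter` (TRUE for TAAG hits).
#' @export
screen_promoters <- function(genome, orfs, window = 200L,
                             motifs = DEFAULT_MOTIFS) {
  if (nrow(orfs) == 0L) {
    return(tibble::tibble(orf = character(), motif = character(),
                          offset = integer(), window_pos = integer(),
                          late_promoter = logical()))
  }
  labels <- if ("name" %in% names(orfs)) orfs$name else
    sprintf("orf%d", seq_len(nrow(orfs)))
  res <- purrr::map(seq_len(nrow(orfs)), function(i) {
    win <- upstream_window(genome, orfs$start[i], orfs$span[i],
                           orfs$strand[i], window = window)
    h <- scan_motifs(win, motifs = motifs)
    if (nrow(h) == 0L) return(NULL)
    h$orf <- labels[i]
    h
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(orf = character(), motif = character(),
                          offset = integer(), window_pos = integer(),
                          late_promoter = logical()))
  }
  out$late_promoter <- out$motif == "TAAG"
  out[, c("orf", "motif", "offset", "window_pos", "late_promoter")]
}
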