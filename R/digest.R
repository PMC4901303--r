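# In-silico restriction digestion of circular genomes, and comparison of a
# fragment profile against an expected one — the classic assembly-validation
# step (digest the assembled sequence with BamHI/EcoRI/PstI and compare to a
# published gel profile).

#' Built-in restriction enzymes
#'
#' Recognition sites and top-strand cut offsets for the enzymes used in
#' baculovirus assembly validation. `cut_offset` is the number of bases
#' before the cut within the site (BamHI G^GATCC has offset 1).
#' Constants of record; users can pass their own table of the same shape
#' to [digest_genome()].
#'
#' @return A tibble: `enzyme`, `site`, `cut_offset`.
#' @export
restriction_enzymes <- function() {
  tibble::tibble(
    enzyme = c("BamHI", "EcoRI", "PstI"),
    site = c("GGATCC", "GAATTC", "CTGCAG"),
    cut_offset = c(1L, 1L, 5L)
  )
}

# site occurrences (0-based starts, both strands, wrap-aware) and resulting
# cut positions for one enzyme
enzyme_cuts <- function(genome, site, cut_offset) {
  site <- toupper(site)
  if (nchar(site) == 0L) stop("empty recognition site", call. = FALSE)
  check_alphabet(site)
  k <- nchar(site)
  if (cut_offset < 0L || cut_offset > k) {
    stop("cut_offset must lie within the site", call. = FALSE)
  }
  L <- genome$length
  circ <- genome$topology == "circular"
  x <- encode_dna(genome$sequence)
  xx <- if (circ) c(x, x[seq_len(min(k - 1L, L))]) else x
  n_win <- if (circ) L else L - k + 1L
  if (n_win < 1L) return(integer())
  idx <- seq_len(n_win)
  rc <- reverse_complement(site)
  pat_f <- encode_dna(site)
  hit_f <- rep(TRUE, n_win)
  for (j in seq_len(k)) hit_f <- hit_f & (xx[idx + j - 1L] == pat_f[j])
  # cut position: top-strand coordinate of the first base after the cut.
  # A palindromic site is one double-strand cut; a non-palindromic one is
  # also searched as its reverse complement with the mirrored offset.
  cuts <- which(hit_f) - 1L + cut_offset
  if (rc != site) {
    pat_r <- encode_dna(rc)
    hit_r <- rep(TRUE, n_win)
    for (j in seq_len(k)) hit_r <- hit_r & (xx[idx + j - 1L] == pat_r[j])
    cuts <- c(cuts, which(hit_r) - 1L + (k - cut_offset))
  }
  cuts <- if (circ) cuts %% L else cuts[cuts >= 0L & cuts <= L]
  sort(unique(cuts))
}

#' Digest a genome in silico
#'
#' Finds every occurrence of each recognition site (both strands,
#' including origin-spanning sites on circular genomes) and returns cut
#' positions and the resulting fragment sizes. On a circular genome the
#' fragments are the arcs between consecutive cuts, so fragment count
#' equals cut count and sizes always sum to the genome length; zero sites
#' leave one uncut fragment.
#'
#' @param genome A [circular_genome()].
#' @param enzymes A tibble like [restriction_enzymes()] (columns `enzyme`,
#'   `site`, `cut_offset`), or a subset of enzyme names from the built-in
#'   table.
#' @return A tibble with one row per enzyme: `enzyme`, `site`, `n_sites`,
#'   `cut_positions` (list of 0-based positions), `fragments` (list of
#'   sizes, descending).
#' @examples
#' g <- circular_genome(strrep("ACGTACGTGG", 100))
#' digest_genome(g, "EcoRI")
#' @export
digest_genome <- function(genome, enzymes = restriction_enzymes()) {
  stopifnot(inherits(genome, "circular_genome"))
  if (is.character(enzymes)) {
    tab <- restriction_enzymes()
    miss <- setdiff(enzymes, tab$enzyme)
    if (length(miss) > 0L) {
      stop(sprintf("unknown enzyme(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    enzymes <- tab[match(enzymes, tab$enzyme), ]
  }
  L <- genome$length
  circ <- genome$topology == "circular"
  rows <- purrr::map(seq_len(nrow(enzymes)), function(i) {
    cuts <- enzyme_cuts(genome, enzymes$site[i], enzymes$cut_offset[i])
    if (length(cuts) == 0L) {
      frags <- L
    } else if (circ) {
      frags <- diff(c(cuts, cuts[1] + L))
    } else {
      frags <- diff(c(0L, cuts, L))
      frags <- frags[frags > 0L]
    }
    tibble::tibble(enzyme = enzymes$enzyme[i], site = toupper(enzymes$site[i]),
                   n_sites = length(cuts),
                   cut_positions = list(cuts),
                   fragments = list(sort(as.integer(frags),
                                         decreasing = TRUE)))
  })
  dplyr::bind_rows(rows)
}

#' Compare an observed fragment profile to an expected one
#'
#' Both size lists are sorted descending and paired in order (sorted
#' greedy one-to-one matching); each pair's relative error is
#' `|obs - exp| / exp`. Sizes left over on either side are reported as
#' unmatched. The comparison passes when every pair is within `tol_frac`
#' and nothing is unmatched.
#'
#' @param observed Numeric vector of observed fragment sizes (bp), or one
#'   row of [digest_genome()] output (its `fragments` entry is used).
#' @param expected Numeric vector of expected sizes (bp).
#' @param tol_frac Tolerated relative size error per pair (default 0.05).
#' @return A list of class `profile_comparison`: `pairs` (tibble with
#'   `observed`, `expected`, `rel_error`, `within_tol`),
#'   `unmatched_observed`, `unmatched_expected`, `tol_frac`, `pass`.
#' @export
compare_profiles <- function(observed, expected, tol_frac = 0.05) {
  if (is.data.frame(observed)) {
    stopifnot(nrow(observed) == 1L, "fragments" %in% names(observed))
    observed <- observed$fragments[[1]]
  }
  if (length(expected) == 0L) stop("expected profile is empty", call. = FALSE)
  obs <- sort(as.numeric(observed), decreasing = TRUE)
  exp <- sort(as.numeric(expected), decreasing = TRUE)
  n <- min(length(obs), length(exp))
  pairs <- tibble::tibble(
    observed = obs[seq_len(n)], expected = exp[seq_len(n)],
    rel_error = abs(obs[seq_len(n)] - exp[seq_len(n)]) / exp[seq_len(n)]
  )
  pairs$within_tol <- pairs$rel_error <= tol_frac
  out <- list(
    pairs = pairs,
    unmatched_observed = if (length(obs) > n) obs[(n + 1L):length(obs)] else numeric(),
    unmatched_expected = if (length(exp) > n) exp[(n + 1L):length(exp)] else numeric(),
    tol_frac = tol_frac,
    pass = all(pairs$within_tol) && length(obs) == length(exp)
  )
  class(out) <- "profile_comparison"
  out
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("<profile_comparison> %d pairs, tol %.3f: %s\n",
              nrow(x$pairs), x$tol_frac, if (x$pass) "PASS" else "FAIL"))
  if (length(x$unmatched_observed)) {
    cat(" unmatched observed:", paste(x$unmatched_observed, collapse = ", "), "\n")
  }
  if (length(x$unmatched_expected)) {
    cat(" unmatched expected:", paste(x$unmatched_expected, collapse = ", "), "\n")
  }
  invisible(x)
}
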