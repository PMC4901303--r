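# ORF calling on circular genomes.
#
# Selection rules: ATG start only, protein length >= min_aa (default 50 aa,
# i.e. ORF >= 153 nt including the stop), both strands, wrap-aware. Within
# a run of in-frame ATGs sharing one stop, only the maximal ORF (most
# upstream ATG) is reported. "Minimal overlapping" between adjacent calls
# is enforced separately by resolve_orf_overlaps() as a stated, deterministic
# rule: longest-first greedy with at most 25% overlap of the shorter ORF.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames on a circular genome
#'
#' Scans all six reading frames, wrapping through the origin on circular
#' genomes. Only ATG starts are considered; each reported ORF runs from the
#' most upstream ATG after the previous in-frame stop to its stop codon
#' (the stop is part of the ORF span but not of the protein).
#'
#' @param genome A [circular_genome()].
#' @param min_aa Minimum protein length in amino acids (default 50).
#' @return A tibble sorted by `start` with columns `start` (0-based
#'   position of the leftmost footprint base on the top strand), `span`
#'   (nt, including the stop codon), `strand`, `frame` (`start %% 3`),
#'   `protein`.
#' @examples
#' g <- circular_genome(paste0("ATG", strrep("GCT", 60), "TAAGGGCC"))
#' find_orfs(g)
#' @export
find_orfs <- function(genome, min_aa = 50L) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  circ <- genome$topology == "circular"
  # A circular genome is scanned as three concatenated copies: any maximal
  # ORF with span <= L whose delimiting upstream stop wraps behind the
  # origin is then guaranteed to appear, with its full context, in the
  # middle copy. Duplicated calls are collapsed mod L.
  plus <- if (circ) strrep(genome$sequence, 3L) else genome$sequence
  minus <- reverse_complement(plus)

  res <- list(scan_strand_orfs(plus, L, circ, min_aa, strand = "+"),
              scan_strand_orfs(minus, L, circ, min_aa, strand = "-"))
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(start = integer(), span = integer(),
                          strand = character(), frame = integer(),
                          protein = character()))
  }
  out <- dplyr::distinct(out, .data$start, .data$span, .data$strand,
                         .keep_all = TRUE)
  out$frame <- out$start %% 3L
  out <- dplyr::arrange(out, .data$start, .data$span, .data$strand)
  out[, c("start", "span", "strand", "frame", "protein")]
}

# Scan one strand given as a linear string `s` (the doubled sequence for
# circular genomes). Emits footprints in top-strand coordinates.
scan_strand_orfs <- function(s, L, circ, min_aa, strand) {
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  acc <- list()
  for (f in 0:2) {
    starts_nt <- seq(f + 1L, n - 2L, by = 3L)
    if (length(starts_nt) == 0L) next
    codons <- paste0(chars[starts_nt], chars[starts_nt + 1L], chars[starts_nt + 2L])
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    # run id: index of the previous stop (0 = scan start, no upstream context)
    run <- cumsum(is_stop)
    run_of_codon <- c(0L, run[-length(run)])  # run the codon belongs to
    stop_idx <- which(is_stop)
    if (length(stop_idx) == 0L) next
    atg_idx <- which(is_atg)
    if (length(atg_idx) == 0L) next
    # first ATG within each run
    first_atg <- tapply(atg_idx, run_of_codon[atg_idx], min)
    for (rid in names(first_atg)) {
      r <- as.integer(rid)
      if (circ && r == 0L) next  # upstream context unknown at scan start
      a <- first_atg[[rid]]
      stop_after <- stop_idx[stop_idx > a]
      if (length(stop_after) == 0L) next
      st <- stop_after[1]
      if (run_of_codon[st] != r) next  # stop belongs to this run by construction
      start_nt <- starts_nt[a] - 1L          # 0-based on `s`
      span <- (st - a + 1L) * 3L             # includes stop codon
      if (span / 3L - 1L < min_aa) next
      if (circ && span > L) next             # would wrap more than once
      acc[[length(acc) + 1L]] <- c(start_nt, span)
    }
  }
  if (length(acc) == 0L) {
    return(tibble::tibble(start = integer(), span = integer(),
                          strand = character(), protein = character()))
  }
  m <- do.call(rbind, acc)
  start_s <- m[, 1]; span <- m[, 2]
  if (strand == "+") {
    start_top <- if (circ) start_s %% L else start_s
  } else {
    n_s <- nchar(s)
    left_top <- n_s - start_s - span          # leftmost footprint base
    start_top <- if (circ) left_top %% L else left_top
  }
  keep <- !duplicated(cbind(start_top, span))
  start_top <- start_top[keep]; span <- span[keep]
  g_str <- if (strand == "+") substr(s, 1L, L) else
    reverse_complement(substr(s, 1L, L))
  # protein: extract on the calling strand
  protein <- vapply(seq_along(start_top), function(i) {
    cds <- if (strand == "+") {
      extract_on(g_str, start_top[i], span[i], L, circ)
    } else {
      reverse_complement(extract_on(g_str, start_top[i], span[i], L, circ))
    }
    translate_cds(cds)
  }, "")
  tibble::tibble(start = as.integer(start_top), span = as.integer(span),
                 strand = strand, protein = protein)
}

extract_on <- function(seq_str, start, span, L, circ) {
  if (start + span <= L) {
    substr(seq_str, start + 1L, start + span)
  } else {
    paste0(substr(seq_str, start + 1L, L),
           substr(seq_str, 1L, start + span - L))
  }
}

#' Resolve overlapping ORF calls
#'
#' Deterministic longest-first greedy: ORFs are considered by decreasing
#' span (ties: lower start, then `+` strand) and an ORF is discarded when
#' its footprint overlap with any already kept ORF exceeds
#' `max_overlap_frac` of the shorter of the two. Overlap is measured on
#' top-strand footprints, circularly.
#'
#' @param orfs Tibble from [find_orfs()].
#' @param genome_length Genome length in bp.
#' @param max_overlap_frac Tolerated overlap as a fraction of the shorter
#'   ORF (default 0.25).
#' @return The kept subset, sorted by `start`.
#' @export
resolve_orf_overlaps <- function(orfs, genome_length, max_overlap_frac = 0.25) {
  if (nrow(orfs) == 0L) return(orfs)
  L <- as.integer(genome_length)
  ord <- order(-orfs$span, orfs$start, orfs$strand != "+")
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      ov <- circular_overlap(orfs$start[i], orfs$span[i],
                             orfs$start[j], orfs$span[j], L)
      if (ov > max_overlap_frac * min(orfs$span[i], orfs$span[j])) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- orfs[sort(kept), , drop = FALSE]
  dplyr::arrange(out, .data$start, .data$span)
}

#' Name ORFs by genome order
#'
#' Assigns zero-padded ordinals clockwise from an anchor ORF (baculovirus
#' convention: the polyhedrin gene is number 001). The default anchor is
#' the ORF with the leftmost start.
#'
#' @param orfs Tibble of ORFs.
#' @param prefix Name prefix, e.g. `"acmnpv"`.
#' @param anchor_start Optional `start` coordinate of the anchor ORF; must
#'   match a row of `orfs`.
#' @return `orfs` with a `name` column, in clockwise order from the anchor.
#' @export
name_orfs <- function(orfs, prefix, anchor_start = NULL) {
  if (nrow(orfs) == 0L) {
    orfs$name <- character(0)
    return(orfs)
  }
  orfs <- dplyr::arrange(orfs, .data$start, .data$span)
  if (is.null(anchor_start)) {
    k <- 1L
  } else {
    k <- which(orfs$start == anchor_start)
    if (length(k) == 0L) stop("anchor ORF not found in list", call. = FALSE)
    k <- k[1]
  }
  ord <- c(seq(k, nrow(orfs)), seq_len(k - 1L))
  orfs <- orfs[ord, , drop = FALSE]
  orfs$name <- sprintf("%s%03d", prefix, seq_len(nrow(orfs)))
  orfs
}

#' Annotate a genome end to end
#'
#' Convenience pipeline: [find_orfs()], [resolve_orf_overlaps()],
#' [name_orfs()].
#'
#' @inheritParams find_orfs
#' @inheritParams resolve_orf_overlaps
#' @param prefix Name prefix for [name_orfs()].
#' @param anchor_start Optional anchor coordinate passed to [name_orfs()].
#' @return A named, overlap-resolved ORF tibble.
#' @export
annotate_orfs <- function(genome, min_aa = 50L, max_overlap_frac = 0.25,
                          prefix = "orf", anchor_start = NULL) {
  orfs <- find_orfs(genome, min_aa = min_aa)
  orfs <- resolve_orf_overlaps(orfs, genome$length,
                               max_overlap_frac = max_overlap_frac)
  name_orfs(orfs, prefix = prefix, anchor_start = anchor_start)
}
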