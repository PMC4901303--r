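# Ortholog assignment and unique-ORF classification.
#
# Criterion: best hit per subject genome by raw alignment score (ties
# broken by higher identity, then lexicographic subject name), with
# Karlin-Altschul E-value over search space m*n = query length x summed
# subject-proteome length. A hit with E above the threshold is recorded
# as absent. Reciprocal-best-hit flags are computed from the symmetric
# score matrix. An ORF with no retained hit in any subject genome is
# "unique" — the class the 12 novel baculovirus ORFs fell into at
# E > 10^-3.

#' Assign orthologs between a focal proteome and subject proteomes
#'
#' @param query Named character vector: the focal genome's proteins.
#' @param subjects Named list of named character vectors, one per subject
#'   genome.
#' @param e_threshold Retain hits with E-value at or below this (default
#'   `1e-3`).
#' @param matrix,gap_open,gap_extend Alignment parameters, see
#'   [align_proteins()].
#' @param K,lambda Karlin-Altschul constants.
#' @return A tibble with one row per (query, subject genome):
#'   `query`, `genome`, `subject` (NA when no hit passes), `raw_score`,
#'   `bits`, `identity`, `evalue`, `reciprocal`.
#' @export
assign_orthologs <- function(query, subjects, e_threshold = 1e-3,
                             matrix = NULL, gap_open = 11L, gap_extend = 1L,
                             K = 0.041, lambda = 0.267) {
  stopifnot(length(query) > 0L, is.list(subjects), length(subjects) > 0L,
            !is.null(names(subjects)))
  if (is.null(matrix)) matrix <- default_matrix()
  out <- list()
  for (g in names(subjects)) {
    B <- subjects[[g]]
    stopifnot(length(B) > 0L)
    sc <- proteome_scores(query, B, matrix, gap_open, gap_extend)
    n_space <- sum(nchar(B))
    m_space <- sum(nchar(query))
    # best hit per query (rows), ties: identity then subject name
    best_j <- vapply(seq_along(query), function(i) {
      r <- sc$raw[i, ]
      cand <- which(r == max(r))
      if (length(cand) > 1L) {
        idc <- sc$identity[i, cand]
        cand <- cand[idc == max(idc)]
        cand <- cand[order(names(B)[cand])]
      }
      cand[1]
    }, 1L)
    # best hit per subject (columns) for reciprocity
    best_i <- vapply(seq_along(B), function(j) {
      r <- sc$raw[, j]
      cand <- which(r == max(r))
      if (length(cand) > 1L) {
        idc <- sc$identity[cand, j]
        cand <- cand[idc == max(idc)]
        cand <- cand[order(names(query)[cand])]
      }
      cand[1]
    }, 1L)
    raw <- sc$raw[cbind(seq_along(query), best_j)]
    ev <- estimate_evalue(raw, nchar(query), n_space, K, lambda)
    ev_rev <- estimate_evalue(raw, nchar(B)[best_j], m_space, K, lambda)
    keep <- ev <= e_threshold
    recip <- keep & (best_i[best_j] == seq_along(query)) &
      (ev_rev <= e_threshold)
    out[[g]] <- tibble::tibble(
      query = names(query), genome = g,
      subject = unname(ifelse(keep, names(B)[best_j], NA_character_)),
      raw_score = unname(ifelse(keep, raw, NA_real_)),
      bits = unname(ifelse(keep, (lambda * raw - log(K)) / log(2),
                           NA_real_)),
      identity = unname(ifelse(keep,
                               sc$identity[cbind(seq_along(query), best_j)],
                               NA_real_)),
      evalue = unname(ifelse(keep, ev, NA_real_)),
      reciprocal = unname(recip)
    )
  }
  dplyr::bind_rows(out)
}

#' Classify unique ORFs
#'
#' An ORF is unique when it has no retained hit (E-value above the
#' threshold used in [assign_orthologs()]) in any subject genome.
#'
#' @param orthologs Tibble from [assign_orthologs()].
#' @return Character vector of unique query names.
#' @export
unique_orfs <- function(orthologs) {
  tab <- dplyr::summarise(
    dplyr::group_by(orthologs, .data$query),
    any_hit = any(!is.na(.data$subject)), .groups = "drop")
  sort(tab$query[!tab$any_hit])
}

#' Per-ORF identity table across genomes (heat-map source)
#'
#' @param orthologs Tibble from [assign_orthologs()].
#' @return A wide tibble: one row per focal ORF, one column per subject
#'   genome holding the best-hit identity fraction (NA where the ORF has
#'   no retained hit — unique ORFs are all-NA rows).
#' @export
identity_heatmap_table <- function(orthologs) {
  tidyr::pivot_wider(
    orthologs[, c("query", "genome", "identity")],
    names_from = "genome", values_from = "identity"
  )
}
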