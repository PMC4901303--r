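# Supermatrix construction: concatenated per-gene protein alignments with
# exact partition bookkeeping, and Poisson-corrected protein distances.

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param alignments Named list; each element is a named character vector
#'   of aligned (equal-length) protein sequences for one gene.
#' @param missing `"pad"` (default): taxa absent from a gene get a gap row
#'   over that partition; `"intersect"`: only taxa present in every gene
#'   are kept.
#' @return A list of class `supermatrix`: `aln` (character matrix, taxa x
#'   columns, single characters), `partitions` (tibble `gene`, `start`,
#'   `end`, 1-based inclusive), `taxa`.
#' @export
concatenate_alignments <- function(alignments,
                                   missing = c("pad", "intersect")) {
  missing <- match.arg(missing)
  stopifnot(is.list(alignments), length(alignments) > 0L,
            !is.null(names(alignments)))
  for (g in names(alignments)) {
    a <- alignments[[g]]
    if (is.null(names(a))) {
      stop(sprintf("gene '%s': sequences must be named by taxon", g),
           call. = FALSE)
    }
    if (anyDuplicated(names(a))) {
      stop(sprintf("gene '%s': duplicate taxon '%s'", g,
                   names(a)[duplicated(names(a))][1]), call. = FALSE)
    }
    if (length(unique(nchar(a))) != 1L) {
      stop(sprintf("gene '%s': unaligned (unequal lengths)", g),
           call. = FALSE)
    }
  }
  taxa_sets <- lapply(alignments, names)
  taxa <- if (missing == "pad") {
    unique(unlist(taxa_sets))
  } else {
    Reduce(intersect, taxa_sets)
  }
  if (length(taxa) == 0L) stop("no taxa shared by all genes", call. = FALSE)
  widths <- vapply(alignments, function(a) nchar(a[[1]]), 1L)
  total <- sum(widths)
  aln <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  at <- 1L
  parts <- list()
  for (g in names(alignments)) {
    a <- alignments[[g]]
    w <- widths[[g]]
    common <- intersect(taxa, names(a))
    block <- do.call(rbind, strsplit(toupper(a[common]), "", fixed = TRUE))
    aln[common, at:(at + w - 1L)] <- block
    parts[[g]] <- tibble::tibble(gene = g, start = at, end = at + w - 1L)
    at <- at + w
  }
  out <- list(aln = aln, partitions = dplyr::bind_rows(parts), taxa = taxa)
  class(out) <- "supermatrix"
  out
}

#' Split a supermatrix back into per-gene alignments
#'
#' Inverse of [concatenate_alignments()] (taxa padded into a gene come
#' back as all-gap rows).
#'
#' @param sm A `supermatrix`.
#' @return Named list of named character vectors.
#' @export
split_supermatrix <- function(sm) {
  stopifnot(inherits(sm, "supermatrix"))
  out <- list()
  for (i in seq_len(nrow(sm$partitions))) {
    p <- sm$partitions[i, ]
    block <- sm$aln[, p$start:p$end, drop = FALSE]
    out[[p$gene]] <- apply(block, 1, paste, collapse = "")
  }
  out
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partitions\n",
              nrow(x$aln), ncol(x$aln), nrow(x$partitions)))
  invisible(x)
}

#' Poisson-corrected protein distances
#'
#' Pairwise p-distance over columns where neither sequence has a gap,
#' corrected as `d = -ln(1 - p)`. Since the correction diverges as p
#' approaches 1, p is capped at `p_cap` (default 0.999, i.e. a distance
#' ceiling of about 6.9 substitutions per site).
#'
#' @param sm A `supermatrix` (or a character matrix of single residues).
#' @param p_cap Cap applied to p before correction.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
protein_distance <- function(sm, p_cap = 0.999) {
  aln <- if (inherits(sm, "supermatrix")) sm$aln else sm
  n <- nrow(aln)
  if (n < 2L) stop("need at least two taxa", call. = FALSE)
  gap <- aln == "-" | aln == "X" | aln == "?"
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      m <- sum(ok)
      if (m == 0L) {
        stop(sprintf("taxa '%s' and '%s' share no comparable columns",
                     rownames(aln)[i], rownames(aln)[j]), call. = FALSE)
      }
      p <- sum(aln[i, ok] != aln[j, ok]) / m
      D[i, j] <- D[j, i] <- -log(1 - min(p, p_cap))
    }
  }
  D
}
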