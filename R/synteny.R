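# Synteny/inversion mapping and the hr-proximity permutation test.
#
# Shared orthologs are reduced to a signed permutation: focal ORFs in
# genome order index the subject ORF's rank, with sign +1 when strands
# agree and -1 when they disagree. Maximal runs of strictly monotone index
# with consistent sign become synteny blocks; decreasing runs with
# negative sign are inversions. Strand sign enters the permutation so an
# inversion is detectable even when order alone stays monotone.

#' Map synteny blocks between two annotated genomes
#'
#' @param focal_orfs Tibble of focal-genome ORFs with `name` (or `label`),
#'   `start`, `strand`.
#' @param subject_orfs Same for the subject genome.
#' @param orthologs Tibble with columns `query` (focal ORF name) and
#'   `subject` (subject ORF name); rows with `subject` NA are ignored. The
#'   output of [assign_orthologs()] filtered to one genome works directly.
#' @return A tibble of blocks: `block`, `orientation` (`"collinear"` /
#'   `"inverted"`), `n_genes`, `queries` and `subjects` (list columns of
#'   member names in block order), `query_index`, `subject_index` (list
#'   columns of genome-order ranks).
#' @export
synteny_map <- function(focal_orfs, subject_orfs, orthologs) {
  name_col <- function(x) if ("name" %in% names(x)) x$name else x$label
  f <- tibble::tibble(query = name_col(focal_orfs),
                      f_start = focal_orfs$start,
                      f_strand = focal_orfs$strand)
  s <- tibble::tibble(subject = name_col(subject_orfs),
                      s_start = subject_orfs$start,
                      s_strand = subject_orfs$strand)
  pairs <- orthologs[!is.na(orthologs$subject), c("query", "subject")]
  pairs <- dplyr::inner_join(pairs, f, by = "query")
  pairs <- dplyr::inner_join(pairs, s, by = "subject")
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(block = integer(), orientation = character(),
                          n_genes = integer(), queries = list(),
                          subjects = list(), query_index = list(),
                          subject_index = list()))
  }
  pairs <- dplyr::arrange(pairs, .data$f_start)
  pairs$query_index <- seq_len(nrow(pairs))
  pairs$subject_index <- rank(pairs$s_start, ties.method = "first")
  pairs$sign <- ifelse(pairs$f_strand == pairs$s_strand, 1L, -1L)

  n <- nrow(pairs)
  # break before i when the (sign, direction) pattern is not continued
  brk <- logical(n)
  brk[1] <- TRUE
  if (n > 1L) {
    for (i in 2:n) {
      same_sign <- pairs$sign[i] == pairs$sign[i - 1L]
      dirn <- sign(pairs$subject_index[i] - pairs$subject_index[i - 1L])
      want <- pairs$sign[i]   # +1 blocks ascend, -1 blocks descend
      brk[i] <- !(same_sign && dirn == want)
    }
  }
  block_id <- cumsum(brk)
  out <- purrr::map(split(seq_len(n), block_id), function(ii) {
    p <- pairs[ii, , drop = FALSE]
    tibble::tibble(
      orientation = if (p$sign[1] == 1L) "collinear" else "inverted",
      n_genes = nrow(p),
      queries = list(p$query), subjects = list(p$subject),
      query_index = list(p$query_index), subject_index = list(p$subject_index)
    )
  })
  out <- dplyr::bind_rows(out)
  out$block <- seq_len(nrow(out))
  out[, c("block", "orientation", "n_genes", "queries", "subjects",
          "query_index", "subject_index")]
}

# circular distance from each position to the nearest hr boundary; 0 when
# the position lies inside an hr
hr_boundary_distance <- function(pos, hr_start, hr_span, L) {
  k <- length(hr_start)
  inside <- rep(FALSE, length(pos))
  for (i in seq_len(k)) {
    off <- (pos - hr_start[i]) %% L
    inside <- inside | off < hr_span[i]
  }
  bounds <- c(hr_start %% L, (hr_start + hr_span) %% L)
  d <- rep(Inf, length(pos))
  for (b in bounds) d <- pmin(d, circular_dist(pos, b, L))
  ifelse(inside, 0, d)
}

#' Permutation test: are positions closer to hr boundaries than chance?
#'
#' The statistic is the mean circular distance from each position
#' (typically unique-ORF midpoints) to the nearest hr boundary (zero
#' inside an hr). The null repositions the points uniformly at random on
#' the circle; the one-sided p-value is
#' `(1 + #\{null <= observed\}) / (n_perm + 1)`.
#'
#' @param midpoints Numeric vector of 0-based positions.
#' @param hrs Tibble of hr loci with `start` and `span` (e.g. from
#'   [detect_hrs()]).
#' @param genome_length Genome length in bp.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed for reproducibility.
#' @return An object of class `hr_proximity_test`: `observed` (mean
#'   distance, bp), `p_value`, `n_perm`, `n_points`, `null_mean`.
#' @export
hr_proximity_test <- function(midpoints, hrs, genome_length,
                              n_perm = 10000L, seed = NULL) {
  if (length(midpoints) == 0L || nrow(hrs) == 0L) {
    stop("need at least one midpoint and one hr locus", call. = FALSE)
  }
  L <- as.numeric(genome_length)
  m <- length(midpoints)
  run <- function() {
    obs <- mean(hr_boundary_distance(midpoints %% L, hrs$start, hrs$span, L))
    null <- vapply(seq_len(n_perm), function(i) {
      mean(hr_boundary_distance(stats::runif(m, 0, L), hrs$start, hrs$span, L))
    }, 1.0)
    list(obs = obs, null = null)
  }
  r <- if (is.null(seed)) run() else with_seed_(seed, run())
  out <- list(observed = r$obs,
              p_value = (1 + sum(r$null <= r$obs)) / (n_perm + 1),
              n_perm = as.integer(n_perm), n_points = m,
              null_mean = mean(r$null))
  class(out) <- "hr_proximity_test"
  out
}

#' @export
print.hr_proximity_test <- function(x, ...) {
  cat(sprintf(paste0("<hr_proximity_test> mean distance %.1f bp ",
                     "(null mean %.1f), one-sided p = %.4g (%d perms)\n"),
              x$observed, x$null_mean, x$p_value, x$n_perm))
  invisible(x)
}

#' Export a Circos-style link table for synteny plotting
#'
#' @param blocks Tibble from [synteny_map()].
#' @param focal_orfs,subject_orfs The ORF tables used to build it (need
#'   `name`/`label`, `start`, `span`).
#' @return A tibble: `block`, `orientation`, `query`, `q_start`, `q_end`,
#'   `subject`, `s_start`, `s_end` (1-based inclusive, link-table style).
#' @export
synteny_links <- function(blocks, focal_orfs, subject_orfs) {
  name_col <- function(x) if ("name" %in% names(x)) x$name else x$label
  fn <- name_col(focal_orfs); sn <- name_col(subject_orfs)
  rows <- purrr::map(seq_len(nrow(blocks)), function(b) {
    q <- blocks$queries[[b]]; s <- blocks$subjects[[b]]
    qi <- match(q, fn); si <- match(s, sn)
    tibble::tibble(
      block = blocks$block[b], orientation = blocks$orientation[b],
      query = q, q_start = focal_orfs$start[qi] + 1L,
      q_end = focal_orfs$start[qi] + focal_orfs$span[qi],
      subject = s, s_start = subject_orfs$start[si] + 1L,
      s_end = subject_orfs$start[si] + subject_orfs$span[si]
    )
  })
  dplyr::bind_rows(rows)
}
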