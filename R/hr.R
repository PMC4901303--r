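# Homologous-region (hr) discovery.
#
# hrs are clusters of imperfect ~38-bp palindromic repeats. The detector is
# self-contained: palindromicity is scored on each window against its own
# reverse complement (the consensus is an output, not an input), qualifying
# windows are reduced to non-overlapping peaks, peaks are clustered by
# circular gap distance, and a per-cluster majority consensus is built.

#' Palindromicity of a DNA window
#'
#' The fraction of positions `i` whose base pairs with the base at the
#' mirrored position `L-1-i` (i.e. the window matches its own reverse
#' complement there). `N` never pairs. Symmetric under reverse
#' complementation of the window.
#'
#' @param window A DNA string.
#' @return A fraction in `[0, 1]`.
#' @examples
#' palindrome_score("GAATTC")  # 1.0
#' palindrome_score("AAAAAA")  # 0.0 (A cannot pair A)
#' @export
palindrome_score <- function(window) {
  stopifnot(is.character(window), length(window) == 1L, nchar(window) > 0L)
  check_alphabet(window)
  x <- encode_dna(window)
  mean(x == COMP_CODE[rev(x)])
}

#' Scan a genome for imperfect palindromic repeat units
#'
#' Slides a window of `unit_len` over the genome (wrapping through the
#' origin on circular genomes) and scores each window with
#' [palindrome_score()]. Qualifying windows (score >= `min_score`) are
#' reduced to non-overlapping peaks by greedy selection: the
#' highest-scoring window is accepted (ties broken leftmost), windows
#' overlapping an accepted one are discarded, and so on. On a perfect
#' tandem array this yields exactly one unit per repeat copy.
#'
#' @param genome A [circular_genome()].
#' @param unit_len Window length in bp (default 38, the classical hr unit).
#' @param min_score Minimum palindromicity (default 0.6).
#' @return A tibble sorted by `start`: `start`, `span`, `score`,
#'   `sequence`.
#' @export
scan_palindromes <- function(genome, unit_len = 38L, min_score = 0.6) {
  stopifnot(inherits(genome, "circular_genome"))
  unit_len <- as.integer(unit_len)
  if (unit_len < 4L) stop("unit_len must be >= 4", call. = FALSE)
  L <- genome$length
  circ <- genome$topology == "circular"
  if (unit_len > L) {
    return(tibble::tibble(start = integer(), span = integer(),
                          score = double(), sequence = character()))
  }
  x <- encode_dna(genome$sequence)
  xx <- if (circ) c(x, x[seq_len(unit_len - 1L)]) else x
  n_win <- if (circ) L else L - unit_len + 1L
  matches <- integer(n_win)
  idx <- seq_len(n_win)
  for (j in seq_len(unit_len)) {
    # position j pairs with mirrored position unit_len+1-j
    matches <- matches +
      (xx[idx + j - 1L] == COMP_CODE[xx[idx + unit_len - j]])
  }
  score <- matches / unit_len
  qual <- which(score >= min_score)
  if (length(qual) == 0L) {
    return(tibble::tibble(start = integer(), span = integer(),
                          score = double(), sequence = character()))
  }
  # greedy peak selection among overlapping qualifying windows
  ord <- qual[order(-score[qual], qual)]
  taken <- logical(0)
  accepted <- integer()
  for (p in ord) {
    clash <- FALSE
    for (a in accepted) {
      d <- if (circ) circular_dist(p - 1L, a - 1L, L) else abs(p - a)
      if (d < unit_len) { clash <- TRUE; break }
    }
    if (!clash) accepted <- c(accepted, p)
  }
  accepted <- sort(accepted)
  starts <- accepted - 1L
  tibble::tibble(
    start = starts, span = unit_len, score = score[accepted],
    sequence = vapply(starts, function(s) extract_seq(genome, s, unit_len), "")
  )
}

#' Cluster palindromic repeat units into homologous regions
#'
#' Single-linkage clustering on circular gap distance: consecutive units
#' separated by at most `max_gap` bp (end to start) belong to one cluster.
#' Clusters with fewer than `min_units` units are discarded. Surviving
#' clusters become hr loci labelled `hr1`, `hr2`, ... clockwise from the
#' origin; each locus interval is the minimal hull covering its units
#' (wrapping the origin when the cluster does).
#'
#' @param units Tibble from [scan_palindromes()] (sorted by `start`).
#' @param genome_length Genome length in bp.
#' @param max_gap Maximum end-to-start gap within a cluster (default 500).
#' @param min_units Minimum units per reported locus (default 2).
#' @param circular Treat coordinates circularly (default TRUE).
#' @return A tibble: `label`, `start`, `span`, `n_units`, `mean_score`,
#'   and a `units` list-column holding each locus's unit tibble.
#' @export
cluster_into_hrs <- function(units, genome_length, max_gap = 500L,
                             min_units = 2L, circular = TRUE) {
  empty <- tibble::tibble(label = character(), start = integer(),
                          span = integer(), n_units = integer(),
                          mean_score = double(), units = list())
  if (nrow(units) == 0L) return(empty)
  L <- as.integer(genome_length)
  units <- dplyr::arrange(units, .data$start)
  n <- nrow(units)
  ends <- units$start + units$span
  if (n == 1L) {
    grp <- 1L
  } else {
    gap <- units$start[-1] - ends[-n]          # between consecutive units
    new_cluster <- c(TRUE, gap > max_gap)
    grp <- cumsum(new_cluster)
  }
  # circular closure: if the wrap gap joins last and first cluster, merge
  if (circular && n > 1L && max(grp) > 1L) {
    wrap_gap <- (units$start[1] + L) - ends[n]
    if (wrap_gap <= max_gap) grp[grp == max(grp)] <- 1L
  }
  clusters <- split(seq_len(n), grp)
  regions <- purrr::map(clusters, function(ii) {
    u <- units[sort(ii), , drop = FALSE]
    if (nrow(u) < min_units) return(NULL)
    if (circular && nrow(u) > 1L) {
      # minimal hull on the circle: the arc left after removing the
      # largest gap between consecutive member units
      gaps <- c(u$start[-1], u$start[1] + L) - (u$start + u$span)
      cut <- which.max(gaps)
      first <- (cut %% nrow(u)) + 1L
      s0 <- u$start[first]
      span <- L - gaps[cut]
      u <- u[order((u$start - s0) %% L), , drop = FALSE]
    } else {
      s0 <- min(u$start)
      span <- max(u$start + u$span) - s0
    }
    tibble::tibble(start = as.integer(s0), span = as.integer(span),
                   n_units = nrow(u), mean_score = mean(u$score),
                   units = list(u))
  })
  regions <- dplyr::bind_rows(regions)
  if (nrow(regions) == 0L) return(empty)
  regions <- dplyr::arrange(regions, .data$start)
  regions$label <- sprintf("hr%d", seq_len(nrow(regions)))
  regions[, c("label", "start", "span", "n_units", "mean_score", "units")]
}

#' Majority consensus of an hr locus
#'
#' Columns of the ungapped stack of equal-length units are called by
#' majority, ties broken alphabetically. Per-column conservation (the
#' fraction of units carrying the consensus base; strict-identity columns
#' have conservation 1) is attached as attribute `"conservation"`.
#'
#' @param units Character vector of equal-length unit sequences, or a
#'   one-row hr tibble from [cluster_into_hrs()], or its `units` tibble.
#' @return The consensus DNA string with attribute `conservation`.
#' @export
hr_consensus <- function(units) {
  if (is.data.frame(units)) {
    if ("units" %in% names(units) && nrow(units) == 1L) {
      units <- units$units[[1]]$sequence
    } else if ("sequence" %in% names(units)) {
      units <- units$sequence
    } else {
      stop("cannot find unit sequences in input", call. = FALSE)
    }
  }
  stopifnot(is.character(units), length(units) >= 1L)
  w <- unique(nchar(units))
  if (length(w) != 1L) stop("units must have equal length", call. = FALSE)
  mat <- do.call(rbind, strsplit(units, "", fixed = TRUE))
  cons <- character(w); conserv <- numeric(w)
  for (j in seq_len(w)) {
    tab <- table(mat[, j])
    best <- sort(names(tab)[tab == max(tab)])[1]  # alphabetical tie-break
    cons[j] <- best
    conserv[j] <- tab[[best]] / length(units)
  }
  structure(paste(cons, collapse = ""), conservation = conserv)
}

#' Detect homologous regions end to end
#'
#' Convenience pipeline: [scan_palindromes()], [cluster_into_hrs()], and
#' [hr_consensus()] per locus.
#'
#' @inheritParams scan_palindromes
#' @inheritParams cluster_into_hrs
#' @return The [cluster_into_hrs()] tibble with an extra `consensus`
#'   character column.
#' @export
detect_hrs <- function(genome, unit_len = 38L, min_score = 0.6,
                       max_gap = 500L, min_units = 2L) {
  units <- scan_palindromes(genome, unit_len = unit_len, min_score = min_score)
  hrs <- cluster_into_hrs(units, genome$length, max_gap = max_gap,
                          min_units = min_units,
                          circular = genome$topology == "circular")
  if (nrow(hrs) == 0L) {
    hrs$consensus <- character(0)
    return(hrs)
  }
  hrs$consensus <- vapply(hrs$units, function(u) {
    as.character(hr_consensus(u$sequence))
  }, "")
  hrs
}
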