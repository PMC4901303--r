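# Independent oracles and fixture builders used across the suite.

random_genome <- function(L, seed, gc = 0.4, id = "rnd") {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  circular_genome(paste(sample(c("A", "C", "G", "T"), L, TRUE, p),
                        collapse = ""), id = id)
}

# ---- six-frame ORF oracle -------------------------------------------------
# Walks every position of each strand, extends codon by codon around the
# circle to the first stop, keeps ATG-started frames, then filters to the
# maximal ORF per (stop, strand).
oracle_find_orfs <- function(genome, min_aa) {
  L <- genome$length
  comp <- function(s) baculokit::reverse_complement(s)
  strands <- list(`+` = genome$sequence, `-` = comp(genome$sequence))
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in names(strands)) {
    s <- strands[[strand]]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    at <- function(i) chars[(i %% L) + 1L]          # 0-based circular
    codon_at <- function(i) paste0(at(i), at(i + 1L), at(i + 2L))
    cands <- list()
    for (p in 0:(L - 1L)) {
      if (codon_at(p) != "ATG") next
      k <- NA
      for (ci in seq_len(L %/% 3L)) {
        if (codon_at(p + 3L * ci) %in% stops) { k <- ci; break }
      }
      if (is.na(k)) next
      span <- 3L * (k + 1L)
      if (span > L) next
      if (k < min_aa) next                          # protein = k aa
      cands[[length(cands) + 1L]] <-
        data.frame(p = p, span = span, stop_at = (p + 3L * k) %% L)
    }
    if (length(cands) == 0L) next
    cands <- do.call(rbind, cands)
    # maximal ORF per shared stop
    keep <- do.call(rbind, lapply(split(cands, cands$stop_at), function(g) {
      g[which.max(g$span), ]
    }))
    top_start <- if (strand == "+") keep$p %% L else
      (L - keep$p - keep$span) %% L
    out[[strand]] <- data.frame(start = top_start, span = keep$span,
                                strand = strand)
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res), , drop = FALSE]
  res[order(res$start, res$span), , drop = FALSE]
}

# ---- exhaustive palindrome-window oracle ---------------------------------
# Direct per-window scoring: position i pairs when it equals the
# complement of the mirrored base.
oracle_window_scores <- function(genome, unit_len) {
  L <- genome$length
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "#")
  vapply(0:(L - 1L), function(p) {
    w <- strsplit(extract_seq(genome, p, unit_len), "", fixed = TRUE)[[1]]
    mean(w == comp[rev(w)])
  }, 1.0)
}

oracle_scan_palindromes <- function(genome, unit_len, min_score) {
  L <- genome$length
  sc <- oracle_window_scores(genome, unit_len)
  qual <- which(sc >= min_score) - 1L
  ord <- qual[order(-sc[qual + 1L], qual)]
  acc <- integer(0)
  for (p in ord) {
    d <- pmin(abs(p - acc), L - abs(p - acc))
    if (length(acc) == 0L || all(d >= unit_len)) acc <- c(acc, p)
  }
  sort(acc)
}

# ---- brute-force affine-gap local alignment ------------------------------
# Smith-Waterman with gap cost open + g*ext, floor 0 (matches the
# convention of the package's aligner).
oracle_local_align <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(-Inf, n + 1L, m + 1L)   # gap in b (A aligned to gap)
  Iy <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                                Ix[i, j + 1L] - ext)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                                Iy[i + 1L, j] - ext)
      sub <- mat[A[i], B[j]]
      M[i + 1L, j + 1L] <- max(0,
                               sub + max(M[i, j], Ix[i, j], Iy[i, j]))
      best <- max(best, M[i + 1L, j + 1L],
                  Ix[i + 1L, j + 1L], Iy[i + 1L, j + 1L])
    }
  }
  best
}

# ---- exhaustive pruning-likelihood oracle --------------------------------
# Sums over every assignment of states to internal nodes.
oracle_tree_lnL <- function(tree, sm, model) {
  aln <- sm$aln[tree$tip.label, , drop = FALSE]
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
    prob_matrix(model, tree$edge.length[e])
  })
  states <- as.matrix(expand.grid(rep(list(1:20), n_int)))
  total <- 0
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (site in seq_len(ncol(aln))) {
    tipc <- match(aln[, site], aa)                # NA = gap
    site_l <- 0
    for (r in seq_len(nrow(states))) {
      st <- states[r, ]
      node_state <- function(v) if (v <= n_tip) tipc[v] else st[v - n_tip]
      pr <- unname(model$freqs[st[1]])            # root = n_tip + 1
      ok <- TRUE
      for (e in seq_len(nrow(tree$edge))) {
        pa <- node_state(tree$edge[e, 1])
        ch <- node_state(tree$edge[e, 2])
        if (is.na(ch)) next                       # gap tip: sums to 1
        pr <- pr * Ps[[e]][pa, ch]
        if (pr == 0) { ok <- FALSE; break }
      }
      if (ok) site_l <- site_l + pr
    }
    total <- total + log(site_l)
  }
  total
}

# ---- small simulated study fixtures --------------------------------------
small_sim <- function(seed, L = 20000, n_orfs = 10, n_hrs = 3,
                      divergence = 0.1, promoter = 2) {
  generate_genome(sim_config(
    genome_length = L, n_orfs = n_orfs, orf_length_range = c(153, 700),
    n_hrs = n_hrs, units_per_hr_range = c(3, 5),
    unit_divergence = divergence, n_promoter_orfs = promoter, seed = seed))
}
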