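# Synthetic circular genomes with planted, truth-tracked features.
#
# The generator builds i.i.d. background at a configured GC content and
# plants: non-overlapping ORFs on both strands (ATG...stop, no internal
# stop, with an in-frame stop codon written immediately upstream so the
# planted ATG is always the maximal start), hr loci as tandem arrays of a
# genome-wide 38-bp perfect-palindrome master unit with per-copy
# divergence, promoter motifs in reserved upstream windows, and
# restriction sites. Background is then scrubbed of spurious ORF calls (>=
# min_aa) and of chance occurrences of planted enzyme sites by point
# edits, so the truth table is the complete truth. Everything is a pure
# function of (config, seed).

#' Configuration for the synthetic-genome generator
#'
#' Defaults mirror the structure of a sequenced group I alphabaculovirus
#' genome: ~120 kb circular, 134 ORFs of at least 50 aa, seven hr loci
#' built from a common imperfect 38-bp palindromic repeat, the four
#' classical promoter motifs planted upstream of six designated ORFs, and
#' an AT-rich base composition.
#'
#' @param genome_length Genome size in bp.
#' @param n_orfs Number of planted ORFs.
#' @param orf_length_range ORF span range in nt (including the stop
#'   codon); both ends are rounded to full codons.
#' @param n_hrs Number of planted hr loci.
#' @param units_per_hr_range Range of repeat-unit copies per hr locus.
#' @param unit_length Repeat-unit length in bp (default 38).
#' @param unit_divergence Per-base substitution probability applied
#'   independently to every planted repeat-unit copy.
#' @param promoter_motifs Motifs planted upstream of designated ORFs.
#' @param n_promoter_orfs Number of ORFs receiving planted motifs.
#' @param restriction_sites Named integer vector: planted site count per
#'   enzyme (names must appear in [restriction_enzymes()]).
#' @param gc_content Background GC fraction.
#' @param min_aa Scrub threshold: background is edited until no unplanted
#'   ORF of at least this protein length remains.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 120023L, n_orfs = 134L,
                       orf_length_range = c(153L, 1350L), n_hrs = 7L,
                       units_per_hr_range = c(3L, 8L), unit_length = 38L,
                       unit_divergence = 0.1,
                       promoter_motifs = DEFAULT_MOTIFS,
                       n_promoter_orfs = 6L,
                       restriction_sites = integer(0),
                       gc_content = 0.41, min_aa = 50L, seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_orfs = as.integer(n_orfs),
              orf_length_range = as.integer(orf_length_range),
              n_hrs = as.integer(n_hrs),
              units_per_hr_range = as.integer(units_per_hr_range),
              unit_length = as.integer(unit_length),
              unit_divergence = unit_divergence,
              promoter_motifs = toupper(promoter_motifs),
              n_promoter_orfs = as.integer(n_promoter_orfs),
              restriction_sites = restriction_sites,
              gc_content = gc_content, min_aa = as.integer(min_aa),
              seed = as.integer(seed))
  stopifnot(cfg$genome_length > 0L, cfg$n_orfs >= 0L, cfg$n_hrs >= 0L,
            cfg$unit_length >= 4L,
            cfg$unit_divergence >= 0, cfg$unit_divergence <= 1,
            cfg$gc_content >= 0, cfg$gc_content <= 1,
            all(cfg$restriction_sites >= 0L),
            cfg$n_promoter_orfs <= cfg$n_orfs)
  class(cfg) <- "sim_config"
  cfg
}

# run code under a seed without disturbing the caller's RNG stream
with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna_chars <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

SENSE_CODONS <- local({
  names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
})

# random coding sequence: ATG + (n_aa - 1) sense codons + stop; n_aa is the
# protein length
random_cds <- function(n_aa) {
  body <- sample(setdiff(SENSE_CODONS, "ATG"), n_aa - 1L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Mutate a DNA sequence by point substitution
#'
#' Each base is substituted independently with probability `rate`,
#' uniformly over the three alternatives.
#'
#' @param seq DNA string.
#' @param rate Substitution probability per base, in `[0, 1]`.
#' @param seed Optional seed (deterministic result when given).
#' @return The mutated string.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  run <- function() {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(chars)) < rate)
    if (length(hit) > 0L) {
      bases <- c("A", "C", "G", "T")
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(bases, b), 1L)
      }, "")
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed_(seed, run())
}

mutate_chars <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, "")
  }
  chars
}

# Non-overlapping placement of blocks of given widths with per-block
# clearance `margin` kept on both sides. Blocks are laid out in random
# order around the (linearised) circle with the free slack distributed
# randomly among the inter-block gaps, so dense genomes (~85% coding,
# typical of NPVs) pack reliably. Returns 0-based block starts; none
# wraps the origin.
place_blocks <- function(widths, L, margin = 2L) {
  n <- length(widths)
  if (n == 0L) return(integer(0))
  margin <- rep_len(margin, n)
  perm <- sample.int(n)
  w <- widths[perm]; m <- margin[perm]
  # required gap before each block (and after the last): both neighbours'
  # clearances
  req <- m + c(m[n], m[-n])
  slack <- L - sum(w) - sum(req)
  if (slack < 0) {
    stop("planted features do not fit at the requested density",
         call. = FALSE)
  }
  extra <- if (slack > 0) {
    as.integer(stats::rmultinom(1, slack, rep(1 / n, n)))
  } else integer(n)
  # start of block i = sum of previous (gap + width) + its own gap
  gaps <- req + extra
  starts_perm <- cumsum(gaps + c(0L, w[-n]))
  starts <- integer(n)
  starts[perm] <- as.integer(starts_perm)
  starts
}

#' Generate a synthetic circular genome with planted features
#'
#' See [sim_config()] for what is planted. The returned truth table is
#' complete: after scrubbing, [find_orfs()] at `min_aa` reports exactly
#' the planted ORFs, and the planted enzymes' sites occur exactly where
#' planted.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_genome`: `genome` (a
#'   [circular_genome()]), `truth` (tibble: `label`, `kind`, `start`,
#'   `span`, `strand`, `protein`, `motif`, `enzyme`, `hr`, `novel`),
#'   `config`.
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed_(cfg$seed, build_sim_genome(cfg))
}

build_sim_genome <- function(cfg) {
  L <- cfg$genome_length
  gv <- random_dna_chars(L, cfg$gc_content)
  # mask: 0 free background, 1 planted-ORF interior (codon-preserving edits
  # allowed), 2 hard (hr, motifs, sites, start/stop codons, guards)
  mask <- integer(L)
  truth <- list()

  # ---- feature geometry ----------------------------------------------
  n_units <- if (cfg$n_hrs > 0L) {
    sample(seq(cfg$units_per_hr_range[1], cfg$units_per_hr_range[2]),
           cfg$n_hrs, replace = TRUE)
  } else integer(0)
  hr_w <- n_units * cfg$unit_length

  lo_aa <- max(cfg$min_aa, cfg$orf_length_range[1] %/% 3L - 1L)
  hi_aa <- max(lo_aa, cfg$orf_length_range[2] %/% 3L - 1L)
  orf_aa <- if (cfg$n_orfs > 0L) {
    sample(seq(lo_aa, hi_aa), cfg$n_orfs, replace = TRUE)
  } else integer(0)
  orf_w <- 3L * (orf_aa + 1L)
  orf_strand <- if (cfg$n_orfs > 0L) {
    sample(c("+", "-"), cfg$n_orfs, replace = TRUE)
  } else character(0)
  promoter_orf <- seq_len(cfg$n_orfs) <= cfg$n_promoter_orfs
  reserve <- ifelse(promoter_orf, 200L, 0L)
  orf_block <- orf_w + 3L + reserve  # guard stop + upstream reserve

  enz_tab <- restriction_enzymes()
  site_enz <- rep(names(cfg$restriction_sites), cfg$restriction_sites)
  site_seqs <- enz_tab$site[match(site_enz, enz_tab$enzyme)]
  if (anyNA(site_seqs) && length(site_enz) > 0L) {
    stop("unknown enzyme in restriction_sites", call. = FALSE)
  }

  widths <- c(hr_w, orf_block, nchar(site_seqs))
  # hr loci get a 350 bp clearance each (700 bp separation), so distinct
  # planted loci stay distinct under the detector's default 500 bp
  # cluster gap
  margins <- c(rep(350L, length(hr_w)), rep(2L, length(orf_block)),
               rep(2L, length(site_seqs)))
  starts <- place_blocks(widths, L, margin = margins)
  hr_start <- starts[seq_along(hr_w)]
  orf_bstart <- starts[cfg$n_hrs + seq_along(orf_w)]
  site_start <- starts[cfg$n_hrs + cfg$n_orfs + seq_along(site_seqs)]

  # ---- hr loci ---------------------------------------------------------
  if (cfg$n_hrs > 0L) {
    half <- random_dna_chars(cfg$unit_length %/% 2L, cfg$gc_content)
    mid <- if (cfg$unit_length %% 2L == 1L) sample(c("A", "C", "G", "T"), 1L)
           else character(0)
    master <- c(half, mid,
                strsplit(reverse_complement(paste(half, collapse = "")),
                         "", fixed = TRUE)[[1]])
    for (h in seq_len(cfg$n_hrs)) {
      s <- hr_start[h]
      for (u in seq_len(n_units[h])) {
        copy <- mutate_chars(master, cfg$unit_divergence)
        us <- s + (u - 1L) * cfg$unit_length
        gv[us + seq_len(cfg$unit_length)] <- copy
        truth[[length(truth) + 1L]] <- tibble::tibble(
          label = sprintf("hr%d_u%d", h, u), kind = "repeat_unit",
          start = us, span = cfg$unit_length, strand = "+",
          hr = sprintf("hr%d", h))
      }
      # level 3: last-resort editable (an edit only adds divergence to a
      # repeat copy; truth records unit coordinates, not sequences)
      mask[s + seq_len(hr_w[h])] <- 3L
      truth[[length(truth) + 1L]] <- tibble::tibble(
        label = sprintf("hr%d", h), kind = "hr", start = s,
        span = hr_w[h], strand = "+", hr = sprintf("hr%d", h))
    }
    attr_master <- paste(master, collapse = "")
  } else attr_master <- NA_character_
  # ---- ORFs ------------------------------------------------------------
  if (cfg$n_orfs > 0L) {
    for (i in seq_len(cfg$n_orfs)) {
      cds <- random_cds(orf_aa[i])
      w <- orf_w[i]
      if (orf_strand[i] == "+") {
        s <- orf_bstart[i] + reserve[i] + 3L
        gv[s + seq_len(w)] <- strsplit(cds, "", fixed = TRUE)[[1]]
        gv[s - 2:0] <- c("T", "A", "A")                 # upstream guard
        mask[s + seq_len(w)] <- 1L
        mask[c(s - 2:0, s + 1:3, s + (w - 2L):w)] <- 2L # guard+start+stop
      } else {
        s <- orf_bstart[i]
        gv[s + seq_len(w)] <- strsplit(reverse_complement(cds), "",
                                       fixed = TRUE)[[1]]
        gv[s + w + 1:3] <- c("T", "T", "A")             # guard (revcomp TAA)
        mask[s + seq_len(w)] <- 1L
        mask[c(s + w + 1:3, s + 1:3, s + (w - 2L):w)] <- 2L
      }
      truth[[length(truth) + 1L]] <- tibble::tibble(
        label = sprintf("orf%03d", i), kind = "ORF", start = s,
        span = w, strand = orf_strand[i])
    }
  }
  # ---- promoter motifs -------------------------------------------------
  if (cfg$n_orfs > 0L && cfg$n_promoter_orfs > 0L &&
      length(cfg$promoter_motifs) > 0L) {
    for (i in which(promoter_orf)) {
      w <- orf_w[i]
      # offsets of each motif's 3' base upstream of the ATG (offset 1 =
      # base immediately 5' of it); offsets 1..3 hold the guard stop, so
      # motifs start at offset >= 4 and do not overlap one another
      koff <- 3L
      for (m in cfg$promoter_motifs) {
        k <- nchar(m)
        off <- koff + sample.int(20L, 1L)
        koff <- off + k + 2L
        if (off + k - 1L > 200L) next
        if (orf_strand[i] == "+") {
          s0 <- orf_bstart[i] + reserve[i] + 3L      # 0-based ATG position
          ms <- s0 - off - k + 1L                    # 0-based motif start
          gv[ms + seq_len(k)] <- strsplit(m, "", fixed = TRUE)[[1]]
          mstrand <- "+"
        } else {
          ms <- orf_bstart[i] + w + off - 1L         # 0-based motif start
          gv[ms + seq_len(k)] <- strsplit(reverse_complement(m), "",
                                          fixed = TRUE)[[1]]
          mstrand <- "-"
        }
        mask[ms + seq_len(k)] <- 2L
        truth[[length(truth) + 1L]] <- tibble::tibble(
          label = sprintf("orf%03d_%s", i, m), kind = "motif",
          start = as.integer(ms), span = k, strand = mstrand,
          motif = m, orf = sprintf("orf%03d", i))
      }
    }
  }
  # ---- restriction sites ----------------------------------------------
  if (length(site_seqs) > 0L) {
    for (i in seq_along(site_seqs)) {
      s <- site_start[i]; k <- nchar(site_seqs[i])
      gv[s + seq_len(k)] <- strsplit(site_seqs[i], "", fixed = TRUE)[[1]]
      mask[s + seq_len(k)] <- 2L
      truth[[length(truth) + 1L]] <- tibble::tibble(
        label = sprintf("%s_site%d", site_enz[i], i),
        kind = "restriction_site", start = s, span = k, strand = "+",
        enzyme = site_enz[i])
    }
  }

  truth <- dplyr::bind_rows(truth)
  for (col in c("protein", "motif", "enzyme", "hr", "orf")) {
    if (!col %in% names(truth)) truth[[col]] <- NA_character_
  }
  truth$novel <- FALSE

  # ---- scrub background ------------------------------------------------
  gv <- scrub_background(gv, mask, truth, cfg)

  genome <- circular_genome(paste(gv, collapse = ""),
                            id = sprintf("sim%d", cfg$seed))
  # freeze proteins after scrubbing (codon-preserving edits may have
  # touched ORF interiors)
  is_orf <- truth$kind == "ORF"
  truth$protein[is_orf] <- vapply(which(is_orf), function(i) {
    translate_cds(extract_seq(genome, truth$start[i], truth$span[i],
                              truth$strand[i]))
  }, "")
  truth <- dplyr::arrange(truth, .data$start, .data$span)
  out <- list(genome = genome, truth = truth, config = cfg,
              hr_master = attr_master, derivation_ops = list())
  class(out) <- "sim_genome"
  out
}

# point-edit background until no unplanted ORF call >= min_aa and no
# unplanted site of a planted enzyme remains
scrub_background <- function(gv, mask, truth, cfg, max_iter = 600L) {
  L <- cfg$genome_length
  truth_orfs <- truth[truth$kind == "ORF", c("start", "span", "strand")]
  planted_enz <- names(cfg$restriction_sites)[cfg$restriction_sites > 0L]
  enz_tab <- restriction_enzymes()
  bases <- c("A", "C", "G", "T")

  orf_owner <- integer(L)  # 1-based truth-orf row covering each position
  tor <- truth[truth$kind == "ORF", ]
  for (i in seq_len(nrow(tor))) {
    orf_owner[(tor$start[i] + seq_len(tor$span[i]) - 1L) %% L + 1L] <- i
  }

  # is substituting position p (0-based) with `alt` allowed? Free
  # background and repeat-unit positions are; planted-ORF interiors only
  # when the owner's codon stays sense.
  edit_ok <- function(p, alt) {
    m <- mask[p + 1L]
    if (m == 2L) return(FALSE)
    if (m != 1L) return(TRUE)
    i <- orf_owner[p + 1L]
    s <- tor$start[i]; w <- tor$span[i]; strand <- tor$strand[i]
    off <- (p - s) %% L                       # offset within footprint
    cpos <- if (strand == "+") off %/% 3L else (w - 1L - off) %/% 3L
    cstart <- if (strand == "+") s + cpos * 3L else s + w - 3L * (cpos + 1L)
    cod <- gv[(cstart + 0:2) %% L + 1L]
    cod[(p - cstart) %% L + 1L] <- alt
    codon <- paste(cod, collapse = "")
    if (strand == "-") codon <- reverse_complement(codon)
    !codon %in% STOP_CODONS
  }
  # one decisive edit against a spurious ORF call: preferably turn a codon
  # near its middle into a stop (splits the run), else break the start
  # codon, else substitute a random editable footprint base
  kill_orf_edit <- function(s, w, strand) {
    n_cod <- w %/% 3L
    inner <- if (n_cod >= 4L) seq(2L, n_cod - 1L) else integer(0)
    # middle-out with random jitter: deterministic choices can oscillate
    # when two overlapping spurious calls share constrained positions
    mid_order <- order(abs(inner - n_cod / 2) +
                         stats::runif(length(inner), 0, n_cod / 3))
    for (cj in inner[mid_order]) {
      cstart <- if (strand == "+") s + 3L * (cj - 1L) else
        s + w - 3L * cj                       # top coord of codon start
      cod_top <- gv[(cstart + 0:2) %% L + 1L]
      cod <- if (strand == "+") cod_top else
        strsplit(reverse_complement(paste(cod_top, collapse = "")), "",
                 fixed = TRUE)[[1]]
      for (stp in sample(STOP_CODONS)) {
        sv <- strsplit(stp, "", fixed = TRUE)[[1]]
        dif <- which(cod != sv)
        if (length(dif) != 1L) next
        j <- dif                               # coding-strand codon index
        top_j <- if (strand == "+") j else 4L - j
        p <- (cstart + top_j - 1L) %% L
        alt_top <- if (strand == "+") sv[j] else
          chartr("ACGT", "TGCA", sv[j])
        if (edit_ok(p, alt_top)) return(list(p = p, alt = alt_top))
      }
    }
    # break the start codon
    startpos <- if (strand == "+") s + 0:2 else s + w - 3L + 0:2
    for (p in startpos %% L) {
      for (alt in sample(setdiff(bases, gv[p + 1L]))) {
        if (edit_ok(p, alt)) return(list(p = p, alt = alt))
      }
    }
    # last resort: random editable footprint base
    for (p in sample((s + seq_len(w) - 1L) %% L)) {
      for (alt in sample(setdiff(bases, gv[p + 1L]))) {
        if (edit_ok(p, alt)) return(list(p = p, alt = alt))
      }
    }
    NULL
  }
  edit_one <- function(cand) {
    for (p in cand) {
      for (alt in sample(setdiff(bases, gv[p + 1L]))) {
        if (edit_ok(p, alt)) return(list(p = p, alt = alt))
      }
    }
    NULL
  }

  hr_blocks <- truth[truth$kind == "hr", c("start", "span")]
  ulen <- cfg$unit_length
  comp <- COMP_CODE
  # background windows at or above the detector-default palindromicity are
  # scrubbed so the planted hr loci are the only cluster-forming signal
  pal_cap <- 0.6

  spurious_palindromes <- function() {
    x <- match(gv, DNA_ALPHABET)
    xx <- c(x, x[seq_len(ulen - 1L)])
    idx <- seq_len(L)
    matches <- integer(L)
    for (j in seq_len(ulen)) {
      matches <- matches + (xx[idx + j - 1L] == comp[xx[idx + ulen - j]])
    }
    qual <- which(matches / ulen >= pal_cap) - 1L   # 0-based starts
    if (length(qual) == 0L || nrow(hr_blocks) == 0L) return(qual)
    keep <- vapply(qual, function(p) {
      all(vapply(seq_len(nrow(hr_blocks)), function(i) {
        circular_overlap(p, ulen, hr_blocks$start[i], hr_blocks$span[i],
                         L) == 0L
      }, TRUE))
    }, TRUE)
    qual[keep]
  }

  break_palindrome_edit <- function(p) {
    # positions of currently-pairing bases within the window
    for (j in sample(seq_len(ulen))) {
      a <- (p + j - 1L) %% L; b <- (p + ulen - j) %% L
      if (gv[a + 1L] != DNA_ALPHABET[comp[match(gv[b + 1L], DNA_ALPHABET)]])
        next
      for (q in c(a, b)) {
        partner <- if (q == a) b else a
        bad <- DNA_ALPHABET[comp[match(gv[partner + 1L], DNA_ALPHABET)]]
        for (alt in sample(setdiff(bases, c(gv[q + 1L], bad)))) {
          if (edit_ok(q, alt)) return(list(p = q, alt = alt))
        }
      }
    }
    NULL
  }

  for (iter in seq_len(max_iter)) {
    genome <- circular_genome(paste(gv, collapse = ""))
    calls <- find_orfs(genome, min_aa = cfg$min_aa)
    spur <- dplyr::anti_join(calls, truth_orfs,
                             by = c("start", "span", "strand"))
    bad_sites <- list()
    for (e in planted_enz) {
      row <- enz_tab[enz_tab$enzyme == e, ]
      cuts_truth <- truth[truth$kind == "restriction_site" &
                            truth$enzyme == e, ]
      sites <- primer_like_sites(gv, row$site, L)
      extra <- setdiff(sites, cuts_truth$start)
      if (length(extra) > 0L) {
        bad_sites[[e]] <- tibble::tibble(start = extra,
                                         span = nchar(row$site))
      }
    }
    bad_sites <- dplyr::bind_rows(bad_sites)
    bad_pal <- spurious_palindromes()
    if (nrow(spur) == 0L && nrow(bad_sites) == 0L &&
        length(bad_pal) == 0L) {
      return(gv)
    }

    edited <- FALSE
    if (nrow(spur) > 0L) {
      for (r in seq_len(nrow(spur))) {
        hit <- kill_orf_edit(spur$start[r], spur$span[r], spur$strand[r])
        if (!is.null(hit)) { gv[hit$p + 1L] <- hit$alt; edited <- TRUE }
      }
    }
    if (nrow(bad_sites) > 0L) {
      for (r in seq_len(nrow(bad_sites))) {
        cand <- (bad_sites$start[r] + seq_len(bad_sites$span[r]) - 1L) %% L
        hit <- edit_one(cand)
        if (!is.null(hit)) { gv[hit$p + 1L] <- hit$alt; edited <- TRUE }
      }
    }
    for (p in bad_pal) {
      hit <- break_palindrome_edit(p)
      if (!is.null(hit)) { gv[hit$p + 1L] <- hit$alt; edited <- TRUE }
    }
    if (!edited) {
      stop("scrub failed: spurious feature cannot be edited away",
           call. = FALSE)
    }
  }
  stop("scrub did not converge", call. = FALSE)
}

# 0-based starts of exact site matches on both strands, wrap-aware, on a
# character-vector genome
primer_like_sites <- function(gv, site, L) {
  x <- match(gv, DNA_ALPHABET)
  k <- nchar(site)
  xx <- c(x, x[seq_len(k - 1L)])
  idx <- seq_len(L)
  res <- integer(0)
  for (pat in unique(c(site, reverse_complement(site)))) {
    pc <- encode_dna(pat)
    hit <- rep(TRUE, L)
    for (j in seq_len(k)) hit <- hit & (xx[idx + j - 1L] == pc[j])
    res <- c(res, which(hit) - 1L)
  }
  sort(unique(res))
}
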