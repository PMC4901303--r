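# Derived (rearranged, diverged) genomes with replayable truth mapping.
#
# Operations are applied left to right, each on the current genome:
#   inversion:      reverse-complement a segment in place
#   translocation:  excise a segment and reinsert it elsewhere
#   loss:           delete a truth ORF's footprint
#   gain:           insert a novel random ORF
# Segments must not bisect planted features (checked). After the ops, the
# sequence diverges by point substitution everywhere except planted motif
# and restriction-site footprints; planted-ORF codons are then repaired so
# start/stop codons survive and no internal stop arises, keeping derived
# proteomes translatable.

op_inversion <- function(start, span) {
  list(type = "inversion", start = as.integer(start), span = as.integer(span))
}
op_translocation <- function(start, span, to) {
  list(type = "translocation", start = as.integer(start),
       span = as.integer(span), to = as.integer(to))
}
op_loss <- function(label) list(type = "loss", label = label)
op_gain <- function(aa, at, label = NULL) {
  list(type = "gain", aa = as.integer(aa), at = as.integer(at), label = label)
}

#' Rearrangement operations for [derive_rearranged_genome()]
#'
#' Constructors for the four supported operations. Coordinates are 0-based
#' and refer to the genome as it stands when the operation is applied
#' (operations apply left to right). `inversion(start, span)`
#' reverse-complements a segment in place; `translocation(start, span,
#' to)` excises a segment and reinserts it so its first base lands at
#' position `to` of the post-excision genome; `loss(label)` deletes the
#' footprint of the named truth ORF; `gain(aa, at)` inserts a novel random
#' ORF of `aa` amino acids at position `at`.
#'
#' @param start,span Segment coordinates (0-based start, width in bp).
#' @param to Destination coordinate for a translocated segment.
#' @param label Truth label of the ORF to delete, or an optional label for
#'   a gained ORF.
#' @param aa Protein length of a gained ORF.
#' @param at Insertion point of a gained ORF.
#' @name rearrangement-ops
NULL

#' @rdname rearrangement-ops
#' @export
rearrangement <- function(type = c("inversion", "translocation", "loss",
                                   "gain"),
                          start = NULL, span = NULL, to = NULL,
                          label = NULL, aa = NULL, at = NULL) {
  type <- match.arg(type)
  switch(type,
    inversion = op_inversion(start, span),
    translocation = op_translocation(start, span, to),
    loss = op_loss(label),
    gain = op_gain(aa, at, label)
  )
}

# features fully inside [s, s+w)? none may straddle the boundary
check_no_bisect <- function(truth, s, w) {
  f_in <- truth$start >= s & truth$start + truth$span <= s + w
  f_out <- truth$start + truth$span <= s | truth$start >= s + w
  if (!all(f_in | f_out)) {
    bad <- truth$label[!(f_in | f_out)][1]
    stop(sprintf("operation segment bisects planted feature '%s'", bad),
         call. = FALSE)
  }
  f_in
}

#' Derive a rearranged, diverged genome from a simulated one
#'
#' @param sim A `sim_genome` from [generate_genome()].
#' @param ops List of operations built with [rearrangement()] (applied
#'   left to right).
#' @param divergence_rate Per-base substitution probability applied after
#'   the rearrangements (motif and restriction-site footprints are
#'   protected; planted-ORF start/stop codons are restored and internal
#'   stops repaired afterwards).
#' @param seed Integer seed.
#' @return A new `sim_genome` whose truth table carries `src_start` and
#'   `src_strand` (coordinates in the source genome) next to the new
#'   coordinates, and whose `derivation_ops` field records the applied
#'   operations.
#' @export
derive_rearranged_genome <- function(sim, ops = list(), divergence_rate = 0,
                                     seed = 1L) {
  stopifnot(inherits(sim, "sim_genome"))
  with_seed_(seed, derive_impl(sim, ops, divergence_rate, seed))
}

derive_impl <- function(sim, ops, divergence_rate, seed) {
  gv <- strsplit(sim$genome$sequence, "", fixed = TRUE)[[1]]
  truth <- sim$truth
  truth$src_start <- truth$start
  truth$src_strand <- truth$strand
  if (!"novel" %in% names(truth)) truth$novel <- FALSE

  flip <- c("+" = "-", "-" = "+")
  for (op in ops) {
    L <- length(gv)
    if (op$type %in% c("inversion", "translocation")) {
      s <- op$start; w <- op$span
      if (s < 0L || w < 1L || s + w > L) {
        stop("operation segment outside the genome (wrapping segments are not supported)",
             call. = FALSE)
      }
      inside <- check_no_bisect(truth, s, w)
      if (op$type == "inversion") {
        gv[s + seq_len(w)] <- strsplit(
          reverse_complement(paste(gv[s + seq_len(w)], collapse = "")),
          "", fixed = TRUE)[[1]]
        # feature at [f, f+fw) maps to [s + (s+w-f-fw), ...), strand flips
        truth$strand[inside] <- flip[truth$strand[inside]]
        truth$start[inside] <- 2L * s + w - truth$start[inside] -
          truth$span[inside]
      } else {
        to <- op$to
        if (to < 0L || to > L - w) {
          stop("translocation destination outside the post-excision genome",
               call. = FALSE)
        }
        seg <- gv[s + seq_len(w)]
        gv <- gv[-(s + seq_len(w))]
        # features after the excised segment shift left
        after <- !inside & truth$start >= s + w
        truth$start[after] <- truth$start[after] - w
        # destination must not bisect a remaining feature
        rem <- truth[!inside, , drop = FALSE]
        ok <- rem$start + rem$span <= to | rem$start >= to
        if (!all(ok)) {
          stop(sprintf("translocation destination bisects feature '%s'",
                       rem$label[!ok][1]), call. = FALSE)
        }
        gv <- append(gv, seg, after = to)
        shift <- !inside & truth$start >= to
        truth$start[shift] <- truth$start[shift] + w
        truth$start[inside] <- truth$start[inside] - s + to
      }
    } else if (op$type == "loss") {
      i <- which(truth$label == op$label & truth$kind == "ORF")
      if (length(i) != 1L) {
        stop(sprintf("loss: no unique truth ORF '%s'", op$label),
             call. = FALSE)
      }
      s <- truth$start[i]; w <- truth$span[i]
      inside <- check_no_bisect(truth, s, w)
      gv <- gv[-(s + seq_len(w))]
      after <- truth$start >= s + w
      truth$start[after] <- truth$start[after] - w
      truth <- truth[!inside, , drop = FALSE]
    } else if (op$type == "gain") {
      cds <- random_cds(op$aa)
      frag <- strsplit(paste0("TAA", cds), "", fixed = TRUE)[[1]]
      at <- op$at
      if (at < 0L || at > L) stop("gain position outside genome", call. = FALSE)
      ok <- truth$start + truth$span <= at | truth$start >= at
      if (!all(ok)) {
        stop(sprintf("gain position bisects feature '%s'",
                     truth$label[!ok][1]), call. = FALSE)
      }
      gv <- append(gv, frag, after = at)
      shift <- truth$start >= at
      truth$start[shift] <- truth$start[shift] + length(frag)
      lab <- if (is.null(op$label)) {
        sprintf("gain%03d", sum(grepl("^gain", truth$label)) + 1L)
      } else op$label
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        label = lab, kind = "ORF", start = at + 3L,
        span = length(frag) - 3L, strand = "+",
        protein = NA_character_, motif = NA_character_,
        enzyme = NA_character_, hr = NA_character_, orf = NA_character_,
        novel = TRUE, src_start = NA_integer_, src_strand = NA_character_))
    } else {
      stop(sprintf("unknown operation type '%s'", op$type), call. = FALSE)
    }
  }

  # divergence outside protected footprints
  L <- length(gv)
  if (divergence_rate > 0) {
    protected <- logical(L)
    prot <- truth[truth$kind %in% c("motif", "restriction_site"), ,
                  drop = FALSE]
    for (i in seq_len(nrow(prot))) {
      protected[(prot$start[i] + seq_len(prot$span[i]) - 1L) %% L + 1L] <- TRUE
    }
    idx <- which(!protected)
    hit <- idx[stats::runif(length(idx)) < divergence_rate]
    if (length(hit) > 0L) {
      bases <- c("A", "C", "G", "T")
      gv[hit] <- vapply(gv[hit], function(b) sample(setdiff(bases, b), 1L), "")
    }
    # repair planted ORFs: restore start/stop, desex internal stops
    tor <- which(truth$kind == "ORF")
    for (i in tor) {
      s <- truth$start[i]; w <- truth$span[i]; strand <- truth$strand[i]
      pos <- (s + seq_len(w) - 1L) %% L + 1L
      cds <- paste(gv[pos], collapse = "")
      if (strand == "-") cds <- reverse_complement(cds)
      cc <- strsplit(cds, "", fixed = TRUE)[[1]]
      n_cod <- w %/% 3L
      cc[1:3] <- c("A", "T", "G")
      last <- paste(cc[w - 2:0], collapse = "")
      if (!last %in% STOP_CODONS) cc[w - 2:0] <- c("T", "A", "A")
      for (cj in seq_len(n_cod - 2L)) {
        j0 <- 3L * cj + 1L
        if (paste(cc[j0 + 0:2], collapse = "") %in% STOP_CODONS) {
          cc[j0] <- "C"   # TAA->CAA, TAG->CAG, TGA->CGA: all sense
        }
      }
      cds <- paste(cc, collapse = "")
      if (strand == "-") cds <- reverse_complement(cds)
      gv[pos] <- strsplit(cds, "", fixed = TRUE)[[1]]
    }
  }

  genome <- circular_genome(paste(gv, collapse = ""),
                            id = sprintf("%s_derived", sim$genome$id))
  is_orf <- truth$kind == "ORF"
  truth$protein[is_orf] <- vapply(which(is_orf), function(i) {
    translate_cds(extract_seq(genome, truth$start[i], truth$span[i],
                              truth$strand[i]))
  }, "")
  truth <- dplyr::arrange(truth, .data$start, .data$span)
  out <- list(genome = genome, truth = truth, config = sim$config,
              hr_master = sim$hr_master,
              derivation_ops = c(sim$derivation_ops, ops))
  class(out) <- "sim_genome"
  out
}

#' Proteome of a simulated genome
#'
#' @param sim A `sim_genome`.
#' @return Named character vector of truth-ORF proteins, ordered by genome
#'   position.
#' @export
sim_proteome <- function(sim) {
  stopifnot(inherits(sim, "sim_genome"))
  orfs <- sim$truth[sim$truth$kind == "ORF", ]
  orfs <- dplyr::arrange(orfs, .data$start)
  stats::setNames(orfs$protein, orfs$label)
}

#' Write a simulated genome to disk
#'
#' Emits `<prefix>.fasta` (genome), `<prefix>_truth.gff3` (truth
#' features), and `<prefix>_config.yaml` (the configuration and any
#' derivation operations).
#'
#' @param sim A `sim_genome`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default the genome id).
#' @return Invisibly, the three paths.
#' @export
write_sim <- function(sim, dir, prefix = NULL) {
  stopifnot(inherits(sim, "sim_genome"))
  if (is.null(prefix)) prefix <- sim$genome$id
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  gff <- file.path(dir, paste0(prefix, "_truth.gff3"))
  yml <- file.path(dir, paste0(prefix, "_config.yaml"))
  write_fasta(stats::setNames(sim$genome$sequence, sim$genome$id), fa)
  write_gff3(sim$truth, sim$genome, gff)
  cfg <- unclass(sim$config)
  cfg$restriction_sites <- as.list(cfg$restriction_sites)
  yaml::write_yaml(list(config = cfg, derivation_ops = sim$derivation_ops),
                   yml)
  invisible(c(fasta = fa, gff3 = gff, yaml = yml))
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %s: %d bp, %d truth features (%d ORFs, %d hrs)\n",
              x$genome$id, x$genome$length, nrow(x$truth),
              sum(x$truth$kind == "ORF"), sum(x$truth$kind == "hr")))
  invisible(x)
}
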