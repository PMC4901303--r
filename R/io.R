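# Readers/writers: FASTA (via Biostrings), GenBank flat file (features +
# sequence, read-only), GFF3 v1.23, Newick.
#
# GFF3 convention for circular genomes: a feature wrapping the origin is
# written as two location parts sharing one ID attribute; readers reassemble
# them. Columns 4/5 are 1-based inclusive per the standard.

#' Read a FASTA file
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read features and sequence from a GenBank flat file
#'
#' A minimal reader for the parts of the format this pipeline touches:
#' the LOCUS line (length, topology), CDS feature locations (including
#' `complement(...)` and origin-wrapping `join(a..L,1..b)` forms) with
#' `/gene`, `/locus_tag` and `/product` qualifiers, and the ORIGIN
#' sequence block.
#'
#' @param path Path to a GenBank flat file.
#' @return A list with `genome` (a [circular_genome()]) and `features`
#'   (a tibble: `label`, `kind` (`"ORF"` for CDS), `start` 0-based, `span`,
#'   `strand`, `product`).
#' @export
read_genbank_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) {
    stop(sprintf("no LOCUS line in '%s' (line 1)", path), call. = FALSE)
  }
  locus <- lines[locus_i[1]]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2]
  bp_i <- match("bp", toks)
  if (is.na(bp_i) || bp_i < 3L) {
    stop(sprintf("malformed LOCUS line at line %d", locus_i[1]), call. = FALSE)
  }
  declared_len <- suppressWarnings(as.integer(toks[bp_i - 1L]))
  topology <- if (any(toks == "circular")) "circular" else "linear"

  # sequence block
  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) {
    stop("no ORIGIN block found", call. = FALSE)
  }
  end_i <- grep("^//", lines)
  end_i <- end_i[end_i > origin_i[1]][1]
  if (is.na(end_i)) end_i <- length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  seq <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
  if (!is.na(declared_len) && nchar(seq) != declared_len) {
    stop(sprintf("LOCUS declares %d bp but ORIGIN holds %d",
                 declared_len, nchar(seq)), call. = FALSE)
  }
  genome <- circular_genome(seq, id = id, topology = topology)

  # feature table: CDS entries
  feat_i <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_i) > 0L) {
    i <- feat_i[1] + 1L
    while (i < origin_i[1]) {
      ln <- lines[i]
      if (grepl("^\\s{5}CDS\\s+", ln)) {
        loc <- trimws(sub("^\\s{5}CDS\\s+", "", ln))
        # continuation lines of the location (no '/')
        j <- i + 1L
        while (j < origin_i[1] && grepl("^\\s{21}[^/]", lines[j])) {
          loc <- paste0(loc, trimws(lines[j])); j <- j + 1L
        }
        quals <- character()
        while (j < origin_i[1] && grepl("^\\s{21}/", lines[j])) {
          quals <- c(quals, trimws(lines[j])); j <- j + 1L
        }
        getq <- function(key) {
          hit <- grep(sprintf("^/%s=", key), quals, value = TRUE)
          if (length(hit) == 0L) return(NA_character_)
          gsub('^/[a-z_]+="?|"$', "", hit[1])
        }
        iv <- parse_genbank_location(loc, genome$length, line = i)
        label <- getq("gene")
        if (is.na(label)) label <- getq("locus_tag")
        feats[[length(feats) + 1L]] <- tibble::tibble(
          label = label, kind = "ORF", start = iv$start, span = iv$span,
          strand = iv$strand, product = getq("product")
        )
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  features <- if (length(feats)) dplyr::bind_rows(feats) else
    tibble::tibble(label = character(), kind = character(),
                   start = integer(), span = integer(),
                   strand = character(), product = character())
  n_unnamed <- sum(is.na(features$label))
  if (n_unnamed > 0L) {
    features$label[is.na(features$label)] <- sprintf("cds%03d", seq_len(n_unnamed))
  }
  list(genome = genome, features = features)
}

parse_genbank_location <- function(loc, L, line = NA) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
    rng <- lapply(parts, parse_gb_range, line = line)
    if (length(rng) == 2L && rng[[1]]$to == L && rng[[2]]$from == 1L) {
      # origin wrap
      start <- rng[[1]]$from - 1L
      span <- (L - rng[[1]]$from + 1L) + rng[[2]]$to
    } else {
      stop(sprintf("unsupported join() location '%s' at line %s", loc, line),
           call. = FALSE)
    }
  } else {
    r <- parse_gb_range(loc, line = line)
    start <- r$from - 1L
    span <- r$to - r$from + 1L
  }
  list(start = start, span = span, strand = strand)
}

parse_gb_range <- function(x, line = NA) {
  x <- gsub("[<>]", "", x)
  m <- regmatches(x, regexec("^(\\d+)\\.\\.(\\d+)$", x))[[1]]
  if (length(m) != 3L) {
    stop(sprintf("malformed location '%s' at line %s", x, line), call. = FALSE)
  }
  list(from = as.integer(m[2]), to = as.integer(m[3]))
}

#' Write a feature table to GFF3
#'
#' Internal 0-based start/span coordinates are converted to 1-based
#' inclusive. A feature wrapping the origin of a circular genome is split
#' into two rows sharing one `ID` attribute.
#'
#' @param features Tibble with `label`, `kind`, `start`, `span`, `strand`.
#' @param genome A [circular_genome()] (provides seqid and length).
#' @param path Output path.
#' @param source Value of GFF3 column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, genome, path, source = "baculokit") {
  L <- genome$length
  rows <- character()
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    attrs <- sprintf("ID=%s;kind=%s", f$label, f$kind)
    if (f$start + f$span <= L) {
      rows <- c(rows, sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                              genome$id, source, f$kind,
                              f$start + 1L, f$start + f$span,
                              f$strand, attrs))
    } else {
      rows <- c(rows,
        sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                genome$id, source, f$kind, f$start + 1L, L, f$strand, attrs),
        sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                genome$id, source, f$kind, 1L, f$start + f$span - L,
                f$strand, attrs))
    }
  }
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", genome$id, L), rows),
             path)
  invisible(path)
}

#' Read a GFF3 feature table written by [write_gff3()]
#'
#' Reassembles origin-wrapping features from their two split rows (matched
#' by shared `ID`).
#'
#' @param path Path to a GFF3 file.
#' @param genome_length Genome length in bp (needed to reassemble wraps).
#' @return A tibble with `label`, `kind`, `start` (0-based), `span`,
#'   `strand`.
#' @export
read_gff3 <- function(path, genome_length) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) {
    return(tibble::tibble(label = character(), kind = character(),
                          start = integer(), span = integer(),
                          strand = character()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed GFF3 row at line %d",
                 which(lines == body[bad[1]])[1]), call. = FALSE)
  }
  tab <- tibble::tibble(
    kind = vapply(parts, `[[`, "", 3L),
    from = as.integer(vapply(parts, `[[`, "", 4L)),
    to = as.integer(vapply(parts, `[[`, "", 5L)),
    strand = vapply(parts, `[[`, "", 7L),
    label = sub("^ID=([^;]+).*$", "\\1", vapply(parts, `[[`, "", 9L))
  )
  out <- lapply(split(tab, factor(tab$label, levels = unique(tab$label))),
    function(g) {
      if (nrow(g) == 1L) {
        tibble::tibble(label = g$label, kind = g$kind, start = g$from - 1L,
                       span = g$to - g$from + 1L, strand = g$strand)
      } else if (nrow(g) == 2L && g$to[1] == genome_length && g$from[2] == 1L) {
        tibble::tibble(label = g$label[1], kind = g$kind[1],
                       start = g$from[1] - 1L,
                       span = (genome_length - g$from[1] + 1L) + g$to[2],
                       strand = g$strand[1])
      } else {
        stop(sprintf("cannot reassemble multi-part feature '%s'", g$label[1]),
             call. = FALSE)
      }
    })
  dplyr::bind_rows(out)
}

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are kept; internal node labels (bootstrap supports) are
#' written as-is. Thin wrapper over [ape::write.tree()].
#'
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
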