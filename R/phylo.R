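# Neighbor-joining trees, non-parametric bootstrap supports, and a
# model-based protein-alignment simulator used by the recovery and
# calibration studies.

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (via [ape::nj()]); negative branch lengths,
#' an occasional artefact of the Q-criterion on noisy distances, are
#' clamped to zero and the total clamped deficit is recorded in attribute
#' `"clamped"`.
#'
#' @param d Symmetric distance matrix with zero diagonal (e.g. from
#'   [protein_distance()]).
#' @return An unrooted `ape::phylo` tree. With two taxa a single-edge
#'   tree is returned with a warning.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d))
  if (nrow(d) < 3L) {
    if (nrow(d) < 2L) stop("need at least two taxa", call. = FALSE)
    warning("fewer than 3 taxa: returning trivial two-leaf tree",
            call. = FALSE)
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               tip.label = rownames(d), Nnode = 1L,
               edge.length = rep(d[1, 2] / 2, 2))
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- deficit
  tr
}

#' Bootstrap supports for an NJ tree
#'
#' Non-parametric bootstrap: alignment columns are resampled with
#' replacement, an NJ tree is built per replicate
#' (Poisson-corrected distances), and each internal edge of the full-data
#' tree receives the fraction of replicates containing its bipartition.
#'
#' @param sm A `supermatrix`.
#' @param n_reps Number of replicates (default 100).
#' @param seed Optional seed; same seed, same supports.
#' @return The full-data NJ tree with `node.label` set to support
#'   fractions in `[0, 1]` (root label empty).
#' @export
bootstrap_support <- function(sm, n_reps = 100L, seed = NULL) {
  stopifnot(inherits(sm, "supermatrix"), n_reps >= 1L)
  run <- function() {
    full <- nj_tree(protein_distance(sm))
    S <- ncol(sm$aln)
    reps <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      cols <- sample.int(S, S, replace = TRUE)
      reps[[r]] <- nj_tree(protein_distance(sm$aln[, cols, drop = FALSE]))
    }
    counts <- ape::prop.clades(full, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    supports <- counts / n_reps
    full$node.label <- as.character(supports)
    full$node.label[1] <- ""    # root of the unrooted representation
    attr(full, "support") <- supports
    full
  }
  if (is.null(seed)) run() else with_seed_(seed, run())
}

#' Simulate a protein alignment on a tree
#'
#' Sites evolve independently under a [subst_model()]: root states are
#' drawn from the stationary frequencies and propagated along every
#' branch with the model's transition probabilities. No indels.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param n_sites Alignment length.
#' @param model A `subst_model` (default Poisson).
#' @param seed Optional seed.
#' @return Named character vector of aligned sequences (one per tip).
#' @export
simulate_protein_alignment <- function(tree, n_sites,
                                       model = subst_model("poisson"),
                                       seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1L)
  run <- function() {
    tr <- stats::reorder(tree, "cladewise")  # parents before children
    n_tip <- length(tr$tip.label)
    n_node <- n_tip + tr$Nnode
    states <- matrix(NA_integer_, n_node, n_sites)
    root <- n_tip + 1L
    states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                                 prob = model$freqs)
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      P <- prob_matrix(model, tr$edge.length[e])
      ps <- states[parent, ]
      # draw child states per site given parent state
      child_states <- integer(n_sites)
      for (a in unique(ps)) {
        ii <- which(ps == a)
        child_states[ii] <- sample.int(20L, length(ii), replace = TRUE,
                                       prob = P[a, ])
      }
      states[child, ] <- child_states
    }
    out <- apply(states[seq_len(n_tip), , drop = FALSE], 1, function(z) {
      paste(AA_ALPHABET[z], collapse = "")
    })
    stats::setNames(out, tr$tip.label)
  }
  if (is.null(seed)) run() else with_seed_(seed, run())
}
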