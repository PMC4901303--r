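# Pruning (post-order) protein likelihood, per-branch scalar optimisation,
# and the constrained-placement comparison: graft a focal taxon as sister
# to each of two candidate groups, optimise branch lengths, and compare
# log-likelihoods. The sign of delta-lnL is the placement call — the same
# quantity used to argue that a viral SNF2-family gene sits with insect
# TTF2 sequences rather than with baculovirus GTA.

prep_likelihood <- function(sm, taxa) {
  stopifnot(inherits(sm, "supermatrix"))
  miss <- setdiff(taxa, rownames(sm$aln))
  if (length(miss) > 0L) {
    stop(sprintf("taxa not in supermatrix: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  aln <- sm$aln[taxa, , drop = FALSE]
  codes <- matrix(match(aln, AA_ALPHABET), nrow = nrow(aln),
                  dimnames = list(taxa, NULL))  # NA = gap/ambiguous
  key <- apply(codes, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(pat = codes[, first, drop = FALSE], w = w, taxa = taxa,
       rep_site = which(first))
}

lnL_core <- function(tree, prep, model, reordered = FALSE) {
  tr <- if (reordered) tree else stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_pat <- ncol(prep$pat)
  tip_row <- match(tr$tip.label, prep$taxa)
  partial <- vector("list", n_tip + tr$Nnode)
  scale_log <- numeric(n_pat)
  for (i in seq_len(n_tip)) {
    M <- matrix(0, 20L, n_pat)
    st <- prep$pat[tip_row[i], ]
    obs <- which(!is.na(st))
    M[cbind(st[obs], obs)] <- 1
    M[, is.na(st)] <- 1          # gaps: all-ones partials (missing data)
    partial[[i]] <- M
  }
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    contrib <- prob_matrix(model, tr$edge.length[e]) %*% partial[[child]]
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      M <- partial[[parent]] * contrib
      cs <- .colSums(M, 20L, n_pat)    # scale by column sum
      if (any(cs <= 0 | !is.finite(cs))) {
        bad <- prep$rep_site[which(cs <= 0 | !is.finite(cs))[1]]
        stop(sprintf("non-finite partial likelihood at site %d", bad),
             call. = FALSE)
      }
      scale_log <- scale_log + log(cs)
      partial[[parent]] <- M / rep(cs, each = 20L)
    }
  }
  root <- n_tip + 1L
  site_l <- as.vector(model$freqs %*% partial[[root]])
  if (any(site_l <= 0 | !is.finite(site_l))) {
    bad <- prep$rep_site[which(site_l <= 0 | !is.finite(site_l))[1]]
    stop(sprintf("non-finite site likelihood at site %d", bad),
         call. = FALSE)
  }
  sum(prep$w * (log(site_l) + scale_log))
}

#' Log-likelihood of a tree given a protein supermatrix
#'
#' Felsenstein pruning with per-branch transition matrices from the
#' model's eigendecomposition. Gap and ambiguous characters are treated
#' as missing data (all-ones partials). Alignment columns are compressed
#' to unique site patterns first.
#'
#' @param tree `ape::phylo` with branch lengths; its tips must all appear
#'   in the supermatrix.
#' @param sm A `supermatrix`.
#' @param model A [subst_model()] (default Poisson).
#' @return The log-likelihood (sum over sites).
#' @export
tree_lnL <- function(tree, sm, model = subst_model("poisson")) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  prep <- prep_likelihood(sm, tree$tip.label)
  lnL_core(tree, prep, model)
}

#' Optimise branch lengths by round-robin scalar search
#'
#' Each branch in turn is optimised by bracketed one-dimensional search
#' ([stats::optimize()]) holding the others fixed; sweeps repeat until
#' the total log-likelihood improves by less than `tol`. The likelihood
#' is non-decreasing across sweeps (a proposed branch value is only
#' accepted when it improves the total).
#'
#' @inheritParams tree_lnL
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_sweeps Upper bound on sweeps (default 25).
#' @param max_branch Upper search bound per branch (default 10
#'   substitutions/site).
#' @return The tree with optimised `edge.length` and attributes `lnL` and
#'   `lnL_path` (per-sweep log-likelihoods).
#' @export
optimize_branch_lengths <- function(tree, sm,
                                    model = subst_model("poisson"),
                                    tol = 1e-6, max_sweeps = 25L,
                                    max_branch = 10) {
  prep <- prep_likelihood(sm, tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  cur <- lnL_core(tree, prep, model, reordered = TRUE)
  path <- cur
  for (sweep in seq_len(max_sweeps)) {
    start <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tree$edge.length[e] <- x
        lnL_core(tree, prep, model, reordered = TRUE)
      }
      opt <- stats::optimize(f, c(0, max_branch), maximum = TRUE,
                             tol = 1e-4)
      if (opt$objective > cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    path <- c(path, cur)
    if (cur - start < tol) break
  }
  attr(tree, "lnL") <- cur
  attr(tree, "lnL_path") <- path
  tree
}

# single-tip phylo used for grafting
tip_tree <- function(label, length = 0.1) {
  tr <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
             edge.length = length, Nnode = 1L)
  class(tr) <- "phylo"
  tr
}

# graft `focal` as sister to `group`'s stem edge in `backbone`
graft_sister <- function(backbone, focal, group, init_len = 0.1) {
  out_taxon <- setdiff(backbone$tip.label, group)[1]
  rt <- ape::root(backbone, outgroup = out_taxon, resolve.root = TRUE)
  if (length(group) == 1L) {
    node <- which(rt$tip.label == group)
  } else {
    node <- ape::getMRCA(rt, group)
    clade <- ape::extract.clade(rt, node)$tip.label
    if (!setequal(clade, group)) {
      warning(sprintf("group {%s} not monophyletic in backbone; grafting at its MRCA edge",
                      paste(group, collapse = ",")), call. = FALSE)
    }
  }
  edge_i <- which(rt$edge[, 2] == node)
  pos <- rt$edge.length[edge_i] / 2
  ape::bind.tree(rt, tip_tree(focal, init_len), where = node,
                 position = pos)
}

#' Compare constrained placements of a focal taxon
#'
#' Builds an NJ backbone from all taxa except the focal one, grafts the
#' focal taxon as sister to group A's stem edge (then group B's),
#' optimises branch lengths for each constrained tree, and returns both
#' log-likelihoods. Positive `delta_lnl = lnl_b - lnl_a` favours
#' placement with group B. Groups that are not monophyletic in the
#' backbone are grafted at their MRCA edge with a warning.
#'
#' @param sm A `supermatrix` containing the focal taxon and both groups.
#' @param focal Focal taxon name.
#' @param group_a,group_b Disjoint character vectors of backbone taxa.
#' @param model A [subst_model()] (default Poisson).
#' @param tol Branch-length optimisation tolerance (default 1e-4).
#' @return An object of class `placement_test`: `focal`, `group_a`,
#'   `group_b`, `lnl_a`, `lnl_b`, `delta_lnl`, `preferred`, `tree_a`,
#'   `tree_b`, `model`.
#' @export
constrained_topology_compare <- function(sm, focal, group_a, group_b,
                                         model = subst_model("poisson"),
                                         tol = 1e-4) {
  stopifnot(inherits(sm, "supermatrix"))
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (focal %in% c(group_a, group_b)) {
    stop("focal taxon must not be in either group", call. = FALSE)
  }
  backbone_taxa <- setdiff(sm$taxa, focal)
  stopifnot(all(group_a %in% backbone_taxa), all(group_b %in% backbone_taxa))
  D <- protein_distance(structure(list(aln = sm$aln[backbone_taxa, ,
                                                    drop = FALSE]),
                                  class = "supermatrix"))
  backbone <- nj_tree(D)
  fit <- function(group) {
    tr <- graft_sister(backbone, focal, group)
    optimize_branch_lengths(tr, sm, model, tol = tol)
  }
  tree_a <- fit(group_a)
  tree_b <- fit(group_b)
  lnl_a <- attr(tree_a, "lnL"); lnl_b <- attr(tree_b, "lnL")
  out <- list(focal = focal, group_a = group_a, group_b = group_b,
              lnl_a = lnl_a, lnl_b = lnl_b, delta_lnl = lnl_b - lnl_a,
              preferred = if (lnl_b > lnl_a) "group_b" else "group_a",
              tree_a = tree_a, tree_b = tree_b, model = model$name)
  class(out) <- "placement_test"
  out
}

#' @export
print.placement_test <- function(x, ...) {
  cat(sprintf("<placement_test> %s: lnL(A) = %.2f, lnL(B) = %.2f, delta = %.2f -> %s\n",
              x$focal, x$lnl_a, x$lnl_b, x$delta_lnl, x$preferred))
  invisible(x)
}
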