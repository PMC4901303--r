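pois <- subst_model("poisson")

test_that("supermatrix concatenation keeps exact partition bookkeeping", {
  a1 <- c(A = "ARND", B = "ARNE", C = "ARNE")
  a2 <- c(A = "CQEGH", B = "CQEGH", D = "CQEGY")
  sm <- concatenate_alignments(list(g1 = a1, g2 = a2), missing = "pad")
  expect_identical(ncol(sm$aln), 9L)
  expect_setequal(sm$taxa, c("A", "B", "C", "D"))
  # taxon absent from a gene is gap-filled over that partition
  expect_identical(paste(sm$aln["D", 1:4], collapse = ""), "----")
  expect_identical(paste(sm$aln["C", 5:9], collapse = ""), "-----")
  # round trip
  back <- split_supermatrix(sm)
  expect_identical(back$g1[c("A", "B", "C")], a1)
  expect_identical(back$g2[c("A", "B", "D")], a2)
  # intersect policy keeps only shared taxa
  sm2 <- concatenate_alignments(list(g1 = a1, g2 = a2),
                                missing = "intersect")
  expect_setequal(sm2$taxa, c("A", "B"))
  expect_error(concatenate_alignments(list(g = c(A = "AR", A = "ND"))),
               "duplicate")
  expect_error(concatenate_alignments(list(g = c(A = "AR", B = "NDE"))),
               "unaligned")
})

test_that("Poisson-corrected distances follow the closed form", {
  sm <- concatenate_alignments(list(
    g = c(A = "AAAAAAAAAA", B = "AAAAAAAAAA", C = "RRRRRAAAAA")))
  D <- protein_distance(sm)
  expect_identical(D["A", "B"], 0)
  expect_equal(D["A", "C"], log(2))   # p = 0.5
  # gap columns excluded from the comparison
  sm2 <- concatenate_alignments(list(g = c(A = "AR-D", B = "ARN-")))
  expect_identical(protein_distance(sm2)["A", "B"], 0)
  # saturated pairs hit the documented cap
  sm3 <- concatenate_alignments(list(g = c(A = "AAAA", B = "RRRR")))
  expect_equal(protein_distance(sm3)["A", "B"], -log(1 - 0.999))
  expect_error(protein_distance(concatenate_alignments(
    list(g = c(A = "A-", B = "-R")))), "comparable")
})

test_that("distance estimates recover the simulating branch length", {
  tree2 <- structure(list(
    edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
    tip.label = c("A", "B"), Nnode = 1L,
    edge.length = c(0.15, 0.15)), class = "phylo")
  d_hat <- vapply(1:60, function(i) {
    aln <- simulate_protein_alignment(tree2, 500, pois, seed = 1000 + i)
    protein_distance(concatenate_alignments(list(g = aln)))["A", "B"]
  }, 1.0)
  # Poisson correction is consistent for the 20-state model up to the
  # different-state probability: E[p] = (19/20)(1 - exp(-20/19 * 0.3))
  p_true <- (19 / 20) * (1 - exp(-20 / 19 * 0.3))
  d_true <- -log(1 - p_true)
  se <- stats::sd(d_hat) / sqrt(length(d_hat))
  expect_lt(abs(mean(d_hat) - d_true), 3 * se + 0.01)
})

test_that("NJ reconstructs additive distances exactly", {
  tree <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.3,D:0.15);")
  D <- ape::cophenetic.phylo(tree)
  nj <- nj_tree(D)
  expect_identical(as.numeric(ape::dist.topo(ape::unroot(tree), nj)), 0)
  Dnj <- ape::cophenetic.phylo(nj)[rownames(D), colnames(D)]
  expect_lt(max(abs(Dnj - D)), 1e-12)
  # negative branch clamping
  Dbad <- matrix(c(0, 1, 1, 1,
                   1, 0, 0.1, 0.1,
                   1, 0.1, 0, 0.1,
                   1, 0.1, 0.1, 0), 4, 4,
                 dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  njb <- nj_tree(Dbad)
  expect_true(all(njb$edge.length >= 0))
  # tiny inputs
  expect_warning(nj_tree(matrix(c(0, 1, 1, 0), 2, 2,
                                dimnames = list(c("A", "B"), c("A", "B")))),
                 "trivial")
})

test_that("pruning lnL equals exhaustive state enumeration (4 and 5 leaves)", {
  set.seed(55)
  for (model in list(pois, subst_model("jtt"))) {
    tr4 <- ape::read.tree(text = "((A:0.12,B:0.3):0.08,C:0.25,D:0.1);")
    aln <- simulate_protein_alignment(tr4, 5, model, seed = 77)
    aln["B"] <- paste0(substr(aln[["B"]], 1, 4), "-")  # gap as missing
    sm <- concatenate_alignments(list(g = aln))
    expect_equal(tree_lnL(tr4, sm, model),
                 oracle_tree_lnL(tr4, sm, model), tolerance = 1e-10)
    tr5 <- ape::read.tree(
      text = "(((A:0.1,B:0.2):0.05,C:0.3):0.07,D:0.15,E:0.22);")
    aln5 <- simulate_protein_alignment(tr5, 4, model, seed = 78)
    sm5 <- concatenate_alignments(list(g = aln5))
    expect_equal(tree_lnL(tr5, sm5, model),
                 oracle_tree_lnL(tr5, sm5, model), tolerance = 1e-10)
  }
})

test_that("two-taxon lnL matches the closed form", {
  sm <- concatenate_alignments(list(g = c(A = "ARNDW", B = "ARNEW")))
  tree <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                         tip.label = c("A", "B"), Nnode = 1L,
                         edge.length = c(0.1, 0.2)), class = "phylo")
  P1 <- prob_matrix(pois, 0.1); P2 <- prob_matrix(pois, 0.2)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  x1 <- match(strsplit("ARNDW", "")[[1]], aa)
  x2 <- match(strsplit("ARNEW", "")[[1]], aa)
  want <- sum(vapply(1:5, function(i) {
    log(sum(pois$freqs * P1[, x1[i]] * P2[, x2[i]]))
  }, 1.0))
  expect_equal(tree_lnL(tree, sm, pois), want, tolerance = 1e-12)
})

test_that("zero branch lengths with identical sequences give sum log pi", {
  sm <- concatenate_alignments(list(g = c(A = "ARND", B = "ARND")))
  tree <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                         tip.label = c("A", "B"), Nnode = 1L,
                         edge.length = c(0, 0)), class = "phylo")
  expect_equal(tree_lnL(tree, sm, pois), 4 * log(1 / 20), tolerance = 1e-12)
})

test_that("lnL is invariant under re-rooting (reversible model)", {
  tr <- ape::read.tree(
    text = "(((A:0.1,B:0.2):0.05,C:0.3):0.07,D:0.15,E:0.22);")
  aln <- simulate_protein_alignment(tr, 200, pois, seed = 81)
  sm <- concatenate_alignments(list(g = aln))
  l0 <- tree_lnL(tr, sm, pois)
  for (og in c("A", "C", "E")) {
    lr <- tree_lnL(ape::root(tr, outgroup = og, resolve.root = TRUE),
                   sm, pois)
    expect_equal(lr, l0, tolerance = 1e-8)
  }
  # and under JTT
  lj0 <- tree_lnL(tr, sm, subst_model("jtt"))
  ljr <- tree_lnL(ape::root(tr, outgroup = "D", resolve.root = TRUE),
                  sm, subst_model("jtt"))
  expect_equal(ljr, lj0, tolerance = 1e-8)
})

test_that("probability matrices agree with the series expansion", {
  for (model in list(pois, subst_model("jtt"))) {
    Q <- model$Q
    for (t in c(0.001, 0.005)) {
      term <- diag(20); Pser <- term
      for (k in 1:6) {
        term <- term %*% Q * (t / k)
        Pser <- Pser + term
      }
      expect_lt(max(abs(prob_matrix(model, t) - Pser)), 1e-10)
    }
    expect_lt(max(abs(prob_matrix(model, 0) - diag(20))), 1e-12)
    # stationarity: pi P = pi
    P <- prob_matrix(model, 1.5)
    expect_lt(max(abs(model$freqs %*% P - model$freqs)), 1e-12)
  }
})

test_that("branch-length optimisation is monotone and finds a fixed point", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.1,C:0.3,D:0.15);")
  aln <- simulate_protein_alignment(tr, 400, pois, seed = 90)
  sm <- concatenate_alignments(list(g = aln))
  fit <- optimize_branch_lengths(tr, sm, pois, tol = 1e-5)
  path <- attr(fit, "lnL_path")
  expect_true(all(diff(path) >= -1e-9))
  # re-optimising an optimum changes nothing appreciable
  fit2 <- optimize_branch_lengths(fit, sm, pois, tol = 1e-5)
  expect_lt(abs(attr(fit2, "lnL") - attr(fit, "lnL")), 1e-3)
  expect_lt(max(abs(fit2$edge.length - fit$edge.length)), 0.05)
})

test_that("optimisation recovers simulating branch lengths at long alignments", {
  tr <- ape::read.tree(text = "((A:0.15,B:0.25):0.1,C:0.2,D:0.3);")
  aln <- simulate_protein_alignment(tr, 8000, pois, seed = 91)
  sm <- concatenate_alignments(list(g = aln))
  start <- tr
  start$edge.length <- start$edge.length * 1.8   # perturbed start
  fit <- optimize_branch_lengths(start, sm, pois, tol = 1e-5)
  truth_po <- stats::reorder(tr, "postorder")    # fit comes back postorder
  expect_identical(fit$edge, truth_po$edge)
  expect_lt(max(abs(fit$edge.length - truth_po$edge.length) /
                  pmax(truth_po$edge.length, 0.05)), 0.15)
})

test_that("bootstrap supports are reproducible and sensible", {
  tr <- ape::read.tree(
    text = "(((A:0.1,B:0.1):0.08,(C:0.1,D:0.1):0.08):0.05,E:0.2,F:0.25);")
  aln <- simulate_protein_alignment(tr, 1500, pois, seed = 92)
  sm <- concatenate_alignments(list(g = aln))
  b1 <- bootstrap_support(sm, n_reps = 25, seed = 7)
  b2 <- bootstrap_support(sm, n_reps = 25, seed = 7)
  expect_identical(b1$node.label, b2$node.label)
  sup <- attr(b1, "support")
  expect_true(all(sup >= 0 & sup <= 1))
  # clean, long simulation: internal edges well supported
  expect_gte(mean(sup[-1]), 0.9)
  # single replicate gives 0/1 supports
  b3 <- bootstrap_support(sm, n_reps = 1, seed = 8)
  expect_true(all(attr(b3, "support") %in% c(0, 1)))
})

test_that("constrained placement prefers the generating group and negates on swap", {
  tr <- ape::read.tree(text = paste0(
    "(((A1:0.1,A2:0.1):0.05,A3:0.15):0.1,",
    "((B1:0.1,(B2:0.05,X:0.05):0.05):0.05,B3:0.15):0.1,O:0.3);"))
  aln <- simulate_protein_alignment(tr, 250, pois, seed = 95)
  sm <- concatenate_alignments(list(g = aln))
  A <- c("A1", "A2", "A3"); B <- c("B1", "B2", "B3")
  pt <- constrained_topology_compare(sm, "X", A, B, pois, tol = 1e-2)
  expect_gt(pt$delta_lnl, 0)
  expect_identical(pt$preferred, "group_b")
  pt2 <- constrained_topology_compare(sm, "X", B, A, pois, tol = 1e-2)
  expect_equal(pt2$delta_lnl, -pt$delta_lnl, tolerance = 1e-6)
  # tidy/glance carry the comparison
  expect_identical(nrow(tidy(pt)), 2L)
  expect_identical(glance(pt)$preferred, "group_b")
  # a focal sequence identical to a group-A member prefers group A
  aln2 <- aln
  aln2[["X"]] <- aln2[["A1"]]
  sm2 <- concatenate_alignments(list(g = aln2))
  pt3 <- constrained_topology_compare(sm2, "X", A, B, pois, tol = 1e-2)
  expect_lt(pt3$delta_lnl, 0)
  expect_error(constrained_topology_compare(sm, "X", A, c("B1", "A1")),
               "disjoint")
})
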