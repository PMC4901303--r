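test_that("local alignment scores match the brute-force affine DP oracle", {
  set.seed(33)
  mat <- baculokit:::default_matrix()
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:25) {
    a <- paste(sample(aa, sample(5:30, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(5:30, 1), TRUE), collapse = "")
    got <- align_proteins(a, b)$raw_score
    want <- oracle_local_align(a, b, mat)
    expect_equal(got, want, info = sprintf("pair %d: %s vs %s", i, a, b))
  }
})

test_that("identical sequences align at identity 1; disjoint ones floor at 0", {
  r <- align_proteins(strrep("MKVLW", 20), strrep("MKVLW", 20))
  expect_identical(r$identity, 1)
  expect_identical(r$aligned_length, 100L)
  r0 <- align_proteins("WWWWWWWWWW", "PPPPPPPPPP")
  expect_identical(r0$raw_score, 0)
  expect_identical(r0$aligned_length, 0L)
  expect_error(align_proteins("MK1V", "MKV"), "non-amino-acid")
})

test_that("E-values follow the Karlin-Altschul closed form", {
  e <- estimate_evalue(40, 200, 200, K = 0.041, lambda = 0.267)
  expect_equal(e, 0.041 * 200 * 200 * exp(-0.267 * 40))
  # linear in n, strictly decreasing in score
  expect_equal(estimate_evalue(40, 200, 400) / e, 2)
  s <- seq(10, 100, by = 10)
  expect_true(all(diff(estimate_evalue(s, 200, 200)) < 0))
  # limit: large score drives E to zero
  expect_lt(estimate_evalue(1e4, 200, 200), 1e-300)
  expect_error(estimate_evalue(10, 0, 5), "positive")
  expect_error(estimate_evalue(10, 5, 5, K = -1), "positive")
})

test_that("a proteome is its own reciprocal best hit set", {
  set.seed(34)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  prot <- setNames(
    vapply(1:6, function(i) paste(sample(aa, 120, TRUE), collapse = ""), ""),
    sprintf("p%d", 1:6))
  ot <- assign_orthologs(prot, list(self = prot))
  expect_identical(ot$subject, ot$query)
  expect_true(all(ot$reciprocal))
  expect_true(all(ot$identity == 1))
})

test_that("reciprocal pairs are symmetric between the two directions", {
  set.seed(35)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  mk <- function(n) vapply(seq_len(n), function(i)
    paste(sample(aa, 100, TRUE), collapse = ""), "")
  A <- setNames(mk(5), sprintf("a%d", 1:5))
  # B: diverged copies of A (point substitutions at the protein level)
  B <- setNames(vapply(A, function(p) {
    ch <- strsplit(p, "")[[1]]
    hit <- sample(100, 15)
    ch[hit] <- sample(aa, 15, TRUE)
    paste(ch, collapse = "")
  }, ""), sprintf("b%d", 1:5))
  ab <- assign_orthologs(A, list(g = B))
  ba <- assign_orthologs(B, list(g = A))
  pa <- ab[ab$reciprocal, c("query", "subject")]
  pb <- ba[ba$reciprocal, c("subject", "query")]
  expect_setequal(paste(pa$query, pa$subject),
                  paste(pb$subject, pb$query))
  expect_identical(nrow(pa), 5L)
})

test_that("planted novel ORFs are classified unique at E > 1e-3", {
  set.seed(36)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  shared <- setNames(vapply(1:8, function(i)
    paste(sample(aa, 150, TRUE), collapse = ""), ""), sprintf("s%d", 1:8))
  novel <- setNames(vapply(1:3, function(i)
    paste(sample(aa, 120, TRUE), collapse = ""), ""), sprintf("u%d", 1:3))
  query <- c(shared, novel)
  subjects <- lapply(1:4, function(g) {
    setNames(vapply(shared, function(p) {
      ch <- strsplit(p, "")[[1]]
      hit <- sample(150, 20)
      ch[hit] <- sample(aa, 20, TRUE)
      paste(ch, collapse = "")
    }, ""), sprintf("g%d_%d", g, 1:8))
  })
  names(subjects) <- sprintf("genome%d", 1:4)
  ot <- assign_orthologs(query, subjects)
  uq <- unique_orfs(ot)
  expect_setequal(uq, names(novel))
  # heat-map table: unique rows all NA, shared rows carry identities
  hm <- identity_heatmap_table(ot)
  unique_rows <- hm[hm$query %in% uq, -1]
  expect_true(all(is.na(unlist(unique_rows))))
  shared_rows <- hm[!hm$query %in% uq, -1]
  expect_true(all(!is.na(unlist(shared_rows))))
  # matrix entries equal the underlying identities
  for (g in names(subjects)) {
    sub <- ot[ot$genome == g & !is.na(ot$identity), ]
    expect_identical(hm[[g]][match(sub$query, hm$query)], sub$identity)
  }
})

test_that("synteny blocks decompose shared orthologs exactly once", {
  mk_orfs <- function(n, starts, strands) {
    tibble::tibble(name = sprintf("o%02d", seq_len(n)), start = starts,
                   span = 300L, strand = strands)
  }
  f <- mk_orfs(8, seq(0, 7000, by = 1000), rep("+", 8))
  # identical order -> one collinear block
  s_same <- f; s_same$name <- sprintf("t%02d", 1:8)
  ortho <- tibble::tibble(query = f$name, subject = s_same$name)
  b1 <- synteny_map(f, s_same, ortho)
  expect_identical(nrow(b1), 1L)
  expect_identical(b1$orientation, "collinear")
  expect_identical(b1$n_genes, 8L)
  # whole-genome reversal -> one inverted block
  s_rev <- tibble::tibble(name = sprintf("t%02d", 1:8),
                          start = rev(seq(0, 7000, by = 1000)),
                          span = 300L, strand = rep("-", 8))
  b2 <- synteny_map(f, s_rev, ortho)
  expect_identical(nrow(b2), 1L)
  expect_identical(b2$orientation, "inverted")
  # internal 3-gene inversion -> 3 blocks, coverage complete
  s_inv <- s_same
  s_inv$start[3:5] <- rev(s_inv$start[3:5])
  s_inv$strand[3:5] <- "-"
  b3 <- synteny_map(f, s_inv, ortho)
  expect_identical(sum(b3$n_genes), 8L)
  expect_identical(b3$orientation[2], "inverted")
  expect_identical(b3$n_genes[2], 3L)
  covered <- unlist(b3$queries)
  expect_setequal(covered, f$name)
  expect_identical(anyDuplicated(covered), 0L)
})

test_that("a planted inversion is recovered as one inverted block", {
  sim <- small_sim(seed = 91, L = 25000, n_orfs = 14, n_hrs = 2,
                   promoter = 0)
  to <- sim$truth[sim$truth$kind == "ORF", ]
  to <- to[order(to$start), ]
  s <- to$start[4] - 2L
  e <- to$start[8] + to$span[8] + 2L
  der <- derive_rearranged_genome(
    sim, list(rearrangement("inversion", start = s, span = e - s)),
    divergence_rate = 0.03, seed = 7)
  ot <- assign_orthologs(sim_proteome(sim), list(d = sim_proteome(der)))
  fo <- sim$truth[sim$truth$kind == "ORF", ]; fo$name <- fo$label
  so <- der$truth[der$truth$kind == "ORF", ]; so$name <- so$label
  blocks <- synteny_map(fo, so, ot)
  inv <- blocks[blocks$orientation == "inverted", ]
  expect_identical(nrow(inv), 1L)
  expect_identical(inv$n_genes, 5L)
  expect_setequal(inv$queries[[1]], to$label[4:8])
})

test_that("hr proximity test: degenerate and boundary cases", {
  hrs_all <- tibble::tibble(start = 0L, span = 10000L)
  r <- hr_proximity_test(c(5, 800), hrs_all, 10000, n_perm = 199, seed = 2)
  expect_identical(r$observed, 0)
  expect_identical(r$p_value, 1)
  # all midpoints inside hrs: observed 0, minimal p bounded below
  hrs <- tibble::tibble(start = c(1000L, 6000L), span = c(400L, 400L))
  r2 <- hr_proximity_test(c(1100, 1200, 6100), hrs, 10000,
                          n_perm = 199, seed = 3)
  expect_identical(r2$observed, 0)
  expect_gte(r2$p_value, 1 / 200)
  expect_lte(r2$p_value, 0.2)
  expect_error(hr_proximity_test(numeric(0), hrs, 1e4), "at least one")
  # tidy output
  td <- tidy(r2)
  expect_identical(td$n_perm, 199L)
})

test_that("permutation p-values are valid under the null", {
  # distances of uniformly repositioned points are exchangeable with the
  # observed ones, so p is (sub)uniform: check type-I error at two levels
  set.seed(44)
  hrs <- tibble::tibble(start = c(2000L, 12000L, 22000L),
                        span = c(300L, 500L, 400L))
  L <- 30000
  pvals <- vapply(1:120, function(i) {
    pts <- runif(6, 0, L)
    hr_proximity_test(pts, hrs, L, n_perm = 199)$p_value
  }, 1.0)
  expect_lte(mean(pvals <= 0.05), 0.12)
  expect_lte(mean(pvals <= 0.2), 0.32)
  expect_gte(mean(pvals <= 0.5), 0.32)
})
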