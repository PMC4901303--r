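test_that("palindrome_score handles perfect, impossible and random windows", {
  expect_identical(palindrome_score("GAATTC"), 1)
  expect_identical(palindrome_score("AAAAAA"), 0)
  expect_identical(palindrome_score("ACGT"), 1)
  # symmetric under reverse complement
  set.seed(4)
  for (i in 1:50) {
    w <- paste(sample(c("A", "C", "G", "T"), 38, TRUE), collapse = "")
    expect_equal(palindrome_score(w),
                 palindrome_score(reverse_complement(w)))
  }
  # N never pairs: only the N positions mismatch
  expect_identical(palindrome_score("GANNTC"), 4 / 6)
  # mean score of random 38-mers is ~0.25 under uniform bases
  set.seed(8)
  scores <- replicate(2000, palindrome_score(
    paste(sample(c("A", "C", "G", "T"), 38, TRUE), collapse = "")))
  expect_lt(abs(mean(scores) - 0.25), 0.01)
})

test_that("scan_palindromes equals the exhaustive window oracle", {
  for (seed in c(12, 13)) {
    g <- random_genome(8000, seed = seed)
    for (ms in c(0.55, 0.7)) {
      got <- scan_palindromes(g, 38, ms)
      want <- oracle_scan_palindromes(g, 38, ms)
      expect_identical(got$start, as.integer(want),
                       info = sprintf("seed %d score %.2f", seed, ms))
    }
  }
})

test_that("a single planted perfect palindrome is found at truth coordinates", {
  set.seed(41)
  half <- paste(sample(c("A", "C", "G", "T"), 19, TRUE), collapse = "")
  unit <- paste0(half, reverse_complement(half))
  g <- circular_genome(paste0(strrep("A", 2000), unit, strrep("A", 2000)))
  got <- scan_palindromes(g, 38, 0.9)
  expect_identical(nrow(got), 1L)
  expect_identical(got$start, 2000L)
  expect_identical(got$score, 1)
})

test_that("mutated planted units are still detected at min_score 0.6", {
  set.seed(42)
  half <- paste(sample(c("A", "C", "G", "T"), 19, TRUE), collapse = "")
  unit <- paste0(half, reverse_complement(half))
  hit <- 0L
  for (seed in 1:20) {
    mut <- mutate_sequence(unit, 0.10, seed = seed)
    g <- circular_genome(paste0(strrep("A", 500), mut, strrep("A", 500)))
    got <- scan_palindromes(g, 38, 0.6)
    if (nrow(got) >= 1L && any(abs(got$start - 500L) < 38L)) hit <- hit + 1L
  }
  expect_gte(hit, 19L)
})

test_that("high-threshold scan of random sequence finds nothing", {
  g <- random_genome(10000, seed = 19, gc = 0.5)
  expect_identical(nrow(scan_palindromes(g, 38, 0.95)), 0L)
})

test_that("clustering groups nearby units and drops sparse singletons", {
  units <- tibble::tibble(
    start = c(1000L, 1138L, 1276L, 8000L),
    span = 38L, score = 1, sequence = "x")
  hrs <- cluster_into_hrs(units, 20000L, max_gap = 500L, min_units = 2L)
  expect_identical(nrow(hrs), 1L)
  expect_identical(hrs$n_units, 3L)
  expect_identical(hrs$start, 1000L)
  expect_identical(hrs$span, 1276L + 38L - 1000L)
  # max_gap 0: only abutting units cluster
  ab <- tibble::tibble(start = c(0L, 38L, 200L), span = 38L, score = 1,
                       sequence = "x")
  hrs0 <- cluster_into_hrs(ab, 20000L, max_gap = 0L, min_units = 2L)
  expect_identical(nrow(hrs0), 1L)
  expect_identical(hrs0$n_units, 2L)
})

test_that("clusters spanning the origin are assembled with wrapping hulls", {
  units <- tibble::tibble(start = c(30L, 19950L, 19990L), span = 38L,
                          score = 1, sequence = "x")
  hrs <- cluster_into_hrs(units, 20000L, max_gap = 500L, min_units = 2L)
  expect_identical(nrow(hrs), 1L)
  expect_identical(hrs$start, 19950L)
  expect_identical(hrs$span, (30L + 38L) + 20000L - 19950L)
  expect_identical(hrs$n_units, 3L)
})

test_that("hr consensus is the column-majority with conservation track", {
  units <- c("AACT", "AACT", "AACT")
  cons <- hr_consensus(units)
  expect_identical(as.character(cons), "AACT")
  expect_identical(attr(cons, "conservation"), rep(1, 4))
  # single unit is its own consensus
  expect_identical(as.character(hr_consensus("GATTACA")), "GATTACA")
  # ties break alphabetically
  tie <- hr_consensus(c("AT", "GT"))
  expect_identical(as.character(tie), "AT")
  expect_identical(attr(tie, "conservation"), c(0.5, 1))
})

test_that("consensus of diverged copies converges to the master", {
  set.seed(50)
  half <- paste(sample(c("A", "C", "G", "T"), 19, TRUE), collapse = "")
  master <- paste0(half, reverse_complement(half))
  bad <- 0L
  for (seed in 1:20) {
    copies <- vapply(1:8, function(i) {
      mutate_sequence(master, 0.1, seed = seed * 100 + i)
    }, "")
    cons <- as.character(hr_consensus(copies))
    hd <- sum(strsplit(cons, "")[[1]] != strsplit(master, "")[[1]])
    if (hd > 2) bad <- bad + 1L
  }
  expect_lte(bad, 1L)
})

test_that("hr detection is rotation invariant on diverged (tie-free) loci", {
  sim <- small_sim(seed = 61, L = 15000, n_orfs = 5, n_hrs = 3,
                   divergence = 0.1)
  g <- sim$genome
  h1 <- detect_hrs(g)
  for (k in c(4000, 14000)) {
    h2 <- detect_hrs(rotate_genome(g, k))
    expect_identical(nrow(h2), nrow(h1))
    expect_setequal((h2$start + k) %% g$length, h1$start)
    expect_setequal(h2$consensus, h1$consensus)
  }
})

test_that("each hr interval is at least unit_len times its unit count", {
  sim <- small_sim(seed = 62, L = 15000, n_orfs = 5, n_hrs = 3)
  hrs <- detect_hrs(sim$genome)
  expect_true(all(hrs$span >= 38L * hrs$n_units))
})

test_that("in-silico PCR finds inward-facing products with exact 3' ends", {
  set.seed(70)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  fwd <- "AGAGTTGGAAATTTCGCGCTC"
  rev <- "GTTTTTACTCTGTCCGCGCG"
  ins <- bg(800 - nchar(fwd) - nchar(rev))
  g <- circular_genome(paste0(bg(500), fwd, ins, reverse_complement(rev),
                              bg(700)))
  p <- insilico_pcr(g, fwd, rev)
  expect_identical(nrow(p), 1L)
  expect_identical(p$size, 800L)
  expect_identical(p$start, 500L)
  expect_identical(p$orientation, "+")
  # forward site alone amplifies nothing
  expect_identical(nrow(insilico_pcr(g, fwd, "ACGTACGTACGTACG")), 0L)
  # product crossing the origin is found, with the same size
  gr <- rotate_genome(g, 700L)
  pr <- insilico_pcr(gr, fwd, rev)
  expect_identical(pr$size, 800L)
  expect_identical(pr$start, (500L - 700L) %% g$length)
  # products above max_product are suppressed
  expect_identical(nrow(insilico_pcr(g, fwd, rev, max_product = 500L)), 0L)
  # primers must be at least 10 nt
  expect_error(insilico_pcr(g, "ACGTACGT", rev), ">= 10")
})

test_that("PCR honours the mismatch budget but never a mismatched 3' end", {
  set.seed(71)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  fwd <- "CCCGCTAATGAACCGTGTGA"
  rev <- "AACCGTTTAAATCCTTCGTGT"
  core <- paste0(fwd, bg(400), reverse_complement(rev))
  # one internal mismatch in the forward footprint
  fwd_mut <- paste0(substr(fwd, 1, 4), "T", substr(fwd, 6, nchar(fwd)))
  stopifnot(fwd_mut != fwd)
  g1 <- circular_genome(paste0(bg(300), sub(fwd, fwd_mut, core, fixed = TRUE),
                               bg(300)))
  expect_identical(nrow(insilico_pcr(g1, fwd, rev, max_mismatch = 0L)), 0L)
  expect_identical(nrow(insilico_pcr(g1, fwd, rev, max_mismatch = 1L)), 1L)
  # a 3' terminal mismatch is never tolerated
  last <- substr(fwd, nchar(fwd), nchar(fwd))
  swap <- chartr("ACGT", "TGCA", last)
  fwd_3p <- paste0(substr(fwd, 1, nchar(fwd) - 1), swap)
  g2 <- circular_genome(paste0(bg(300), sub(fwd, fwd_3p, core, fixed = TRUE),
                               bg(300)))
  expect_identical(nrow(insilico_pcr(g2, fwd, rev, max_mismatch = 2L)), 0L)
})

test_that("identical forward and reverse primers are flagged", {
  g <- random_genome(2000, seed = 72)
  expect_warning(insilico_pcr(g, "AGAGTTGGAAATTTCGCGCTC",
                              "AGA GTT GGA AAT TTC GCG CTC"),
                 "identical")
})
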