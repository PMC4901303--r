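test_that("generation is a pure function of (config, seed)", {
  cfg <- sim_config(genome_length = 12000, n_orfs = 6, n_hrs = 2,
                    orf_length_range = c(153, 500),
                    units_per_hr_range = c(2, 4), n_promoter_orfs = 2,
                    seed = 5)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$truth, b$truth)
  # a different seed changes the genome
  cfg2 <- sim_config(genome_length = 12000, n_orfs = 6, n_hrs = 2,
                     orf_length_range = c(153, 500),
                     units_per_hr_range = c(2, 4), n_promoter_orfs = 2,
                     seed = 6)
  expect_false(identical(generate_genome(cfg2)$genome$sequence,
                         a$genome$sequence))
})

test_that("planted ORFs are exactly the ORFs the caller finds", {
  for (seed in c(1, 2)) {
    sim <- small_sim(seed = seed, L = 25000, n_orfs = 12)
    calls <- find_orfs(sim$genome, 50)
    truth <- sim$truth[sim$truth$kind == "ORF", ]
    expect_identical(nrow(calls), nrow(truth))
    expect_setequal(paste(calls$start, calls$span, calls$strand),
                    paste(truth$start, truth$span, truth$strand))
    # truth proteins match re-translation
    expect_identical(
      sort(calls$protein),
      sort(truth$protein))
  }
})

test_that("zero unit divergence plants identical repeat copies", {
  sim <- small_sim(seed = 3, divergence = 0)
  units <- sim$truth[sim$truth$kind == "repeat_unit", ]
  seqs <- vapply(seq_len(nrow(units)), function(i) {
    extract_seq(sim$genome, units$start[i], units$span[i])
  }, "")
  expect_identical(length(unique(seqs)), 1L)
  expect_identical(unique(seqs), sim$hr_master)
  expect_identical(palindrome_score(sim$hr_master), 1)
})

test_that("infeasible packing raises a capacity error", {
  cfg <- sim_config(genome_length = 5000, n_orfs = 40,
                    orf_length_range = c(300, 600), n_hrs = 0,
                    n_promoter_orfs = 0, seed = 1)
  expect_error(generate_genome(cfg), "density")
})

test_that("mutate_sequence hits the binomial substitution bounds", {
  s <- strrep("ACGT", 2500)
  expect_identical(mutate_sequence(s, 0, seed = 1), s)
  m1 <- mutate_sequence(s, 1, seed = 2)
  expect_identical(sum(strsplit(m1, "")[[1]] == strsplit(s, "")[[1]]), 0L)
  m <- mutate_sequence(s, 0.1, seed = 3)
  n_sub <- sum(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.1)
  expect_gte(n_sub, bounds[1]); expect_lte(n_sub, bounds[2])
  # deterministic given seed
  expect_identical(mutate_sequence(s, 0.1, seed = 3), m)
})

test_that("no-op derivation with zero divergence is the identity", {
  sim <- small_sim(seed = 4, L = 15000, n_orfs = 6, n_hrs = 2)
  der <- derive_rearranged_genome(sim, list(), 0, seed = 1)
  expect_identical(der$genome$sequence, sim$genome$sequence)
  expect_identical(der$truth$start, der$truth$src_start)
})

test_that("an inversion strand-flips and order-reverses covered ORFs", {
  sim <- small_sim(seed = 8, L = 25000, n_orfs = 12, n_hrs = 2)
  to <- sim$truth[sim$truth$kind == "ORF", ]
  to <- to[order(to$start), ]
  s <- to$start[3] - 2L
  e <- to$start[7] + to$span[7] + 2L
  der <- derive_rearranged_genome(
    sim, list(rearrangement("inversion", start = s, span = e - s)),
    0, seed = 1)
  dt <- der$truth[der$truth$kind == "ORF", ]
  inv <- dt[dt$label %in% to$label[3:7], ]
  src <- to[3:7, ]
  expect_true(all(inv$strand[match(src$label, inv$label)] !=
                    src$strand))
  # order reversed inside the segment
  ord_new <- inv$label[order(inv$start)]
  expect_identical(ord_new, rev(src$label))
  # sequence of an inverted ORF is conserved on its own strand
  i <- match(src$label[1], der$truth$label)
  expect_identical(
    extract_seq(der$genome, der$truth$start[i], der$truth$span[i],
                der$truth$strand[i]),
    extract_seq(sim$genome, src$start[1], src$span[1], src$strand[1]))
})

test_that("gene loss and gain update the truth table and coordinates", {
  sim <- small_sim(seed = 12, L = 15000, n_orfs = 6, n_hrs = 0)
  to <- sim$truth[sim$truth$kind == "ORF", ]
  victim <- to$label[2]
  # insertion point: middle of the largest inter-feature gap
  tr <- sim$truth[order(sim$truth$start), ]
  gaps <- c(tr$start[-1], sim$genome$length) - (tr$start + tr$span)
  i <- which.max(gaps)
  at <- as.integer(tr$start[i] + tr$span[i] + gaps[i] %/% 2)
  der <- derive_rearranged_genome(
    sim,
    list(rearrangement("gain", aa = 80, at = at, label = "novel1"),
         rearrangement("loss", label = victim)),
    0, seed = 2)
  dt <- der$truth[der$truth$kind == "ORF", ]
  expect_false(victim %in% dt$label)
  expect_true("novel1" %in% dt$label)
  expect_identical(der$genome$length,
                   sim$genome$length - to$span[2] + 3L * 81L + 3L)
  nov <- dt[dt$label == "novel1", ]
  expect_identical(nchar(nov$protein), 80L)
  expect_true(nov$novel)
  # remaining ORFs still translate to their source proteins
  keep <- dt[!dt$label %in% "novel1", ]
  src <- to[match(keep$label, to$label), ]
  expect_identical(keep$protein, src$protein)
})

test_that("operations that bisect planted features are rejected", {
  sim <- small_sim(seed = 13, L = 15000, n_orfs = 6, n_hrs = 1)
  to <- sim$truth[sim$truth$kind == "ORF", ]
  mid <- to$start[1] + 10L
  expect_error(derive_rearranged_genome(
    sim, list(rearrangement("inversion", start = mid, span = 500L)),
    0, seed = 1), "bisects")
})

test_that("divergence leaves motif footprints intact and proteomes translatable", {
  sim <- small_sim(seed = 14, L = 20000, n_orfs = 8, n_hrs = 2,
                   promoter = 3)
  der <- derive_rearranged_genome(sim, list(), 0.05, seed = 9)
  m <- der$truth[der$truth$kind == "motif", ]
  for (i in seq_len(nrow(m))) {
    got <- extract_seq(der$genome, m$start[i], m$span[i], m$strand[i])
    expect_identical(got, m$motif[i])
  }
  # all ORFs translate without internal stops (repair pass)
  dt <- der$truth[der$truth$kind == "ORF", ]
  for (i in seq_len(nrow(dt))) {
    expect_silent(translate_cds(
      extract_seq(der$genome, dt$start[i], dt$span[i], dt$strand[i])))
  }
  # and real divergence happened
  expect_false(identical(der$genome$sequence, sim$genome$sequence))
})

test_that("sidecar files round-trip the genome and truth", {
  sim <- small_sim(seed = 15, L = 12000, n_orfs = 5, n_hrs = 1)
  dir <- withr::local_tempdir()
  paths <- write_sim(sim, dir)
  fa <- read_fasta(paths["fasta"])
  expect_identical(unname(fa), sim$genome$sequence)
  feats <- read_gff3(paths["gff3"], sim$genome$length)
  expect_identical(nrow(feats), nrow(sim$truth))
  cfg <- yaml::read_yaml(paths["yaml"])
  expect_identical(cfg$config$genome_length, 12000L)
})
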