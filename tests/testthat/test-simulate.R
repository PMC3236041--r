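test_that("cog table config is validated", {
  expect_error(cog_sim_config(10, 20), "n_categories")
  expect_error(cog_sim_config(10, 5, "geometric", k = 1.2), "ratio")
  expect_error(cog_sim_config(10, 5, "dirichlet", alpha = 0), "alpha")
  expect_error(cog_sim_config(10, 5, "transposon_burst", burst_mass = 1),
               "burst_mass")
})

test_that("uniform model puts one gene per category when n = S", {
  sim <- simulate_cog_table(cog_sim_config(4, 4, "uniform"))
  expect_true(all(sim$truth$counts == 1))
  expect_equal(nrow(sim$assignments), 4)
})

test_that("category counts always sum to the number of genes", {
  for (model in c("uniform", "brokenstick", "geometric", "dirichlet",
                  "transposon_burst")) {
    sim <- simulate_cog_table(cog_sim_config(500, 40, model, seed = 3))
    expect_equal(sum(sim$truth$counts), 500)
    expect_equal(nrow(sim$assignments), 500)
    expect_false(any(duplicated(sim$assignments$gene_id)))
  }
})

test_that("burst family size falls in its binomial 99% interval", {
  sim <- simulate_cog_table(cog_sim_config(
    10000, 100, "transposon_burst", n_burst = 1, burst_mass = 0.3,
    seed = 1))
  burst_count <- sim$truth$counts[[sim$truth$burst_categories]]
  lo <- qbinom(0.005, 10000, 0.3)
  hi <- qbinom(0.995, 10000, 0.3)
  expect_gte(burst_count, lo)
  expect_lte(burst_count, hi)
})

test_that("generators are reproducible from the seed", {
  cfg <- cog_sim_config(300, 30, "dirichlet", alpha = 0.3, seed = 99)
  expect_identical(simulate_cog_table(cfg), simulate_cog_table(cfg))

  pcfg <- proteome_sim_config(3, 3, list(A_B = 1), list(C = 2), seed = 4)
  p1 <- simulate_proteomes(pcfg)
  p2 <- simulate_proteomes(pcfg)
  expect_identical(lapply(p1$proteomes, as.character),
                   lapply(p2$proteomes, as.character))
  expect_identical(p1$truth, p2$truth)

  gcfg <- genome_pair_sim_config(2000, 2000, list(c(100, 0.9)), seed = 8)
  g1 <- simulate_genome_pair(gcfg)
  g2 <- simulate_genome_pair(gcfg)
  expect_identical(as.character(g1$seq_a), as.character(g2$seq_a))
  expect_identical(as.character(g1$seq_b), as.character(g2$seq_b))
  expect_identical(g1$truth, g2$truth)

  # byte-identical FASTA output
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(p1$proteomes$A, f1)
  write_fasta(p2$proteomes$A, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("mean sorted broken-stick draws converge to the expectation", {
  S <- 50
  N <- 5000
  expected <- broken_stick(S)$proportions
  mean_sorted <- function(R, seed) {
    set.seed(seed)
    acc <- numeric(S)
    for (r in seq_len(R)) {
      cnt <- as.integer(stats::rmultinom(1, N, expected))
      acc <- acc + sort(cnt, decreasing = TRUE) / N
    }
    acc / R
  }
  kdist <- function(R) max(abs(cumsum(mean_sorted(R, 123)) -
                                 cumsum(expected)))
  expect_lt(kdist(200), kdist(10))
})

test_that("proteome families are planted at the configured identity", {
  # identity 1: all members identical
  ps <- simulate_proteomes(proteome_sim_config(
    3, 1, within_family_identity = 1, seed = 2))
  seqs <- vapply(ps$proteomes, function(x) as.character(x[[1]]), "")
  expect_equal(length(unique(seqs)), 1L)

  # identity 0.5, length 100: measured pairwise identity 0.5 +/- 0.1
  ps2 <- simulate_proteomes(proteome_sim_config(
    3, 20, protein_length = 100, within_family_identity = 0.5, seed = 6))
  ids <- numeric(0)
  for (fam in sprintf("core%03d", 1:20)) {
    members <- ps2$truth[!is.na(ps2$truth$family) &
                           ps2$truth$family == fam, ]
    a <- as.character(ps2$proteomes[[members$genome[1]]][[members$gene_id[1]]])
    b <- as.character(ps2$proteomes[[members$genome[2]]][[members$gene_id[2]]])
    ids <- c(ids, global_identity(a, b))
  }
  expect_gt(mean(ids), 0.4)
  expect_lt(mean(ids), 0.6)
})

test_that("unique genes carry no family label in the truth manifest", {
  ps <- simulate_proteomes(proteome_sim_config(
    3, 0, n_unique = list(A = 5), seed = 9))
  expect_equal(nrow(ps$truth), 5)
  expect_true(all(is.na(ps$truth$family)))
  expect_true(all(ps$truth$genome == "A"))
  expect_equal(length(ps$proteomes$A), 5)
  expect_equal(length(ps$proteomes$B), 0)
})

test_that("genome pair plants segments where the truth says", {
  g <- simulate_genome_pair(genome_pair_sim_config(
    1000, 1000, list(c(100, 1.0)), seed = 5))
  expect_equal(nrow(g$truth), 1)
  expect_equal(g$truth$length, 100)
  a <- substr(as.character(g$seq_a), g$truth$a_start + 1, g$truth$a_end)
  b <- substr(as.character(g$seq_b), g$truth$b_start + 1, g$truth$b_end)
  expect_identical(a, b)
})

test_that("planted identity is honoured within sampling error", {
  g <- simulate_genome_pair(genome_pair_sim_config(
    5000, 5000, list(c(200, 0.9)), seed = 14))
  a <- strsplit(substr(as.character(g$seq_a), g$truth$a_start + 1,
                       g$truth$a_end), "")[[1]]
  b <- strsplit(substr(as.character(g$seq_b), g$truth$b_start + 1,
                       g$truth$b_end), "")[[1]]
  expect_equal(mean(a == b), 0.9, tolerance = 0.06)
})

test_that("without planted segments the genomes share no long match", {
  g <- simulate_genome_pair(genome_pair_sim_config(1000, 1000, seed = 23))
  expect_equal(nrow(g$truth), 0)
  expect_lt(lcs_oracle(as.character(g$seq_a), as.character(g$seq_b)), 30)
})

test_that("oversized planted segments are rejected", {
  expect_error(genome_pair_sim_config(100, 500, list(c(150, 0.9))),
               "exceeds")
  expect_error(genome_pair_sim_config(
    200, 1000, list(c(90, 1), c(90, 1), c(90, 1))), "exceeds")
})
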