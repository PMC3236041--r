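make_fasta <- function(seqs, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fna", .local_envir = env)
  write_fasta(Biostrings::DNAStringSet(seqs), path)
  path
}

test_that("genome_summary computes size and GC from FASTA alone", {
  path <- make_fasta(c(ctg1 = "ACGT"))
  gs <- genome_summary(path)
  expect_equal(gs$size_bp, 4)
  expect_equal(gs$gc_pct, 50)
  expect_equal(gs$contigs, 1)
  expect_equal(gs$coding_fraction, 0)
  expect_true(is.na(gs$gene_count))
})

test_that("ambiguous bases are excluded from the GC denominator", {
  path <- make_fasta(c(ctg1 = "GGCCNNNN"))
  gs <- genome_summary(path)
  expect_equal(gs$gc_pct, 100)
  expect_equal(gs$size_bp, 8)
})

test_that("coding bp is the union of CDS intervals", {
  set.seed(121)
  path <- make_fasta(c(chr = random_dna_string(100)))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\ttest\tCDS\t1\t50\t.\t+\t0\tID=cds1",
    "chr\ttest\tCDS\t41\t90\t.\t-\t0\tID=cds2"), gff)
  gs <- genome_summary(path, gff)
  expect_equal(gs$coding_bp, 90)  # overlap 41..50 counted once
  expect_equal(gs$coding_fraction, 0.9)
  expect_equal(gs$gene_count, 2)
})

test_that("annotation on an unknown contig is an error", {
  path <- make_fasta(c(chr = "ACGTACGTAC"))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "elsewhere\ttest\tCDS\t1\t5\t.\t+\t0\tID=cds1"), gff)
  expect_error(genome_summary(path, gff), "unknown contig")
})

test_that("the fallback coordinate TSV dialect is accepted", {
  set.seed(122)
  path <- make_fasta(c(chr = random_dna_string(200)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("start\tend", "1\t50", "101\t150"), tsv)
  gs <- genome_summary(path, tsv)
  expect_equal(gs$coding_bp, 100)
})

test_that("simulated genomes report their configured size", {
  g <- simulate_genome_pair(genome_pair_sim_config(1234, 999, seed = 3))
  path <- make_fasta(c(genome_a = as.character(g$seq_a)))
  expect_equal(genome_summary(path)$size_bp, 1234)
})

test_that("run_pipeline writes schema-valid, seed-deterministic reports", {
  dir_in <- withr::local_tempdir()
  sim <- simulate_cog_table(cog_sim_config(400, 60, "dirichlet",
                                           alpha = 0.3, seed = 5))
  asg <- file.path(dir_in, "assignments.tsv")
  write_assignments(sim$assignments, asg)
  ps <- simulate_proteomes(proteome_sim_config(
    3, 3, n_unique = list(A = 1), within_family_identity = 0.9,
    seed = 5))
  prot_paths <- vapply(names(ps$proteomes), function(g) {
    p <- file.path(dir_in, paste0(g, ".faa"))
    write_fasta(ps$proteomes[[g]], p)
    p
  }, "")
  gp <- simulate_genome_pair(genome_pair_sim_config(
    3000, 3000, list(c(300, 0.95)), seed = 5))
  gen_paths <- c(file.path(dir_in, "a.fna"), file.path(dir_in, "b.fna"))
  write_fasta(Biostrings::DNAStringSet(c(ga = as.character(gp$seq_a))),
              gen_paths[1])
  write_fasta(Biostrings::DNAStringSet(c(gb = as.character(gp$seq_b))),
              gen_paths[2])

  out1 <- withr::local_tempdir()
  cfg <- run_config(out1, assignments = asg, proteomes = prot_paths,
                    genomes = gen_paths, summary_fasta = gen_paths[1],
                    seed = 7)
  res <- run_pipeline(cfg, quiet = TRUE)
  expect_setequal(names(res),
                  c("redundancy", "shared", "distance", "summary"))
  for (f in c("redundancy.json", "shared.json", "distance.json",
              "summary.json", "report.json", "hsps.tsv",
              "overlay_SIM.tsv")) {
    expect_true(file.exists(file.path(out1, f)), info = f)
  }
  rep1 <- jsonlite::read_json(file.path(out1, "report.json"))
  expect_equal(rep1$config$seed, 7)

  # rerun with the same seed: byte-identical JSON
  out2 <- withr::local_tempdir()
  cfg2 <- run_config(out2, assignments = asg, proteomes = prot_paths,
                     genomes = gen_paths, summary_fasta = gen_paths[1],
                     seed = 7)
  run_pipeline(cfg2, quiet = TRUE)
  j1 <- gsub(basename(out1), "OUT", readLines(file.path(out1, "report.json")),
             fixed = TRUE)
  j2 <- gsub(basename(out2), "OUT", readLines(file.path(out2, "report.json")),
             fixed = TRUE)
  expect_identical(j1, j2)
})

test_that("redundancy stage reproduces closed-form H_max and H_exp", {
  # 2,022 items over 1,300 categories laid out as evenly as possible
  dir_in <- withr::local_tempdir()
  counts <- rep(c(2L, 1L), c(722, 578))  # 722*2 + 578 = 2022
  asg <- data.frame(
    genome_id = "EVEN",
    gene_id = sprintf("g%04d", seq_len(2022)),
    category_id = rep(sprintf("C%04d", seq_len(1300)), counts))
  path <- file.path(dir_in, "even.tsv")
  write_assignments(asg, path)
  out <- withr::local_tempdir()
  res <- run_pipeline(run_config(out, assignments = path, seed = 1),
                      quiet = TRUE)
  rr <- res$redundancy$EVEN
  expect_equal(rr$H_max, log(2022))
  expect_equal(rr$H_exp, h_exp(1300))
  expect_equal(rr$N, 2022)
  expect_equal(rr$S, 1300)
})

test_that("missing inputs are rejected at configuration time", {
  expect_error(run_config(tempdir(), assignments = "does-not-exist.tsv"),
               "not found")
  expect_error(run_config(tempdir(), genomes = "only-one.fna"),
               "not found")
})

test_that("the command-line wrapper runs and honours exit codes", {
  script <- system.file("scripts", "cogent-cli.R", package = "cogent")
  expect_true(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  dir_in <- withr::local_tempdir()
  sim <- simulate_cog_table(cog_sim_config(200, 40, "dirichlet", seed = 2))
  asg <- file.path(dir_in, "assignments.tsv")
  write_assignments(sim$assignments, asg)
  out <- file.path(dir_in, "cli-out")

  status <- system2(rscript, c(script, "redundancy",
                               "--assignments", asg, "--out", out,
                               "--seed", "2"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  expect_true(file.exists(file.path(out, "redundancy.json")))

  usage <- system2(rscript, c(script, "redundancy"),
                   stdout = FALSE, stderr = FALSE)
  expect_equal(usage, 2)

  data_err <- system2(rscript, c(script, "redundancy",
                                 "--assignments", asg,
                                 "--genome-id", "ABSENT",
                                 "--out", out),
                      stdout = FALSE, stderr = FALSE)
  expect_equal(data_err, 1)
})
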