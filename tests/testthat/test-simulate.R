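test_that("build_genome assembles telomere tracts around a random core", {
  g <- build_genome(120000, 6000, 0.5, seed = 601)
  expect_identical(g$genome_length, 132000L)
  expect_identical(length(g$sequence), 132000L)
  s <- as.character(g$sequence)
  expect_identical(substr(s, 1, 12), "CCCTAACCCTAA")
  expect_identical(substr(s, 132000 - 11, 132000), "TTAGGGTTAGGG")
  # core GC within 3 binomial standard errors of the target
  core <- substr(s, 6001, 126000)
  gc <- gc_fraction(core)
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 120000))
  # deterministic given seed
  g2 <- build_genome(120000, 6000, 0.5, seed = 601)
  expect_identical(as.character(g2$sequence), s)
  # tract lengths not divisible by 6 end in a partial motif
  g3 <- build_genome(10000, 8, 0.5, seed = 1)
  expect_identical(substr(as.character(g3$sequence), 1, 8), "CCCTAACC")
  expect_error(build_genome(10000, 2000, 0.5), "10x")
  expect_error(build_genome(120000, 6000, 0), "core_gc")
})

test_that("read_sim_config validates fragment and error settings", {
  expect_error(read_sim_config(coverage = 0), "positive")
  expect_error(read_sim_config(1, fragment_mean = 150), "2x read_length")
  expect_error(read_sim_config(1, error_rate = 0.2), "error_rate")
})

test_that("error-free reads are exact genome substrings in correct orientation", {
  g <- build_genome(80000, 2000, 0.5, seed = 602)
  sim <- simulate_reads(g, read_sim_config(coverage = 0.5, error_rate = 0,
                                           seed = 603))
  expect_identical(sim$n_pairs, round(0.5 * 84000 / 200))
  s <- as.character(g$sequence)
  rc <- revcomp(s)
  idx <- seq(1, sim$n_pairs, length.out = 20)
  for (i in as.integer(idx)) {
    expect_true(grepl(as.character(sim$read1[[i]]), s, fixed = TRUE))
    expect_true(grepl(as.character(sim$read2[[i]]), rc, fixed = TRUE))
  }
})

test_that("substitution errors occur at the configured rate", {
  g <- build_genome(60000, 1200, 0.5, seed = 604)
  # same seed: fragment coordinates are drawn before error injection, so the
  # error-free run is the base-level truth for the noisy run
  clean <- simulate_reads(g, read_sim_config(2, error_rate = 0, seed = 605))
  noisy <- simulate_reads(g, read_sim_config(2, error_rate = 0.01, seed = 605))
  a <- charToRaw(paste(c(as.character(clean$read1),
                         as.character(clean$read2)), collapse = ""))
  b <- charToRaw(paste(c(as.character(noisy$read1),
                         as.character(noisy$read2)), collapse = ""))
  expect_identical(length(a), length(b))
  n_bases <- length(a)
  expect_gt(n_bases, 1e5)
  rate <- mean(a != b)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / n_bases))
})

test_that("identical seeds give byte-identical FASTQ output", {
  g <- build_genome(60000, 1200, 0.5, seed = 606)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_reads_fastq(simulate_reads(g, read_sim_config(0.5, seed = 607)), f1)
  write_reads_fastq(simulate_reads(g, read_sim_config(0.5, seed = 607)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed gives different reads
  f3 <- tempfile(fileext = ".fastq")
  write_reads_fastq(simulate_reads(g, read_sim_config(0.5, seed = 608)), f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("unaligned SAM output round-trips through the BAM ingestion path", {
  g <- build_genome(60000, 1200, 0.5, seed = 609)
  sim <- simulate_reads(g, read_sim_config(0.2, seed = 610,
                                           read_group = "covX_rep1"))
  sam <- tempfile(fileext = ".sam")
  write_reads_sam(sim, sam)
  reads <- read_sequence_reads(sam)
  expect_length(reads, 2 * sim$n_pairs)
  expect_true(all(reads$read_group == "covX_rep1"))
  expect_true(all(reads$flags$unmapped))
  expect_true(all(reads$flags$paired))
  expect_true(all(passes_filters(reads)))
  # sequences survive the round trip (mates interleaved)
  expect_identical(as.character(reads$bases[1]), as.character(sim$read1[[1]]))
  expect_identical(as.character(reads$bases[2]), as.character(sim$read2[[1]]))
})

test_that("a single adequate-coverage run recovers the known telomere length", {
  g <- build_genome(400000, 30000, 0.5, seed = 611)
  tab <- coverage_titration(g, coverages = 10, replicates = 1,
                            error_rate = 0, seed = 612)
  expect_identical(nrow(tab), 1L)
  expect_lt(abs(tab$estimate_kb - 30) / 30, 0.05)
})

test_that("estimate SD shrinks roughly as the square root of coverage", {
  g <- build_genome(50000, 5000, 0.5, seed = 613)
  prof <- gc_profile(g$sequence, window = 100)
  lo <- coverage_titration(g, coverages = 1, replicates = 20,
                           error_rate = 0, seed = 614, profile = prof)
  hi <- coverage_titration(g, coverages = 4, replicates = 20,
                           error_rate = 0, seed = 615, profile = prof)
  ratio <- sd(lo$estimate_kb) / sd(hi$estimate_kb)
  expect_gt(ratio, 1.2)   # expected 2 with generous sampling slack
  expect_lt(ratio, 3.3)
})

test_that("runs without reads are recorded as missing, never fabricated", {
  g <- build_genome(50000, 5000, 0.5, seed = 616)
  tab <- coverage_titration(g, coverages = 0.0001, replicates = 1, seed = 617)
  expect_identical(nrow(tab), 1L)
  expect_true(is.na(tab$estimate_kb))
  empty <- coverage_titration(g, coverages = numeric(0), seed = 618)
  expect_identical(nrow(empty), 0L)
})

test_that("titration summary splits coverage groups and is deterministic", {
  g <- build_genome(100000, 3000, 0.5, seed = 619)
  tab1 <- coverage_titration(g, coverages = c(0.5, 1, 4, 6),
                             replicates = 3, seed = 620)
  tab2 <- coverage_titration(g, coverages = c(0.5, 1, 4, 6),
                             replicates = 3, seed = 620)
  expect_identical(tab1, tab2)
  s <- titration_summary(tab1)
  expect_identical(s$n_runs, 12L)
  expect_identical(s$n_high, 6L)
  expect_equal(s$mean_high, mean(tab1$estimate_kb[tab1$coverage > 2.5]))
  expect_equal(s$sd_all, sd(tab1$estimate_kb))
  # degenerate grid: no high-coverage block, no F-test
  s_lo <- titration_summary(coverage_titration(g, coverages = 0.2,
                                               replicates = 3, seed = 621))
  expect_identical(s_lo$n_high, 0L)
  expect_null(s_lo$f_test)
})
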