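test_that("tally_reads fills the repeat and GC histograms", {
  t <- tally_reads(new_tally("rg"), strrep("TTAGGG", 16))  # 96 bp, GC 0.50
  expect_identical(t$total_reads, 1L)
  expect_identical(t$repeat_hist[["16"]], 1L)
  expect_identical(t$gc_hist[["0.50"]], 1L)
  t <- tally_reads(t, strrep("A", 100))
  expect_identical(t$repeat_hist[["0"]], 1L)
  expect_identical(t$gc_hist[["0.00"]], 1L)
  # additivity: same read twice doubles its cells
  t2 <- tally_reads(tally_reads(new_tally(), strrep("TTAGGG", 16)),
                    strrep("TTAGGG", 16))
  expect_identical(t2$repeat_hist[["16"]], 2L)
  expect_identical(t2$total_reads, 2L)
  # histogram conservation
  expect_identical(sum(t$repeat_hist), t$total_reads)
  expect_identical(sum(t$gc_hist), t$total_reads)
})

test_that("zero-length reads are skipped with a warning, not an error", {
  expect_warning(t <- tally_reads(new_tally(), c("", "ACGTAC")),
                 "zero-length")
  expect_identical(t$total_reads, 1L)
})

test_that("merge_tallies is an associative, conservative elementwise sum", {
  withr::with_seed(201, {
    mk <- function() tally_reads(new_tally("g"), random_dna(30, 100))
    a <- mk(); b <- mk(); c <- mk()
    e <- new_tally("g")
    expect_identical(merge_tallies(a, e), a)
    expect_identical(merge_tallies(a, b)$total_reads,
                     a$total_reads + b$total_reads)
    expect_identical(merge_tallies(merge_tallies(a, b), c),
                     merge_tallies(a, merge_tallies(b, c)))
    expect_error(merge_tallies(a, new_tally("g", cap = 10L)), "cap")
  })
})

test_that("chunked tallying then merging equals one-pass tallying", {
  withr::with_seed(202, {
    reads <- c(random_dna(60, 100),
               paste0(random_dna(10, 20), strrep("TTAGGG", 12)))
    whole <- tally_reads(new_tally("g"), reads)
    chunks <- split(reads, rep(1:3, length.out = length(reads)))
    merged <- Reduce(merge_tallies,
                     lapply(chunks, function(ch)
                       tally_reads(new_tally("g"), ch)))
    expect_identical(merged, whole)
  })
})

test_that("tail sums are non-increasing in k and start at the total", {
  withr::with_seed(203, {
    t <- tally_reads(new_tally(), c(random_dna(50, 100),
                                    strrep("TTAGGG", 16),
                                    strrep("CCCTAA", 10)))
    tails <- vapply(0:t$cap, function(k) telomeric_read_count(t, k),
                    integer(1))
    expect_identical(tails[1], t$total_reads)
    expect_true(all(diff(tails) <= 0L))
  })
})

test_that("repeat_spectrum conserves reads and is strand-symmetric", {
  reads <- rep(strrep("TTAGGG", 16), 10)
  sp <- repeat_spectrum(reads, motifs = "TTAGGG")
  expect_identical(unname(sp["TTAGGG", "16"]), 10L)
  expect_identical(sum(sp), 10L)
  withr::with_seed(204, {
    mixed <- c(random_dna(40, 100), rep(strrep("CCCTAA", 12), 5))
    sp2 <- repeat_spectrum(mixed, motifs = c("TTAGGG", "AGGTGT"))
    expect_true(all(rowSums(sp2) == length(mixed)))
    # spectrum against a motif equals spectrum against its reverse complement
    expect_identical(
      unname(repeat_spectrum(mixed, motifs = "TTAGGG")),
      unname(repeat_spectrum(mixed, motifs = "CCCTAA")))
  })
})

test_that("control hexamers rarely repeat in random sequence", {
  withr::with_seed(205, {
    reads <- random_dna(10000, 100)
    sp <- repeat_spectrum(reads, motifs = control_hexamers(), cap = 25L)
    max_count <- apply(sp, 1, function(v) max(which(v > 0L)) - 1L)
    expect_true(all(max_count <= 4L))
  })
})

test_that("SAM ingestion yields every record with read groups and flags", {
  sam <- tempfile(fileext = ".sam")
  write_sam_fixture(sam, list(
    sam_record("r1", strrep("TTAGGG", 16), flag = 4L, rg = "L1"),
    sam_record("r2", strrep("ACGT", 25), flag = 0L, rg = "L2"),
    sam_record("r3", strrep("ACGT", 25), flag = 0L, rg = NA)
  ), rg_ids = c("L1", "L2"))
  reads <- read_sequence_reads(sam)
  expect_length(reads, 3)
  expect_identical(reads$name, c("r1", "r2", "r3"))
  expect_identical(reads$read_group, c("L1", "L2", "unknown"))
  expect_identical(reads$flags$unmapped, c(TRUE, FALSE, FALSE))
})

test_that("header-only SAM gives an empty stream", {
  sam <- tempfile(fileext = ".sam")
  write_sam_fixture(sam, list())
  expect_length(read_sequence_reads(sam), 0)
  expect_error(read_sequence_reads(tempfile(fileext = ".sam")), "not found")
})

test_that("filters drop secondary/supplementary/dup/qc-fail but keep unmapped", {
  sam <- tempfile(fileext = ".sam")
  write_sam_fixture(sam, list(
    sam_record("u", "ACGTACGTAC", flag = 4L),            # unmapped
    sam_record("m", "ACGTACGTAC", flag = 0L),            # plain mapped
    sam_record("s", "ACGTACGTAC", flag = 256L),          # secondary
    sam_record("p", "ACGTACGTAC", flag = 2048L),         # supplementary
    sam_record("d", "ACGTACGTAC", flag = 1024L),         # duplicate
    sam_record("q", "ACGTACGTAC", flag = 512L)           # qc fail
  ))
  reads <- read_sequence_reads(sam)
  expect_identical(passes_filters(reads),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(passes_filters(reads, keep_dups = TRUE),
                   c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("tally_file groups by read group and applies filters", {
  sam <- tempfile(fileext = ".sam")
  write_sam_fixture(sam, list(
    sam_record("a", strrep("TTAGGG", 16), flag = 4L, rg = "L1"),
    sam_record("b", strrep("A", 96), flag = 4L, rg = "L1"),
    sam_record("c", strrep("A", 96), flag = 1024L, rg = "L1"),  # duplicate
    sam_record("d", strrep("C", 96), flag = 4L, rg = "L2")
  ), rg_ids = c("L1", "L2"))
  tl <- tally_file(sam)
  expect_named(tl, c("L1", "L2"))
  expect_identical(tl$L1$total_reads, 2L)
  expect_identical(tl$L2$total_reads, 1L)
})

test_that("tally TSV round-trips bit-exactly", {
  withr::with_seed(206, {
    t1 <- tally_reads(new_tally("L1"), random_dna(40, 100))
    t2 <- tally_reads(new_tally("L2"),
                      c(random_dna(10, 100), strrep("TTAGGG", 16)))
    f <- tempfile(fileext = ".tsv")
    write_tally_tsv(list(t1, t2), f)
    back <- read_tally_tsv(f)
    expect_identical(back$L1, t1)
    expect_identical(back$L2, t2)
  })
})

test_that("FASTQ ingestion uses the caller-supplied read-group label", {
  g <- build_genome(6e4, 600, 0.5, seed = 9)
  sim <- simulate_reads(g, read_sim_config(coverage = 1, seed = 9))
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(sim, fq)
  reads <- read_sequence_reads(fq, read_group = "laneA")
  expect_length(reads, 2 * sim$n_pairs)
  expect_true(all(reads$read_group == "laneA"))
  expect_identical(as.character(reads$bases[1]), as.character(sim$read1[[1]]))
})
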