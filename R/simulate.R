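# Synthetic validation: telomere-bearing genomes, a paired-end read simulator
# with uniform substitution errors, and the coverage titration that checks the
# estimator recovers a known telomere length.

with_seed_opt <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(as.integer(seed), fn())
}

telomere_tract <- function(motif, len) {
  substr(strrep(motif, ceiling(len / 6)), 1L, len)
}

#' Build a synthetic telomere-bearing genome
#'
#' A single chromosome: a random i.i.d. core flanked by perfect telomere
#' tracts, CCCTAA repeats on the left (p-arm, reference strand) and TTAGGG
#' repeats on the right (q-arm). Tract lengths not divisible by 6 end in a
#' partial motif. The core must dominate the genome so telomeric reads
#' contaminate the GC-band normalizer negligibly.
#'
#' @param core_length core size in bp, at least 10x `telomere_length`.
#' @param telomere_length telomere tract length per end, in bp.
#' @param core_gc target core GC fraction in (0, 1); G/C and A/T are drawn
#'   evenly within their pair.
#' @param seed optional integer seed; the genome is deterministic given it.
#' @return an object of class `simulated_genome`: `sequence` (a `DNAString`),
#'   `core_length`, `telomere_length`, `core_gc`, `seed`, `genome_length`,
#'   `n_ends` (2) — the last three doubling as the truth manifest for
#'   recovery tests.
#' @export
build_genome <- function(core_length = 5e6, telomere_length = 30000,
                         core_gc = 0.5, seed = NULL) {
  core_length <- as.integer(core_length)
  telomere_length <- as.integer(telomere_length)
  if (core_length < 10L * telomere_length)
    stop("core_length must be at least 10x telomere_length")
  if (telomere_length < 6L) stop("telomere_length must be at least 6 bp")
  if (!(core_gc > 0 && core_gc < 1)) stop("core_gc must be in (0, 1)")
  core <- with_seed_opt(seed, function() {
    paste(sample(c("A", "C", "G", "T"), core_length, replace = TRUE,
                 prob = c((1 - core_gc) / 2, core_gc / 2,
                          core_gc / 2, (1 - core_gc) / 2)),
          collapse = "")
  })
  seqstr <- paste0(telomere_tract(TELOMERE_MOTIF_RC, telomere_length),
                   core,
                   telomere_tract(TELOMERE_MOTIF, telomere_length))
  structure(
    list(sequence = Biostrings::DNAString(seqstr),
         core_length = core_length,
         telomere_length = telomere_length,
         core_gc = core_gc,
         seed = seed,
         genome_length = core_length + 2L * telomere_length,
         n_ends = 2L),
    class = "simulated_genome"
  )
}

#' @export
print.simulated_genome <- function(x, ...) {
  cat(sprintf(
    "simulated_genome: %d bp (%d bp core at GC %.2f + 2 x %d bp telomere)\n",
    x$genome_length, x$core_length, x$core_gc, x$telomere_length))
  invisible(x)
}

#' Read-simulation configuration
#'
#' @param coverage fold coverage (mean sequenced bases per genome position).
#' @param read_length read length in bp (default 100).
#' @param fragment_mean,fragment_sd fragment (insert) length distribution in
#'   bp; mean must be at least twice the read length. Defaults 350/50 match a
#'   typical paired-end 100 bp library.
#' @param error_rate per-base substitution probability in `[0, 0.1)`
#'   (default 0.01).
#' @param seed optional integer seed.
#' @param read_group label stamped on simulated reads (default encodes the
#'   coverage).
#' @return an object of class `read_sim_config`.
#' @export
read_sim_config <- function(coverage, read_length = 100L,
                            fragment_mean = 350, fragment_sd = 50,
                            error_rate = 0.01, seed = NULL,
                            read_group = sprintf("cov%g", coverage)) {
  if (coverage <= 0) stop("coverage must be positive")
  read_length <- as.integer(read_length)
  if (fragment_mean < 2 * read_length)
    stop("fragment_mean must be at least 2x read_length")
  if (!(error_rate >= 0 && error_rate < 0.1))
    stop("error_rate must be in [0, 0.1)")
  structure(
    list(coverage = coverage, read_length = read_length,
         fragment_mean = fragment_mean, fragment_sd = fragment_sd,
         error_rate = error_rate, seed = seed, read_group = read_group),
    class = "read_sim_config"
  )
}

# substitute a uniformly random different base at i.i.d. error positions,
# operating on all reads concatenated into one long sequence
inject_errors <- function(reads, error_rate) {
  long <- unlist(reads)
  L <- length(long)
  nerr <- stats::rbinom(1L, L, error_rate)
  if (nerr == 0L) return(reads)
  pos <- sort(sample.int(L, nerr))
  bases <- c("A", "C", "G", "T")
  orig <- match(
    as.character(Biostrings::extractAt(long, IRanges::IRanges(pos, width = 1L))),
    bases)
  repl <- bases[(orig - 1L + sample.int(3L, nerr, replace = TRUE)) %% 4L + 1L]
  long <- Biostrings::replaceLetterAt(long, pos, repl)
  rl <- Biostrings::width(reads)[1]
  Biostrings::extractAt(long, IRanges::IRanges(seq(1L, L, by = rl), width = rl))
}

#' Simulate paired-end reads from a genome
#'
#' Draws `round(coverage * genome_length / (2 * read_length))` fragments with
#' uniformly placed starts and normal fragment lengths truncated to
#' `[2 * read_length, genome_length]`; read 1 is the first `read_length` bases
#' of the fragment and read 2 the reverse complement of the last. Substitution
#' errors are then applied i.i.d. per base. Deterministic given the config
#' seed.
#'
#' @param genome a [build_genome()] object, `DNAString` or character scalar.
#' @param config a [read_sim_config()].
#' @return an object of class `simulated_reads`: `read1`, `read2`
#'   (`DNAStringSet`s of equal length), `n_pairs`, `read_group`, `config`.
#' @export
simulate_reads <- function(genome, config) {
  stopifnot(inherits(config, "read_sim_config"))
  seqref <- if (inherits(genome, "simulated_genome")) genome$sequence
            else if (methods::is(genome, "DNAString")) genome
            else Biostrings::DNAString(toupper(genome))
  G <- length(seqref)
  rl <- config$read_length
  if (G < 2L * rl) stop("genome shorter than one fragment")
  n_pairs <- round(config$coverage * G / (2 * rl))
  if (n_pairs < 1L) n_pairs <- 0L
  sim <- with_seed_opt(config$seed, function() {
    if (n_pairs == 0L) {
      empty <- Biostrings::DNAStringSet()
      return(list(read1 = empty, read2 = empty))
    }
    fl <- pmin(pmax(round(stats::rnorm(n_pairs, config$fragment_mean,
                                       config$fragment_sd)), 2L * rl), G)
    st <- 1L + as.integer(floor(stats::runif(n_pairs) * (G - fl + 1)))
    r1 <- Biostrings::extractAt(seqref, IRanges::IRanges(st, width = rl))
    r2 <- Biostrings::reverseComplement(
      Biostrings::extractAt(seqref, IRanges::IRanges(st + fl - rl, width = rl)))
    if (config$error_rate > 0) {
      both <- inject_errors(c(r1, r2), config$error_rate)
      r1 <- both[seq_len(n_pairs)]
      r2 <- both[n_pairs + seq_len(n_pairs)]
    }
    list(read1 = r1, read2 = r2)
  })
  structure(
    list(read1 = sim$read1, read2 = sim$read2, n_pairs = n_pairs,
         read_group = config$read_group, config = config),
    class = "simulated_reads"
  )
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("simulated_reads '%s': %d pairs of %d bp\n",
              x$read_group, x$n_pairs, x$config$read_length))
  invisible(x)
}

sim_read_names <- function(sim) {
  sprintf("%s:%07d", sim$read_group, seq_len(sim$n_pairs))
}

#' Write simulated reads as FASTQ
#'
#' Mate suffixes `/1` and `/2`; constant quality `I`. One path writes an
#' interleaved file, two paths write a file per mate. Byte-identical output
#' for identical simulation seeds.
#'
#' @param sim a [simulate_reads()] object.
#' @param path one or two output paths (`.gz` accepted).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_reads"), length(path) %in% 1:2)
  nm <- sim_read_names(sim)
  qual <- Biostrings::BStringSet(rep(strrep("I", sim$config$read_length),
                                     sim$n_pairs))
  r1 <- sim$read1
  r2 <- sim$read2
  names(r1) <- paste0(nm, "/1")
  names(r2) <- paste0(nm, "/2")
  if (length(path) == 2L) {
    Biostrings::writeXStringSet(r1, path[1], format = "fastq", qualities = qual)
    Biostrings::writeXStringSet(r2, path[2], format = "fastq", qualities = qual)
  } else {
    ord <- as.vector(rbind(seq_len(sim$n_pairs),
                           sim$n_pairs + seq_len(sim$n_pairs)))
    all <- c(r1, r2)[ord]
    Biostrings::writeXStringSet(all, path, format = "fastq",
                                qualities = c(qual, qual)[ord])
  }
  invisible(path)
}

#' Write simulated reads as unaligned SAM
#'
#' Paired, unmapped records (flags 77/141) with an `@RG` header and `RG` tags,
#' so the BAM/SAM ingestion path can be exercised end to end on simulated
#' data. The simulation seed and coverage are stamped in an `@CO` line.
#'
#' @param sim a [simulate_reads()] object.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_reads"))
  nm <- sim_read_names(sim)
  qual <- strrep("I", sim$config$read_length)
  rec <- function(name, flag, seq) {
    paste(name, flag, "*", 0L, 0L, "*", "*", 0L, 0L, seq, qual,
          paste0("RG:Z:", sim$read_group), sep = "\t")
  }
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@RG\tID:%s\tSM:simulated", sim$read_group),
    sprintf("@CO\tsimulated reads: coverage=%g error_rate=%g seed=%s",
            sim$config$coverage, sim$config$error_rate,
            ifelse(is.null(sim$config$seed), "NA", sim$config$seed)),
    as.vector(rbind(rec(nm, 77L, as.character(sim$read1)),
                    rec(nm, 141L, as.character(sim$read2))))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Coverage titration on a synthetic genome
#'
#' Runs the full simulate-tally-estimate pipeline once per (coverage,
#' replicate) combination, each with an independently derived seed, using
#' `n_ends = 2` and `L_gc` profiled from the same genome. Runs whose GC band
#' receives no reads are recorded as `NA`, never fabricated.
#'
#' @param genome a [build_genome()] object.
#' @param coverages numeric vector of fold coverages.
#' @param replicates simulated runs per coverage (default 5).
#' @param error_rate,read_length,fragment_mean,fragment_sd see
#'   [read_sim_config()].
#' @param k,band_lo,band_hi estimator settings (defaults 7 and 0.48-0.52).
#' @param seed optional integer master seed from which per-run seeds are
#'   drawn.
#' @param profile optional precomputed [gc_profile()] of the genome (at
#'   `window = read_length`); computed when missing.
#' @return data.frame with one row per run: `coverage`, `replicate`, `seed`,
#'   `total_reads`, `gc_band_reads`, `tel_reads`, `estimate_kb`; the
#'   `estimator_params` used are attached as attribute `"params"`.
#' @export
coverage_titration <- function(genome, coverages = seq(0.2, 10, by = 0.2),
                               replicates = 5L, error_rate = 0.01,
                               read_length = 100L, fragment_mean = 350,
                               fragment_sd = 50, k = 7L, band_lo = 0.48,
                               band_hi = 0.52, seed = NULL, profile = NULL) {
  stopifnot(inherits(genome, "simulated_genome"))
  if (is.null(profile)) profile <- gc_profile(genome$sequence,
                                              window = read_length)
  params <- estimator_params(k = k, band_lo = band_lo, band_hi = band_hi,
                             n_ends = genome$n_ends, profile = profile)
  grid <- expand.grid(replicate = seq_len(replicates), coverage = coverages)
  n_runs <- nrow(grid)
  if (n_runs == 0L) {
    out <- data.frame(coverage = numeric(0), replicate = integer(0),
                      seed = integer(0), total_reads = integer(0),
                      gc_band_reads = integer(0), tel_reads = integer(0),
                      estimate_kb = numeric(0))
    attr(out, "params") <- params
    return(out)
  }
  run_seeds <- with_seed_opt(seed, function() {
    sample.int(.Machine$integer.max, n_runs)
  })
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- read_sim_config(
      coverage = grid$coverage[i], read_length = read_length,
      fragment_mean = fragment_mean, fragment_sd = fragment_sd,
      error_rate = error_rate, seed = run_seeds[i],
      read_group = sprintf("cov%g_rep%d", grid$coverage[i], grid$replicate[i]))
    sim <- simulate_reads(genome, cfg)
    tly <- tally_reads(new_tally(cfg$read_group), c(sim$read1, sim$read2))
    kb <- tryCatch(estimate_length(tly, params)$length_kb,
                   error = function(e) NA_real_)
    rows[[i]] <- data.frame(
      coverage = grid$coverage[i], replicate = grid$replicate[i],
      seed = run_seeds[i], total_reads = tly$total_reads,
      gc_band_reads = gc_band_read_count(tly, band_lo, band_hi),
      tel_reads = telomeric_read_count(tly, k),
      estimate_kb = kb)
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  out
}

#' Summarize a coverage titration
#'
#' Mean and sample SD of the estimates over all runs and over the
#' adequate-coverage subset (coverage above the cutoff), plus the F-test for
#' variance inflation below the cutoff.
#'
#' @param titration data.frame from [coverage_titration()].
#' @param cutoff coverage threshold separating low from adequate coverage
#'   (default 2.5).
#' @return an object of class `titration_summary`: `n_runs`, `n_missing`,
#'   `mean_all`, `sd_all`, `mean_high`, `sd_high`, `n_high`, `f_test`
#'   (low-coverage variance over high-coverage variance, or `NULL` when
#'   either side has fewer than 2 runs), `cutoff`.
#' @export
titration_summary <- function(titration, cutoff = 2.5) {
  ok <- !is.na(titration$estimate_kb)
  est <- titration$estimate_kb[ok]
  cov <- titration$coverage[ok]
  high <- cov > cutoff
  low <- cov < cutoff
  f_test <- if (sum(low) >= 2L && sum(high) >= 2L) {
    variance_f_test(est[low], est[high])
  } else NULL
  structure(
    list(n_runs = nrow(titration), n_missing = sum(!ok),
         mean_all = mean(est), sd_all = stats::sd(est),
         mean_high = if (any(high)) mean(est[high]) else NA_real_,
         sd_high = if (sum(high) >= 2L) stats::sd(est[high]) else NA_real_,
         n_high = sum(high), f_test = f_test, cutoff = cutoff),
    class = "titration_summary"
  )
}

#' @export
print.titration_summary <- function(x, ...) {
  cat(sprintf("coverage titration: %d runs (%d missing)\n",
              x$n_runs, x$n_missing))
  cat(sprintf("  all runs:        mean %.2f kb, SD %.2f kb\n",
              x$mean_all, x$sd_all))
  if (x$n_high >= 2L) {
    cat(sprintf("  coverage > %.1fX: mean %.2f kb, SD %.2f kb (%d runs)\n",
                x$cutoff, x$mean_high, x$sd_high, x$n_high))
  } else {
    cat(sprintf("  coverage > %.1fX: no runs\n", x$cutoff))
  }
  if (!is.null(x$f_test)) {
    cat(sprintf("  low vs high coverage variance: F = %.3g, p = %.3g\n",
                x$f_test$F, x$f_test$p))
  }
  invisible(x)
}

#' Self-contained simulation validation pipeline
#'
#' Builds a telomere-bearing genome, runs the coverage titration and
#' summarizes recovery: the estimator should return the known telomere length
#' (slightly under, since junction-straddling reads with fewer than k repeats
#' are lost) with variance inflating at low coverage.
#'
#' @inheritParams build_genome
#' @inheritParams coverage_titration
#' @param seed master seed; genome and titration seeds are derived from it.
#' @return list of class `pipeline_validation`: `genome` (its truth fields are
#'   the recovery reference), `table` (the titration) and `summary`.
#' @export
run_pipeline_validate <- function(core_length = 5e6, telomere_length = 30000,
                                  core_gc = 0.5,
                                  coverages = seq(0.2, 10, by = 0.2),
                                  replicates = 5L, error_rate = 0.01,
                                  read_length = 100L, fragment_mean = 350,
                                  fragment_sd = 50, k = 7L, band_lo = 0.48,
                                  band_hi = 0.52, seed = NULL) {
  seeds <- with_seed_opt(seed, function() sample.int(.Machine$integer.max, 2))
  genome <- build_genome(core_length, telomere_length, core_gc,
                         seed = seeds[1])
  tab <- coverage_titration(genome, coverages = coverages,
                            replicates = replicates, error_rate = error_rate,
                            read_length = read_length,
                            fragment_mean = fragment_mean,
                            fragment_sd = fragment_sd, k = k,
                            band_lo = band_lo, band_hi = band_hi,
                            seed = seeds[2])
  structure(
    list(genome = genome, table = tab,
         summary = titration_summary(tab)),
    class = "pipeline_validation"
  )
}

#' @export
print.pipeline_validation <- function(x, ...) {
  print(x$genome)
  print(x$summary)
  invisible(x)
}
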