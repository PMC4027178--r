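# Shared fixture builders: everything is generated in code at test time.

random_dna <- function(n, len, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  gen <- function() {
    vapply(seq_len(n), function(i) {
      paste(sample(alphabet, len, replace = TRUE), collapse = "")
    }, character(1))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# independent brute-force oracle: greedy non-overlapping left-to-right scan
oracle_count <- function(seq, motif) {
  L <- nchar(seq)
  m <- nchar(motif)
  if (L < m) return(0L)
  cnt <- 0L
  i <- 1L
  while (i <= L - m + 1L) {
    if (substr(seq, i, i + m - 1L) == motif) {
      cnt <- cnt + 1L
      i <- i + m
    } else {
      i <- i + 1L
    }
  }
  cnt
}

# a SAM file written line by line; records are (name, flag, seq, rg or NA);
# records whose flag lacks the unmapped bit are placed on a dummy reference
write_sam_fixture <- function(path, records, rg_ids = "L1") {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              "@SQ\tSN:ref\tLN:100000",
              sprintf("@RG\tID:%s\tSM:fixture", rg_ids))
  body <- vapply(records, function(r) {
    mapped <- bitwAnd(r$flag, 4L) == 0L
    line <- paste(r$name, r$flag,
                  if (mapped) "ref" else "*",
                  if (mapped) 100L else 0L,
                  if (mapped) 60L else 0L,
                  if (mapped) sprintf("%dM", nchar(r$seq)) else "*",
                  "*", 0L, 0L, r$seq,
                  strrep("I", nchar(r$seq)), sep = "\t")
    if (!is.null(r$rg) && !is.na(r$rg)) {
      line <- paste(line, paste0("RG:Z:", r$rg), sep = "\t")
    }
    line
  }, character(1))
  writeLines(c(header, body), path)
  path
}

sam_record <- function(name, seq, flag = 4L, rg = "L1") {
  list(name = name, flag = flag, seq = seq, rg = rg)
}

# tally built directly from given histogram entries (counts keyed by repeat r)
tally_from_hist <- function(h, gc_bins = NULL, read_group = "t", cap = 25L) {
  t <- new_tally(read_group, cap = cap)
  for (r in names(h)) t$repeat_hist[[r]] <- as.integer(h[[r]])
  if (is.null(gc_bins)) {
    t$gc_hist[["0.48"]] <- sum(unlist(h))
  } else {
    for (b in names(gc_bins)) t$gc_hist[[b]] <- as.integer(gc_bins[[b]])
  }
  t$total_reads <- as.integer(sum(unlist(h)))
  t
}
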