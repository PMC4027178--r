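# Per-read-group accumulators. A tally stores the full repeat-count histogram
# h[r] and a GC histogram in fixed 0.02-wide bins, so that the telomeric read
# count t_k is recoverable for every threshold k, and the 48-52% GC band (or
# any other band on the grid) can be queried without rescanning reads.

GC_BIN_WIDTH <- 0.02
N_GC_BINS <- 50L

# bin index 0..49 for a GC fraction; the epsilon guards against 0.48*50
# landing just below an integer in floating point
gc_bin_index <- function(frac) {
  pmin(as.integer(floor(frac / GC_BIN_WIDTH + 1e-9)), N_GC_BINS - 1L)
}

gc_bin_labels <- function() sprintf("%.2f", (seq_len(N_GC_BINS) - 1L) * GC_BIN_WIDTH)

#' Create an empty read-group tally
#'
#' @param read_group label of the read group the tally accumulates.
#' @param cap highest repeat count tracked individually; reads with more
#'   repeats are bucketed at the cap. No 150 bp read can carry more than 25
#'   hexamer repeats, hence the default.
#' @return an object of class `read_group_tally`.
#' @export
new_tally <- function(read_group = "unknown", cap = 25L) {
  cap <- as.integer(cap)
  stopifnot(cap >= 1L)
  structure(
    list(
      read_group = read_group,
      total_reads = 0L,
      repeat_hist = stats::setNames(integer(cap + 1L), 0:cap),
      gc_hist = stats::setNames(integer(N_GC_BINS), gc_bin_labels()),
      cap = cap,
      gc_bin_width = GC_BIN_WIDTH
    ),
    class = "read_group_tally"
  )
}

#' @export
print.read_group_tally <- function(x, ...) {
  cat(sprintf("read_group_tally '%s': %d reads, %d with >=7 repeats\n",
              x$read_group, x$total_reads,
              sum(x$repeat_hist[as.integer(names(x$repeat_hist)) >= 7L])))
  invisible(x)
}

#' Accumulate reads into a tally
#'
#' Updates the repeat-count histogram (strand-symmetric telomere repeat count,
#' capped) and the GC histogram. Zero-length reads are skipped with a warning.
#'
#' @param tally a [new_tally()] object.
#' @param reads sequences: character vector, `DNAStringSet` or a
#'   [sequence_reads] object (its bases are used; apply [passes_filters()]
#'   first).
#' @return the updated tally.
#' @export
tally_reads <- function(tally, reads) {
  stopifnot(inherits(tally, "read_group_tally"))
  if (inherits(reads, "sequence_reads")) reads <- reads$bases
  x <- as_dna(reads)
  w <- Biostrings::width(x)
  if (any(w == 0L)) {
    warning(sum(w == 0L), " zero-length read(s) skipped")
    x <- x[w > 0L]
    w <- w[w > 0L]
  }
  if (length(x) == 0L) return(tally)
  rc <- pmin(telomere_repeat_count(x), tally$cap)
  gcf <- as.vector(Biostrings::letterFrequency(x, letters = "CG")) / w
  bin <- gc_bin_index(gcf)
  tally$total_reads <- tally$total_reads + length(x)
  tally$repeat_hist <- tally$repeat_hist +
    tabulate(rc + 1L, nbins = tally$cap + 1L)
  tally$gc_hist <- tally$gc_hist + tabulate(bin + 1L, nbins = N_GC_BINS)
  tally
}

#' Merge two tallies
#'
#' Elementwise sum of histograms and totals; associative and commutative, so
#' per-chunk or per-file tallies can be combined in any order.
#'
#' @param a,b tallies with identical `cap` and GC bin width.
#' @return merged tally; the read-group label is kept when equal, otherwise
#'   set to `"pooled"`.
#' @export
merge_tallies <- function(a, b) {
  stopifnot(inherits(a, "read_group_tally"), inherits(b, "read_group_tally"))
  if (a$cap != b$cap || a$gc_bin_width != b$gc_bin_width)
    stop("cannot merge tallies with different cap or GC bin width")
  out <- a
  out$read_group <- if (identical(a$read_group, b$read_group))
    a$read_group else "pooled"
  out$total_reads <- a$total_reads + b$total_reads
  out$repeat_hist <- a$repeat_hist + b$repeat_hist
  out$gc_hist <- a$gc_hist + b$gc_hist
  out
}

#' Tally a whole file per read group
#'
#' Streams a BAM/SAM/FASTQ file, applies the record filters and accumulates
#' one tally per read group found.
#'
#' @inheritParams read_sequence_reads
#' @inheritParams passes_filters
#' @param cap see [new_tally()].
#' @return named list of `read_group_tally`, keyed by read group.
#' @export
tally_file <- function(path, format = "auto", read_group = "unknown",
                       keep_dups = FALSE, cap = 25L) {
  reads <- read_sequence_reads(path, format = format, read_group = read_group)
  keep <- passes_filters(reads, keep_dups = keep_dups)
  reads <- reads[keep]
  groups <- split(seq_along(reads$read_group), reads$read_group)
  lapply(groups, function(i) {
    tally_reads(new_tally(reads$read_group[i[1]], cap = cap), reads$bases[i])
  })
}

#' Repeat spectrum of a read set against a motif panel
#'
#' For each motif, the frequency of reads by per-read occurrence count
#' (strand-symmetric: the maximum of the motif count and its
#' reverse-complement count). Against the 54 control hexamers the spectrum
#' decays monotonically, while the telomere motif shows a high-repeat excess.
#'
#' @param reads sequences (character, `DNAStringSet` or [sequence_reads]).
#' @param motifs character vector of hexamers (default: telomere motif plus
#'   all controls).
#' @param cap highest count tracked; larger counts bucketed at the cap.
#' @return integer matrix, rows = motifs, columns = repeat counts `0..cap`;
#'   every row sums to the number of reads.
#' @export
repeat_spectrum <- function(reads,
                            motifs = c(TELOMERE_MOTIF, control_hexamers()),
                            cap = 25L) {
  stopifnot(length(motifs) >= 1L)
  if (inherits(reads, "sequence_reads")) reads <- reads$bases
  x <- as_dna(reads)
  cap <- as.integer(cap)
  out <- matrix(0L, nrow = length(motifs), ncol = cap + 1L,
                dimnames = list(motifs, 0:cap))
  for (i in seq_along(motifs)) {
    m <- validate_hexamer(motifs[i])
    cnt <- pmax(count_occurrences(x, m), count_occurrences(x, revcomp(m)))
    out[i, ] <- tabulate(pmin(cnt, cap) + 1L, nbins = cap + 1L)
  }
  out
}

#' Write tallies to TSV
#'
#' One row per tally with bit-exact integer counts: `read_group`, `total`,
#' one `gc_bin_<lo>` column per GC bin and one `tel_<r>` column per repeat
#' count.
#'
#' @param tallies a single tally or list of tallies (equal cap).
#' @param path output file.
#' @export
write_tally_tsv <- function(tallies, path) {
  if (inherits(tallies, "read_group_tally")) tallies <- list(tallies)
  cap <- tallies[[1]]$cap
  rows <- lapply(tallies, function(t) {
    stopifnot(t$cap == cap)
    c(list(read_group = t$read_group, total = t$total_reads),
      as.list(stats::setNames(t$gc_hist, paste0("gc_bin_", names(t$gc_hist)))),
      as.list(stats::setNames(t$repeat_hist,
                              paste0("tel_", names(t$repeat_hist)))))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read tallies back from TSV
#'
#' @param path file written by [write_tally_tsv()].
#' @return named list of `read_group_tally`.
#' @export
read_tally_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(read_group = "character"))
  gc_cols <- grep("^gc_bin_", names(df), value = TRUE)
  tel_cols <- grep("^tel_", names(df), value = TRUE)
  cap <- length(tel_cols) - 1L
  out <- lapply(seq_len(nrow(df)), function(i) {
    t <- new_tally(df$read_group[i], cap = cap)
    t$total_reads <- as.integer(df$total[i])
    t$gc_hist[] <- as.integer(df[i, gc_cols])
    t$repeat_hist[] <- as.integer(df[i, tel_cols])
    t
  })
  stats::setNames(out, df$read_group)
}
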