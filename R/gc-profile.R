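# Reference GC profile: cumulative genome length per GC band, the genome-side
# normalizer L_gc. Windows are non-overlapping and match the read length so
# that the genome-side GC distribution is measured on the same length scale as
# the read-side GC histogram.

#' GC profile of a reference
#'
#' Tiles each reference sequence with non-overlapping windows (default 100 bp,
#' matching the read length), drops windows containing any ambiguous base and
#' trailing partial windows, and accumulates the retained length per 0.02-wide
#' GC bin.
#'
#' @param reference a FASTA path (gzip accepted), character vector,
#'   `DNAString` or `DNAStringSet`.
#' @param window window size in bp, at least 6.
#' @return an object of class `gc_profile` with fields `window`,
#'   `band_lengths` (bp per bin), `total_effective_length` and
#'   `n_excluded_windows`.
#' @export
gc_profile <- function(reference, window = 100L) {
  window <- as.integer(window)
  if (window < 6L) stop("window must be at least 6 bp")
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  ref <- as_dna(reference)
  if (length(ref) == 0L || sum(Biostrings::width(ref)) == 0L)
    stop("reference is empty")
  band <- stats::setNames(numeric(N_GC_BINS), gc_bin_labels())
  excluded <- 0L
  for (i in seq_along(ref)) {
    nwin <- Biostrings::width(ref)[i] %/% window
    if (nwin == 0L) next
    v <- Biostrings::Views(ref[[i]],
                           start = (seq_len(nwin) - 1L) * window + 1L,
                           width = window)
    freq <- Biostrings::letterFrequency(v, letters = c("CG", "AT"))
    keep <- freq[, "C|G"] + freq[, "A|T"] == window
    excluded <- excluded + sum(!keep)
    if (!any(keep)) next
    bins <- gc_bin_index(freq[keep, "C|G"] / window)
    band <- band + tabulate(bins + 1L, nbins = N_GC_BINS) * as.numeric(window)
  }
  structure(
    list(window = window, band_lengths = band,
         total_effective_length = sum(band),
         n_excluded_windows = excluded),
    class = "gc_profile"
  )
}

#' @export
print.gc_profile <- function(x, ...) {
  cat(sprintf(
    "gc_profile: window %d bp, effective length %.0f bp (%d window(s) excluded)\n",
    x$window, x$total_effective_length, x$n_excluded_windows))
  cat(sprintf("  length at GC 48-52%%: %.0f bp\n",
              length_at_band(x, 0.48, 0.52)))
  invisible(x)
}

check_on_grid <- function(x, what) {
  if (abs(x * 50 - round(x * 50)) > 1e-6)
    stop(what, " = ", x, " is not on the 0.02 GC-bin grid")
  as.integer(round(x * 50))
}

#' Cumulative reference length within a GC band
#'
#' Sums the profile over bins whose interval lies within `[lo, hi)` — the
#' half-open band convention used identically for reads, so numerator and
#' normalizer see the same band definition. `length_at_band(p, 0, 1)` returns
#' the total effective length.
#'
#' @param profile a [gc_profile()].
#' @param lo,hi band bounds on the 0.02 grid, `0 <= lo < hi <= 1`.
#' @return length in bp (L_gc).
#' @export
length_at_band <- function(profile, lo = 0.48, hi = 0.52) {
  stopifnot(inherits(profile, "gc_profile"))
  if (!(lo >= 0 && lo < hi && hi <= 1)) stop("need 0 <= lo < hi <= 1")
  i <- check_on_grid(lo, "lo")
  j <- check_on_grid(hi, "hi")
  sum(profile$band_lengths[(i + 1L):j])
}

#' Write a GC profile to TSV
#'
#' Header line carries the window size; rows are `bin_lo`, `bin_hi`,
#' `cumulative_bp` with bit-exact integer bp.
#'
#' @param profile a [gc_profile()].
#' @param path output file.
#' @export
write_gc_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gc_profile window=%d excluded_windows=%d",
                     profile$window, profile$n_excluded_windows), con)
  df <- data.frame(
    bin_lo = gc_bin_labels(),
    bin_hi = sprintf("%.2f", seq_len(N_GC_BINS) * GC_BIN_WIDTH),
    cumulative_bp = sprintf("%.0f", profile$band_lengths)
  )
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a GC profile from TSV
#'
#' @param path file written by [write_gc_profile()].
#' @return a `gc_profile` object.
#' @export
read_gc_profile <- function(path) {
  hdr <- readLines(path, n = 1L)
  window <- as.integer(sub(".*window=(\\d+).*", "\\1", hdr))
  excl <- as.integer(sub(".*excluded_windows=(\\d+).*", "\\1", hdr))
  df <- utils::read.delim(path, skip = 1L)
  band <- stats::setNames(numeric(N_GC_BINS), gc_bin_labels())
  band[sprintf("%.2f", df$bin_lo)] <- df$cumulative_bp
  structure(
    list(window = window, band_lengths = band,
         total_effective_length = sum(band), n_excluded_windows = excl),
    class = "gc_profile"
  )
}
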