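# Read ingestion: BAM/SAM (read-group aware, unmapped records included) and
# FASTQ, normalized to a light container consumed by the tally layer.

SEQREAD_FLAGS <- c("paired", "unmapped", "secondary", "supplementary",
                   "duplicate", "qc_fail")

#' Construct a set of sequence reads
#'
#' The unit scanned for telomere motifs: read names, bases, a read-group label
#' per read, and the subset of SAM flag bits that matters for filtering.
#'
#' @param bases `DNAStringSet` (or character vector) of read sequences.
#' @param name character vector of read names (recycled default).
#' @param read_group character vector of read-group labels; `"unknown"` when
#'   absent.
#' @param flags data.frame with logical columns `paired`, `unmapped`,
#'   `secondary`, `supplementary`, `duplicate`, `qc_fail`; defaults to all
#'   `FALSE`.
#' @return an object of class `sequence_reads`.
#' @export
sequence_reads <- function(bases, name = NULL, read_group = "unknown",
                           flags = NULL) {
  bases <- as_dna(bases)
  n <- length(bases)
  if (is.null(name)) name <- sprintf("read%06d", seq_len(n))
  if (is.null(flags)) {
    flags <- as.data.frame(
      matrix(FALSE, n, length(SEQREAD_FLAGS),
             dimnames = list(NULL, SEQREAD_FLAGS))
    )
  }
  stopifnot(
    length(name) == n, nrow(flags) == n,
    all(SEQREAD_FLAGS %in% names(flags))
  )
  read_group <- rep_len(as.character(read_group), n)
  read_group[is.na(read_group) | read_group == ""] <- "unknown"
  structure(
    list(name = as.character(name), bases = bases,
         read_group = read_group, flags = flags),
    class = "sequence_reads"
  )
}

#' @export
length.sequence_reads <- function(x) length(x$bases)

#' @export
print.sequence_reads <- function(x, ...) {
  cat(sprintf("sequence_reads: %d reads, %d read group(s)\n",
              length(x), length(unique(x$read_group))))
  invisible(x)
}

#' Subset sequence reads
#' @param x a `sequence_reads` object.
#' @param i index vector.
#' @param ... unused.
#' @export
`[.sequence_reads` <- function(x, i, ...) {
  sequence_reads(x$bases[i], x$name[i], x$read_group[i],
                 x$flags[i, , drop = FALSE])
}

decode_sam_flags <- function(flag) {
  data.frame(
    paired        = bitwAnd(flag, 0x1)   != 0L,
    unmapped      = bitwAnd(flag, 0x4)   != 0L,
    secondary     = bitwAnd(flag, 0x100) != 0L,
    supplementary = bitwAnd(flag, 0x800) != 0L,
    duplicate     = bitwAnd(flag, 0x400) != 0L,
    qc_fail       = bitwAnd(flag, 0x200) != 0L
  )
}

guess_read_format <- function(path) {
  p <- tolower(sub("\\.gz$", "", path))
  if (grepl("\\.bam$", p)) return("bam")
  if (grepl("\\.sam$", p)) return("sam")
  if (grepl("\\.(fastq|fq)$", p)) return("fastq")
  stop("cannot guess format of '", path, "'; pass format= explicitly")
}

#' Read sequencing reads from BAM, SAM or FASTQ
#'
#' Yields every record, mapped or not — telomeric reads are typically unmapped
#' or misplaced, so unmapped records must be processed. BAM/SAM read groups
#' come from the RG tag (`"unknown"` when absent); FASTQ has no read-group
#' concept, so one caller-supplied label applies to the whole file. Note that
#' for reverse-strand alignments BAM stores the reverse complement of the
#' original read; all downstream motif counting is strand-symmetric, so this
#' does not affect results.
#'
#' @param path input file; gzipped FASTQ is accepted.
#' @param format `"auto"` (by extension), `"bam"`, `"sam"` or `"fastq"`.
#' @param read_group label applied to FASTQ reads (default `"unknown"`).
#' @return a [sequence_reads] object.
#' @export
read_sequence_reads <- function(path, format = c("auto", "bam", "sam", "fastq"),
                                read_group = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") format <- guess_read_format(path)
  if (format == "fastq") {
    bases <- Biostrings::readDNAStringSet(path, format = "fastq")
    nm <- sub("[ /].*$", "", names(bases))
    names(bases) <- NULL
    return(sequence_reads(bases, name = nm, read_group = read_group))
  }
  if (format == "sam") {
    path <- Rsamtools::asBam(path, destination = tempfile(), indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag", "seq"),
                                   tag = "RG")
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  rg <- rec$tag$RG
  if (is.null(rg)) rg <- rep("unknown", length(rec$qname))
  sequence_reads(rec$seq, name = rec$qname, read_group = rg,
                 flags = decode_sam_flags(rec$flag))
}

#' Which reads pass the tallying filters
#'
#' Secondary, supplementary, QC-fail and (by default) duplicate records are
#' dropped so that each sequenced molecule is counted once; unmapped reads
#' always pass.
#'
#' @param reads a [sequence_reads] object.
#' @param keep_dups keep duplicate-flagged reads (default `FALSE`).
#' @return logical vector, `TRUE` for reads to tally.
#' @export
passes_filters <- function(reads, keep_dups = FALSE) {
  f <- reads$flags
  drop <- f$secondary | f$supplementary | f$qc_fail
  if (!keep_dups) drop <- drop | f$duplicate
  !drop
}
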