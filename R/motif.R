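# Sequence-level primitives: motif occurrence counting, GC fraction and the
# control-hexamer set used to calibrate the telomeric-read threshold.

TELOMERE_MOTIF <- "TTAGGG"
TELOMERE_MOTIF_RC <- "CCCTAA"

#' Coerce sequences to a DNAStringSet
#'
#' Accepts a character vector (lowercase is uppercased on ingest), a
#' `DNAString` or a `DNAStringSet`. IUPAC ambiguity codes are tolerated; they
#' never match an exact A/C/G/T motif and count toward sequence length.
#'
#' @param x character vector, `DNAString` or `DNAStringSet`.
#' @return a `DNAStringSet`.
#' @keywords internal
as_dna <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (methods::is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x)) return(Biostrings::DNAStringSet(toupper(x)))
  stop("sequences must be a character vector, DNAString or DNAStringSet")
}

validate_hexamer <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif))
    stop("motif must be a single string")
  motif <- toupper(motif)
  if (nchar(motif) != 6L)
    stop("motif must be exactly 6 bases, got ", nchar(motif))
  if (grepl("[^ACGT]", motif))
    stop("motif alphabet is restricted to A, C, G, T: ", motif)
  motif
}

# TRUE when some proper prefix of the motif equals its suffix, i.e. matches
# can overlap; TTAGGG and CCCTAA have no such border.
has_self_overlap <- function(motif) {
  n <- nchar(motif)
  any(vapply(seq_len(n - 1L), function(i) {
    substr(motif, 1L, i) == substr(motif, n - i + 1L, n)
  }, logical(1)))
}

#' Count non-overlapping motif occurrences in sequences
#'
#' Counts exact, case-insensitive occurrences of a hexamer motif, scanning
#' left to right without re-using characters. For motifs that cannot overlap
#' themselves (TTAGGG, CCCTAA) this equals the count of all match positions.
#' Ambiguity codes (N etc.) never match.
#'
#' @param seq sequences: character vector, `DNAString` or `DNAStringSet`.
#'   Empty sequences are allowed and yield 0.
#' @param motif a single 6-base string over A/C/G/T.
#' @return integer vector of occurrence counts, one per sequence.
#' @examples
#' count_occurrences("TTAGGGTTAGGGTTAGGG", "TTAGGG")
#' @export
count_occurrences <- function(seq, motif = TELOMERE_MOTIF) {
  motif <- validate_hexamer(motif)
  x <- as_dna(seq)
  n <- Biostrings::vcountPattern(motif, x, fixed = TRUE)
  if (has_self_overlap(motif) && any(n > 1L)) {
    # greedy non-overlapping selection among all match positions
    idx <- which(n > 1L)
    m <- Biostrings::vmatchPattern(motif, x[idx], fixed = TRUE)
    starts <- IRanges::start(m)
    n[idx] <- vapply(starts, function(s) {
      cnt <- 0L
      nxt <- 1L
      for (p in s) {
        if (p >= nxt) {
          cnt <- cnt + 1L
          nxt <- p + 6L
        }
      }
      cnt
    }, integer(1))
  }
  n
}

#' Strand-symmetric telomere repeat count
#'
#' Number of telomere repeat units in a read, taken as the maximum of the
#' TTAGGG count and the CCCTAA count so that the result does not depend on
#' which strand of the telomere was sequenced:
#' `telomere_repeat_count(x) == telomere_repeat_count(revcomp(x))`.
#'
#' @inheritParams count_occurrences
#' @return integer vector of repeat counts.
#' @export
telomere_repeat_count <- function(seq) {
  x <- as_dna(seq)
  pmax(
    Biostrings::vcountPattern(TELOMERE_MOTIF, x, fixed = TRUE),
    Biostrings::vcountPattern(TELOMERE_MOTIF_RC, x, fixed = TRUE)
  )
}

#' GC fraction of sequences
#'
#' (G + C) / length. Ambiguous bases (N) count toward the denominator but not
#' the numerator; telomere repeat sequence has GC exactly 0.5.
#'
#' @inheritParams count_occurrences
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  x <- as_dna(seq)
  w <- Biostrings::width(x)
  if (any(w == 0L))
    stop("gc_fraction is undefined for empty sequences")
  as.vector(Biostrings::letterFrequency(x, letters = "CG")) / w
}

#' Reverse complement
#'
#' @param seq character vector, `DNAString` or `DNAStringSet`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  unname(as.character(Biostrings::reverseComplement(as_dna(seq))))
}

#' Control hexamers: non-cyclic permutations of TTAGGG
#'
#' Every distinct arrangement of the letters {T,T,A,G,G,G} that is not a
#' cyclic rotation of TTAGGG. There are 6!/(2!3!) = 60 distinct arrangements
#' and 6 rotations, leaving 54 controls. Read spectra against these motifs
#' decay monotonically in repeat count, whereas the true telomere motif shows
#' an excess of high-repeat reads — the basis for the telomeric-read
#' threshold.
#'
#' @return sorted character vector of 54 hexamers.
#' @export
control_hexamers <- function() {
  letters6 <- c("T", "T", "A", "G", "G", "G")
  perms <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    out <- NULL
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out <- rbind(out, cbind(v[i], rest))
    }
    out
  }
  all6 <- unique(apply(perms(letters6), 1L, paste, collapse = ""))
  rot <- vapply(0:5, function(i) {
    s <- TELOMERE_MOTIF
    paste0(substr(s, i + 1L, 6L), substr(s, 1L, i))
  }, character(1))
  sort(setdiff(all6, rot))
}
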