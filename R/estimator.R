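# The length estimator. A read group's mean telomere length is
#
#     l = (t_k / n_gc) * (L_gc / n_ends)
#
# where t_k is the number of reads with >= k telomere repeats, n_gc the number
# of reads in the telomere-matched GC band (48-52% by default), L_gc the
# cumulative reference length at that GC composition and n_ends the number of
# telomere ends (46 = 23 x 2 for a haploid human reference). t_k/n_gc is the
# telomeric fraction of GC-matched sequencing, and L_gc/n_ends converts it to
# physical bp per end; GC-matched normalization cancels the GC amplification
# bias of sequencing libraries that makes raw read totals a poor depth
# measure.

#' Estimator parameters
#'
#' @param k telomeric-read repeat threshold (default 7).
#' @param band_lo,band_hi GC band matching telomeric composition, on the 0.02
#'   grid (default 0.48-0.52; telomere repeats are exactly 50% GC).
#' @param n_ends number of telomere ends over which total telomeric content is
#'   averaged (default 46 = 23 chromosomes x 2 ends; a single simulated
#'   chromosome uses 2).
#' @param l_gc cumulative reference length (bp) in the GC band; either given
#'   directly or derived from `profile`.
#' @param profile optional [gc_profile()] from which `l_gc` is computed at
#'   `[band_lo, band_hi)`.
#' @return an object of class `estimator_params`.
#' @export
estimator_params <- function(k = 7L, band_lo = 0.48, band_hi = 0.52,
                             n_ends = 46L, l_gc = NULL, profile = NULL) {
  if (is.null(l_gc) == is.null(profile))
    stop("supply exactly one of l_gc or profile")
  if (!is.null(profile)) l_gc <- length_at_band(profile, band_lo, band_hi)
  k <- as.integer(k)
  n_ends <- as.integer(n_ends)
  check_on_grid(band_lo, "band_lo")
  check_on_grid(band_hi, "band_hi")
  stopifnot(k >= 1L, band_lo >= 0, band_lo < band_hi, band_hi <= 1,
            n_ends >= 1L, l_gc > 0)
  structure(
    list(k = k, band_lo = band_lo, band_hi = band_hi,
         n_ends = n_ends, l_gc = l_gc),
    class = "estimator_params"
  )
}

#' Telomeric read count at threshold k
#'
#' Tail sum of the repeat-count histogram: the number of reads carrying `k` or
#' more telomere repeats.
#'
#' @param tally a `read_group_tally`.
#' @param k threshold, `0 <= k <= cap` (`k = 0` returns the total read count).
#' @return integer count t_k.
#' @export
telomeric_read_count <- function(tally, k = 7L) {
  stopifnot(inherits(tally, "read_group_tally"))
  k <- as.integer(k)
  if (k < 0L || k > tally$cap)
    stop("k must be in [0, cap = ", tally$cap, "]")
  sum(tally$repeat_hist[as.integer(names(tally$repeat_hist)) >= k])
}

#' Reads within a GC band
#'
#' Sum of the GC histogram over bins within `[band_lo, band_hi)`; half-open,
#' matching the reference-side band convention (a read with GC exactly 0.52
#' falls in the bin starting at 0.52 and is excluded from the default band).
#'
#' @param tally a `read_group_tally`.
#' @param band_lo,band_hi bounds on the 0.02 grid.
#' @return integer count n_gc.
#' @export
gc_band_read_count <- function(tally, band_lo = 0.48, band_hi = 0.52) {
  stopifnot(inherits(tally, "read_group_tally"))
  if (!(band_lo >= 0 && band_lo < band_hi && band_hi <= 1))
    stop("need 0 <= band_lo < band_hi <= 1")
  i <- check_on_grid(band_lo, "band_lo")
  j <- check_on_grid(band_hi, "band_hi")
  sum(tally$gc_hist[(i + 1L):j])
}

#' Estimate mean telomere length for one read group
#'
#' @param tally a `read_group_tally`.
#' @param params an [estimator_params()].
#' @return an object of class `telomere_estimate` with `length_bp`,
#'   `length_kb`, `t_k`, `n_gc`, `total_reads`, `read_group` and `params`.
#' @export
estimate_length <- function(tally, params) {
  stopifnot(inherits(tally, "read_group_tally"),
            inherits(params, "estimator_params"))
  t_k <- telomeric_read_count(tally, params$k)
  n_gc <- gc_band_read_count(tally, params$band_lo, params$band_hi)
  if (n_gc == 0L)
    stop("no GC-band reads in read group '", tally$read_group,
         "'; estimate undefined")
  length_bp <- (t_k / n_gc) * (params$l_gc / params$n_ends)
  structure(
    list(read_group = tally$read_group, length_bp = length_bp,
         length_kb = length_bp / 1000, t_k = t_k, n_gc = n_gc,
         total_reads = tally$total_reads, params = params),
    class = "telomere_estimate"
  )
}

#' @export
print.telomere_estimate <- function(x, ...) {
  cat(sprintf(
    "telomere_estimate '%s': %.2f kb (t_%d = %d, n_gc = %d, total = %d)\n",
    x$read_group, x$length_kb, x$params$k, x$t_k, x$n_gc, x$total_reads))
  invisible(x)
}

#' Threshold sweep
#'
#' Re-estimates length over a range of repeat thresholds from one tally (no
#' rescan); because t_k is a tail sum, lengths are non-increasing in k. Used
#' to study threshold sensitivity, e.g. the laxer thresholds appropriate for
#' the sparse off-target reads of exome libraries.
#'
#' @param tally a `read_group_tally`.
#' @param params an [estimator_params()]; its `k` is ignored.
#' @param k_range integer vector of thresholds within `[0, cap]`.
#' @return data.frame with one row per k: `k`, `tel_reads`, `gc_band_reads`,
#'   `length_bp`, `length_kb`.
#' @export
sweep_k <- function(tally, params, k_range = 1:16) {
  rows <- lapply(as.integer(k_range), function(k) {
    p <- params
    p$k <- k
    if (k == 0L) {
      # k = 0 counts every read; estimate_length requires k >= 1 semantics
      t_k <- tally$total_reads
      n_gc <- gc_band_read_count(tally, p$band_lo, p$band_hi)
      lb <- (t_k / n_gc) * (p$l_gc / p$n_ends)
      data.frame(k = k, tel_reads = t_k, gc_band_reads = n_gc,
                 length_bp = lb, length_kb = lb / 1000)
    } else {
      e <- estimate_length(tally, p)
      data.frame(k = k, tel_reads = e$t_k, gc_band_reads = e$n_gc,
                 length_bp = e$length_bp, length_kb = e$length_kb)
    }
  })
  do.call(rbind, rows)
}

#' Pooled estimate over several read groups
#'
#' Merges the tallies first and then estimates, i.e. a read-count-weighted
#' pooling — identical to estimating on the concatenated read stream, not a
#' mean of per-group estimates.
#'
#' @param tallies list of `read_group_tally`.
#' @param params an [estimator_params()].
#' @return a `telomere_estimate`.
#' @export
aggregate_sample <- function(tallies, params) {
  if (inherits(tallies, "read_group_tally")) tallies <- list(tallies)
  stopifnot(length(tallies) >= 1L)
  estimate_length(Reduce(merge_tallies, tallies), params)
}

#' Per-read-group report table
#'
#' One row per read group plus an optional pooled row. Read groups with no
#' GC-band reads get `NA` length (never a silent 0) with a warning.
#'
#' @param tallies named list of `read_group_tally`.
#' @param params an [estimator_params()].
#' @param sample sample label for the report.
#' @param pooled append a pooled row (read group `"ALL"`)?
#' @return data.frame with columns `sample`, `read_group`, `total_reads`,
#'   `gc_band_reads`, `tel_reads`, `k`, `band_lo`, `band_hi`, `L_gc`,
#'   `n_ends`, `length_kb`.
#' @export
estimate_report <- function(tallies, params, sample = "sample",
                            pooled = TRUE) {
  if (inherits(tallies, "read_group_tally")) tallies <- list(tallies)
  one_row <- function(tally, label) {
    kb <- tryCatch(estimate_length(tally, params)$length_kb,
                   error = function(e) {
                     warning(conditionMessage(e), call. = FALSE)
                     NA_real_
                   })
    data.frame(
      sample = sample, read_group = label,
      total_reads = tally$total_reads,
      gc_band_reads = gc_band_read_count(tally, params$band_lo, params$band_hi),
      tel_reads = telomeric_read_count(tally, params$k),
      k = params$k, band_lo = params$band_lo, band_hi = params$band_hi,
      L_gc = params$l_gc, n_ends = params$n_ends, length_kb = kb
    )
  }
  rows <- lapply(seq_along(tallies), function(i) {
    label <- if (!is.null(names(tallies))) names(tallies)[i]
             else tallies[[i]]$read_group
    one_row(tallies[[i]], label)
  })
  if (pooled && length(tallies) >= 1L)
    rows <- c(rows, list(one_row(Reduce(merge_tallies, tallies), "ALL")))
  if (length(rows) == 0L) {
    return(data.frame(sample = character(0), read_group = character(0),
                      total_reads = integer(0), gc_band_reads = integer(0),
                      tel_reads = integer(0), k = integer(0),
                      band_lo = numeric(0), band_hi = numeric(0),
                      L_gc = numeric(0), n_ends = integer(0),
                      length_kb = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
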