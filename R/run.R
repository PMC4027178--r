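# End-to-end scan workflow: files in, per-read-group report out. The CLI
# script in inst/cli/telolen.R is a thin wrapper over these functions.

#' Scan sequencing files and report telomere length per read group
#'
#' Tallies one or more BAM/SAM/FASTQ files, merging tallies that share a group
#' key across files, and reports one row per group plus a pooled row.
#'
#' @param inputs character vector of input paths.
#' @param params an [estimator_params()].
#' @param keep_dups keep duplicate-flagged reads (default `FALSE`).
#' @param group_by `"readgroup"` (RG tag; FASTQ files group by file name),
#'   `"file"` (one group per input file) or `"sample"` (everything pooled into
#'   one group).
#' @param sample sample label for the report.
#' @param out optional path; when given the report is also written as TSV.
#' @param pooled append the pooled `"ALL"` row (default `TRUE`).
#' @return the report data.frame (see [estimate_report()]).
#' @export
run_scan <- function(inputs, params, keep_dups = FALSE,
                     group_by = c("readgroup", "file", "sample"),
                     sample = "sample", out = NULL, pooled = TRUE) {
  group_by <- match.arg(group_by)
  stopifnot(length(inputs) >= 1L)
  tallies <- list()
  for (path in inputs) {
    label <- switch(group_by,
                    file = basename(path),
                    sample = sample,
                    readgroup = basename(path))  # FASTQ fallback label
    per_file <- tally_file(path, read_group = label, keep_dups = keep_dups)
    if (group_by != "readgroup") {
      merged <- Reduce(merge_tallies, per_file)
      merged$read_group <- label
      per_file <- stats::setNames(list(merged), label)
    }
    message(sprintf("%s: %d read(s) tallied in %d group(s)", path,
                    sum(vapply(per_file, function(t) t$total_reads,
                               numeric(1))),
                    length(per_file)))
    for (g in names(per_file)) {
      tallies[[g]] <- if (is.null(tallies[[g]])) per_file[[g]]
                      else merge_tallies(tallies[[g]], per_file[[g]])
    }
  }
  report <- estimate_report(tallies, params, sample = sample,
                            pooled = pooled && length(tallies) > 0L)
  if (!is.null(out)) {
    utils::write.table(report, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  report
}
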