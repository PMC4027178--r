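# Replicate-variability and comparison statistics for evaluating estimates:
# CV across sequencing lanes, variance F-test between coverage groups, and a
# bootstrap test for the difference of two correlations sharing one variable.

#' Coefficient of variation across replicates
#'
#' Sample standard deviation (n-1 denominator) divided by the mean; the lane
#' CV of a multiply-sequenced sample.
#'
#' @param values numeric vector of at least 2 nonnegative length estimates
#'   (kb) with positive mean.
#' @return CV as a fraction.
#' @export
replicate_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 replicate values")
  if (any(values < 0)) stop("replicate values must be nonnegative")
  m <- mean(values)
  if (m <= 0) stop("mean of replicates must be positive")
  stats::sd(values) / m
}

#' Lane-variability table from a report
#'
#' Groups a per-read-group report by sample and computes replicate statistics,
#' using only rows with a defined estimate and excluding any pooled rows.
#'
#' @param report data.frame as produced by [estimate_report()] (columns
#'   `sample`, `read_group`, `length_kb`).
#' @param min_lanes keep samples with at least this many lanes (default 2).
#' @return data.frame: `sample`, `n_lanes`, `mean_kb`, `sd_kb`, `cv`.
#' @export
replicate_cv_table <- function(report, min_lanes = 2L) {
  stopifnot(all(c("sample", "read_group", "length_kb") %in% names(report)))
  report <- report[report$read_group != "ALL" & !is.na(report$length_kb), ]
  rows <- lapply(split(report$length_kb, report$sample), function(v) {
    data.frame(n_lanes = length(v), mean_kb = mean(v),
               sd_kb = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               cv = if (length(v) >= 2L && mean(v) > 0)
                 stats::sd(v) / mean(v) else NA_real_)
  })
  out <- cbind(sample = names(rows), do.call(rbind, rows))
  rownames(out) <- NULL
  out[out$n_lanes >= min_lanes, ]
}

#' Variance F-test between two groups
#'
#' `F = var(a) / var(b)` with a two-sided p-value from the F distribution on
#' `(length(a) - 1, length(b) - 1)` degrees of freedom — used to test whether
#' estimates at low sequencing coverage vary more than at adequate coverage.
#'
#' @param group_a,group_b numeric vectors of at least 2 values each with
#'   positive variance.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
variance_f_test <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(group_a) == 0 || stats::var(group_b) == 0)
    stop("degenerate group: zero variance")
  vt <- stats::var.test(group_a, group_b)
  list(F = unname(vt$statistic), p = vt$p.value,
       df1 = unname(vt$parameter[1]), df2 = unname(vt$parameter[2]))
}

#' Bootstrap test for the difference of two correlations
#'
#' Tests whether `cor(x, y1)` differs from `cor(x, y2)` when both share the
#' same x (e.g. two telomere measures against donor age). Paired case
#' resampling: index triples `(x_i, y1_i, y2_i)` are drawn with replacement,
#' the difference of correlations recomputed per resample, and the observed
#' difference referred to a two-sided normal with the bootstrap SD.
#'
#' @param x,y1,y2 numeric vectors of equal length (>= 5), none constant.
#' @param B number of bootstrap resamples (>= 100; default 1000).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param seed optional integer seed; results are bit-reproducible given the
#'   seed. (Same seed with permuted rows gives the same distribution family
#'   but not bit-identical output.)
#' @return list with `delta_rho`, `sd`, `p`, `B_used` (resamples where both
#'   correlations were defined), `method`.
#' @export
bootstrap_corr_diff <- function(x, y1, y2, B = 1000L,
                                method = c("pearson", "spearman"),
                                seed = NULL) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y1) != n || length(y2) != n) stop("x, y1, y2 lengths must match")
  if (n < 5L) stop("need at least 5 observations")
  if (B < 100L) stop("need at least 100 bootstrap resamples")
  if (stats::sd(x) == 0 || stats::sd(y1) == 0 || stats::sd(y2) == 0)
    stop("constant input vector: correlation undefined")
  delta <- stats::cor(x, y1, method = method) -
    stats::cor(x, y2, method = method)
  boot_one <- function() {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y1[i]) == 0 ||
        stats::sd(y2[i]) == 0) return(NA_real_)
    stats::cor(x[i], y1[i], method = method) -
      stats::cor(x[i], y2[i], method = method)
  }
  reps <- if (is.null(seed)) {
    replicate(B, boot_one())
  } else {
    withr::with_seed(seed, replicate(B, boot_one()))
  }
  reps <- reps[!is.na(reps)]
  s <- stats::sd(reps)
  p <- if (s == 0) {
    if (delta == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(delta) / s)
  }
  list(delta_rho = delta, sd = s, p = min(p, 1), B_used = length(reps),
       method = method)
}
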