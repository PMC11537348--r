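# Benchmarking of filtration runs against ground truth, paired method
# comparisons, the custom-metric threshold grid search, and coverage
# depth/breadth diagnostics for mismapping forensics.

#' Score a filtration run against ground truth
#'
#' @param surviving_ids Identifiers of reads that survived filtration.
#' @param truth Truth table with columns `read_id` and `truth_label`
#'   (`"host"`/`"microbe"`).
#' @return List of class `benchmark_result`: `human_remaining` (surviving
#'   reads whose truth is host), `microbial_lost` (truth-microbe reads absent
#'   from the surviving set), and per-class totals.
#' @export
evaluate_filtering <- function(surviving_ids, truth) {
  surviving_ids <- unique(as.character(surviving_ids))
  unknown <- setdiff(surviving_ids, truth$read_id)
  if (length(unknown)) {
    stop("surviving ids missing from the truth table: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  surviving <- truth$read_id %in% surviving_ids
  host <- truth$truth_label == "host"
  structure(list(human_remaining = sum(surviving & host),
                 microbial_lost = sum(!surviving & !host),
                 total_host = sum(host),
                 total_microbe = sum(!host)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> human remaining ", x$human_remaining, "/",
      x$total_host, "; microbial lost ", x$microbial_lost, "/",
      x$total_microbe, "\n", sep = "")
  invisible(x)
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Paired test on `x - y`. Zero differences are dropped before ranking. The
#' statistic `W` is the smaller of the positive- and negative-rank sums. The
#' two-sided P-value is exact for small samples — the closed-form signed-rank
#' null distribution when at most 25 tie-free non-zero pairs remain, or
#' direct enumeration of all `2^n` sign assignments (midranks) when ties are
#' present and `n <= 15` — and a normal approximation with continuity and
#' tie correction otherwise.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `statistic` (W), `p_value`, `n` (non-zero pairs) and
#'   `exact` (whether the exact null was used).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all paired differences are zero; the signed-rank test is undefined",
         call. = FALSE)
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !ties) {
    # exact: two-sided p = P(V <= W) + P(V >= S - W) = 2 P(V <= W) by symmetry
    p <- min(1, 2 * stats::psignrank(w, n))
    exact <- TRUE
  } else if (n <= 15) {
    # ties: enumerate the 2^n sign assignments on the observed midranks
    signs <- matrix(as.integer(intToBits(seq_len(2^n) - 1L))[
      rep(seq_len(n), 2^n) + rep((seq_len(2^n) - 1L) * 32L, each = n)],
      nrow = n)
    t_all <- colSums(r * signs)
    s_tot <- sum(r)
    p <- min(1, mean(t_all <= w) + mean(t_all >= s_tot - w))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu + 0.5) / sqrt(sigma2)  # continuity correction toward the mean
    p <- min(1, 2 * stats::pnorm(z))
    exact <- FALSE
  }
  list(statistic = w, p_value = p, n = n, exact = exact)
}

#' Grid search over custom-metric thresholds and run lengths
#'
#' Computes every read's PML distribution once, then evaluates the custom
#' score over the grid of minimum run lengths and thresholds against ground
#' truth labels. Host recall is the fraction of truth-host reads flagged;
#' precision the fraction of flagged reads that are truth-host.
#'
#' @param labeled_reads Read table with `sequence` and `truth_label` columns.
#' @param index A [build_index()] over the host reference set.
#' @param thresholds Numeric vector; default `seq(0.145, 0.200, by = 0.005)`.
#' @param run_lengths Integer vector; default `2:12`.
#' @param digits Score/threshold comparison precision as in [classify_read()].
#' @return `data.frame` of class `grid_search_result` with one row per
#'   (threshold, min_run_length) cell: `recall_host`, `precision_host`,
#'   `microbial_retained_fraction`.
#' @export
threshold_grid_search <- function(labeled_reads, index,
                                  thresholds = seq(0.145, 0.200, by = 0.005),
                                  run_lengths = 2:12, digits = 3L) {
  stopifnot(length(thresholds) >= 1, length(run_lengths) >= 1)
  pmls <- lapply(labeled_reads$sequence, compute_pml, index = index)
  host <- labeled_reads$truth_label == "host"
  rows <- lapply(as.integer(run_lengths), function(w) {
    scores <- round(vapply(pmls, score_custom, numeric(1), w = w), digits)
    t(vapply(thresholds, function(th) {
      flagged <- scores >= th
      c(recall_host = sum(flagged & host) / max(1L, sum(host)),
        precision_host = if (any(flagged)) sum(flagged & host) / sum(flagged) else NA_real_,
        microbial_retained_fraction =
          sum(!flagged & !host) / max(1L, sum(!host)))
    }, numeric(3)))
  })
  # rows iterate w-outer / threshold-inner; labels below follow the same order
  out <- cbind(
    data.frame(threshold = rep(thresholds, times = length(run_lengths)),
               min_run_length = rep(as.integer(run_lengths),
                                    each = length(thresholds))),
    as.data.frame(do.call(rbind, rows)))
  class(out) <- c("grid_search_result", "data.frame")
  out
}

#' Coverage depth and breadth of an interval set
#'
#' @param intervals Two-column matrix or `data.frame` of 0-based half-open
#'   `(start, end)` intervals within `[0, genome_length)`.
#' @param genome_length Genome length in bases.
#' @param genome_id Identifier carried into the summary.
#' @return List of class `coverage_summary`: `mean_depth` (total covered
#'   bases / genome length) and `breadth` (fraction of positions covered at
#'   least once). A high depth concentrated on a low breadth is the
#'   signature of artifactual mismapping to a shared segment.
#' @export
coverage_depth_breadth <- function(intervals, genome_length, genome_id = "") {
  intervals <- as.data.frame(intervals)
  stopifnot(ncol(intervals) >= 2, genome_length >= 1)
  start <- as.integer(intervals[[1]])
  end <- as.integer(intervals[[2]])
  if (length(start) && (any(start < 0) || any(end > genome_length) ||
                        any(end <= start))) {
    stop("intervals must satisfy 0 <= start < end <= genome_length",
         call. = FALSE)
  }
  if (length(start) == 0) {
    depth <- 0
    breadth <- 0
  } else {
    ir <- IRanges::IRanges(start = start + 1L, end = end)  # 1-based closed
    depth <- sum(IRanges::width(ir)) / genome_length
    breadth <- sum(IRanges::width(IRanges::reduce(ir))) / genome_length
  }
  structure(list(genome_id = genome_id, genome_length = genome_length,
                 mean_depth = depth, breadth = breadth),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat("<coverage_summary> ", if (nzchar(x$genome_id)) paste0(x$genome_id, ": "),
      "depth=", signif(x$mean_depth, 4), ", breadth=", signif(x$breadth, 4),
      "\n", sep = "")
  invisible(x)
}

#' Boxplot-style summary statistics
#'
#' Median, quartiles and 1.5*IQR whisker bounds for report tables.
#'
#' @param x Numeric vector.
#' @return Named list: `median`, `q1`, `q3`, `whisker_low`, `whisker_high`.
#' @export
boxplot_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = q[1] - 1.5 * iqr, whisker_high = q[3] + 1.5 * iqr)
}
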