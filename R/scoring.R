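# Per-read host scores from a PML distribution.
#
# Three metrics condense the distribution into one number:
#   maximum  - max(values)
#   average  - mean(values) over all L positions
#   custom   - (1/(2L)) * ( max(values) + (sum of qualifying run lengths)
#                            * ln(|R| + 1) )
#              with R = { runs r : len(r) > w }, natural logarithm.
# A "run" is a maximal ramp segment (values[i] == values[i-1] + 1) and its
# length is the peak PML value inside the segment, so one contiguous matching
# stretch of k bases yields one run of length k. Default thresholds come from
# a theoretical host read of length 150 carrying a single contiguous matching
# run of length 31: maximum 31, average 3.306, custom 0.175 (w = 5).

#' Scoring configuration
#'
#' @param metric One of `"custom"`, `"maximum"`, `"average"`.
#' @param threshold Decision threshold; `NULL` selects the metric's default
#'   (maximum 31, average 3.306, custom 0.175), each derived from the
#'   theoretical 150-bp host read with one run of length 31.
#' @param min_run_length Minimum run length `w` of the custom metric; runs
#'   must be strictly longer than `w` to enter the magnified term. Default 5.
#' @param digits Precision at which scores are compared to the threshold (see
#'   [classify_read()]); default 3, matching the precision at which default
#'   thresholds are stated.
#' @return Object of class `scoring_config`.
#' @export
scoring_config <- function(metric = c("custom", "maximum", "average"),
                           threshold = NULL, min_run_length = 5L, digits = 3L) {
  metric <- match.arg(metric)
  defaults <- c(maximum = 31, average = 3.306, custom = 0.175)
  threshold <- threshold %||% unname(defaults[metric])
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            min_run_length >= 0, digits >= 0)
  structure(list(metric = metric, threshold = threshold,
                 min_run_length = as.integer(min_run_length),
                 digits = as.integer(digits)),
            class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("<scoring_config> metric=", x$metric, ", threshold=", x$threshold,
      if (x$metric == "custom") paste0(", w=", x$min_run_length), "\n", sep = "")
  invisible(x)
}

#' Extract matching runs from a PML distribution
#'
#' A run is a maximal segment of positions where each value continues the
#' ramp (`values[i] == values[i-1] + 1`); its length is the peak PML value in
#' the segment. Segments consisting of zeros yield no run.
#'
#' @param pml A [pml_distribution()].
#' @return `data.frame` with columns `start` (0-based segment start) and
#'   `length` (peak PML value), in increasing start order.
#' @examples
#' extract_runs(pml_distribution(c(1, 2, 3, 2, 3, 4, 0, 1)))$length  # 3 4 1
#' @export
extract_runs <- function(pml) {
  stopifnot(inherits(pml, "pml_distribution"))
  v <- pml$values
  # segment starts: position 1, and every break of the ramp
  starts <- c(1L, which(diff(v) != 1L) + 1L)
  ends <- c(starts[-1] - 1L, length(v))
  peak <- v[ends]  # within a segment values strictly increase
  keep <- peak > 0L
  data.frame(start = starts[keep] - 1L, length = peak[keep])
}

#' Maximum-metric score
#' @param pml A [pml_distribution()].
#' @return `max(values)`.
#' @export
score_maximum <- function(pml) {
  stopifnot(inherits(pml, "pml_distribution"))
  max(pml$values)
}

#' Average-metric score
#' @param pml A [pml_distribution()].
#' @return Arithmetic mean of `values` over all `L` positions.
#' @export
score_average <- function(pml) {
  stopifnot(inherits(pml, "pml_distribution"))
  mean(pml$values)
}

#' Custom-metric score
#'
#' `(1/(2L)) * ( max(values) + (sum_{r in R} len(r)) * ln(|R| + 1) )` with
#' `R = { runs r : len(r) > w }`. With empty `R` the score reduces to
#' `max(values) / (2L)`.
#'
#' @param pml A [pml_distribution()].
#' @param w Minimum run length (strict: runs must exceed `w`).
#' @return Numeric score.
#' @export
score_custom <- function(pml, w = 5L) {
  stopifnot(inherits(pml, "pml_distribution"), w >= 0)
  runs <- extract_runs(pml)
  r <- runs$length[runs$length > w]
  (max(pml$values) + sum(r) * log(length(r) + 1)) / (2 * pml$L)
}

score_by_metric <- function(pml, metric, w = 5L) {
  switch(metric,
         maximum = score_maximum(pml),
         average = score_average(pml),
         custom = score_custom(pml, w),
         stop("unknown metric: ", metric, call. = FALSE))
}

#' Derive a decision threshold from the theoretical host read
#'
#' Builds the PML distribution of a read of length `L` whose only matching
#' stretch is a single contiguous run of length `run_length` (ramp
#' `1..run_length`, zeros elsewhere) and applies the named metric to it. With
#' the defaults `L = 150`, `run_length = 31`, `w = 5` this reproduces the
#' shipped thresholds: 31 (maximum), 3.30666... (average; 3.306 truncated to
#' three decimals) and 0.17495... (custom; 0.175 rounded to three decimals).
#'
#' @param metric `"maximum"`, `"average"` or `"custom"`.
#' @param L Read length of the theoretical read.
#' @param run_length Length of its single matching run; must not exceed `L`.
#' @param w Minimum run length for the custom metric.
#' @return Numeric threshold at full precision.
#' @export
derive_theoretical_threshold <- function(metric, L = 150L, run_length = 31L,
                                         w = 5L) {
  if (!metric %in% c("maximum", "average", "custom")) {
    stop("unknown metric: ", metric, call. = FALSE)
  }
  stopifnot(run_length <= L, run_length >= 1)
  values <- integer(L)
  values[seq_len(run_length)] <- seq_len(run_length)
  score_by_metric(pml_distribution(values, read_id = "theoretical"), metric, w)
}

#' Classify a read as host or non-host
#'
#' The score is computed by the configured metric and compared against the
#' threshold at the configuration's stored precision: a read is called host
#' when `round(score, digits) >= threshold`. Rounding before comparison makes
#' the threshold-defining theoretical read itself classify as host under the
#' default three-decimal thresholds.
#'
#' @param pml A [pml_distribution()].
#' @param config A [scoring_config()].
#' @return `data.frame` row with `read_id`, `metric`, `score` (full
#'   precision) and `is_host`.
#' @export
classify_read <- function(pml, config = scoring_config()) {
  stopifnot(inherits(pml, "pml_distribution"), inherits(config, "scoring_config"))
  score <- score_by_metric(pml, config$metric, config$min_run_length)
  data.frame(read_id = pml$read_id, metric = config$metric, score = score,
             is_host = round(score, config$digits) >= config$threshold)
}
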