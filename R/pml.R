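# Exact per-position matching statistics.
#
# For a read x[1..L] and a match index, values[i] is the length of the
# longest suffix of x[1..i] that occurs as an exact substring of any indexed
# strand. This is the classical matching-statistics quantity; compressed-index
# tools report a pseudo-matching-length approximation of it, and the scoring
# layer treats the two identically. The computation uses the ramp bound
# values[i] <= values[i-1] + 1 together with the fact that substring presence
# is monotone in suffix length, so each position needs only a short descent
# of exact presence queries.

#' Construct / validate a PML distribution
#'
#' @param values Integer vector of per-position matching lengths.
#' @param read_id Read identifier carried through scoring.
#' @return Object of class `pml_distribution` with fields `read_id`, `values`
#'   and `L` (read length).
#' @details Invariants enforced: `values[1]` is 0 or 1; the ramp property
#'   `values[i] <= values[i-1] + 1`; and `values[i] <= i`.
#' @export
pml_distribution <- function(values, read_id = "") {
  values <- as.integer(values)
  L <- length(values)
  if (L == 0) stop("a PML distribution needs at least one position", call. = FALSE)
  if (anyNA(values) || any(values < 0)) {
    stop("PML values must be non-negative integers", call. = FALSE)
  }
  if (!values[1] %in% c(0L, 1L)) {
    stop("the first PML value must be 0 or 1", call. = FALSE)
  }
  if (L > 1 && any(diff(values) > 1L)) {
    stop("PML values violate the ramp property values[i] <= values[i-1] + 1",
         call. = FALSE)
  }
  if (any(values > seq_len(L))) {
    stop("PML values cannot exceed the prefix length", call. = FALSE)
  }
  structure(list(read_id = read_id, values = values, L = L),
            class = "pml_distribution")
}

#' @export
print.pml_distribution <- function(x, ...) {
  cat("<pml_distribution> ", if (nzchar(x$read_id)) paste0(x$read_id, ", "),
      "L=", x$L, ", max=", max(x$values), "\n", sep = "")
  invisible(x)
}

# Core scan. Returns the full values vector, or stops early and returns the
# partial maximum once a matching length of `stop_at` is seen (used by the
# alignment-surrogate seed test).
ms_scan <- function(read_sequence, index, stop_at = Inf) {
  stopifnot(inherits(index, "match_index"))
  read_sequence <- toupper(read_sequence)
  if (!nzchar(read_sequence)) stop("read sequence must be non-empty", call. = FALSE)
  assert_dna(read_sequence, "read sequence")
  L <- nchar(read_sequence)
  values <- integer(L)
  v <- 0L
  text <- index$text
  for (i in seq_len(L)) {
    v <- min(v + 1L, i)
    while (v > 0L &&
           !grepl(substr(read_sequence, i - v + 1L, i), text, fixed = TRUE)) {
      v <- v - 1L
    }
    values[i] <- v
    if (v >= stop_at) return(list(values = values[seq_len(i)], reached = TRUE))
  }
  list(values = values, reached = FALSE)
}

#' Compute the exact matching-statistics (PML) distribution of a read
#'
#' @param read_sequence Single read sequence over `{A,C,G,T,N}`.
#' @param index A [build_index()] object.
#' @param read_id Identifier stored in the result.
#' @return A [pml_distribution()]: `values[i]` is the length of the longest
#'   suffix of the first `i` read bases occurring exactly in the index
#'   (forward or reverse-complement strand). Positions at or immediately after
#'   an `N` drop to 0/restart, since `N` matches nothing.
#' @examples
#' idx <- build_index(reference_collection(c(r = "ACGTACGT")))
#' compute_pml("ACGT", idx)$values  # 1 2 3 4
#' @export
compute_pml <- function(read_sequence, index, read_id = "") {
  pml_distribution(ms_scan(read_sequence, index)$values, read_id = read_id)
}

#' Longest exact match between a read and an index
#'
#' @inheritParams compute_pml
#' @return Integer: `max(values)` of [compute_pml()]; 0 when no read character
#'   matches the index.
#' @export
max_exact_match <- function(read_sequence, index) {
  max(ms_scan(read_sequence, index)$values)
}

# TRUE iff the read attains a matching length of at least `seed_length`;
# stops scanning as soon as the bound is reached.
ms_reaches <- function(read_sequence, index, seed_length) {
  ms_scan(read_sequence, index, stop_at = seed_length)$reached
}
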