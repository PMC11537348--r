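# Host-filtration pipeline: stage primitives and the three method topologies.
#
# Every method starts with a 45-bp minimum length filter, then removes host
# reads in one or more stages:
#   Method 1: two alignment-surrogate stages (one reference each), then an
#             index stage over the aggregate reference set.
#   Method 2: one or more sequential alignment-surrogate stages, then the
#             aggregate index stage.
#   Method 3: the aggregate index stage only.
# The alignment surrogate declares a read mapped when it shares an exact
# substring of at least `seed_length` bases (default 31) with the stage
# reference; the index stage scores full PML distributions via classify_read.
# For paired-end data a pair survives only if BOTH mates survive every
# removal stage; single-surviving mates are dropped as orphans and counted.

#' Pipeline method configuration
#'
#' @param method 1, 2 or 3 (see module description above).
#' @param alignment_refs Character labels of reference collections used by the
#'   alignment-surrogate stages, in stage order. Method 1 requires exactly
#'   two, method 2 at least one, method 3 none.
#' @param index_refs Labels of the collections aggregated into the index
#'   stage (at least one).
#' @param scoring A [scoring_config()] for the index stage.
#' @param min_length Minimum read length kept by the length filter (default 45).
#' @param seed_length Exact-match seed length of the alignment surrogate
#'   (default 31).
#' @param paired Whether the input is paired-end.
#' @return Object of class `method_config`.
#' @export
method_config <- function(method, alignment_refs = character(),
                          index_refs, scoring = scoring_config(),
                          min_length = 45L, seed_length = 31L,
                          paired = FALSE) {
  stopifnot(method %in% 1:3, inherits(scoring, "scoring_config"),
            min_length >= 1, seed_length >= 1, length(index_refs) >= 1)
  n_align <- length(alignment_refs)
  ok <- switch(as.character(method),
               "1" = n_align == 2, "2" = n_align >= 1, "3" = n_align == 0)
  if (!ok) {
    stop("method ", method, " is incompatible with ", n_align,
         " alignment reference(s)", call. = FALSE)
  }
  structure(list(method = as.integer(method),
                 alignment_refs = as.character(alignment_refs),
                 index_refs = as.character(index_refs), scoring = scoring,
                 min_length = as.integer(min_length),
                 seed_length = as.integer(seed_length),
                 paired = isTRUE(paired)),
            class = "method_config")
}

#' Minimum-length filter
#'
#' @param reads A [read_records()] table.
#' @param min_length Inclusive minimum: reads of exactly `min_length` bases
#'   are kept.
#' @return List with `kept` and `removed` tables, input order preserved.
#' @export
length_filter <- function(reads, min_length = 45L) {
  stopifnot(min_length >= 1)
  keep <- nchar(reads$sequence) >= min_length
  list(kept = reads[keep, , drop = FALSE],
       removed = reads[!keep, , drop = FALSE])
}

#' Alignment-surrogate filter
#'
#' A read is "mapped" (and removed as host) iff its longest exact substring
#' match against the stage reference reaches `seed_length` bases on either
#' strand — a deterministic stand-in for seed-and-extend alignment.
#'
#' @param reads A [read_records()] table.
#' @param index A [build_index()] over the stage reference.
#' @param seed_length Minimum exact-match length declaring a mapping.
#' @return List with `mapped_ids` (character) and `unmapped` (read table).
#' @export
alignment_filter <- function(reads, index, seed_length = 31L) {
  stopifnot(seed_length >= 1)
  mapped <- vapply(reads$sequence, ms_reaches, logical(1),
                   index = index, seed_length = seed_length, USE.NAMES = FALSE)
  list(mapped_ids = reads$read_id[mapped],
       unmapped = reads[!mapped, , drop = FALSE])
}

#' Index-based filter
#'
#' Computes the full PML distribution of every read against the aggregate
#' index and removes reads whose [classify_read()] call is host.
#'
#' @param reads A [read_records()] table.
#' @param index A [build_index()] over the aggregate reference set.
#' @param scoring A [scoring_config()].
#' @return List with `host_ids`, `nonhost` (read table) and `scores`
#'   (per-read score table).
#' @export
index_filter <- function(reads, index, scoring = scoring_config()) {
  scores <- do.call(rbind, lapply(seq_len(nrow(reads)), function(i) {
    classify_read(compute_pml(reads$sequence[i], index,
                              read_id = reads$read_id[i]), scoring)
  }))
  if (is.null(scores)) {
    scores <- data.frame(read_id = character(), metric = character(),
                         score = numeric(), is_host = logical())
  }
  list(host_ids = scores$read_id[scores$is_host],
       nonhost = reads[!scores$is_host, , drop = FALSE],
       scores = scores)
}

#' Re-synchronize read pairs after a removal stage
#'
#' A pair is retained iff both mates are present; reads whose mate is missing
#' are dropped and counted as orphans.
#'
#' @param reads A [read_records()] table with `mate` in `{1, 2}`.
#' @return List with `reads` (retained pairs, input order) and `orphans`
#'   (count of dropped single mates).
#' @export
pair_sync <- function(reads) {
  if (any(reads$mate == 0)) {
    stop("pair_sync requires paired reads (mate 1/2)", call. = FALSE)
  }
  key <- paste(reads$read_id, reads$mate)
  if (anyDuplicated(key)) {
    stop("duplicate read_id within a mate file: ",
         reads$read_id[duplicated(key)][1], call. = FALSE)
  }
  ids1 <- reads$read_id[reads$mate == 1L]
  ids2 <- reads$read_id[reads$mate == 2L]
  complete <- intersect(ids1, ids2)
  keep <- reads$read_id %in% complete
  list(reads = reads[keep, , drop = FALSE], orphans = sum(!keep))
}

#' Run a host-filtration method
#'
#' Executes the configured topology: length filter, then the method's
#' alignment-surrogate stages in order, then the aggregate index stage, with
#' pair re-synchronization after every stage for paired input. Stage counts
#' reconcile (`input = removed + surviving + orphaned`) at every row of the
#' report.
#'
#' @param reads A [read_records()] table (both mates interleaved or stacked
#'   for paired data).
#' @param config A [method_config()].
#' @param references Named list of [reference_collection()] objects; must
#'   contain every label in `config$alignment_refs` and `config$index_refs`.
#' @return List of class `filter_run` with `reads` (surviving table),
#'   `report` (a `filter_report`) and `scores` (index-stage score table).
#' @export
run_method <- function(reads, config, references) {
  stopifnot(inherits(config, "method_config"))
  labels <- unique(c(config$alignment_refs, config$index_refs))
  missing <- setdiff(labels, names(references))
  if (length(missing)) {
    stop("missing reference label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (config$paired && any(reads$mate == 0)) {
    stop("paired configuration but unpaired reads present", call. = FALSE)
  }

  stages <- data.frame(stage = character(), input = integer(),
                       removed = integer(), orphaned = integer(),
                       surviving = integer())
  sync <- function(current, n_in, n_removed, stage) {
    orphans <- 0L
    if (config$paired) {
      s <- pair_sync(current)
      current <- s$reads
      orphans <- s$orphans
    }
    stages[nrow(stages) + 1L, ] <<- list(stage, n_in, n_removed, orphans,
                                         nrow(current))
    current
  }

  lf <- length_filter(reads, config$min_length)
  current <- sync(lf$kept, nrow(reads), nrow(lf$removed), "length_filter")

  for (lab in config$alignment_refs) {
    idx <- build_index(references[[lab]])
    af <- alignment_filter(current, idx, config$seed_length)
    current <- sync(af$unmapped, nrow(current), length(af$mapped_ids),
                    paste0("align:", lab))
  }

  agg <- build_index(references[config$index_refs])
  ixf <- index_filter(current, agg, config$scoring)
  current <- sync(ixf$nonhost, nrow(ixf$nonhost) + length(ixf$host_ids),
                  length(ixf$host_ids),
                  paste0("index:", paste(config$index_refs, collapse = "+")))

  report <- structure(list(method = config$method, stages = stages,
                           orphans = sum(stages$orphaned),
                           input = nrow(reads), surviving = nrow(current)),
                      class = "filter_report")
  structure(list(reads = current, report = report, scores = ixf$scores),
            class = "filter_run")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> method ", x$method, ": ", x$input, " reads in, ",
      x$surviving, " surviving (", x$orphans, " orphaned)\n", sep = "")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report A `filter_report` from [run_method()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
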