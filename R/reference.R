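# Reference collections and the exact substring match index.
#
# The index answers one question: does a query string occur, with no
# mismatches, on the forward or reverse-complement strand of any reference
# record? Per the conservative ambiguity policy, `N` never matches any
# character (including another `N`): reference Ns are rewritten to a
# lower-case sentinel outside the query alphabet before indexing.

#' Construct a reference collection
#'
#' A reference collection is a named character vector of upper-case DNA
#' sequences over `{A,C,G,T,N}`; names are the record identifiers. It is the
#' container consumed by [build_index()].
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet] of
#'   reference sequences; lower case is accepted and upper-cased.
#' @param ids Record identifiers; defaults to `names(sequences)` or
#'   `ref1, ref2, ...` when unnamed.
#' @return Named character vector with class `reference_collection`.
#' @export
reference_collection <- function(sequences, ids = NULL) {
  if (methods::is(sequences, "DNAStringSet")) {
    ids <- ids %||% names(sequences)
    sequences <- as.character(sequences)
  }
  if (length(sequences) == 0) {
    stop("a reference collection must contain at least one record", call. = FALSE)
  }
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) {
    stop("reference sequences must be non-empty", call. = FALSE)
  }
  assert_dna(sequences, "reference sequence")
  ids <- ids %||% names(sequences) %||% paste0("ref", seq_along(sequences))
  names(sequences) <- ids
  structure(sequences, class = "reference_collection")
}

#' Read a reference collection from FASTA
#'
#' Multi-record, wrapped-line FASTA; gzip-compressed files are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A [reference_collection()].
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  reference_collection(as.character(x), ids = ids)
}

#' Write a reference collection to FASTA
#'
#' @param refs A [reference_collection()] (or named character vector).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  x <- Biostrings::DNAStringSet(unclass(refs))
  names(x) <- names(refs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Build an exact substring match index
#'
#' Indexes the forward and reverse-complement strands of every record of one
#' or more reference collections. Queries ([index_contains()],
#' [compute_pml()]) are exact: a string is present iff it occurs verbatim on
#' some indexed strand. `N` in a reference never matches a query character.
#'
#' @param refs A [reference_collection()], a named character vector of DNA
#'   sequences, or a list of either (concatenated into one aggregate index).
#' @return An object of class `match_index`.
#' @export
build_index <- function(refs) {
  if (is.list(refs) && !methods::is(refs, "DNAStringSet")) {
    refs <- do.call(c, lapply(refs, function(r) unclass(reference_collection(r))))
  }
  refs <- reference_collection(refs)
  fwd <- unclass(refs)
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd)))
  # "|" separates records so matches cannot span them; "n" is the sentinel a
  # query over {A,C,G,T,N} can never hit.
  text <- paste(c(fwd, rev), collapse = "|")
  text <- gsub("N", "n", text, fixed = TRUE)
  structure(
    list(text = text, labels = names(refs),
         total_length = sum(nchar(fwd))),
    class = "match_index"
  )
}

#' @export
print.match_index <- function(x, ...) {
  cat("<match_index> ", length(x$labels), " record(s), ",
      x$total_length, " bp per strand\n", sep = "")
  invisible(x)
}

#' Test exact substring presence in an index
#'
#' @param index A [build_index()] object.
#' @param query Single DNA string.
#' @return `TRUE` iff `query` occurs on an indexed strand with no mismatches.
#' @export
index_contains <- function(index, query) {
  stopifnot(inherits(index, "match_index"), is.character(query), length(query) == 1)
  grepl(query, index$text, fixed = TRUE)
}
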