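# FASTQ input/output and the read-record table.
#
# Reads are carried as a data.frame with columns read_id, sequence, quality
# and mate (0 for single-end, 1/2 for paired). Mate tags of the form
# "id/1", "id/2" or a whitespace-delimited "1:..."/"2:..." field are parsed
# and stripped from the identifier.

#' Construct a read-record table
#'
#' @param read_id Character identifiers.
#' @param sequence DNA sequences over `{A,C,G,T,N}`.
#' @param quality Quality strings, same lengths as `sequence`; default
#'   constant Q37 (`"F"`).
#' @param mate Integer 0 (single-end), 1 or 2.
#' @return `data.frame` of class `read_records`.
#' @export
read_records <- function(read_id, sequence, quality = NULL, mate = 0L) {
  sequence <- toupper(sequence)
  assert_dna(sequence, "read sequence")
  quality <- quality %||% strrep("F", nchar(sequence))
  if (any(nchar(quality) != nchar(sequence))) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  mate <- rep_len(as.integer(mate), length(sequence))
  stopifnot(all(mate %in% 0:2))
  out <- data.frame(read_id = as.character(read_id), sequence = sequence,
                    quality = quality, mate = mate)
  class(out) <- c("read_records", "data.frame")
  out
}

parse_mate_tags <- function(ids) {
  mate <- integer(length(ids))
  slash <- grepl("/[12]$", ids)
  mate[slash] <- as.integer(sub("^.*/([12])$", "\\1", ids[slash]))
  ids[slash] <- sub("/[12]$", "", ids[slash])
  # whitespace-delimited Casava-style tag: "id 1:N:0:..." / "id 2:..."
  ws <- !slash & grepl("\\s[12](:|$)", ids)
  mate[ws] <- as.integer(sub("^.*\\s([12])(:.*)?$", "\\1", ids[ws]))
  ids <- sub("\\s.*$", "", ids)
  list(read_id = ids, mate = mate)
}

#' Read a FASTQ file into a read-record table
#'
#' Four-line records; gzip-compressed files accepted. Trailing `/1`, `/2` or
#' whitespace-delimited mate tags are parsed into the `mate` column and
#' stripped from `read_id`; `mate` overrides the parsed value when given.
#'
#' @param path FASTQ file path.
#' @param mate Force all records to this mate (0/1/2); `NULL` keeps parsed tags.
#' @return A [read_records()] table.
#' @export
read_fastq <- function(path, mate = NULL) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tags <- parse_mate_tags(names(x))
  read_records(tags$read_id, as.character(x),
               as.character(S4Vectors::mcols(x)$qualities),
               mate = mate %||% tags$mate)
}

#' Write a read-record table to FASTQ
#'
#' @param reads A [read_records()] table.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param mate_suffix Append `/1`, `/2` to identifiers of paired reads.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, mate_suffix = TRUE) {
  ids <- reads$read_id
  if (mate_suffix) {
    paired <- reads$mate > 0
    ids[paired] <- paste0(ids[paired], "/", reads$mate[paired])
  }
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
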