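# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is restored afterwards so simulation functions are pure in (inputs, seed).
with_rng_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DNA alphabet checks; sequences are handled as plain upper-case character
# strings over {A,C,G,T,N} throughout.
assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  if (!is.character(x) || anyNA(x)) {
    stop(what, " must be a character vector without NAs", call. = FALSE)
  }
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    stop(what, " contains characters outside the DNA alphabet: ",
         paste(utils::head(unique(unlist(regmatches(x[bad], gregexpr(pat, x[bad])))), 5),
               collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements (`N` maps to `N`).
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(x) {
  assert_dna(toupper(x), "sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

trunc_digits <- function(x, digits) trunc(x * 10^digits) / 10^digits
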