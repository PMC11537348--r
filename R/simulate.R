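# Labeled synthetic genomes and reads.
#
# The generator emulates the statistical structure of a host/microbe
# benchmark: i.i.d.-uniform genomes, uniformly placed error-free or
# substitution-perturbed reads with ground-truth labels and source intervals,
# and two engineered failure mechanisms — a region held out of the filtering
# reference (emulating an incomplete assembly such as a missing chromosome)
# and an identical low-complexity segment spliced into both a host and a
# microbe genome (emulating shared sequence that makes leaked host reads
# mismap to microbes).

#' Generate a synthetic genome
#'
#' @param length Genome length in bases (>= 300).
#' @param seed RNG seed; the sequence is a pure function of it.
#' @param label `"host"` or `"microbe"`.
#' @param id Record identifier; defaults to `<label>_g<seed>`.
#' @return Object of class `synthetic_genome`: list with `label`, `id`,
#'   `sequence`, `seed`. Bases are i.i.d. uniform over `{A,C,G,T}`.
#' @export
generate_genome <- function(length, seed, label = c("host", "microbe"),
                            id = NULL) {
  label <- match.arg(label)
  stopifnot(length >= 300)
  sequence <- with_rng_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
  structure(list(label = label, id = id %||% paste0(label, "_g", seed),
                 sequence = sequence, seed = as.integer(seed)),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome> ", x$id, " (", x$label, "), ",
      nchar(x$sequence), " bp\n", sep = "")
  invisible(x)
}

as_reference <- function(genome) {
  reference_collection(stats::setNames(genome$sequence, genome$id))
}

#' Hold a region out of the filtering reference
#'
#' Returns two versions of a genome: `filter_reference` with the half-open
#' interval `[start, end)` excised (flanks concatenated) and
#' `full_reference`, unchanged. Error-free reads simulated from inside the
#' held-out region cannot exact-seed-match the filter reference beyond flank
#' overlap, reproducing the leak caused by incomplete reference assemblies.
#'
#' @param genome A [generate_genome()] object.
#' @param start,end 0-based half-open interval to excise.
#' @return List with `filter_reference` and `full_reference`, both
#'   `synthetic_genome` objects.
#' @export
holdout_region <- function(genome, start, end) {
  n <- nchar(genome$sequence)
  if (!(start >= 0 && start < end && end <= n)) {
    stop("invalid holdout interval [", start, ", ", end, ") for genome of length ",
         n, call. = FALSE)
  }
  excised <- paste0(substr(genome$sequence, 1L, start),
                    substr(genome$sequence, end + 1L, n))
  filter_ref <- genome
  filter_ref$sequence <- excised
  filter_ref$id <- paste0(genome$id, "_holdout_", start, "_", end)
  list(filter_reference = filter_ref, full_reference = genome)
}

#' Splice an identical segment into two genomes
#'
#' Inserts `segment` into both genomes at the given 0-based positions,
#' emulating low-complexity sequence shared between host and microbial
#' references. An empty segment leaves the genomes unchanged.
#'
#' @param host_genome,microbe_genome [generate_genome()] objects.
#' @param segment DNA string over `{A,C,G,T}`.
#' @param host_pos,microbe_pos Insertion offsets (0-based; the segment starts
#'   at this position in the modified genome).
#' @return List with modified `host` and `microbe` genomes.
#' @export
inject_shared_segment <- function(host_genome, microbe_genome, segment,
                                  host_pos, microbe_pos) {
  assert_dna(toupper(segment), "segment", allow_n = FALSE)
  splice <- function(genome, pos) {
    n <- nchar(genome$sequence)
    if (pos < 0 || pos > n) {
      stop("insertion position ", pos, " outside genome of length ", n,
           call. = FALSE)
    }
    genome$sequence <- paste0(substr(genome$sequence, 1L, pos),
                              toupper(segment),
                              substr(genome$sequence, pos + 1L, n))
    genome
  }
  list(host = splice(host_genome, host_pos),
       microbe = splice(microbe_genome, microbe_pos))
}

#' Read simulation configuration
#'
#' @param n_reads Number of reads (read pairs, when `paired`).
#' @param read_length Read length in bases (default 150).
#' @param error_rate Per-base substitution probability in `[0, 1)`; each
#'   erroneous base is replaced by a uniformly chosen different base.
#' @param paired Emit inward-facing mate pairs from fragments of fixed
#'   `fragment_length` (no size jitter).
#' @param fragment_length Fragment length for paired mode (default 300).
#' @param host_proportion Host fraction used by [mix_reads()] (default 0.5).
#' @param seed RNG seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_reads, read_length = 150L, error_rate = 0,
                              paired = FALSE, fragment_length = 300L,
                              host_proportion = 0.5, seed = 1L) {
  stopifnot(n_reads >= 1, read_length >= 1,
            error_rate >= 0, error_rate < 1,
            host_proportion >= 0, host_proportion <= 1,
            fragment_length >= read_length)
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, paired = isTRUE(paired),
                 fragment_length = as.integer(fragment_length),
                 host_proportion = host_proportion, seed = as.integer(seed)),
            class = "simulation_config")
}

add_substitutions <- function(sequences, error_rate) {
  if (error_rate <= 0) return(sequences)
  bases <- c("A", "C", "G", "T")
  vapply(sequences, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < error_rate)
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate labeled reads from a genome
#'
#' Start positions are uniform over the valid range, strands uniform, and
#' each base is substituted independently with probability
#' `config$error_rate`. The recorded source interval is always on the forward
#' strand of the genome (0-based, half-open); minus-strand reads are the
#' reverse complement of that interval. Quality strings are constant Q37.
#'
#' @param genome A [generate_genome()] object (or any `synthetic_genome`).
#' @param config A [simulation_config()].
#' @return `data.frame`: [read_records()] columns plus `truth_label`,
#'   `genome_id`, `start`, `end`, `strand`.
#' @export
simulate_reads <- function(genome, config) {
  stopifnot(inherits(config, "simulation_config"))
  glen <- nchar(genome$sequence)
  L <- config$read_length
  if (glen < max(L, if (config$paired) config$fragment_length else L)) {
    stop("genome shorter than the simulated read/fragment length", call. = FALSE)
  }
  with_rng_seed(config$seed, {
    n <- config$n_reads
    span <- if (config$paired) config$fragment_length else L
    start <- sample.int(glen - span + 1L, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    if (!config$paired) {
      seqs <- substring(genome$sequence, start + 1L, start + L)
      seqs[strand == "-"] <- reverse_complement(seqs[strand == "-"])
      out <- read_records(sprintf("%s_r%06d", genome$id, seq_len(n)),
                          add_substitutions(seqs, config$error_rate))
      out$truth_label <- genome$label
      out$genome_id <- genome$id
      out$start <- start
      out$end <- start + L
      out$strand <- strand
    } else {
      # inward-facing mates: mate 1 from the fragment's 5' end on the
      # fragment strand, mate 2 the reverse complement of its 3' end
      left <- substring(genome$sequence, start + 1L, start + L)
      right <- substring(genome$sequence, start + span - L + 1L, start + span)
      m1 <- ifelse(strand == "+", left, reverse_complement(right))
      m2 <- ifelse(strand == "+", reverse_complement(right), left)
      ids <- sprintf("%s_p%06d", genome$id, seq_len(n))
      out <- read_records(rep(ids, 2L),
                          add_substitutions(c(m1, m2), config$error_rate),
                          mate = rep(1:2, each = n))
      out$truth_label <- genome$label
      out$genome_id <- genome$id
      out$start <- rep(ifelse(strand == "+", start, start + span - L),
                       2L)[seq_len(2L * n)]
      # mate 2 covers the opposite fragment end
      s2 <- ifelse(strand == "+", start + span - L, start)
      out$start[seq_len(n) + n] <- s2
      out$end <- out$start + L
      out$strand <- c(strand, ifelse(strand == "+", "-", "+"))
    }
    out
  })
}

#' Mix labeled host and microbe reads into one shuffled dataset
#'
#' @param host_reads,microbe_reads Labeled read tables from
#'   [simulate_reads()].
#' @param host_proportion Fraction of host reads in the output.
#' @param n_total Output size; defaults to the largest mixture of the stated
#'   composition the inputs can supply.
#' @param seed Shuffle seed.
#' @return Shuffled labeled read table with exactly
#'   `round(n_total * host_proportion)` host reads.
#' @export
mix_reads <- function(host_reads, microbe_reads, host_proportion = 0.5,
                      n_total = NULL, seed = 1L) {
  stopifnot(host_proportion >= 0, host_proportion <= 1)
  if (is.null(n_total)) {
    n_total <- if (host_proportion %in% c(0, 1)) {
      if (host_proportion == 1) nrow(host_reads) else nrow(microbe_reads)
    } else {
      min(floor(nrow(host_reads) / host_proportion),
          floor(nrow(microbe_reads) / (1 - host_proportion)))
    }
  }
  n_host <- round(n_total * host_proportion)
  n_microbe <- n_total - n_host
  if (n_host > nrow(host_reads) || n_microbe > nrow(microbe_reads)) {
    stop("not enough reads for the requested mixture", call. = FALSE)
  }
  out <- rbind(utils::head(host_reads, n_host),
               utils::head(microbe_reads, n_microbe))
  with_rng_seed(seed, out[sample.int(nrow(out)), , drop = FALSE])
}

#' Write a ground-truth table as TSV
#'
#' @param reads Labeled read table from [simulate_reads()] / [mix_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(reads, path) {
  utils::write.table(
    reads[, c("read_id", "truth_label", "genome_id", "start", "end", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth table from TSV
#' @param path TSV written by [write_truth_table()].
#' @return `data.frame` with the truth columns.
#' @export
read_truth_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
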