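# Synthetic re-identification cohorts.
#
# Emulates the two inputs of the re-identification model: a genotype panel of
# unrelated samples drawn under Hardy-Weinberg equilibrium, and per-sample
# metagenome pileups in which host-derived reads are scarce (site coverage is
# Poisson with a small mean, as in fecal sequencing after host filtration).
# Given the donor's genotype, each covering read supports the reference
# allele with the probability implied by the per-site error model:
# 1 - eps (g = 0), 1/2 (g = 1), eps (g = 2).

#' Generate a synthetic genotype/metagenome cohort
#'
#' @param n_samples Number of individuals (each contributes one genotype and
#'   one metagenome whose true donor is itself); at least 2.
#' @param n_sites Number of biallelic SNP sites.
#' @param mean_depth Poisson mean of per-site metagenome read depth; values
#'   well below 1 give the sparse coverage typical of filtered fecal data.
#' @param epsilon Per-base error probability used for read generation.
#' @param seed RNG seed; the cohort is a pure function of the arguments.
#' @param freq_sampler Function `n -> p` drawing alternative allele
#'   frequencies; default uniform on `[0.05, 0.95]`.
#' @return List with `panel` (sites x samples genotype matrix), `freqs`
#'   (named frequency vector), `pileups` (named list of pileup tables, one
#'   per sample's metagenome) and `donors` (metagenome id -> genotype id).
#' @export
synthesize_cohort <- function(n_samples, n_sites, mean_depth = 0.1,
                              epsilon = 1e-6, seed = 1L,
                              freq_sampler = NULL) {
  stopifnot(n_samples >= 2, n_sites >= 1, mean_depth > 0)
  freq_sampler <- freq_sampler %||% function(n) stats::runif(n, 0.05, 0.95)
  with_rng_seed(seed, {
    site_ids <- sprintf("snp%05d", seq_len(n_sites))
    sample_ids <- sprintf("sample%03d", seq_len(n_samples))
    p <- stats::setNames(freq_sampler(n_sites), site_ids)
    # genotypes under HWE, independent across sites and samples
    panel <- matrix(
      stats::rbinom(n_sites * n_samples, 2L, rep(p, times = n_samples)),
      nrow = n_sites, dimnames = list(site_ids, sample_ids))
    ref_prob <- c(`0` = 1 - epsilon, `1` = 0.5, `2` = epsilon)
    pileups <- lapply(seq_len(n_samples), function(j) {
      n <- stats::rpois(n_sites, mean_depth)
      covered <- which(n > 0)
      g <- panel[covered, j]
      k <- stats::rbinom(length(covered), n[covered],
                         ref_prob[as.character(g)])
      data.frame(site_id = site_ids[covered], n = n[covered], k = k)
    })
    names(pileups) <- paste0("meta_", sample_ids)
    list(panel = panel, freqs = p, pileups = pileups,
         donors = stats::setNames(sample_ids, names(pileups)))
  })
}

#' Random read attrition of pileup sets
#'
#' Models host filtration removing human reads: every read (site-coverage
#' unit) is retained independently with probability `retention_fraction`,
#' and `n`, `k` are recomputed. Sites losing all reads drop out of the
#' pileup.
#'
#' @param pileup_sets Named list of pileup tables (`site_id`, `n`, `k`).
#' @param retention_fraction Probability each read survives, in `[0, 1]`.
#' @param seed RNG seed.
#' @return Pileup sets of the same shape with thinned counts.
#' @export
attrition_experiment <- function(pileup_sets, retention_fraction, seed = 1L) {
  stopifnot(retention_fraction >= 0, retention_fraction <= 1)
  with_rng_seed(seed, {
    lapply(pileup_sets, function(pu) {
      if (nrow(pu) == 0) return(pu)
      k_new <- stats::rbinom(nrow(pu), pu$k, retention_fraction)
      alt_new <- stats::rbinom(nrow(pu), pu$n - pu$k, retention_fraction)
      out <- data.frame(site_id = pu$site_id, n = k_new + alt_new, k = k_new)
      out[out$n >= 1, , drop = FALSE]
    })
  })
}
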