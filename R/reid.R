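# Genotype-likelihood re-identification model.
#
# Given (i) per-SNP pileup counts (n reads covering the site, k supporting
# the reference allele) extracted from putatively microbial sequencing data
# and (ii) a biallelic genotype panel, the model scores how likely each
# candidate genotype is to have produced the observed reads. With per-base
# error probability eps and g in {0, 1, 2} alternative alleles,
#
#   L(g, n, k) = (1/2^n) * [(2-g) eps + g (1-eps)]^(n-k)
#                        * [g eps + (2-g) (1-eps)]^k
#
# and the likelihood score LS of a genotype is the sum of ln L over sites.
# Population moments under Hardy-Weinberg genotype frequencies give E(LS)
# and V(LS); (LS - E)/sqrt(V) is referred to the standard normal for an
# upper one-sided P-value, and Bonferroni thresholds over the number of
# tests call matches. Sites are first reduced to an approximately
# independent set by greedy sliding-window LD pruning on genotype dosages.

#' Re-identification configuration
#'
#' @param epsilon Per-base error probability (default `1e-6`).
#' @param prune_window,prune_step,prune_r2 Sliding-window LD pruning
#'   parameters: window size in sites, step in sites, and the squared
#'   Pearson-correlation threshold above which the later site of a pair is
#'   dropped. Defaults 100 / 30 / 0.1.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List of class `reid_config`.
#' @export
reid_config <- function(epsilon = 1e-6, prune_window = 100L, prune_step = 30L,
                        prune_r2 = 0.1, alpha = 0.05) {
  stopifnot(epsilon > 0, epsilon < 0.5, prune_window >= 1, prune_step >= 1,
            prune_r2 >= 0, alpha > 0, alpha < 1)
  structure(list(epsilon = epsilon, prune_window = as.integer(prune_window),
                 prune_step = as.integer(prune_step), prune_r2 = prune_r2,
                 alpha = alpha),
            class = "reid_config")
}

# log of the per-site likelihood, vectorized over sites
site_log_likelihood <- function(g, n, k, epsilon) {
  if (any(!g %in% c(0, 1, 2))) {
    stop("genotype must be 0, 1 or 2", call. = FALSE)
  }
  if (any(k < 0) || any(k > n)) {
    stop("reference read counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  alt_term <- (2 - g) * epsilon + g * (1 - epsilon)   # per-read alt probability * 2
  ref_term <- g * epsilon + (2 - g) * (1 - epsilon)   # per-read ref probability * 2
  -n * log(2) + (n - k) * log(alt_term) + k * log(ref_term)
}

#' Per-site genotype likelihood
#'
#' `L(g, n, k) = (1/2^n) [(2-g)e + g(1-e)]^(n-k) [g e + (2-g)(1-e)]^k`.
#' Computed in log space; for `g = 1` the value is exactly `2^-n` regardless
#' of `k` and `epsilon`.
#'
#' @param g Genotype: 0 (ref/ref), 1 (het), 2 (alt/alt).
#' @param n Reads covering the site.
#' @param k Reads supporting the reference allele.
#' @param epsilon Per-base error probability.
#' @param log Return the natural log of the likelihood.
#' @return Likelihood (or its log), vectorized over sites.
#' @export
site_likelihood <- function(g, n, k, epsilon = 1e-6, log = FALSE) {
  ll <- site_log_likelihood(g, n, k, epsilon)
  if (log) ll else exp(ll)
}

#' Likelihood score of a genotype against a pileup set
#'
#' `LS = sum_i ln L(g_i, n_i, k_i)` over the pileup sites. Sites whose
#' genotype is missing (`NA`) are skipped and counted.
#'
#' @param genotypes Named vector of genotypes in `{0,1,2}` (names = site ids),
#'   `NA` allowed.
#' @param pileups `data.frame` with columns `site_id`, `n`, `k`.
#' @param epsilon Per-base error probability.
#' @return List with `ls`, `n_sites` (sites scored) and `n_missing`.
#' @export
likelihood_score <- function(genotypes, pileups, epsilon = 1e-6) {
  g <- genotypes[match(pileups$site_id, names(genotypes))]
  known <- !is.na(g)
  if (!any(known)) {
    stop("no overlapping sites between genotype and pileups", call. = FALSE)
  }
  ls <- sum(site_log_likelihood(g[known], pileups$n[known], pileups$k[known],
                                epsilon))
  list(ls = ls, n_sites = sum(known), n_missing = sum(!known))
}

#' Hardy-Weinberg genotype frequencies
#'
#' @param p Alternative allele frequency in `[0, 1]`.
#' @return Numeric vector `(P0, P1, P2) = ((1-p)^2, 2p(1-p), p^2)`.
#' @export
hwe_probs <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  c((1 - p)^2, 2 * p * (1 - p), p^2)
}

# per-site population mean and variance of ln L under HWE
site_moments <- function(p, n, k, epsilon) {
  ll <- vapply(0:2, site_log_likelihood, numeric(length(n)),
               n = n, k = k, epsilon = epsilon)
  ll <- matrix(ll, ncol = 3)
  pg <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  e <- rowSums(pg * ll)
  v <- rowSums(pg * (ll - e)^2)
  list(e = e, v = v)
}

#' Population expectation of the likelihood score
#'
#' `E(LS) = sum_i sum_g P(g, p_i) ln L(g, n_i, k_i)` under Hardy-Weinberg
#' genotype frequencies.
#'
#' @param freqs Named vector of alternative allele frequencies (names =
#'   site ids) covering every pileup site.
#' @inheritParams likelihood_score
#' @return Numeric `E`.
#' @export
expected_score <- function(freqs, pileups, epsilon = 1e-6) {
  p <- freqs[match(pileups$site_id, names(freqs))]
  if (anyNA(p)) {
    stop("allele frequency missing for site(s): ",
         paste(utils::head(pileups$site_id[is.na(p)], 3), collapse = ", "),
         call. = FALSE)
  }
  sum(site_moments(p, pileups$n, pileups$k, epsilon)$e)
}

#' Population variance of the likelihood score
#'
#' `V(LS) = sum_i sum_g P(g, p_i) [ln L(g, n_i, k_i) - E(LS_i)]^2`; per-site
#' variances are summed under the independence assumption.
#'
#' @inheritParams expected_score
#' @return Numeric `V` (non-negative).
#' @export
variance_score <- function(freqs, pileups, epsilon = 1e-6) {
  p <- freqs[match(pileups$site_id, names(freqs))]
  if (anyNA(p)) {
    stop("allele frequency missing for site(s): ",
         paste(utils::head(pileups$site_id[is.na(p)], 3), collapse = ", "),
         call. = FALSE)
  }
  sum(site_moments(p, pileups$n, pileups$k, epsilon)$v)
}

#' Standardized likelihood score and P-value
#'
#' `z = (LS - E) / sqrt(V)`; the P-value is the upper one-sided standard
#' normal tail (a higher-than-population likelihood score indicates the
#' candidate genotype is the donor).
#'
#' @param ls,e,v Likelihood score and its population moments.
#' @return List with `z` and `p`.
#' @export
standardized_pvalue <- function(ls, e, v) {
  if (any(v <= 0)) {
    stop("population variance must be positive to standardize", call. = FALSE)
  }
  z <- (ls - e) / sqrt(v)
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Greedy sliding-window LD pruning
#'
#' Slides a window of `window` sites advancing by `step`; within each window,
#' kept sites are scanned pairwise in index order and the later site of any
#' pair whose squared Pearson correlation of genotype dosages exceeds
#' `r2_max` is dropped. Monomorphic sites (constant dosage column) carry no
#' correlation signal and are always kept. Deterministic.
#'
#' @param panel Numeric matrix of genotypes in `{0,1,2}` (`NA` allowed),
#'   sites in rows (rownames = site ids), samples in columns; at least two
#'   samples.
#' @param window,step Window size and step in sites (defaults 100 / 30).
#' @param r2_max Squared-correlation threshold (default 0.1).
#' @return Character vector of kept site ids (row order preserved).
#' @export
ld_prune <- function(panel, window = 100L, step = 30L, r2_max = 0.1) {
  stopifnot(is.matrix(panel))
  if (ncol(panel) < 2) {
    stop("LD pruning needs at least two samples", call. = FALSE)
  }
  n_sites <- nrow(panel)
  ids <- rownames(panel) %||% as.character(seq_len(n_sites))
  if (n_sites == 0) return(character())
  kept <- rep(TRUE, n_sites)
  starts <- seq(1L, n_sites, by = step)
  for (s in starts) {
    win <- s:min(s + window - 1L, n_sites)
    active <- win[kept[win]]
    if (length(active) < 2) next
    cm <- suppressWarnings(stats::cor(t(panel[active, , drop = FALSE]),
                                      use = "pairwise.complete.obs"))
    cm[is.na(cm)] <- 0  # monomorphic or disjoint-coverage pairs
    for (a in seq_along(active)) {
      if (!kept[active[a]]) next
      for (b in seq_along(active)) {
        if (b <= a || !kept[active[b]]) next
        if (cm[a, b]^2 > r2_max) kept[active[b]] <- FALSE
      }
    }
  }
  ids[kept]
}

#' Bonferroni significance thresholds
#'
#' @param alpha Family-wise level.
#' @param m_meta,m_geno Numbers of metagenome and genotype samples tested.
#' @return List with `pairwise` (`alpha / (m_meta * m_geno)`) and
#'   `per_metagenome` (`alpha / m_meta`).
#' @export
bonferroni_thresholds <- function(alpha, m_meta, m_geno) {
  stopifnot(m_meta >= 1, m_geno >= 1)
  list(pairwise = alpha / (m_meta * m_geno),
       per_metagenome = alpha / m_meta)
}

#' Re-identification of metagenome donors from a genotype panel
#'
#' For every (metagenome, genotype) pair: restricts to LD-pruned panel sites
#' covered by at least one read with a non-degenerate population frequency
#' (`0 < p < 1`), computes the likelihood score, its Hardy-Weinberg
#' population moments, the standardized score and the upper one-sided
#' P-value, and calls matches at the pairwise (`alpha / (M_meta * M_geno)`)
#' and per-metagenome (`alpha / M_meta`) Bonferroni thresholds. Pruning is
#' run per metagenome on its covered-site list. Metagenomes with no usable
#' covered site are flagged insufficient and excluded from the pair table.
#'
#' @param panel Genotype matrix as in [ld_prune()].
#' @param pileup_sets Named list of pileup `data.frame`s (`site_id`, `n`,
#'   `k`), one per metagenome; sites with `n = 0` are ignored.
#' @param freqs Named vector of alternative allele frequencies.
#' @param config A [reid_config()].
#' @return List of class `reid_result`: `pairs` (`data.frame` with one row
#'   per scored pair), `thresholds`, and `insufficient` (metagenome ids
#'   excluded for lack of covered sites).
#' @export
reidentify <- function(panel, pileup_sets, freqs, config = reid_config()) {
  stopifnot(is.matrix(panel), inherits(config, "reid_config"))
  m_meta <- length(pileup_sets)
  m_geno <- ncol(panel)
  thr <- bonferroni_thresholds(config$alpha, m_meta, m_geno)
  geno_ids <- colnames(panel) %||% paste0("sample", seq_len(m_geno))
  meta_ids <- names(pileup_sets) %||% paste0("metagenome", seq_len(m_meta))
  usable_p <- freqs > 0 & freqs < 1

  rows <- list()
  insufficient <- character()
  for (m in seq_len(m_meta)) {
    pu <- pileup_sets[[m]]
    pu <- pu[pu$n >= 1, , drop = FALSE]
    covered <- intersect(rownames(panel), pu$site_id)
    covered <- covered[usable_p[covered]]
    if (length(covered) == 0) {
      insufficient <- c(insufficient, meta_ids[m])
      next
    }
    sub_panel <- panel[covered, , drop = FALSE]
    pruned <- if (length(covered) > 1) {
      ld_prune(sub_panel, config$prune_window, config$prune_step,
               config$prune_r2)
    } else {
      covered
    }
    pu <- pu[match(pruned, pu$site_id), , drop = FALSE]
    mom <- site_moments(freqs[pruned], pu$n, pu$k, config$epsilon)
    e <- sum(mom$e)
    v <- sum(mom$v)
    for (j in seq_len(m_geno)) {
      g <- panel[pruned, j]
      known <- !is.na(g)
      if (!any(known)) next
      ls <- sum(site_log_likelihood(g[known], pu$n[known], pu$k[known],
                                    config$epsilon))
      # moments restricted to the same known-genotype sites
      e_j <- sum(mom$e[known])
      v_j <- sum(mom$v[known])
      zp <- standardized_pvalue(ls, e_j, v_j)
      rows[[length(rows) + 1L]] <- data.frame(
        metagenome = meta_ids[m], genotype = geno_ids[j],
        n_sites = sum(known), ls = ls, e = e_j, v = v_j,
        z = zp$z, p = zp$p,
        match_pairwise = zp$p < thr$pairwise,
        match_per_metagenome = zp$p < thr$per_metagenome)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metagenome = character(), genotype = character(),
               n_sites = integer(), ls = numeric(), e = numeric(),
               v = numeric(), z = numeric(), p = numeric(),
               match_pairwise = logical(), match_per_metagenome = logical())
  structure(list(pairs = pairs, thresholds = thr,
                 insufficient = insufficient,
                 m_meta = m_meta, m_geno = m_geno),
            class = "reid_result")
}

#' @export
print.reid_result <- function(x, ...) {
  cat("<reid_result> ", x$m_meta, " metagenome x ", x$m_geno,
      " genotype samples; ", sum(x$pairs$match_pairwise),
      " pairwise-significant pair(s); ", length(x$insufficient),
      " metagenome(s) with insufficient reads\n", sep = "")
  invisible(x)
}

#' Read a genotype panel from TSV
#'
#' Rows are sites, with a `site_id` column followed by one column per sample
#' holding 0/1/2 or NA.
#'
#' @param path TSV path.
#' @return Genotype matrix (sites x samples) for [reidentify()].
#' @export
read_genotype_panel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "site_id"), drop = FALSE])
  storage.mode(m) <- "numeric"
  bad <- !is.na(m) & !m %in% c(0, 1, 2)
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  rownames(m) <- df$site_id
  m
}

#' Read allele frequencies from TSV (`site_id`, `p`)
#' @param path TSV path.
#' @return Named numeric vector of alternative allele frequencies.
#' @export
read_allele_frequencies <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$p, df$site_id)
}

#' Read a pileup table from TSV (`site_id`, `n`, `k`)
#' @param path TSV path.
#' @return `data.frame` with sites having `n >= 1`.
#' @export
read_pileup <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (any(df$k > df$n) || any(df$k < 0)) {
    stop("pileup counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  df[df$n >= 1, , drop = FALSE]
}
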