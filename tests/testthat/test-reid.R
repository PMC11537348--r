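test_that("per-site likelihoods match closed-form identities", {
  # heterozygous: L = 2^-n regardless of k and epsilon
  expect_equal(site_likelihood(1, 4, 2), 2^-4)
  expect_equal(site_likelihood(1, 4, 0, epsilon = 0.01), 2^-4)
  # homozygous reference observed without error
  expect_equal(site_likelihood(0, 3, 3, epsilon = 1e-6), (1 - 1e-6)^3)
  # two reference reads from alt/alt require two errors
  expect_equal(site_likelihood(2, 2, 2, epsilon = 1e-6), 1e-12)
  expect_error(site_likelihood(3, 2, 1), "genotype must be")
  expect_error(site_likelihood(0, 2, 3), "0 <= k <= n")
})

test_that("likelihood scores sum per-site logs (naive-oracle agreement)", {
  # all heterozygous: LS = -ln(2) * sum(n)
  pu <- data.frame(site_id = c("a", "b", "c"), n = c(2, 5, 1), k = c(0, 3, 1))
  g_het <- stats::setNames(c(1, 1, 1), c("a", "b", "c"))
  expect_equal(likelihood_score(g_het, pu)$ls, -log(2) * 8)

  single <- likelihood_score(stats::setNames(0, "s"),
                             data.frame(site_id = "s", n = 1, k = 1))
  expect_equal(single$ls, log(1 - 1e-6))

  # naive product-then-log oracle; reads drawn consistently with the
  # genotype at a moderate error rate so the product stays in double range
  withr::local_seed(71)
  n_sites <- 50
  eps <- 0.01
  ids <- sprintf("s%02d", seq_len(n_sites))
  g <- stats::setNames(sample(0:2, n_sites, TRUE), ids)
  pu <- data.frame(site_id = ids, n = sample(1:6, n_sites, TRUE))
  pu$k <- stats::rbinom(n_sites, pu$n, c(1 - eps, 0.5, eps)[g + 1])
  naive <- log(prod(vapply(seq_len(n_sites), function(i) {
    site_likelihood(g[i], pu$n[i], pu$k[i], epsilon = eps)
  }, numeric(1))))
  expect_equal(likelihood_score(g, pu, epsilon = eps)$ls, naive,
               tolerance = 1e-9)

  # missing genotypes skip the site and are reported
  g_na <- g
  g_na[1] <- NA
  expect_equal(likelihood_score(g_na, pu)$n_missing, 1)
  expect_error(likelihood_score(stats::setNames(NA, "s"),
                                data.frame(site_id = "s", n = 1, k = 1)),
               "no overlapping sites")
})

test_that("Hardy-Weinberg frequencies are correct and sum to one", {
  expect_equal(hwe_probs(0), c(1, 0, 0))
  expect_equal(hwe_probs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_probs(0.2), c(0.64, 0.32, 0.04))
  for (p in seq(0, 1, by = 0.1)) {
    expect_equal(sum(hwe_probs(p)), 1, tolerance = 1e-12)
  }
})

test_that("population moments match hand evaluation and Monte Carlo", {
  # degenerate population: everyone is ref/ref
  pu1 <- data.frame(site_id = "s", n = 2, k = 1)
  expect_equal(expected_score(c(s = 0), pu1), site_likelihood(0, 2, 1, log = TRUE))
  expect_equal(variance_score(c(s = 0), pu1), 0)

  # single site, p = 0.5, n = 1, k = 1: three-branch sum evaluates to
  # 0.25 ln(1-e) + 0.5 ln(1/2) + 0.25 ln(e) = -3.8004516 at e = 1e-6
  pu <- data.frame(site_id = "s", n = 1, k = 1)
  expect_equal(expected_score(c(s = 0.5), pu), -3.8004516, tolerance = 1e-7)
  branch <- c(log(1 - 1e-6), log(0.5), log(1e-6))
  e_hand <- sum(hwe_probs(0.5) * branch)
  v_hand <- sum(hwe_probs(0.5) * (branch - e_hand)^2)
  expect_equal(variance_score(c(s = 0.5), pu), v_hand)

  # Monte-Carlo oracle over a random panel
  withr::local_seed(73)
  ids <- sprintf("s%02d", 1:20)
  p <- stats::setNames(stats::runif(20, 0.1, 0.9), ids)
  pu <- data.frame(site_id = ids, n = sample(1:4, 20, TRUE))
  pu$k <- stats::rbinom(20, pu$n, 0.5)
  draws <- 1e5
  g_mat <- matrix(stats::rbinom(20 * draws, 2, rep(p, draws)), nrow = 20)
  ll_mat <- matrix(site_likelihood(as.vector(g_mat), rep(pu$n, draws),
                                   rep(pu$k, draws), log = TRUE), nrow = 20)
  ls_draws <- colSums(ll_mat)
  e <- expected_score(p, pu)
  v <- variance_score(p, pu)
  se <- stats::sd(ls_draws) / sqrt(draws)
  expect_lt(abs(mean(ls_draws) - e), 3 * se)
  expect_equal(stats::var(ls_draws), v, tolerance = 0.05)

  expect_error(expected_score(c(other = 0.5), pu1), "frequency missing")
})

test_that("standardization and P-values follow the normal model", {
  expect_equal(standardized_pvalue(-5, -5, 2)$p, 0.5)
  expect_equal(standardized_pvalue(-5, -5, 2)$z, 0)
  q <- standardized_pvalue(10 + 1.959964 * sqrt(4), 10, 4)
  expect_equal(q$p, 0.025, tolerance = 1e-5)
  expect_error(standardized_pvalue(1, 0, 0), "variance must be positive")

  # integral oracle for the upper tail
  withr::local_seed(79)
  for (z in stats::rnorm(10, sd = 2)) {
    p <- standardized_pvalue(z, 0, 1)$p
    oracle <- stats::integrate(stats::dnorm, z, Inf, rel.tol = 1e-12)$value
    expect_equal(p, oracle, tolerance = 1e-9)
  }
})

test_that("LD pruning drops correlated later sites and keeps independent ones", {
  withr::local_seed(83)
  # duplicated site: the later copy is dropped
  base <- matrix(stats::rbinom(40 * 6, 2, 0.4), nrow = 6,
                 dimnames = list(sprintf("s%d", 1:6), NULL))
  base["s4", ] <- base["s2", ]
  kept <- ld_prune(base, window = 10, step = 5, r2_max = 0.1)
  expect_true("s2" %in% kept)
  expect_false("s4" %in% kept)

  # mutually independent sites on many samples all survive
  indep <- matrix(stats::rbinom(20 * 500, 2, 0.5), nrow = 20,
                  dimnames = list(sprintf("i%02d", 1:20), NULL))
  expect_equal(length(ld_prune(indep, 100, 30, 0.1)), 20)

  # no surviving within-window pair violates the threshold
  corr <- matrix(stats::rbinom(30 * 200, 2, 0.5), nrow = 30,
                 dimnames = list(sprintf("c%02d", 1:30), NULL))
  corr[seq(2, 30, by = 3), ] <- corr[seq(1, 29, by = 3), ]  # planted pairs
  kept <- ld_prune(corr, window = 30, step = 10, r2_max = 0.1)
  sub <- corr[kept, , drop = FALSE]
  cm <- suppressWarnings(stats::cor(t(sub)))
  diag(cm) <- 0
  expect_true(all(cm^2 <= 0.1 + 1e-12, na.rm = TRUE))

  expect_equal(ld_prune(base[0, , drop = FALSE]), character())
  expect_error(ld_prune(base[, 1, drop = FALSE]), "at least two samples")
})

test_that("Bonferroni thresholds and degenerate re-identification calls", {
  thr <- bonferroni_thresholds(0.05, 343, 343)
  expect_equal(signif(thr$pairwise, 3), 4.25e-7)
  expect_equal(signif(thr$per_metagenome, 3), 1.46e-4)

  single <- bonferroni_thresholds(0.05, 1, 1)
  expect_equal(single$pairwise, 0.05)
  expect_equal(single$per_metagenome, 0.05)
})

test_that("synthetic cohorts are deterministic and match their error model", {
  a <- synthesize_cohort(5, 200, mean_depth = 2, seed = 91)
  b <- synthesize_cohort(5, 200, mean_depth = 2, seed = 91)
  expect_identical(a, b)

  # pooled reference fraction at het sites is ~1/2
  big <- synthesize_cohort(4, 3000, mean_depth = 1.5, seed = 92)
  ks <- ns <- 0
  for (j in seq_len(4)) {
    pu <- big$pileups[[j]]
    het <- big$panel[pu$site_id, j] == 1
    ks <- ks + sum(pu$k[het])
    ns <- ns + sum(pu$n[het])
  }
  expect_gt(ns, 500)
  expect_lt(abs(ks / ns - 0.5), 3 * sqrt(0.25 / ns))
})

test_that("re-identification recovers donors and flags starved metagenomes", {
  cohort <- synthesize_cohort(8, 600, mean_depth = 0.5, seed = 93)
  res <- reidentify(cohort$panel, cohort$pileups, cohort$freqs)
  expect_s3_class(res$pairs, "data.frame")
  expect_equal(res$m_meta, 8)
  # every metagenome's top likelihood score belongs to its donor
  for (m in names(cohort$pileups)) {
    sub <- res$pairs[res$pairs$metagenome == m, ]
    expect_equal(sub$genotype[which.max(sub$ls)],
                 unname(cohort$donors[m]))
  }
  # the donor is also the most significant candidate for its metagenome,
  # and clearly elevated above the population (small panels prune hard, so
  # full Bonferroni significance needs the larger cohort sizes)
  donor_rows <- res$pairs[paste0("meta_", res$pairs$genotype) ==
                            res$pairs$metagenome, ]
  for (m in names(cohort$pileups)) {
    sub <- res$pairs[res$pairs$metagenome == m, ]
    expect_equal(sub$genotype[which.min(sub$p)], unname(cohort$donors[m]))
  }
  expect_gt(mean(donor_rows$z), 1.5)

  # total attrition starves every metagenome
  gone <- attrition_experiment(cohort$pileups, 0, seed = 94)
  res0 <- reidentify(cohort$panel, gone, cohort$freqs)
  expect_equal(length(res0$insufficient), 8)
  expect_equal(nrow(res0$pairs), 0)

  # full retention is the identity
  same <- attrition_experiment(cohort$pileups, 1, seed = 94)
  for (j in seq_along(same)) {
    a <- same[[j]]
    b <- cohort$pileups[[j]]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
  }
})
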