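test_that("genome generation is a pure function of its seed", {
  a <- generate_genome(1000, seed = 7, label = "host")
  b <- generate_genome(1000, seed = 7, label = "host")
  c <- generate_genome(1000, seed = 8, label = "host")
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, c$sequence))
  expect_error(generate_genome(100, seed = 1), "length >= 300")
})

test_that("base composition of a large genome is uniform within binomial bounds", {
  g <- generate_genome(1e5, seed = 9, label = "microbe")
  freq <- table(strsplit(g$sequence, "", fixed = TRUE)[[1]]) / 1e5
  # 3 sigma for a binomial proportion at p = 0.25, n = 1e5 is ~0.004
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("holdout excises the stated interval and nothing else", {
  g <- generate_genome(1000, seed = 3, label = "host")
  ho <- holdout_region(g, 400, 700)
  expect_equal(nchar(ho$filter_reference$sequence), 700)
  expect_identical(ho$full_reference$sequence, g$sequence)
  expect_identical(ho$filter_reference$sequence,
                   paste0(substr(g$sequence, 1, 400),
                          substr(g$sequence, 701, 1000)))
  expect_error(holdout_region(g, 700, 400), "invalid holdout")
  expect_error(holdout_region(g, 0, 1001), "invalid holdout")
})

test_that("reads from a held-out region map only to the full reference", {
  g <- generate_genome(1000, seed = 19, label = "host")
  ho <- holdout_region(g, 400, 700)
  idx_full <- build_index(c(full = ho$full_reference$sequence))
  idx_filt <- build_index(c(filt = ho$filter_reference$sequence))
  inside <- substr(g$sequence, 451, 600)   # wholly inside the holdout
  outside <- substr(g$sequence, 101, 250)  # wholly retained
  expect_gte(max_exact_match(inside, idx_full), 31)
  expect_lt(max_exact_match(inside, idx_filt), 31)
  expect_gte(max_exact_match(outside, idx_full), 31)
  expect_gte(max_exact_match(outside, idx_filt), 31)
})

test_that("an injected shared segment links host reads to the microbe genome", {
  host <- generate_genome(2000, seed = 21, label = "host")
  microbe <- generate_genome(2000, seed = 22, label = "microbe")
  seg <- strrep("AC", 100)  # 200 bp, period-2 low complexity
  mod <- inject_shared_segment(host, microbe, seg, 1000, 500)
  expect_equal(nchar(mod$host$sequence), 2200)
  expect_equal(nchar(mod$microbe$sequence), 2200)

  host_read <- substr(mod$host$sequence, 1026, 1175)  # inside the segment
  idx_microbe <- build_index(c(m = mod$microbe$sequence))
  expect_gte(max_exact_match(host_read, idx_microbe), 150)

  # a low-complexity read yields one long ramp: a single extracted run
  runs <- extract_runs(compute_pml(host_read, idx_microbe))
  expect_equal(nrow(runs), 1)
  expect_gte(runs$length, 150)

  unchanged <- inject_shared_segment(host, microbe, "", 0, 0)
  expect_identical(unchanged$host$sequence, host$sequence)
  expect_identical(unchanged$microbe$sequence, microbe$sequence)
})

test_that("error-free reads are exact substrings of their source interval", {
  g <- generate_genome(3000, seed = 25, label = "host")
  reads <- simulate_reads(g, simulation_config(n_reads = 40, seed = 26))
  for (i in seq_len(nrow(reads))) {
    src <- substr(g$sequence, reads$start[i] + 1, reads$end[i])
    if (reads$strand[i] == "-") src <- reverse_complement(src)
    expect_identical(reads$sequence[i], src)
  }
  expect_true(all(reads$end - reads$start == 150))
})

test_that("substitution counts match the binomial expectation", {
  g <- generate_genome(5000, seed = 27, label = "host")
  cfg <- simulation_config(n_reads = 3000, error_rate = 0.01, seed = 28)
  reads <- simulate_reads(g, cfg)
  mismatches <- vapply(seq_len(nrow(reads)), function(i) {
    src <- substr(g$sequence, reads$start[i] + 1, reads$end[i])
    if (reads$strand[i] == "-") src <- reverse_complement(src)
    sum(strsplit(src, "")[[1]] != strsplit(reads$sequence[i], "")[[1]])
  }, numeric(1))
  # mean L * e = 1.5; 3 sigma of the mean over 3000 reads is ~0.07
  expect_equal(mean(mismatches), 1.5, tolerance = 0.1 / 1.5)
})

test_that("simulation output is byte-identical across runs of the same seed", {
  g <- generate_genome(2000, seed = 31, label = "microbe")
  cfg <- simulation_config(n_reads = 25, error_rate = 0.02, seed = 32)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(g, cfg), f1)
  write_fastq(simulate_reads(g, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("mixtures honor the requested composition exactly", {
  g1 <- generate_genome(2000, seed = 41, label = "host")
  g2 <- generate_genome(2000, seed = 42, label = "microbe")
  h <- simulate_reads(g1, simulation_config(n_reads = 500, seed = 43))
  m <- simulate_reads(g2, simulation_config(n_reads = 700, seed = 44))

  fifty <- mix_reads(h, m, 0.5, seed = 45)
  expect_equal(sum(fifty$truth_label == "host"), 500)
  expect_equal(nrow(fifty), 1000)

  none <- mix_reads(h, m, 0, seed = 45)
  expect_equal(sum(none$truth_label == "host"), 0)

  thirty <- mix_reads(h, m, 0.3, n_total = 1000, seed = 45)
  expect_equal(sum(thirty$truth_label == "host"), 300)

  expect_error(mix_reads(h, m, 0.9, n_total = 1000, seed = 45),
               "not enough reads")
})

test_that("truth tables round-trip through TSV", {
  g <- generate_genome(1500, seed = 51, label = "host")
  reads <- simulate_reads(g, simulation_config(n_reads = 10, seed = 52))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(reads, tsv)
  back <- read_truth_table(tsv)
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$start, reads$start)
  expect_identical(back$truth_label, reads$truth_label)
})
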