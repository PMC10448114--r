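test_that("transcriptome truth is deterministic with an exact TOP count", {
  t1 <- simulate_transcriptome(n_transcripts = 1000, top_fraction = 0.1,
                               seed = 7)
  t2 <- simulate_transcriptome(n_transcripts = 1000, top_fraction = 0.1,
                               seed = 7)
  expect_identical(t1$transcripts, t2$transcripts)
  expect_identical(t1$mixtures, t2$mixtures)
  expect_identical(sum(t1$transcripts$is_top), 100L)

  t0 <- simulate_transcriptome(n_transcripts = 50, top_fraction = 0, seed = 8)
  expect_identical(sum(t0$transcripts$is_top), 0L)
  expect_error(simulate_transcriptome(n_transcripts = 0), "positive")
})

test_that("truth tables respect rate and mixture invariants", {
  tr <- simulate_transcriptome(n_transcripts = 300, seed = 9)
  expect_true(all(tr$transcripts$k_d > 0))
  expect_true(all(tr$transcripts$k_s > 0))
  w <- tr$mixtures[, c("w_short", "w_mid", "w_long")]
  expect_true(all(w >= 0))
  expect_equal(rowSums(as.matrix(w)), rep(1, nrow(w)), tolerance = 1e-12)
  expect_true(all(tr$mixtures$mean_short < tr$mixtures$mean_mid))
  expect_true(all(tr$mixtures$mean_mid < tr$mixtures$mean_long))
})

test_that("tail reads reproduce the configured mixture", {
  # single-component mixture, measurement noise off: empirical mean ~ 60
  tr <- simulate_transcriptome(n_transcripts = 20, top_fraction = 0,
                               tail_weights = c(0, 1, 0),
                               tail_sds = c(7, 8, 15), seed = 10)
  reads <- simulate_tail_reads(tr, "D0", depth = 500, seed = 11,
                               noise_sd = 0, qc_fail_fraction = 0)
  expect_gt(nrow(reads), 5000)
  expect_lt(abs(mean(reads$polya_length) - 60), 1)
  expect_true(all(reads$qc_tag == "PASS"))
  expect_error(simulate_tail_reads(tr, "D9"), "unknown condition")
})

test_that("QC failures occur at the configured rate", {
  tr <- simulate_transcriptome(n_transcripts = 50, seed = 12)
  reads <- simulate_tail_reads(tr, "D0", depth = 100, seed = 13,
                               qc_fail_fraction = 0.05)
  n <- nrow(reads)
  n_fail <- sum(reads$qc_tag != "PASS")
  expect_gt(n, 10000)
  expect_lt(abs(n_fail - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95))
})

test_that("a fixed seed gives byte-identical written tables", {
  tr <- simulate_transcriptome(n_transcripts = 10, seed = 14)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_polya_table(simulate_tail_reads(tr, "D0", depth = 20, seed = 15), p1)
  write_polya_table(simulate_tail_reads(tr, "D0", depth = 20, seed = 15), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("empirical tail distribution converges to the mixture law", {
  tr <- simulate_transcriptome(n_transcripts = 1, top_fraction = 0,
                               tail_weights = c(0, 0.6, 0.4),
                               baseline_mean_range = c(100, 100), seed = 16)
  reads <- simulate_tail_reads(tr, "D0", depth = 1e5, seed = 17,
                               noise_sd = 0, qc_fail_fraction = 0)
  mix_cdf <- function(x) 0.6 * pnorm(x, 60, 10) + 0.4 * pnorm(x, 120, 15)
  grid <- seq(0, 250, by = 0.5)
  emp <- ecdf(reads$polya_length)
  expect_lt(max(abs(emp(grid) - mix_cdf(grid))), 0.02)
})

test_that("labeling courses follow first-order kinetics", {
  tr <- simulate_transcriptome(n_transcripts = 5, top_fraction = 0, seed = 18)
  tr$transcripts$k_d <- log(2) / 360  # half-life 6 h
  tr$transcripts$half_life_min <- 360
  # noiseless catabolic course: f(6 h) / f(0 h) = 1/2 exactly
  cat6 <- simulate_slam_course(tr, "catabolic", timepoints_h = c(0, 6),
                               coverage = Inf, background = 0)
  f0 <- cat6$conversion_rate[cat6$time_h == 0]
  f6 <- cat6$conversion_rate[cat6$time_h == 6]
  expect_equal(f6 / f0, rep(0.5, length(f0)), tolerance = 1e-12)

  # binomial sampling concentrates on the analytic curve as coverage
  # grows: at conversion p the relative sd is sqrt((1-p)/(p * coverage)),
  # below 0.25% everywhere here, so 1% is a > 4 sigma envelope
  tr$transcripts$saturation_conversion <- rep(0.5, 5)
  exact <- simulate_slam_course(tr, "catabolic", timepoints_h = c(0, 6),
                                coverage = Inf, background = 0)
  noisy <- simulate_slam_course(tr, "catabolic", timepoints_h = c(0, 6),
                                coverage = 1e5, seed = 19,
                                background = 0)
  expect_lt(max(abs(noisy$conversion_rate - exact$conversion_rate) /
                  exact$conversion_rate), 0.01)

  # background-only transcript: flat conversions at the background rate
  tr$transcripts$saturation_conversion <- 0.001
  flat <- simulate_slam_course(tr, "catabolic", coverage = Inf,
                               background = 0.001)
  expect_equal(unique(flat$conversion_rate), 0.001)

  expect_error(simulate_slam_course(tr, "catabolic",
                                    timepoints_h = c(3, 6, 9)),
               "anchor")
})

test_that("count matrices encode the injected TE change by construction", {
  tr <- simulate_transcriptome(n_transcripts = 8, top_fraction = 0.5,
                               top_delta_te = 1, top_log2fc = 0,
                               excluded_fraction = 0, seed = 20)
  cm <- simulate_count_matrices(tr, dispersion = 0, rfp_extra_dispersion = 0,
                                libsize_sd = 0)
  ratio <- cm$rfp$counts / cm$rna$counts
  is_d6 <- cm$rna$sample_meta$condition == "D6"
  top <- tr$transcripts$is_top
  # noiseless construction: RFP/RNA doubles between conditions for TE genes
  expect_equal(unname(rowMeans(ratio[top, is_d6]) /
                        rowMeans(ratio[top, !is_d6])),
               rep(2, sum(top)), tolerance = 0.02)
  expect_equal(unname(rowMeans(ratio[!top, is_d6])),
               unname(rowMeans(ratio[!top, !is_d6])), tolerance = 0.02)

  tr2 <- simulate_transcriptome(n_transcripts = 5, n_replicates = 1,
                                seed = 21)
  expect_error(simulate_count_matrices(tr2), "2 replicates")

  c1 <- simulate_count_matrices(tr, seed = 22)
  c2 <- simulate_count_matrices(tr, seed = 22)
  expect_identical(c1$rna$counts, c2$rna$counts)
  expect_identical(c1$rfp$counts, c2$rfp$counts)
})

test_that("simulated UTRs are perfectly separable by the TOP rule", {
  tr <- simulate_transcriptome(n_transcripts = 2000, top_fraction = 0.5,
                               seed = 23)
  utrs <- simulate_utr_sequences(tr, seed = 24)
  calls <- classify_top_motif(utrs$utr5)
  expect_identical(calls$is_top, tr$transcripts$is_top)
  runs <- calls$run_length[tr$transcripts$is_top]
  expect_setequal(sort(unique(runs)), 4:15)

  # FASTA round trip
  path <- withr::local_tempfile(fileext = ".fa")
  write_utr_fasta(utrs, path)
  back <- read_utr_fasta(path)
  expect_equal(back$utr5, utrs$utr5)
})
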