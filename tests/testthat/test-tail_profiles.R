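test_that("bin fractions follow the <30 / 30-90 / >90 nt convention", {
  expect_equal(unname(bin_fractions(c(10, 45, 60, 100))),
               c(0.25, 0.50, 0.25))
  # boundary lengths belong to the ~60 nt band on both sides
  expect_equal(unname(bin_fractions(c(30, 90))), c(0, 1, 0))
  expect_equal(unname(bin_fractions(c(1, 5, 29.9))), c(1, 0, 0))
  expect_equal(sum(bin_fractions(runif(100, 0, 200))), 1)
  expect_error(bin_fractions(numeric()), "non-empty")
  expect_error(bin_fractions(c(10, -2)), "non-negative")
})

make_reads <- function(transcript_id, lengths_by_sample,
                       condition = "D0") {
  dplyr::bind_rows(lapply(names(lengths_by_sample), function(s) {
    lens <- lengths_by_sample[[s]]
    tibble::tibble(
      read_id = sprintf("%s_%s_%d", transcript_id, s, seq_along(lens)),
      transcript_id = transcript_id, sample_id = s, condition = condition,
      polya_length = lens, qc_tag = "PASS")
  }))
}

test_that("profiling applies the pooled minimum-read and exclusion filters", {
  # 29 reads pooled over samples: below the default threshold of 30
  low <- make_reads("txLow", list(s1 = runif(14, 10, 100),
                                  s2 = runif(15, 10, 100)))
  # 45 reads split 15/15/15: retained, three profiles of 15 reads
  ok <- make_reads("txOk", list(s1 = runif(15, 10, 100),
                                s2 = runif(15, 10, 100),
                                s3 = runif(15, 10, 100)))
  # abundant but excluded (mitochondrial / pseudogene contig)
  mito <- make_reads("mt-tx", list(s1 = runif(500, 10, 100)))
  gs <- gene_sets(universe = c("txLow", "txOk", "mt-tx"),
                  exclusions = "mt-tx")
  prof <- build_tail_profiles(rbind(low, ok, mito), gs)
  expect_setequal(unique(prof$transcript_id), "txOk")
  expect_identical(nrow(prof), 3L)
  expect_true(all(prof$n_reads == 15L))
  expect_equal(prof$frac_lt30 + prof$frac_60 + prof$frac_gt90,
               rep(1, 3), tolerance = 1e-12)
  # histogram totals equal read counts
  expect_identical(vapply(prof$histogram, function(h) sum(as.integer(h)),
                          integer(1)),
                   prof$n_reads)
  expect_identical(nrow(build_tail_profiles(low[0, ])), 0L)
})

test_that("profile bin fractions equal brute-force counting on raw reads", {
  tr <- simulate_transcriptome(n_transcripts = 40, seed = 30)
  reads <- simulate_tail_reads(tr, "D0", depth = 60, seed = 31)
  pass <- reads[reads$qc_tag == "PASS", ]
  prof <- build_tail_profiles(pass, min_reads = 30)
  for (i in seq_len(nrow(prof))) {
    raw <- pass$polya_length[pass$transcript_id == prof$transcript_id[i] &
                               pass$sample_id == prof$sample_id[i]]
    expect_identical(prof$frac_lt30[i], sum(raw < 30) / length(raw))
    expect_identical(prof$frac_60[i],
                     sum(raw >= 30 & raw <= 90) / length(raw))
    expect_identical(prof$frac_gt90[i], sum(raw > 90) / length(raw))
  }
})

test_that("relative-frequency histograms normalise per replicate", {
  reads <- make_reads("tx1", list(s1 = c(60, 60, 90, 120)))
  prof <- build_tail_profiles(reads, min_reads = 1)
  h <- relative_frequency_histogram(prof, "D0", bin_width = 30)
  expect_equal(h$per_replicate$freq[h$per_replicate$bin_start == 60], 0.5)
  expect_equal(h$per_replicate$freq[h$per_replicate$bin_start == 90], 0.25)
  expect_equal(h$per_replicate$freq[h$per_replicate$bin_start == 120], 0.25)

  # every replicate's frequencies sum to one; identical replicates agree
  reads2 <- make_reads("tx1", list(s1 = c(10, 40, 70, 100, 130),
                                   s2 = c(10, 40, 70, 100, 130)))
  prof2 <- build_tail_profiles(reads2, min_reads = 1)
  h2 <- relative_frequency_histogram(prof2, "D0")
  sums <- tapply(h2$per_replicate$freq, h2$per_replicate$sample_id, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  spread <- tapply(h2$per_replicate$freq, h2$per_replicate$bin_start, sd)
  expect_equal(max(as.numeric(spread)), 0)
  expect_error(relative_frequency_histogram(prof2, "D9"), "no profiles")
})

test_that("the tail-shift t-test matches the pooled-variance oracle", {
  prof <- dplyr::bind_rows(
    tibble::tibble(transcript_id = "tx1", sample_id = paste0("a", 1:3),
                   condition = "D0", n_reads = 50L,
                   frac_lt30 = c(0.10, 0.12, 0.11), frac_60 = 0.5,
                   frac_gt90 = 0.39, histogram = list(NULL)),
    tibble::tibble(transcript_id = "tx1", sample_id = paste0("b", 1:3),
                   condition = "D6", n_reads = 50L,
                   frac_lt30 = c(0.30, 0.31, 0.29), frac_60 = 0.5,
                   frac_gt90 = 0.19, histogram = list(NULL)))
  res <- test_bin_fraction_change(prof, "D0", "D6", "lt30")
  expect_equal(res$p_value,
               pooled_t_p(c(0.10, 0.12, 0.11), c(0.30, 0.31, 0.29)))
  expect_lt(res$p_value, 0.001)
  expect_true(res$significant)
  expect_equal(res$delta, 0.19)
  expect_equal(res$fold_change, 0.30 / 0.11, tolerance = 1e-9)

  # agreement with stats::t.test on random per-replicate fractions
  set.seed(41)
  for (rep in 1:20) {
    a <- runif(3); b <- runif(4)
    p2 <- dplyr::bind_rows(
      tibble::tibble(transcript_id = "g", sample_id = paste0("x", 1:3),
                     condition = "A", n_reads = 10L, frac_lt30 = a,
                     frac_60 = 0, frac_gt90 = 0, histogram = list(NULL)),
      tibble::tibble(transcript_id = "g", sample_id = paste0("y", 1:4),
                     condition = "B", n_reads = 10L, frac_lt30 = b,
                     frac_60 = 0, frac_gt90 = 0, histogram = list(NULL)))
    mine <- test_bin_fraction_change(p2, "A", "B", "lt30")
    ref <- t.test(b, a, var.equal = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("degenerate and under-replicated tail-shift cases follow the rules", {
  base <- function(id, cond, samples, fr) {
    tibble::tibble(transcript_id = id, sample_id = samples,
                   condition = cond, n_reads = 10L, frac_lt30 = fr,
                   frac_60 = 0, frac_gt90 = 0, histogram = list(NULL))
  }
  # equal constant groups: p = 1, not significant
  prof <- rbind(base("tx1", "A", paste0("a", 1:3), rep(0.2, 3)),
                base("tx1", "B", paste0("b", 1:3), rep(0.2, 3)))
  res <- test_bin_fraction_change(prof, "A", "B", "lt30")
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_true(res$degenerate)
  # different constant groups: p = 0 with the degenerate flag
  prof2 <- rbind(base("tx1", "A", paste0("a", 1:3), rep(0.2, 3)),
                 base("tx1", "B", paste0("b", 1:3), rep(0.4, 3)))
  res2 <- test_bin_fraction_change(prof2, "A", "B", "lt30")
  expect_equal(res2$p_value, 0)
  expect_true(res2$degenerate)
  # one replicate: skipped with a logged reason
  prof3 <- rbind(base("tx1", "A", "a1", 0.2),
                 base("tx1", "B", paste0("b", 1:3), c(0.1, 0.2, 0.3)))
  res3 <- test_bin_fraction_change(prof3, "A", "B", "lt30")
  expect_identical(nrow(res3), 0L)
  skipped <- attr(res3, "skipped")
  expect_identical(skipped$transcript_id, "tx1")
  expect_match(skipped$reason, "fewer than 2 replicates")
})

test_that("stronger simulated weight transfer gives larger ~60 nt deltas", {
  deltas <- vapply(c(0.05, 0.15, 0.30), function(transfer) {
    tr <- simulate_transcriptome(n_transcripts = 60, top_fraction = 0.5,
                                 top_w_long_to_mid = transfer,
                                 top_w_mid_to_short = 0,
                                 excluded_fraction = 0, seed = 42)
    reads <- rbind(simulate_tail_reads(tr, "D0", depth = 80, seed = 43),
                   simulate_tail_reads(tr, "D6", depth = 80, seed = 44))
    prof <- build_tail_profiles(reads[reads$qc_tag == "PASS", ])
    sh <- test_bin_fraction_change(prof, "D0", "D6", "about60")
    top_ids <- tr$transcripts$transcript_id[tr$transcripts$is_top]
    median(sh$delta[sh$transcript_id %in% top_ids])
  }, numeric(1))
  expect_true(all(diff(deltas) > 0))
})
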