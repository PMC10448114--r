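#' Tail-length bin fractions for one set of reads
#'
#' Splits poly(A) tail lengths into the three functional bins used
#' throughout the package: `<30` nt (decay-prone, below one PABP
#' footprint), `30-90` nt (the "~60 nt" class, boundary values included on
#' both sides), and `>90` nt (extended tails). The bin edges are
#' configurable; with edges `c(e1, e2)` the bins are `[0, e1)`,
#' `[e1, e2]`, `(e2, Inf)`.
#'
#' @param tail_lengths Non-empty numeric vector of non-negative tail
#'   lengths (nt).
#' @param edges Two increasing bin edges, default `c(30, 90)`.
#' @return Named numeric vector `c(frac_lt30, frac_60, frac_gt90)` summing
#'   to 1.
#' @export
bin_fractions <- function(tail_lengths, edges = c(30, 90)) {
  if (length(tail_lengths) == 0) stopf("tail_lengths must be non-empty")
  if (any(tail_lengths < 0)) stopf("tail lengths must be non-negative")
  if (length(edges) != 2 || diff(edges) <= 0) {
    stopf("edges must be two strictly increasing values")
  }
  c(frac_lt30 = mean(tail_lengths < edges[1]),
    frac_60 = mean(tail_lengths >= edges[1] & tail_lengths <= edges[2]),
    frac_gt90 = mean(tail_lengths > edges[2]))
}

#' Build per-transcript, per-sample poly(A) tail profiles
#'
#' Aggregates PASS-filtered reads into one profile per transcript and
#' sample: the read count, the three bin fractions and a 1-nt histogram.
#' Transcripts on the exclusion list (mitochondrial genome, pseudogenes)
#' are dropped, and a transcript is retained only if its total read count
#' pooled over *all* samples and conditions reaches `min_reads`; no
#' per-sample minimum is imposed.
#'
#' @param reads Tibble of reads (assumed already PASS-filtered; see
#'   [read_polya_table()] with `require_pass = TRUE`).
#' @param gene_sets Optional [gene_sets()] object supplying the exclusion
#'   list.
#' @param min_reads Minimum pooled read count per transcript (default 30).
#' @param edges Bin edges passed to [bin_fractions()].
#' @return A tibble with columns `transcript_id`, `sample_id`, `condition`,
#'   `n_reads`, `frac_lt30`, `frac_60`, `frac_gt90` and a list-column
#'   `histogram` of per-1-nt integer counts (names are floored lengths).
#'   An empty read list yields an empty tibble.
#' @export
build_tail_profiles <- function(reads, gene_sets = NULL, min_reads = 30,
                                edges = c(30, 90)) {
  empty <- tibble::tibble(
    transcript_id = character(), sample_id = character(),
    condition = character(), n_reads = integer(),
    frac_lt30 = numeric(), frac_60 = numeric(), frac_gt90 = numeric(),
    histogram = list())
  if (nrow(reads) == 0) return(empty)
  if (!is.null(gene_sets)) {
    reads <- reads[!reads$transcript_id %in% gene_sets$exclusions, ]
  }
  totals <- table(reads$transcript_id)
  keep <- names(totals)[totals >= min_reads]
  reads <- reads[reads$transcript_id %in% keep, ]
  if (nrow(reads) == 0) return(empty)
  reads |>
    dplyr::group_by(.data$transcript_id, .data$sample_id) |>
    dplyr::summarise(
      condition = .data$condition[1],
      n_reads = dplyr::n(),
      frac_lt30 = mean(.data$polya_length < edges[1]),
      frac_60 = mean(.data$polya_length >= edges[1] &
                       .data$polya_length <= edges[2]),
      frac_gt90 = mean(.data$polya_length > edges[2]),
      histogram = list(table(floor(.data$polya_length))),
      .groups = "drop"
    )
}

#' Relative-frequency histogram of tail lengths for one condition
#'
#' Pools the per-transcript histograms of all profiles of a condition into
#' one tail-length distribution per replicate, normalised to sum to 1, and
#' reports the mean relative frequency across replicates per bin. Lengths
#' beyond `max_length` are capped into the last bin for display.
#'
#' @param profiles Output of [build_tail_profiles()].
#' @param condition Condition label to plot.
#' @param bin_width Bin width in nt (default 1).
#' @param max_length Display cap in nt (default 250).
#' @return A list of class `tail_freq_hist` with elements `per_replicate`
#'   (tibble `bin_start`, `sample_id`, `freq`; each replicate's frequencies
#'   sum to 1) and `mean` (tibble `bin_start`, `freq`).
#' @export
relative_frequency_histogram <- function(profiles, condition, bin_width = 1,
                                         max_length = 250) {
  prof <- profiles[profiles$condition == condition, ]
  if (nrow(prof) == 0) stopf("no profiles for condition '%s'", condition)
  long <- dplyr::bind_rows(lapply(seq_len(nrow(prof)), function(i) {
    h <- prof$histogram[[i]]
    tibble::tibble(sample_id = prof$sample_id[i],
                   length = as.numeric(names(h)),
                   count = as.integer(h))
  }))
  long$bin_start <- pmin(floor(long$length / bin_width) * bin_width,
                         floor(max_length / bin_width) * bin_width)
  per_rep <- long |>
    dplyr::group_by(.data$sample_id, .data$bin_start) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select(-"count") |>
    tidyr::complete(.data$sample_id, .data$bin_start,
                    fill = list(freq = 0))
  mean_tab <- per_rep |>
    dplyr::group_by(.data$bin_start) |>
    dplyr::summarise(freq = mean(.data$freq), .groups = "drop")
  structure(list(per_replicate = per_rep, mean = mean_tab,
                 condition = condition, bin_width = bin_width),
            class = "tail_freq_hist")
}

#' @export
print.tail_freq_hist <- function(x, ...) {
  cat(sprintf("tail_freq_hist: condition %s, %d replicates, %d bins of %g nt\n",
              x$condition, length(unique(x$per_replicate$sample_id)),
              nrow(x$mean), x$bin_width))
  invisible(x)
}

#' Differential tail-shift test between two conditions
#'
#' For each transcript, compares the per-replicate bin fractions (the test
#' units) of two conditions with a two-tailed two-sample Student's t test
#' with pooled variance (Welch's correction is available via
#' `var_equal = FALSE`). Transcripts with fewer than two replicates in
#' either condition are skipped and recorded with a reason. A raw p-value
#' threshold is applied, with no multiple-testing correction at this stage
#' (reported shifts are screening calls, not FDR-controlled discoveries).
#'
#' Degenerate zero-variance cases are resolved by rule: if both groups have
#' zero variance, the p-value is 1 when the means are equal and 0
#' otherwise, with `degenerate = TRUE`.
#'
#' @param profiles Output of [build_tail_profiles()].
#' @param cond_a,cond_b Baseline and contrast condition labels; `delta` is
#'   `mean(cond_b) - mean(cond_a)` on the proportion scale.
#' @param bin `"lt30"` or `"about60"`: which bin fraction to test.
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @param var_equal Use the pooled-variance Student's t test (default);
#'   `FALSE` switches to Welch.
#' @return A tibble with one row per tested transcript: `transcript_id`,
#'   `bin`, `mean_a`, `mean_b`, `delta`, `fold_change` (NA when the
#'   baseline mean is 0), `statistic`, `df`, `p_value`, `significant`,
#'   `degenerate`. Skipped transcripts are attached as the `"skipped"`
#'   attribute (tibble of `transcript_id`, `reason`).
#' @export
test_bin_fraction_change <- function(profiles, cond_a, cond_b,
                                     bin = c("lt30", "about60"),
                                     alpha = 0.05, var_equal = TRUE) {
  bin <- match.arg(bin)
  col <- if (bin == "lt30") "frac_lt30" else "frac_60"
  pa <- profiles[profiles$condition == cond_a, c("transcript_id", col)]
  pb <- profiles[profiles$condition == cond_b, c("transcript_id", col)]
  if (nrow(pa) == 0 || nrow(pb) == 0) {
    stopf("no profiles for condition '%s'",
          if (nrow(pa) == 0) cond_a else cond_b)
  }
  grp <- function(x) split(x[[col]], x$transcript_id)
  ga <- grp(pa)
  gb <- grp(pb)
  ids <- union(names(ga), names(gb))
  na <- vapply(ids, function(id) length(ga[[id]] %||% numeric()), integer(1))
  nb <- vapply(ids, function(id) length(gb[[id]] %||% numeric()), integer(1))
  ok <- na >= 2 & nb >= 2
  skipped <- tibble::tibble(
    transcript_id = ids[!ok],
    reason = sprintf("fewer than 2 replicates (n_a=%d, n_b=%d)",
                     na[!ok], nb[!ok]))
  ids <- ids[ok]
  if (length(ids) == 0) {
    res <- tibble::tibble(transcript_id = character(), bin = character(),
                          mean_a = numeric(), mean_b = numeric(),
                          delta = numeric(), fold_change = numeric(),
                          statistic = numeric(), df = numeric(),
                          p_value = numeric(), significant = logical(),
                          degenerate = logical())
    attr(res, "skipped") <- skipped
    return(res)
  }
  na <- na[ok]; nb <- nb[ok]
  ma <- vapply(ids, function(id) mean(ga[[id]]), numeric(1))
  mb <- vapply(ids, function(id) mean(gb[[id]]), numeric(1))
  va <- vapply(ids, function(id) var(ga[[id]]), numeric(1))
  vb <- vapply(ids, function(id) var(gb[[id]]), numeric(1))
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  degenerate <- se == 0
  tstat <- ifelse(degenerate, NA_real_, (mb - ma) / se)
  p <- ifelse(degenerate,
              ifelse(ma == mb, 1, 0),
              2 * pt(-abs(tstat), df))
  res <- tibble::tibble(
    transcript_id = ids, bin = bin,
    mean_a = unname(ma), mean_b = unname(mb),
    delta = unname(mb - ma),
    fold_change = unname(ifelse(ma > 0, mb / ma, NA_real_)),
    statistic = unname(tstat), df = unname(df),
    p_value = unname(p),
    significant = unname(p) <= alpha,
    degenerate = unname(degenerate))
  attr(res, "skipped") <- skipped
  res
}
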