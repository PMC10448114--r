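#' Simulate a transcriptome with known post-transcriptional ground truth
#'
#' Generates the per-transcript truth table that drives every other
#' simulator in the package. Each transcript carries a decay rate, a
#' steady-state synthesis rate, a baseline expression level, a
#' per-condition poly(A) tail-length mixture, a differential-accumulation
#' log2 fold change, a translational-engagement change and a TOP/non-TOP
#' label. Defaults encode the differentiation scenario the pipeline is
#' built around:
#'
#' * tail lengths follow a three-component Gaussian mixture with modes
#'   around 15, 60 and 120 nt (a short decay-prone class, the dominant
#'   ~60 nt class covered by two PABP footprints, and a long ~120 nt
#'   class);
#' * TOP transcripts are long-lived (decay half-lives drawn from the upper
#'   part of the 60-2400 min log-uniform range), abundant,
#'   transcriptionally downregulated during differentiation, and gain
#'   translational engagement;
#' * during differentiation TOP transcripts shift tail-mixture weight from
#'   the ~120 nt to the ~60 nt component, and at the final condition also
#'   from ~60 nt into the <30 nt class (the two-phase deadenylation
#'   signature).
#'
#' Regeneration from the same arguments and seed is deterministic.
#'
#' @param n_transcripts Number of transcripts (> 0).
#' @param top_fraction Fraction of transcripts carrying a TOP motif; the
#'   realised count is exactly `round(n_transcripts * top_fraction)`.
#' @param conditions Ordered condition labels; the first is the baseline
#'   (undifferentiated) state and effects scale linearly with progression
#'   to the last.
#' @param n_replicates Biological replicates per condition (>= 2 for any
#'   downstream testing).
#' @param decay_half_life_range,top_decay_half_life_range Decay half-life
#'   ranges in minutes; values are drawn log-uniformly.
#' @param baseline_mean_range,top_baseline_mean_range Baseline expression
#'   (expected counts), drawn log-uniformly; TOP transcripts are drawn from
#'   the abundant end as expected of translation-machinery mRNAs.
#' @param excluded_fraction Fraction of (non-TOP) transcripts flagged as
#'   mitochondrial-genome or pseudogene contigs, which tail profiling must
#'   ignore.
#' @param top_log2fc Differential-accumulation log2 fold change
#'   (last vs first condition) given to TOP transcripts.
#' @param de_fraction,de_log2fc Fraction of non-TOP transcripts that are
#'   differentially accumulated and the magnitude (random sign) of their
#'   log2 fold change.
#' @param top_delta_te Change in log2 translational efficiency for TOP
#'   transcripts between the first and last condition.
#' @param saturation_range Range of the per-transcript saturation T-to-C
#'   conversion rate reached after prolonged 4sU labeling.
#' @param tail_weights,tail_means,tail_sds Baseline mixture weights, means
#'   and SDs (nt) for the short/~60/~120 components (weights sum to 1,
#'   means strictly increasing).
#' @param top_w_long_to_mid Mixture weight moved from the ~120 nt to the
#'   ~60 nt component for TOP transcripts in every post-baseline condition.
#' @param top_w_mid_to_short Additional weight moved from the ~60 nt to the
#'   short component for TOP transcripts at the final condition only.
#' @param down_w_mid_to_short Weight moved into the short component at the
#'   final condition for *all* downregulated transcripts (the generic
#'   deadenylation that accompanies decay).
#' @param seed Integer seed; identical `(arguments, seed)` give identical
#'   truth tables.
#' @return An object of class `sim_truth`: a list with `transcripts`
#'   (tibble of per-transcript truth), `mixtures` (tibble of per
#'   transcript-condition tail mixtures), `conditions`, `n_replicates`,
#'   `seed` and `params`.
#' @export
simulate_transcriptome <- function(n_transcripts = 1000,
                                   top_fraction = 0.1,
                                   conditions = c("D0", "D6"),
                                   n_replicates = 3,
                                   decay_half_life_range = c(60, 2400),
                                   top_decay_half_life_range = c(600, 2400),
                                   baseline_mean_range = c(20, 2000),
                                   top_baseline_mean_range = c(200, 2000),
                                   excluded_fraction = 0.02,
                                   top_log2fc = -1,
                                   de_fraction = 0.2,
                                   de_log2fc = 1.5,
                                   top_delta_te = 0.8,
                                   saturation_range = c(0.02, 0.10),
                                   tail_weights = c(0.10, 0.55, 0.35),
                                   tail_means = c(15, 60, 120),
                                   tail_sds = c(7, 10, 15),
                                   top_w_long_to_mid = 0.20,
                                   top_w_mid_to_short = 0.10,
                                   down_w_mid_to_short = 0.05,
                                   seed = NULL) {
  if (n_transcripts <= 0) stopf("n_transcripts must be positive")
  if (length(conditions) < 2) stopf("need at least two conditions")
  if (abs(sum(tail_weights) - 1) > 1e-8) stopf("tail_weights must sum to 1")
  if (any(diff(tail_means) <= 0)) stopf("tail_means must be increasing")
  if (!is.null(seed)) set.seed(seed)

  n <- as.integer(n_transcripts)
  ids <- sprintf("TX%05d", seq_len(n))
  n_top <- round(n * top_fraction)
  is_top <- rep(FALSE, n)
  if (n_top > 0) is_top[sample.int(n, n_top)] <- TRUE

  n_excl <- round(n * excluded_fraction)
  excluded <- rep(FALSE, n)
  non_top_idx <- which(!is_top)
  if (n_excl > 0 && length(non_top_idx) > 0) {
    excluded[sample(non_top_idx, min(n_excl, length(non_top_idx)))] <- TRUE
  }

  runif_log <- function(m, range) {
    exp(runif(m, log(range[1]), log(range[2])))
  }
  half_life <- runif_log(n, decay_half_life_range)
  half_life[is_top] <- runif_log(sum(is_top), top_decay_half_life_range)
  k_d <- log(2) / half_life

  baseline <- runif_log(n, baseline_mean_range)
  baseline[is_top] <- runif_log(sum(is_top), top_baseline_mean_range)
  k_s <- baseline * k_d  # steady state: abundance = synthesis / decay

  log2fc <- numeric(n)
  log2fc[is_top] <- top_log2fc
  de <- !is_top & runif(n) < de_fraction
  log2fc[de] <- de_log2fc * sample(c(-1, 1), sum(de), replace = TRUE)

  delta_te <- numeric(n)
  delta_te[is_top] <- top_delta_te

  saturation <- runif(n, saturation_range[1], saturation_range[2])

  transcripts <- tibble::tibble(
    transcript_id = ids, is_top = is_top, excluded = excluded,
    half_life_min = half_life, k_d = k_d, k_s = k_s,
    baseline_mean = baseline, log2fc_expr = log2fc,
    delta_log2_te = delta_te, saturation_conversion = saturation
  )

  # Per-condition mixtures. Condition index i (1 = baseline) gets:
  #  - TOP: long->mid transfer for every i > 1; mid->short added at i = K.
  #  - non-TOP downregulated: mid->short at i = K only.
  K <- length(conditions)
  mixtures <- dplyr::bind_rows(lapply(seq_len(K), function(i) {
    w <- matrix(tail_weights, nrow = n, ncol = 3, byrow = TRUE)
    if (i > 1) {
      w[is_top, 3] <- w[is_top, 3] - top_w_long_to_mid
      w[is_top, 2] <- w[is_top, 2] + top_w_long_to_mid
      if (i == K) {
        w[is_top, 2] <- w[is_top, 2] - top_w_mid_to_short
        w[is_top, 1] <- w[is_top, 1] + top_w_mid_to_short
        down <- !is_top & log2fc < 0
        w[down, 2] <- w[down, 2] - down_w_mid_to_short
        w[down, 1] <- w[down, 1] + down_w_mid_to_short
      }
    }
    if (any(w < 0)) stopf("tail mixture weights became negative; reduce the weight transfers")
    tibble::tibble(
      transcript_id = ids, condition = conditions[i],
      w_short = w[, 1], w_mid = w[, 2], w_long = w[, 3],
      mean_short = tail_means[1], mean_mid = tail_means[2],
      mean_long = tail_means[3],
      sd_short = tail_sds[1], sd_mid = tail_sds[2], sd_long = tail_sds[3]
    )
  }))

  structure(list(transcripts = transcripts, mixtures = mixtures,
                 conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 seed = seed,
                 params = list(top_log2fc = top_log2fc,
                               top_delta_te = top_delta_te,
                               tail_weights = tail_weights,
                               tail_means = tail_means,
                               tail_sds = tail_sds)),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d transcripts (%d TOP, %d excluded), conditions %s, %d replicates\n",
              nrow(x$transcripts), sum(x$transcripts$is_top),
              sum(x$transcripts$excluded),
              paste(x$conditions, collapse = "/"), x$n_replicates))
  invisible(x)
}

# Linear progression of condition effects along the differentiation axis.
condition_progress <- function(truth, condition) {
  i <- match(condition, truth$conditions)
  if (is.na(i)) {
    stopf("unknown condition '%s' (known: %s)", condition,
          paste(truth$conditions, collapse = ", "))
  }
  (i - 1) / (length(truth$conditions) - 1)
}

#' Simulate per-read poly(A) tail measurements for one condition
#'
#' For each transcript and replicate, the read depth is drawn from a
#' negative binomial around `depth` scaled by the transcript's relative
#' abundance in that condition, and tail lengths are drawn from the
#' condition's Gaussian mixture with additive measurement noise, truncated
#' at zero by resampling. A configurable fraction of reads receives a
#' non-PASS QC tag.
#'
#' @param truth A `sim_truth` object.
#' @param condition One of `truth$conditions`.
#' @param depth Mean read depth per transcript and replicate for a
#'   transcript of average abundance.
#' @param seed Optional integer seed.
#' @param qc_fail_fraction Fraction of reads tagged non-PASS.
#' @param noise_sd Gaussian measurement noise SD (nt) added to the true
#'   tail length.
#' @param depth_size Negative-binomial size (inverse dispersion) of the
#'   per-transcript read depth.
#' @return A tibble of reads with columns `read_id`, `transcript_id`,
#'   `sample_id`, `condition`, `polya_length`, `qc_tag`.
#' @export
simulate_tail_reads <- function(truth, condition, depth = 100, seed = NULL,
                                qc_fail_fraction = 0.05, noise_sd = 5,
                                depth_size = 10) {
  stopifnot(inherits(truth, "sim_truth"))
  prog <- condition_progress(truth, condition)
  if (!is.null(seed)) set.seed(seed)
  tx <- truth$transcripts
  mix <- truth$mixtures[truth$mixtures$condition == condition, ]
  mix <- mix[match(tx$transcript_id, mix$transcript_id), ]

  rel <- tx$baseline_mean * 2^(tx$log2fc_expr * prog)
  mu <- depth * rel / mean(rel)
  n_tx <- nrow(tx)

  out <- vector("list", truth$n_replicates)
  for (r in seq_len(truth$n_replicates)) {
    depths <- rnbinom(n_tx, size = depth_size, mu = mu)
    total <- sum(depths)
    if (total == 0) {
      out[[r]] <- NULL
      next
    }
    idx <- rep.int(seq_len(n_tx), depths)
    # mixture component per read, then truncated-normal tail length
    u <- runif(total)
    w1 <- mix$w_short[idx]
    w12 <- w1 + mix$w_mid[idx]
    comp <- 1L + (u >= w1) + (u >= w12)
    m <- cbind(mix$mean_short, mix$mean_mid, mix$mean_long)[cbind(idx, comp)]
    s <- cbind(mix$sd_short, mix$sd_mid, mix$sd_long)[cbind(idx, comp)]
    len <- rnorm(total, m, s) + rnorm(total, 0, noise_sd)
    bad <- which(len < 0)
    while (length(bad) > 0) {
      len[bad] <- rnorm(length(bad), m[bad], s[bad]) +
        rnorm(length(bad), 0, noise_sd)
      bad <- bad[len[bad] < 0]
    }
    qc <- rep("PASS", total)
    n_fail <- rbinom(1, total, qc_fail_fraction)
    if (n_fail > 0) {
      qc[sample.int(total, n_fail)] <- sample(
        c("NOREGION", "SUFFCLIP", "ADAPTER", "READ_FAILED_LOAD"),
        n_fail, replace = TRUE)
    }
    sample_id <- sprintf("%s_rep%d", condition, r)
    out[[r]] <- tibble::tibble(
      read_id = sprintf("%s_read%07d", sample_id, seq_len(total)),
      transcript_id = tx$transcript_id[idx],
      sample_id = sample_id,
      condition = condition,
      polya_length = len,
      qc_tag = qc
    )
  }
  dplyr::bind_rows(out)
}

#' Simulate a metabolic-labeling conversion time course
#'
#' Generates per-transcript T-to-C conversion rates over a labeling (or
#' chase) time course under first-order turnover kinetics. For the anabolic
#' design (pulse labeling at steady state) the labeled fraction follows
#' `f(t) = 1 - exp(-k_d t)`; for the catabolic design (chase after
#' saturating labeling) it follows `f(t) = exp(-k_d t)`. The observed
#' conversion rate is `background + f * (saturation - background)`, sampled
#' binomially over `coverage` informative positions. The catabolic t = 0
#' records carry the saturation conversion rate used downstream as the
#' normalization anchor.
#'
#' @param truth A `sim_truth` object (supplies `k_d` and the per-transcript
#'   saturation conversion).
#' @param design `"anabolic"` (label accumulation) or `"catabolic"` (label
#'   chase).
#' @param timepoints_h Collection times in hours; must include 0 (the
#'   normalization anchor).
#' @param coverage Number of informative T positions per observation; the
#'   observed rate is a binomial proportion over this coverage. Use a large
#'   value (or `Inf`) for a noiseless course.
#' @param seed Optional integer seed.
#' @param background Background conversion rate in unlabeled RNA.
#' @return A tibble with columns `transcript_id`, `design`, `time_h`,
#'   `replicate`, `conversion_rate`, `coverage`.
#' @export
simulate_slam_course <- function(truth,
                                 design = c("catabolic", "anabolic"),
                                 timepoints_h = c(0, 3, 6, 9),
                                 coverage = 200, seed = NULL,
                                 background = 0.001) {
  stopifnot(inherits(truth, "sim_truth"))
  design <- match.arg(design)
  if (!0 %in% timepoints_h) {
    stopf("timepoints_h must include 0 (normalization anchor)")
  }
  if (!is.null(seed)) set.seed(seed)
  tx <- truth$transcripts
  grid <- expand.grid(transcript_id = tx$transcript_id,
                      time_h = timepoints_h,
                      replicate = seq_len(truth$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(grid$transcript_id, tx$transcript_id)
  t_min <- grid$time_h * 60
  f <- if (design == "anabolic") 1 - exp(-tx$k_d[i] * t_min) else
    exp(-tx$k_d[i] * t_min)
  p <- background + f * (tx$saturation_conversion[i] - background)
  p <- pmin(pmax(p, 0), 1)
  rate <- if (is.finite(coverage)) {
    rbinom(length(p), size = coverage, prob = p) / coverage
  } else p
  tibble::tibble(
    transcript_id = grid$transcript_id,
    design = design,
    time_h = grid$time_h,
    replicate = grid$replicate,
    conversion_rate = rate,
    coverage = coverage
  )
}

#' Simulate paired RNA-seq and ribosome-footprint count matrices
#'
#' RNA counts are negative binomial around per-condition means from the
#' truth table (baseline times the condition's share of the
#' differential-accumulation fold change), with log-normal library-size
#' factors. Ribosome-footprint (RFP) counts are coupled to the *realised*
#' RNA expression of the same biological sample: the RFP mean is the
#' size-factor-corrected RNA count times `2^(delta_log2_te * progress)`,
#' and the conditional draw adds only a small technical excess dispersion.
#' This within-sample coupling mirrors the fact that footprints sample the
#' mRNA pool actually present in that replicate (it is the structure the
#' paired permutation test of [delta_log2_te()] assumes under the null),
#' while keeping each assay's marginal negative-binomial dispersion at
#' approximately `dispersion` (the shared biological variation enters the
#' RFP counts through the realised RNA draw, not a second time).
#'
#' @param truth A `sim_truth` object.
#' @param seed Optional integer seed.
#' @param dispersion Biological negative-binomial dispersion
#'   (`var = mu + dispersion * mu^2`); the marginal dispersion of each
#'   assay's counts.
#' @param rfp_extra_dispersion Technical excess dispersion of the
#'   footprint counts conditional on the realised mRNA pool (default
#'   0.01; set to 0 for purely Poisson footprint sampling).
#' @param libsize_sd SD of the log-normal library-size factors.
#' @return A list with elements `rna` and `rfp`, both [count_matrix()]
#'   objects with matched condition/replicate structure.
#' @export
simulate_count_matrices <- function(truth, seed = NULL, dispersion = 0.05,
                                    rfp_extra_dispersion = 0.01,
                                    libsize_sd = 0.1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (truth$n_replicates < 2) stopf("need at least 2 replicates per condition")
  if (!is.null(seed)) set.seed(seed)
  tx <- truth$transcripts
  n <- nrow(tx)
  conds <- truth$conditions
  size <- if (dispersion > 0) 1 / dispersion else Inf

  samples <- expand.grid(replicate = seq_len(truth$n_replicates),
                         condition = conds,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_s <- nrow(samples)
  sf_rna <- exp(rnorm(n_s, 0, libsize_sd))
  sf_rfp <- exp(rnorm(n_s, 0, libsize_sd))

  size_rfp <- if (rfp_extra_dispersion > 0) 1 / rfp_extra_dispersion else Inf
  rna <- matrix(0L, n, n_s)
  rfp <- matrix(0L, n, n_s)
  for (j in seq_len(n_s)) {
    prog <- condition_progress(truth, samples$condition[j])
    mu_rna <- tx$baseline_mean * 2^(tx$log2fc_expr * prog) * sf_rna[j]
    k_rna <- if (is.finite(size)) rnbinom(n, size = size, mu = mu_rna) else
      round(mu_rna)
    te <- 2^(tx$delta_log2_te * prog)
    mu_rfp <- (k_rna / sf_rna[j]) * te * sf_rfp[j]
    k_rfp <- if (is.finite(size_rfp)) {
      rnbinom(n, size = size_rfp, mu = mu_rfp)
    } else round(mu_rfp)
    rna[, j] <- k_rna
    rfp[, j] <- k_rfp
  }
  ids_rna <- sprintf("%s_rep%d_rna", samples$condition, samples$replicate)
  ids_rfp <- sprintf("%s_rep%d_rfp", samples$condition, samples$replicate)
  dimnames(rna) <- list(tx$transcript_id, ids_rna)
  dimnames(rfp) <- list(tx$transcript_id, ids_rfp)
  meta <- function(ids, assay) tibble::tibble(
    sample_id = ids, condition = samples$condition, assay = assay,
    replicate = samples$replicate)
  list(rna = count_matrix(rna, meta(ids_rna, "rna")),
       rfp = count_matrix(rfp, meta(ids_rfp, "rfp")))
}

#' Simulate 5'UTR sequences with and without a TOP motif
#'
#' TOP transcripts receive a 5'UTR beginning with a cytidine followed by a
#' pyrimidine run of total length 4-15 (uniform) terminated by a purine;
#' non-TOP transcripts receive purine-initiated UTRs. The RNA alphabet
#' `A/C/G/U` is used throughout.
#'
#' @param truth A `sim_truth` object.
#' @param seed Optional integer seed.
#' @param utr_length Total UTR length in nucleotides.
#' @return A tibble with columns `transcript_id`, `utr5`.
#' @export
simulate_utr_sequences <- function(truth, seed = NULL, utr_length = 60) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.null(seed)) set.seed(seed)
  tx <- truth$transcripts
  pyr <- c("C", "U")
  pur <- c("A", "G")
  nt <- c("A", "C", "G", "U")
  seqs <- vapply(seq_len(nrow(tx)), function(i) {
    if (tx$is_top[i]) {
      run <- sample(4:15, 1)
      head_part <- c("C", sample(pyr, run - 1, replace = TRUE),
                     sample(pur, 1))
    } else {
      head_part <- sample(pur, 1)
    }
    rest <- utr_length - length(head_part)
    paste(c(head_part, if (rest > 0) sample(nt, rest, replace = TRUE)),
          collapse = "")
  }, character(1))
  tibble::tibble(transcript_id = tx$transcript_id, utr5 = seqs)
}

#' Write or read 5'UTR sequences as FASTA
#'
#' @param utrs Tibble with columns `transcript_id`, `utr5` (RNA alphabet).
#' @param path FASTA path.
#' @return `write_utr_fasta` returns `path` invisibly; `read_utr_fasta`
#'   returns a tibble with columns `transcript_id`, `utr5`.
#' @export
write_utr_fasta <- function(utrs, path) {
  set <- Biostrings::RNAStringSet(setNames(utrs$utr5, utrs$transcript_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_utr_fasta
#' @export
read_utr_fasta <- function(path) {
  set <- Biostrings::readRNAStringSet(path)
  tibble::tibble(transcript_id = names(set),
                 utr5 = unname(as.character(set)))
}
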