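#' Simulate a complete differentiation study
#'
#' Generates, with one seed, every input the pipeline consumes: the truth
#' table, per-condition poly(A) tail reads, anabolic and catabolic
#' labeling time courses, paired RNA/RFP count matrices and 5'UTR
#' sequences. Arguments are passed through to the individual simulators;
#' the defaults encode the differentiation scenario described in
#' [simulate_transcriptome()].
#'
#' @param seed Integer seed driving all generators.
#' @param n_transcripts,top_fraction Passed to [simulate_transcriptome()].
#' @param depth Mean tail-read depth per transcript and replicate.
#' @param coverage Informative positions per conversion observation.
#' @param timepoints_h Labeling time points in hours.
#' @param ... Further arguments for [simulate_transcriptome()].
#' @return A list of class `tail_study`: `truth`, `tail_reads` (all
#'   conditions pooled), `slam` (both designs pooled), `counts`
#'   (list `rna`/`rfp`), `utrs`, and `seed`.
#' @export
simulate_study <- function(seed = 1, n_transcripts = 1000,
                           top_fraction = 0.1, depth = 100, coverage = 200,
                           timepoints_h = c(0, 3, 6, 9), ...) {
  truth <- simulate_transcriptome(n_transcripts = n_transcripts,
                                  top_fraction = top_fraction,
                                  seed = derive_seed(seed, 1), ...)
  tail_reads <- dplyr::bind_rows(lapply(seq_along(truth$conditions),
    function(i) {
      simulate_tail_reads(truth, truth$conditions[i], depth = depth,
                          seed = derive_seed(seed, 10 + i))
    }))
  slam <- dplyr::bind_rows(
    simulate_slam_course(truth, "catabolic", timepoints_h = timepoints_h,
                         coverage = coverage, seed = derive_seed(seed, 20)),
    simulate_slam_course(truth, "anabolic", timepoints_h = timepoints_h,
                         coverage = coverage, seed = derive_seed(seed, 21)))
  counts <- simulate_count_matrices(truth, seed = derive_seed(seed, 30))
  utrs <- simulate_utr_sequences(truth, seed = derive_seed(seed, 40))
  structure(list(truth = truth, tail_reads = tail_reads, slam = slam,
                 counts = counts, utrs = utrs, seed = seed),
            class = "tail_study")
}

#' @export
print.tail_study <- function(x, ...) {
  cat(sprintf("tail_study (seed %s): %d transcripts, %d tail reads, %d conversion records\n",
              format(x$seed), nrow(x$truth$transcripts),
              nrow(x$tail_reads), nrow(x$slam)))
  invisible(x)
}

#' Run the integrated TOP-transcript analysis on a simulated study
#'
#' Chains the analysis stages of the package over the outputs of
#' [simulate_study()], comparing the first (baseline) and last (contrast)
#' conditions:
#'
#' 1. PASS filtering, exclusion of mitochondrial/pseudogene contigs, and
#'    tail profiling with the pooled minimum-read filter
#'    ([build_tail_profiles()]);
#' 2. per-transcript tail-shift tests for the `<30` nt and `~60` nt bins
#'    ([test_bin_fraction_change()]);
#' 3. hypergeometric overrepresentation of TOP transcripts among the
#'    significant gainers of each bin ([hypergeometric_enrichment()]);
#' 4. decay-kinetics fitting with saturation normalization and the
#'    acceptance filters ([normalize_conversions()], [fit_kinetics()]);
#' 5. differential accumulation ([nb_wald_test()]) and translational
#'    engagement ([delta_log2_te()]) on the count matrices;
#' 6. TOP-motif classification of the 5'UTRs ([classify_top_motif()]).
#'
#' The TOP gene set used for enrichment comes from the motif classifier
#' applied to the simulated UTRs, so the analysis only sees information an
#' experimenter would have.
#'
#' @param study A `tail_study` from [simulate_study()].
#' @param config A [default_pipeline_config()] list.
#' @param n_perm Monte-Carlo permutations for the TE test.
#' @return A list of class `tail_study_results` with elements `profiles`,
#'   `shift_lt30`, `shift_60`, `enrichment_lt30`, `enrichment_60`,
#'   `decay_fits`, `diff_acc`, `translation`, `top_calls` and `summary`
#'   (one-row tibble of headline numbers).
#' @export
analyze_study <- function(study, config = default_pipeline_config(),
                          n_perm = 2000) {
  stopifnot(inherits(study, "tail_study"))
  truth <- study$truth
  cond_a <- truth$conditions[1]
  cond_b <- truth$conditions[length(truth$conditions)]

  top_calls <- classify_top_motif(study$utrs$utr5)
  top_ids <- study$utrs$transcript_id[top_calls$is_top]
  gs <- gene_sets(
    universe = truth$transcripts$transcript_id,
    top_genes = top_ids,
    exclusions = truth$transcripts$transcript_id[truth$transcripts$excluded])

  pass <- study$tail_reads[study$tail_reads$qc_tag == "PASS", ]
  profiles <- build_tail_profiles(pass, gs,
                                  min_reads = config$min_reads_per_contig,
                                  edges = config$bin_edges)
  shift_lt30 <- test_bin_fraction_change(profiles, cond_a, cond_b, "lt30",
                                         alpha = config$alpha_tail)
  shift_60 <- test_bin_fraction_change(profiles, cond_a, cond_b, "about60",
                                       alpha = config$alpha_tail)

  enrich <- function(shifts) {
    tested <- shifts$transcript_id[shifts$significant & shifts$delta > 0]
    universe <- shifts$transcript_id  # transcripts captured at test depth
    hypergeometric_enrichment(
      k = length(intersect(tested, gs$top_genes)),
      s = length(tested),
      M = length(intersect(universe, gs$top_genes)),
      N = length(universe))
  }
  enrichment_lt30 <- enrich(shift_lt30)
  enrichment_60 <- enrich(shift_60)

  norm <- normalize_conversions(study$slam,
                                background = config$slam_background)
  decay_fits <- fit_kinetics(norm, "decay", r2_min = config$r2_min,
                             half_life_bounds = config$half_life_bounds_min,
                             background = config$slam_background)

  diff_acc <- nb_wald_test(study$counts$rna, alpha_q = config$alpha_q)
  translation <- delta_log2_te(study$counts$rna, study$counts$rfp,
                               n_perm = n_perm,
                               seed = derive_seed(study$seed, 50),
                               te_threshold = config$te_threshold)

  ok_fits <- decay_fits[decay_fits$status == "ok", ]
  is_top_fit <- ok_fits$transcript_id %in% gs$top_genes
  top_te <- translation[translation$gene_id %in% gs$top_genes, ]
  summary <- tibble::tibble(
    n_profiled = length(unique(profiles$transcript_id)),
    n_shift_60_up = sum(shift_60$significant & shift_60$delta > 0),
    n_shift_lt30_up = sum(shift_lt30$significant & shift_lt30$delta > 0),
    enrichment_p_60 = enrichment_60$p_upper,
    enrichment_p_lt30 = enrichment_lt30$p_upper,
    median_half_life_top_h = median(ok_fits$half_life_min[is_top_fit]) / 60,
    median_half_life_nontop_h =
      median(ok_fits$half_life_min[!is_top_fit]) / 60,
    n_diff_acc_sig = sum(diff_acc$significant),
    frac_top_engaged = mean(top_te$engaged),
    median_delta_te_top = median(top_te$delta_log2_te))
  structure(list(profiles = profiles, shift_lt30 = shift_lt30,
                 shift_60 = shift_60, enrichment_lt30 = enrichment_lt30,
                 enrichment_60 = enrichment_60, decay_fits = decay_fits,
                 diff_acc = diff_acc, translation = translation,
                 top_calls = top_calls, gene_sets = gs, summary = summary),
            class = "tail_study_results")
}

#' @export
print.tail_study_results <- function(x, ...) {
  s <- x$summary
  cat("Integrated TOP-transcript analysis\n")
  cat(sprintf("  transcripts profiled:            %d\n", s$n_profiled))
  cat(sprintf("  ~60 nt gainers (p <= 0.05):      %d (TOP enrichment p = %.3g)\n",
              s$n_shift_60_up, s$enrichment_p_60))
  cat(sprintf("  <30 nt gainers (p <= 0.05):      %d (TOP enrichment p = %.3g)\n",
              s$n_shift_lt30_up, s$enrichment_p_lt30))
  cat(sprintf("  median decay half-life (h):      TOP %.1f vs non-TOP %.1f\n",
              s$median_half_life_top_h, s$median_half_life_nontop_h))
  cat(sprintf("  differentially accumulated:      %d (q <= 0.05)\n",
              s$n_diff_acc_sig))
  cat(sprintf("  TOP translationally engaged:     %.0f%% (median dTE %.2f)\n",
              100 * s$frac_top_engaged, s$median_delta_te_top))
  invisible(x)
}
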