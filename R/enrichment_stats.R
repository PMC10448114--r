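#' Classify a 5'UTR sequence as TOP / non-TOP
#'
#' A transcript carries a 5'-terminal oligopyrimidine (TOP) motif when its
#' 5'UTR starts with a pyrimidine and the maximal pyrimidine run beginning
#' at position 1 has length at least `min_run` (default 4, matching the
#' canonical 4-15 pyrimidine tract). Runs longer than 15 still classify as
#' TOP; the run length is reported uncapped. DNA and RNA alphabets are both
#' accepted (T is treated as U). `strict` additionally requires the
#' canonical cytidine at position +1.
#'
#' @param utr5_sequence Character vector of 5'UTR sequences (A/C/G/T/U,
#'   case-insensitive).
#' @param min_run Minimum pyrimidine run length (default 4).
#' @param strict Require the first nucleotide to be C (default `FALSE`:
#'   any pyrimidine start qualifies).
#' @return A tibble with one row per sequence: `is_top`, `run_length` (the
#'   5'-terminal pyrimidine run length, 0 for purine starts).
#' @export
classify_top_motif <- function(utr5_sequence, min_run = 4, strict = FALSE) {
  if (length(utr5_sequence) == 0) stopf("no sequences supplied")
  s <- toupper(as.character(utr5_sequence))
  if (any(!nzchar(s))) stopf("empty sequence at position %d",
                             which(!nzchar(s))[1])
  bad <- grepl("[^ACGTU]", s)
  if (any(bad)) {
    stopf("sequence %d contains characters outside the A/C/G/T/U alphabet",
          which(bad)[1])
  }
  m <- regexpr("^[CTU]+", s)
  run <- ifelse(m > 0, attr(m, "match.length"), 0L)
  is_top <- run >= min_run
  if (strict) is_top <- is_top & substr(s, 1, 1) == "C"
  tibble::tibble(is_top = is_top, run_length = as.integer(run))
}

# Upper-tail hypergeometric probability P(X >= k), log-space summation.
# Vectorized over k for a fixed (s, M, N).
hyper_upper <- function(k, s, M, N) {
  hi <- min(s, M)
  denom <- lchoose(N, s)
  vapply(k, function(kk) {
    if (kk > hi) return(0)
    i <- kk:hi
    sum(exp(lchoose(M, i) + lchoose(N - M, s - i) - denom))
  }, numeric(1))
}

#' Hypergeometric gene-set overrepresentation test
#'
#' Upper-tail hypergeometric probability of observing at least `k`
#' set members (e.g. known TOP mRNAs) in a tested population of size `s`
#' drawn from a universe of `N` genes containing `M` set members:
#' `p = sum_(i=k)^(min(s,M)) C(M,i) C(N-M,s-i) / C(N,s)`, evaluated in log
#' space for numerical stability.
#'
#' @param k Number of set members in the tested population (successes).
#' @param s Size of the tested population (sample size).
#' @param M Number of set members in the universe.
#' @param N Universe size.
#' @return An object of class `enrichment_result`: list with `k`, `s`,
#'   `M`, `N`, `p_upper`.
#' @export
hypergeometric_enrichment <- function(k, s, M, N) {
  vals <- c(k = k, s = s, M = M, N = N)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stopf("k, s, M, N must be non-negative integers")
  }
  if (s > N) stopf("invalid bounds: s > N")
  if (M > N) stopf("invalid bounds: M > N")
  if (k > s) stopf("invalid bounds: k > s")
  if (k > M) stopf("invalid bounds: k > M")
  structure(list(k = k, s = s, M = M, N = N,
                 p_upper = hyper_upper(k, s, M, N)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "hypergeometric enrichment: k=%d of s=%d drawn, M=%d of N=%d in universe; P(X >= k) = %.4g\n",
    x$k, x$s, x$M, x$N, x$p_upper))
  invisible(x)
}

#' Two-sided Kolmogorov-Smirnov test
#'
#' Compares the empirical cumulative distributions of two samples:
#' `D = sup |ECDF_a - ECDF_b|`, with the p-value from the asymptotic KS
#' distribution or, optionally, the exact small-sample distribution.
#'
#' @param sample_a,sample_b Numeric vectors of at least 2 observations
#'   each.
#' @param exact `NULL` (let [stats::ks.test()] decide), `TRUE` or `FALSE`.
#' @return A list with `statistic` (D) and `p_value`.
#' @export
ks_two_sided <- function(sample_a, sample_b, exact = NULL) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stopf("each sample needs at least 2 observations")
  }
  res <- suppressWarnings(
    ks.test(sample_a, sample_b, alternative = "two.sided", exact = exact))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

# Games-Howell pairwise comparisons: Welch degrees of freedom with the
# studentized-range distribution.
games_howell <- function(groups) {
  k <- length(groups)
  nm <- names(groups)
  stats <- lapply(groups, function(x) {
    list(n = length(x), m = mean(x), v = var(x))
  })
  pairs <- utils::combn(k, 2)
  dplyr::bind_rows(apply(pairs, 2, function(ij) {
    a <- stats[[ij[1]]]
    b <- stats[[ij[2]]]
    se2 <- a$v / a$n + b$v / b$n
    tval <- (a$m - b$m) / sqrt(se2)
    df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
    tibble::tibble(
      group1 = nm[ij[1]], group2 = nm[ij[2]],
      diff = a$m - b$m, statistic = tval, df = df,
      p_value = ptukey(abs(tval) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE))
  }))
}

#' Assumption-guided group comparison
#'
#' Selects and runs the comparison appropriate to the data, following the
#' screening procedure: normality of each group is checked with a
#' Shapiro-Wilk test and variance homogeneity with a Levene test (both at
#' `alpha_screen`). Two normal, homoscedastic groups get a two-tailed
#' Student's t test (paired variant when `paired = TRUE`); two normal
#' heteroscedastic groups get a Welch t test; two non-normal groups get a
#' Wilcoxon test (signed-rank when paired, rank-sum otherwise). More than
#' two normal homoscedastic groups get a one-way ANOVA followed by
#' Dunnett's comparisons against the reference group; heteroscedastic
#' normal groups get Games-Howell comparisons; non-normal groups get a
#' Kruskal-Wallis test with Bonferroni-corrected pairwise Wilcoxon
#' comparisons. The full decision trace (screening p-values) is returned
#' with every result.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with at
#'   least 3 observations so that normality is testable).
#' @param paired For two groups: treat observations as paired (equal
#'   lengths required).
#' @param reference Name or index of the reference group for Dunnett
#'   comparisons (default: the first group).
#' @param alpha_screen Significance level of the screening tests (default
#'   0.05).
#' @return A list of class `group_comparison`: `test_name` (one of
#'   `student_t`, `paired_t`, `welch_t`, `wilcoxon_unpaired`,
#'   `wilcoxon_paired`, `anova_dunnett`, `games_howell`,
#'   `kruskal_bonferroni`), `statistic`, `p_value`, `comparisons` (tibble
#'   of pairwise results, or `NULL` for two-group tests) and `trace`
#'   (shapiro p per group, levene p, group count, normality and
#'   homoscedasticity verdicts).
#' @export
compare_groups <- function(groups, paired = FALSE, reference = NULL,
                           alpha_screen = 0.05) {
  if (!is.list(groups) || length(groups) < 2) {
    stopf("groups must be a list of at least two numeric vectors")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes < 3)) {
    stopf("group '%s' has fewer than 3 observations; normality is untestable",
          names(groups)[which(sizes < 3)[1]])
  }
  k <- length(groups)
  if (paired && (k != 2 || sizes[1] != sizes[2])) {
    stopf("paired comparisons require exactly two groups of equal size")
  }
  shapiro_p <- vapply(groups, function(x) {
    if (sd(x) == 0) 0 else shapiro.test(x)$p.value
  }, numeric(1))
  stacked <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups)))
  levene_p <- car::leveneTest(value ~ group, data = stacked,
                              center = mean)[1, "Pr(>F)"]
  normal <- all(shapiro_p > alpha_screen)
  homoscedastic <- levene_p > alpha_screen
  trace <- list(shapiro_p = shapiro_p, levene_p = levene_p,
                n_groups = k, normal = normal,
                homoscedastic = homoscedastic, paired = paired)

  comparisons <- NULL
  if (k == 2) {
    a <- groups[[1]]
    b <- groups[[2]]
    if (normal) {
      if (paired) {
        ht <- t.test(a, b, paired = TRUE)
        test_name <- "paired_t"
      } else if (homoscedastic) {
        ht <- t.test(a, b, var.equal = TRUE)
        test_name <- "student_t"
      } else {
        ht <- t.test(a, b, var.equal = FALSE)
        test_name <- "welch_t"
      }
    } else {
      ht <- suppressWarnings(wilcox.test(a, b, paired = paired))
      test_name <- if (paired) "wilcoxon_paired" else "wilcoxon_unpaired"
    }
    statistic <- unname(ht$statistic)
    p_value <- ht$p.value
  } else {
    if (normal && homoscedastic) {
      ref <- reference %||% names(groups)[1]
      if (is.numeric(ref)) ref <- names(groups)[ref]
      stacked$group <- stats::relevel(stacked$group, ref = ref)
      fit <- aov(value ~ group, data = stacked)
      anova_tab <- summary(fit)[[1]]
      dn <- summary(multcomp::glht(
        fit, linfct = multcomp::mcp(group = "Dunnett")))
      comparisons <- tibble::tibble(
        comparison = names(dn$test$coefficients),
        estimate = unname(dn$test$coefficients),
        statistic = unname(dn$test$tstat),
        p_value = unname(dn$test$pvalues))
      test_name <- "anova_dunnett"
      statistic <- anova_tab[["F value"]][1]
      p_value <- anova_tab[["Pr(>F)"]][1]
    } else if (normal) {
      comparisons <- games_howell(groups)
      test_name <- "games_howell"
      statistic <- max(abs(comparisons$statistic))
      p_value <- min(comparisons$p_value)
    } else {
      kw <- kruskal.test(value ~ group, data = stacked)
      pw <- suppressWarnings(stats::pairwise.wilcox.test(
        stacked$value, stacked$group, p.adjust.method = "bonferroni"))
      comparisons <- tibble::as_tibble(as.data.frame(as.table(pw$p.value)),
                                       .name_repair = "minimal")
      names(comparisons) <- c("group1", "group2", "p_value")
      comparisons <- comparisons[!is.na(comparisons$p_value), ]
      test_name <- "kruskal_bonferroni"
      statistic <- unname(kw$statistic)
      p_value <- kw$p.value
    }
  }
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, comparisons = comparisons,
                 trace = trace),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: %s, statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  cat(sprintf("  screening: min Shapiro-Wilk p = %.3g, Levene p = %.3g\n",
              min(x$trace$shapiro_p), x$trace$levene_p))
  invisible(x)
}
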