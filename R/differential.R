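#' Median-of-ratios size factors
#'
#' Library-size normalization by the median-of-ratios method: the
#' pseudo-reference for each gene is the geometric mean of its counts over
#' samples (genes with any zero count are excluded from the reference), and
#' each sample's factor is the median over genes of the ratio of its count
#' to the reference.
#'
#' @param counts Integer matrix (genes x samples) or a [count_matrix()].
#' @return Positive numeric vector of per-sample factors, named by sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stopf(paste("no gene has nonzero counts in every sample;",
                "consider adding a pseudocount before normalization"))
  }
  logref <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2, function(x) {
    exp(median(log(x) - logref))
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) stopf("degenerate size factors")
  sf
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_(j >= i) (p_(j) * m / j)`, capped at 1, with the original
#' order restored. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (no NAs).
#' @return Vector of q-values, same length and order; elementwise
#'   `q >= p` and `q <= 1`.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stopf("p-values must lie in [0, 1] with no NAs")
  }
  p.adjust(p_values, method = "BH")
}

resolve_counts <- function(counts, conditions) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(conditions)) conditions <- counts$sample_meta$condition
    counts <- counts$counts
  }
  if (is.null(conditions)) stopf("condition labels are required")
  counts <- as.matrix(counts)
  if (length(conditions) != ncol(counts)) {
    stopf("condition labels must match the number of samples")
  }
  list(counts = counts, conditions = as.character(conditions))
}

#' Negative-binomial Wald test for differential transcript accumulation
#'
#' A transparent two-group differential-accumulation test: counts are
#' normalized by median-of-ratios [size_factors()], per-gene dispersions
#' are estimated by the method of moments on normalized counts (floored at
#' `dispersion_floor`, and by default additionally floored at a fitted
#' mean-dispersion trend so that under-dispersed moment estimates do not
#' overstate precision), the per-gene effect is the log2 ratio of
#' normalized condition means with a 0.5 pseudocount, and the Wald
#' statistic `log2FC / SE` uses a delta-method standard error under the
#' NB variance model `var = mu + alpha mu^2`. Two-sided p-values come from
#' the standard normal and are Benjamini-Hochberg adjusted; calls are made
#' at `q <= 0.05`.
#'
#' This is a deliberately simplified statistic with a full specification;
#' it does not reproduce empirical-Bayes dispersion shrinkage or fold
#' change moderation of tools like DESeq2.
#'
#' @param counts Integer matrix (genes x samples) or [count_matrix()].
#' @param conditions Character vector of condition labels (two levels, at
#'   least two replicates each); taken from the metadata when `counts` is
#'   a `count_matrix`. The first unique label is the baseline; fold
#'   changes are contrast vs baseline.
#' @param dispersion `"trended"` (default: per-gene moment estimates
#'   floored at a loess mean-dispersion trend) or `"per-gene"` (raw moment
#'   estimates).
#' @param dispersion_floor Lower bound for any dispersion estimate.
#' @param alpha_q Significance threshold on the q-value (default 0.05).
#' @return A tibble: `gene_id`, `base_mean`, `log2_fold_change`,
#'   `standard_error`, `wald_p`, `q_value`, `significant`.
#' @export
nb_wald_test <- function(counts, conditions = NULL,
                         dispersion = c("trended", "per-gene"),
                         dispersion_floor = 1e-8, alpha_q = 0.05) {
  dispersion <- match.arg(dispersion)
  x <- resolve_counts(counts, conditions)
  counts <- x$counts
  conditions <- x$conditions
  levs <- unique(conditions)
  if (length(levs) != 2) stopf("exactly two condition levels are required")
  ja <- which(conditions == levs[1])
  jb <- which(conditions == levs[2])
  if (length(ja) < 2 || length(jb) < 2) {
    stopf("each condition needs at least 2 replicates")
  }
  sf <- size_factors(counts)
  y <- sweep(counts, 2, sf, "/")

  cond_stats <- function(j) {
    yj <- y[, j, drop = FALSE]
    list(mu = rowMeans(yj),
         v = apply(yj, 1, var),
         n = length(j),
         m1s = mean(1 / sf[j]))
  }
  a <- cond_stats(ja)
  b <- cond_stats(jb)

  # MoM: Var(y) = mu * E[1/s] + alpha * mu^2 within each condition
  num <- (a$n - 1) * (a$v - a$mu * a$m1s) + (b$n - 1) * (b$v - b$mu * b$m1s)
  den <- (a$n - 1) * a$mu^2 + (b$n - 1) * b$mu^2
  alpha_raw <- ifelse(den > 0, num / den, 0)
  alpha_raw[!is.finite(alpha_raw)] <- 0
  alpha_g <- pmax(alpha_raw, dispersion_floor)

  base_mean <- rowMeans(y)
  if (dispersion == "trended") {
    use <- base_mean > 0
    if (sum(use) >= 20) {
      trend_fit <- tryCatch(
        loess(alpha_raw[use] ~ log(base_mean[use]), span = 0.6,
              degree = 1, family = "symmetric"),
        error = function(e) NULL)
      if (!is.null(trend_fit)) {
        trend <- rep(dispersion_floor, length(base_mean))
        trend[use] <- pmax(predict(trend_fit), dispersion_floor)
        alpha_g <- pmax(alpha_g, trend)
      }
    }
  }

  pc <- 0.5
  var_mu <- function(s, alpha) {
    # Var of the mean of normalized counts over the condition's replicates
    (s$mu * s$m1s + alpha * s$mu^2) / s$n
  }
  va <- var_mu(a, alpha_g)
  vb <- var_mu(b, alpha_g)
  lfc <- log2((b$mu + pc) / (a$mu + pc))
  se <- sqrt(va / (a$mu + pc)^2 + vb / (b$mu + pc)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(z))
  q <- bh_adjust(p)
  tibble::tibble(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    base_mean = unname(base_mean),
    log2_fold_change = unname(lfc),
    standard_error = unname(se),
    wald_p = unname(p),
    q_value = unname(q),
    significant = unname(q <= alpha_q))
}

#' Differential translational engagement by permutation
#'
#' Computes, per gene, the change in log2 translational efficiency (TE)
#' between two conditions from matched RNA-seq and ribosome-footprint
#' libraries, with a label-permutation p-value. Each assay is size-factor
#' normalized independently (RFP and RNA library depths are unrelated);
#' the per-replicate TE is `log2((rfp + 0.5) / (rna + 0.5))` on normalized
#' counts, and the statistic is `delta = mean TE(contrast) - mean
#' TE(baseline)`. Condition labels are permuted jointly across the two
#' assays, preserving the RNA/RFP pairing of each biological sample:
#' exhaustively when there are at most 500 distinct relabelings, otherwise
#' by `n_perm` Monte-Carlo draws. A gene is called translationally engaged
#' when `|delta| > te_threshold`.
#'
#' @param rna,rfp Count matrices (genes x samples) or [count_matrix()]
#'   objects with identical gene sets and matched sample columns (same
#'   condition/replicate in the same position).
#' @param conditions Condition labels per sample column (two levels);
#'   taken from the RNA metadata if omitted.
#' @param n_perm Number of Monte-Carlo permutations when exhaustive
#'   enumeration is not used.
#' @param exhaustive `NULL` (default): enumerate exhaustively when there
#'   are at most 500 distinct relabelings, otherwise Monte-Carlo. Set
#'   `FALSE` to force Monte-Carlo (e.g. to check agreement with the
#'   exhaustive p-values) or `TRUE` to force enumeration.
#' @param seed Optional seed for the Monte-Carlo draw.
#' @param te_threshold Engagement call threshold on `|delta|` (default
#'   0.5).
#' @return A tibble: `gene_id`, `delta_log2_te`, `perm_p`, `engaged`; the
#'   attribute `"exhaustive"` records whether enumeration was exhaustive.
#' @export
delta_log2_te <- function(rna, rfp, conditions = NULL, n_perm = 10000,
                          seed = NULL, te_threshold = 0.5,
                          exhaustive = NULL) {
  if (inherits(rna, "count_matrix") && inherits(rfp, "count_matrix")) {
    pair_ok <- identical(rna$sample_meta$condition,
                         rfp$sample_meta$condition) &&
      identical(rna$sample_meta$replicate, rfp$sample_meta$replicate)
    if (!pair_ok) stopf("mismatched RNA/RFP sample pairing")
  }
  xr <- resolve_counts(rna, conditions)
  xf <- resolve_counts(rfp, xr$conditions)
  if (!identical(dim(xr$counts), dim(xf$counts)) ||
      !identical(rownames(xr$counts), rownames(xf$counts))) {
    stopf("RNA and RFP matrices must have identical genes and sample count")
  }
  conditions <- xr$conditions
  levs <- unique(conditions)
  if (length(levs) != 2) stopf("exactly two condition levels are required")
  yr <- sweep(xr$counts, 2, size_factors(xr$counts), "/")
  yf <- sweep(xf$counts, 2, size_factors(xf$counts), "/")
  te <- log2(yf + 0.5) - log2(yr + 0.5)

  is_b <- conditions == levs[2]
  nb <- sum(is_b)
  n <- length(conditions)
  contrast <- function(b_idx) {
    w <- rep(-1 / (n - nb), n)
    w[b_idx] <- 1 / nb
    w
  }
  obs <- as.vector(te %*% contrast(which(is_b)))

  n_distinct <- choose(n, nb)
  use_exhaustive <- exhaustive %||% (n_distinct <= 500)
  if (use_exhaustive) {
    sets <- utils::combn(n, nb)
    W <- apply(sets, 2, contrast)
  } else {
    if (!is.null(seed)) set.seed(seed)
    W <- vapply(seq_len(n_perm),
                function(i) contrast(sample.int(n, nb)), numeric(n))
  }
  perm <- abs(te %*% W)
  p <- unname(rowMeans(perm >= abs(obs) - 1e-12))
  res <- tibble::tibble(
    gene_id = rownames(xr$counts) %||%
      as.character(seq_len(nrow(xr$counts))),
    delta_log2_te = obs,
    perm_p = p,
    engaged = abs(obs) > te_threshold)
  attr(res, "exhaustive") <- use_exhaustive
  res
}
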