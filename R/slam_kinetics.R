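#' Normalize conversion rates to the saturation conversion
#'
#' Converts observed T-to-C conversion rates into labeled fractions by
#' normalizing to the maximum conversion expected for the same transcript
#' after prolonged 4sU labeling, taken as the replicate-mean conversion of
#' the catabolic time course at t = 0 (the chase starts from a saturated
#' transcriptome). Values above 1 are kept (not clipped) so that
#' measurement noise remains visible to the fit.
#'
#' @param records Tibble of conversion records with columns
#'   `transcript_id`, `design` (`"anabolic"`/`"catabolic"`), `time_h`,
#'   `replicate`, `conversion_rate`. Catabolic t = 0 records must be
#'   present for a transcript to be normalizable.
#' @param background Background conversion rate subtracted from both the
#'   observed and the saturation conversion (default 0).
#' @return The input tibble with added columns `saturation`,
#'   `norm_fraction` and `status` (`"ok"` or `"unnormalizable"`).
#'   Unnormalizable transcripts (saturation <= background, or no catabolic
#'   anchor) have `norm_fraction = NA` and must be excluded from fitting.
#' @export
normalize_conversions <- function(records, background = 0) {
  needed <- c("transcript_id", "design", "time_h", "replicate",
              "conversion_rate")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stopf("records is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  anchor <- records[records$design == "catabolic" & records$time_h == 0, ]
  sat <- tapply(anchor$conversion_rate, anchor$transcript_id, mean)
  s <- as.numeric(sat[records$transcript_id])
  ok <- !is.na(s) & s > background
  out <- records
  out$saturation <- s
  out$norm_fraction <- ifelse(
    ok, (records$conversion_rate - background) / (s - background), NA_real_)
  out$status <- ifelse(ok, "ok", "unnormalizable")
  out
}

# Shared status rule: ok iff r2 > r2_min and half-life inside the bounds.
fit_status <- function(r2, half_life, r2_min = 0.6,
                       half_life_bounds = c(0, 5000)) {
  if (is.na(r2) || is.na(half_life)) return("insufficient_data")
  if (r2 <= r2_min) return("low_r2")
  if (half_life <= half_life_bounds[1] || half_life >= half_life_bounds[2]) {
    return("outlier")
  }
  "ok"
}

kinetic_fit_row <- function(transcript_id = NA_character_, mode, k = NA_real_,
                            r2 = NA_real_, n_points = 0L,
                            status = "insufficient_data") {
  tibble::tibble(
    transcript_id = transcript_id, mode = mode, k = k,
    half_life_min = if (is.na(k)) NA_real_ else log(2) / k,
    r_squared = r2, n_points = as.integer(n_points), status = status)
}

fit_exponential <- function(times_h, fractions, mode, transcript_id,
                            r2_min, half_life_bounds,
                            coverage = NULL, saturation = NULL,
                            background = 0) {
  keep <- is.finite(times_h) & is.finite(fractions)
  times_h <- times_h[keep]
  fractions <- fractions[keep]
  if (length(unique(times_h)) < 3) {
    return(kinetic_fit_row(transcript_id, mode))
  }
  t_min <- times_h * 60
  k0 <- log(2) / 180
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                     ptol = 1e-15)
  one_fit <- function(start, weights = NULL) {
    args <- if (mode == "decay") {
      list(fractions ~ A * exp(-k * t_min), start = start,
           lower = c(A = 0, k = 1e-9), control = ctrl)
    } else {
      list(fractions ~ 1 - exp(-k * t_min), start = start,
           lower = c(k = 1e-9), control = ctrl)
    }
    if (!is.null(weights)) args$weights <- weights
    tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
  }
  start0 <- if (mode == "decay") {
    list(A = max(mean(fractions[t_min == 0]), 1e-6), k = k0)
  } else list(k = k0)
  fit <- one_fit(start0)
  if (is.null(fit)) return(kinetic_fit_row(transcript_id, mode))
  # Binomial-variance reweighting: normalized fractions inherit noise
  # Var(p)/scale^2 with p the conversion probability implied by the fitted
  # curve; two reweighted refits (IRLS). Falls back to the previous fit on
  # any numerical failure.
  if (!is.null(coverage) && !is.null(saturation) &&
      is.finite(coverage) && saturation > background) {
    scale <- saturation - background
    for (iter in 1:2) {
      p <- background + pmax(pmin(stats::fitted(fit), 2), 0) * scale
      p <- pmin(pmax(p, 0.5 / coverage), 1 - 0.5 / coverage)
      w <- scale^2 * coverage / (p * (1 - p))
      refit <- one_fit(as.list(coef(fit)), weights = w)
      if (is.null(refit)) break
      fit <- refit
    }
  }
  k <- unname(coef(fit)[["k"]])
  ss_res <- sum((fractions - stats::fitted(fit))^2)
  ss_tot <- sum((fractions - mean(fractions))^2)
  # flat data: r2 defined as 0 so the low_r2 filter removes it
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  hl <- log(2) / k
  kinetic_fit_row(transcript_id, mode, k, r2, length(fractions),
                  fit_status(r2, hl, r2_min, half_life_bounds))
}

#' Fit first-order decay kinetics to a labeled-fraction time course
#'
#' Fits `f(t) = A * exp(-k t)` (amplitude free) to saturation-normalized
#' labeled fractions by nonlinear least squares (Levenberg-Marquardt), with
#' `k` constrained positive, initial guess `k0 = ln2 / 180 min` and
#' `A0 = f(0)`. Replicates should be supplied as pooled points (the default
#' convention of [fit_kinetics()]). The fit is performed in minutes
#' internally; times are accepted in hours.
#'
#' The goodness-of-fit is `r2 = 1 - SSres / SStot` over the fitted points;
#' flat data (`SStot = 0`) yields `r2 = 0`. The status is `"ok"` only when
#' `r2 > 0.6` and the half-life lies strictly inside (0, 5000) minutes;
#' otherwise `"low_r2"`, `"outlier"` or `"insufficient_data"` (fewer than 3
#' distinct time points, or non-convergence).
#'
#' When the binomial sampling scale of the conversion measurements is known
#' (`coverage` informative positions, per-transcript `saturation`
#' conversion), the least squares are iteratively reweighted by the implied
#' binomial variance of each point, which prevents the high-conversion
#' (noisiest) observations from dominating the fit. The r-squared is always
#' computed unweighted.
#'
#' @param times_h Time points in hours (replicated values allowed).
#' @param fractions Normalized labeled fractions, same length.
#' @param transcript_id Optional id recorded in the result.
#' @param r2_min,half_life_bounds Acceptance filters (defaults 0.6 and
#'   (0, 5000) minutes).
#' @param coverage,saturation,background Optional binomial noise model for
#'   variance weighting: conversions were binomial over `coverage`
#'   positions with saturation conversion `saturation` above `background`.
#'   Omit (default) for unweighted least squares.
#' @return A one-row tibble: `transcript_id`, `mode`, `k` (1/min),
#'   `half_life_min`, `r_squared`, `n_points`, `status`.
#' @export
fit_decay <- function(times_h, fractions, transcript_id = NA_character_,
                      r2_min = 0.6, half_life_bounds = c(0, 5000),
                      coverage = NULL, saturation = NULL, background = 0) {
  fit_exponential(times_h, fractions, "decay", transcript_id, r2_min,
                  half_life_bounds, coverage, saturation, background)
}

#' Fit first-order synthesis (label-accumulation) kinetics
#'
#' Fits `f(t) = 1 - exp(-k t)` to saturation-normalized labeled fractions
#' of a pulse-labeling course. Under steady-state turnover the label
#' approaches saturation at the transcript's turnover rate, so the
#' recovered half-life is the time to half-saturation. Same fitting and
#' filtering contract as [fit_decay()].
#'
#' @inheritParams fit_decay
#' @return A one-row tibble as in [fit_decay()], with `mode = "synthesis"`.
#' @export
fit_synthesis <- function(times_h, fractions, transcript_id = NA_character_,
                          r2_min = 0.6, half_life_bounds = c(0, 5000),
                          coverage = NULL, saturation = NULL,
                          background = 0) {
  fit_exponential(times_h, fractions, "synthesis", transcript_id, r2_min,
                  half_life_bounds, coverage, saturation, background)
}

#' Fit kinetics for every transcript of a normalized conversion table
#'
#' Applies [fit_decay()] (to the catabolic records) or [fit_synthesis()]
#' (to the anabolic records) per transcript, pooling all replicates into a
#' joint fit. Transcripts marked unnormalizable are reported with status
#' `"unnormalizable"` and are not fitted.
#'
#' Binomial variance weighting (see [fit_decay()]) is used automatically
#' when the table carries `coverage` and `saturation` columns.
#'
#' @param normalized Output of [normalize_conversions()].
#' @param mode `"decay"` or `"synthesis"`.
#' @param r2_min,half_life_bounds Acceptance filters passed through.
#' @param background Background conversion rate used in the normalization
#'   (for the variance weights).
#' @return A tibble with one row per transcript (columns as in
#'   [fit_decay()]).
#' @export
fit_kinetics <- function(normalized, mode = c("decay", "synthesis"),
                         r2_min = 0.6, half_life_bounds = c(0, 5000),
                         background = 0) {
  mode <- match.arg(mode)
  design <- if (mode == "decay") "catabolic" else "anabolic"
  recs <- normalized[normalized$design == design, ]
  if (nrow(recs) == 0) stopf("no %s records to fit", design)
  has_noise_model <- all(c("coverage", "saturation") %in% names(recs))
  parts <- split(recs, recs$transcript_id)
  dplyr::bind_rows(lapply(names(parts), function(id) {
    d <- parts[[id]]
    if (any(d$status == "unnormalizable")) {
      out <- kinetic_fit_row(id, mode)
      out$status <- "unnormalizable"
      return(out)
    }
    fit_exponential(d$time_h, d$norm_fraction, mode, id, r2_min,
                    half_life_bounds,
                    coverage = if (has_noise_model) d$coverage[1] else NULL,
                    saturation = if (has_noise_model) d$saturation[1] else
                      NULL,
                    background = background)
  }))
}

#' Re-apply acceptance filters to a table of kinetic fits
#'
#' Recomputes each fit's status from its `r_squared` and `half_life_min`
#' under (possibly new) thresholds, leaving `insufficient_data` and
#' `unnormalizable` fits untouched. Lowering `r2_min` can never demote a
#' previously accepted fit.
#'
#' @param fits Tibble of fits from [fit_kinetics()].
#' @param r2_min Minimum r-squared for acceptance (default 0.6).
#' @param half_life_bounds Open interval of acceptable half-lives in
#'   minutes (default (0, 5000)).
#' @return `fits` with refreshed `status`; the per-status counts are
#'   attached as the `"counts"` attribute (named integer vector).
#' @export
filter_fits <- function(fits, r2_min = 0.6, half_life_bounds = c(0, 5000)) {
  terminal <- fits$status %in% c("insufficient_data", "unnormalizable")
  new_status <- fits$status
  new_status[!terminal] <- vapply(which(!terminal), function(i) {
    fit_status(fits$r_squared[i], fits$half_life_min[i], r2_min,
               half_life_bounds)
  }, character(1))
  fits$status <- new_status
  counts <- table(factor(new_status,
                         levels = c("ok", "low_r2", "outlier",
                                    "insufficient_data", "unnormalizable")))
  attr(fits, "counts") <- setNames(as.integer(counts), names(counts))
  fits
}
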