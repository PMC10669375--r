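# Longitudinal-inconsistency metric and correlation with pulmonary
# function tests.
#
# Scan-technology and physiological variability shows up as rapid
# exam-to-exam fluctuation of the cyst score.  For each group of three
# consecutive scores the longitudinal inconsistency is the residual
# standard error of the straight-line fit through them: with 3 points and
# 2 fitted parameters there is 1 residual degree of freedom, so the value
# is sqrt(SSR).  A patient with n scans yields n - 2 such measures; the
# maximum is the patient's worst inconsistency.

#' Time-ordered cyst-score series for one patient
#'
#' @param patient_id opaque identifier.
#' @param times years since the first exam, strictly increasing.
#' @param scores cyst-score fractions in `[0, 1]`.
#' @return object of class `score_series`.
#' @export
score_series <- function(patient_id, times, scores) {
  times <- as.numeric(times); scores <- as.numeric(scores)
  if (length(times) != length(scores)) stop("times and scores differ in length")
  if (length(times) < 1) stop("a score series needs at least one exam")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(scores < 0 | scores > 1)) stop("cyst scores must lie in [0, 1]")
  structure(list(patient_id = as.character(patient_id), times = times,
                 scores = scores), class = "score_series")
}

#' @export
print.score_series <- function(x, ...) {
  cat(sprintf("score_series '%s': %d exams over %.1f years, scores %.3f..%.3f\n",
              x$patient_id, length(x$times), diff(range(x$times)),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Longitudinal inconsistency of three consecutive cyst scores
#'
#' Ordinary least squares line through the three `(time, score)` points;
#' returns the residual standard error `sqrt(SSR / (n - 2))`, which for
#' n = 3 equals `sqrt(SSR)`.  Collinear points give exactly 0.
#'
#' @param times three strictly increasing times (years).
#' @param scores three cyst scores.
#' @return non-negative scalar in cyst-score units.
#' @export
triple_inconsistency <- function(times, scores) {
  if (length(times) != 3 || length(scores) != 3)
    stop("exactly three points are required")
  if (anyDuplicated(times)) stop("duplicate times in triple")
  xc <- times - mean(times)
  b <- sum(xc * scores) / sum(xc^2)
  resid <- scores - mean(scores) - b * xc
  sqrt(sum(resid^2))
}

#' All sliding-window inconsistencies of a series
#'
#' A series of n exams yields n - 2 inconsistency measures (one per group
#' of three consecutive exams); series shorter than 3 yield none.
#'
#' @param series a [score_series].
#' @return numeric vector of length `max(0, n - 2)`.
#' @export
series_inconsistencies <- function(series) {
  stopifnot(inherits(series, "score_series"))
  n <- length(series$times)
  if (n < 3) {
    message("series '", series$patient_id,
            "' has fewer than 3 exams; no inconsistency measures")
    return(numeric(0))
  }
  vapply(seq_len(n - 2), function(i)
    triple_inconsistency(series$times[i:(i + 2)], series$scores[i:(i + 2)]),
    0)
}

#' Worst (maximum) inconsistency of a series
#'
#' @param series a [score_series].
#' @return scalar, or `NA` for series shorter than 3 exams.
#' @export
max_inconsistency <- function(series) {
  stopifnot(inherits(series, "score_series"))
  if (length(series$times) < 3) return(NA_real_)
  max(series_inconsistencies(series))
}

#' Squared Pearson correlation
#'
#' Pairs with a missing value in either variable are dropped; at least
#' three complete pairs are required.
#'
#' @param x,y paired numeric vectors.
#' @return R^2 in `[0, 1]`, or `NA` when either variable has zero variance.
#' @export
pearson_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Inconsistency summary for a cohort of score series
#'
#' @param series_list list of [score_series].
#' @return list with `measures` (data frame patient_id/inconsistency),
#'   `mean`, `sd`, and `patient_max` (per-patient worst inconsistency).
#' @export
summarize_inconsistency <- function(series_list) {
  rows <- lapply(series_list, function(s) {
    v <- suppressMessages(series_inconsistencies(s))
    if (!length(v)) return(NULL)
    data.frame(patient_id = s$patient_id, inconsistency = v)
  })
  measures <- do.call(rbind, rows)
  maxima <- vapply(series_list, max_inconsistency, 0)
  names(maxima) <- vapply(series_list, `[[`, "", "patient_id")
  list(measures = measures,
       mean = if (is.null(measures)) NA_real_ else mean(measures$inconsistency),
       sd = if (is.null(measures)) NA_real_ else stats::sd(measures$inconsistency),
       patient_max = maxima[!is.na(maxima)])
}

#' Correlate cyst scores with concurrent pulmonary function tests
#'
#' Scores are joined to PFT records on `patient_id` and `exam_date` within
#' `window_days` (default 0: the same hospital visit), then the squared
#' Pearson correlation of the cyst score with each PFT measure is
#' computed.
#'
#' @param scores data frame with `patient_id`, `exam_date`, `cyst_score`.
#' @param pft data frame with `patient_id`, `exam_date` and any of
#'   `FEV1_pp`, `FEV1_FVC_pp`, `DLco_adj_pp` (% predicted).
#' @param window_days match tolerance in days.
#' @return data frame with columns `measure`, `r2`, `n`.
#' @export
correlate_pft <- function(scores, pft, window_days = 0) {
  scores$exam_date <- as.Date(scores$exam_date)
  pft$exam_date <- as.Date(pft$exam_date)
  measures <- intersect(c("FEV1_pp", "FEV1_FVC_pp", "DLco_adj_pp"), names(pft))
  if (!length(measures)) stop("no PFT measure columns found")
  matched <- lapply(seq_len(nrow(scores)), function(i) {
    cand <- pft[pft$patient_id == scores$patient_id[i] &
                  abs(as.numeric(pft$exam_date - scores$exam_date[i])) <=
                    window_days, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cbind(scores[i, c("patient_id", "exam_date", "cyst_score")],
          cand[which.min(abs(as.numeric(cand$exam_date -
                                          scores$exam_date[i]))),
               measures, drop = FALSE])
  })
  joined <- do.call(rbind, matched)
  out <- lapply(measures, function(m) {
    if (is.null(joined)) return(data.frame(measure = m, r2 = NA_real_, n = 0L))
    ok <- is.finite(joined$cyst_score) & is.finite(joined[[m]])
    r2 <- if (sum(ok) >= 3) pearson_r2(joined$cyst_score[ok], joined[[m]][ok])
          else NA_real_
    data.frame(measure = m, r2 = r2, n = sum(ok))
  })
  do.call(rbind, out)
}
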