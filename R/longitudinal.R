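#' Longitudinal treatment-response comparison
#'
#' Symptom scores recorded at baseline and weeks 1, 2, 3, 4 and 8 under
#' medication are converted to proportional reduction rates from baseline,
#' and biotypes (or biotype-by-medication cells) are compared per scale and
#' week with two-sample t-tests under false-discovery-rate control.
#'
#' @name longitudinal
NULL

#' Proportional symptom reduction from baseline
#'
#' `(score_baseline - score_week) / score_baseline`; positive values are
#' improvement. Invariant to a common positive rescaling of the scale's
#' unit. Records with a zero baseline are undefined and must be excluded
#' upstream.
#'
#' @param baseline baseline (week 0) score, > 0.
#' @param score score at the later week (vectorized).
#' @return reduction rate(s).
#' @export
reduction_rate <- function(baseline, score) {
  if (any(baseline <= 0)) stop("baseline score must be positive")
  (baseline - score) / baseline
}

#' Reduction rates for a long-format longitudinal table
#'
#' @param records data.frame with columns `subject_id`, `scale`, `week`,
#'   `score` (week 0 = baseline; weeks beyond baseline may be missing).
#' @return data.frame `subject_id`, `scale`, `week`, `reduction` for every
#'   post-baseline observation whose baseline is positive; zero-baseline
#'   records are dropped with a message.
#' @export
reduction_table <- function(records) {
  need <- c("subject_id", "scale", "week", "score")
  if (!all(need %in% names(records))) {
    stop("records need columns ", paste(need, collapse = ", "))
  }
  base <- records[records$week == 0, c("subject_id", "scale", "score")]
  names(base)[3L] <- "baseline"
  post <- records[records$week > 0 & is.finite(records$score), , drop = FALSE]
  m <- merge(post, base, by = c("subject_id", "scale"))
  if (nrow(m) < nrow(post)) {
    message(nrow(post) - nrow(m), " observation(s) without baseline dropped")
  }
  bad <- m$baseline <= 0
  if (any(bad)) {
    message(sum(bad), " record(s) with zero baseline excluded")
    m <- m[!bad, , drop = FALSE]
  }
  data.frame(subject_id = m$subject_id, scale = m$scale, week = m$week,
             reduction = reduction_rate(m$baseline, m$score))
}

#' Compare reduction rates between groups across weeks
#'
#' Per scale and week, a pooled-variance two-sample t-test on the reduction
#' rates between two groups; adjusted p-values (Benjamini-Hochberg by
#' default) are computed within the family of all scales at a given week.
#' The grouping is either biotype (1 vs 2) or biotype-by-medication, whose
#' headline contrast is biotype 1 on MPH vs biotype 2 on ATX.
#'
#' @param records long-format longitudinal data.frame (`subject_id`,
#'   `scale`, `week`, `score`).
#' @param pheno data.frame with `subject_id`, `biotype` and (for the
#'   medication grouping) `medication` in {"MPH", "ATX", "none"}.
#' @param grouping `"biotype"` or `"biotype_medication"`.
#' @param weeks weeks to test (default 1, 2, 3, 4, 8).
#' @param correction `"fdr"` (Benjamini-Hochberg), `"bonferroni"` or
#'   `"none"`.
#' @param min_n minimum subjects per cell; smaller contrasts are skipped and
#'   recorded with `skipped = TRUE`.
#' @return data.frame scale, week, grouping, t, p_raw, p_adj, n_a, n_b,
#'   skipped.
#' @export
compare_groups_over_weeks <- function(records, pheno,
                                      grouping = c("biotype",
                                                   "biotype_medication"),
                                      weeks = c(1, 2, 3, 4, 8),
                                      correction = c("fdr", "bonferroni",
                                                     "none"),
                                      min_n = 2L) {
  grouping <- match.arg(grouping)
  correction <- match.arg(correction)
  red <- reduction_table(records)
  red <- merge(red, pheno, by = "subject_id")
  if (grouping == "biotype") {
    in_a <- red$biotype == 1L
    in_b <- red$biotype == 2L
  } else {
    if (!"medication" %in% names(red)) stop("phenotypes need a medication column")
    in_a <- red$biotype == 1L & red$medication == "MPH"
    in_b <- red$biotype == 2L & red$medication == "ATX"
  }
  if (!any(in_a) || !any(in_b)) {
    message("fewer than two groups present; no contrasts computed")
    return(data.frame(scale = character(), week = numeric(),
                      grouping = character(), t = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      n_a = integer(), n_b = integer(), skipped = logical()))
  }
  rows <- list()
  for (w in weeks) {
    for (s in sort(unique(red$scale))) {
      pick <- red$week == w & red$scale == s
      a <- red$reduction[pick & in_a]
      b <- red$reduction[pick & in_b]
      if (length(a) < min_n || length(b) < min_n) {
        rows[[length(rows) + 1L]] <- data.frame(
          scale = s, week = w, grouping = grouping, t = NA_real_,
          p_raw = NA_real_, n_a = length(a), n_b = length(b), skipped = TRUE)
        next
      }
      tt <- if (stats::var(a) == 0 && stats::var(b) == 0 &&
                mean(a) == mean(b)) {
        list(t = 0, p = 1)  # identical degenerate groups
      } else two_sample_t(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        scale = s, week = w, grouping = grouping, t = tt$t, p_raw = tt$p,
        n_a = length(a), n_b = length(b), skipped = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (w in unique(out$week)) {  # family = all scales at a given week
    sel <- out$week == w & !out$skipped
    if (!any(sel)) next
    out$p_adj[sel] <- switch(correction,
      fdr = fdr_adjust(out$p_raw[sel]),
      bonferroni = bonferroni_adjust(out$p_raw[sel]),
      none = out$p_raw[sel])
  }
  out <- out[, c("scale", "week", "grouping", "t", "p_raw", "p_adj",
                 "n_a", "n_b", "skipped")]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values; never below the raw p, never above 1.
#'
#' @param p p-values in (0, 1].
#' @return adjusted p-values in the original order.
#' @export
fdr_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
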