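## Nonparametric group comparisons used throughout the cohort analysis.

#' Mann-Whitney comparison of two samples
#'
#' Rank-sum test with midranks for ties.  Small samples (both n <= 20, no
#' ties) use the exact null distribution; otherwise a tie-corrected normal
#' approximation with continuity correction is used, and the method is
#' reported.  Comparisons where either sample has two or fewer datapoints
#' are refused with an explicit status rather than an arbitrary p-value.
#'
#' @param a,b Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exactCutoff Largest per-sample n for which the exact distribution
#'   is used (default 20).
#' @param labelA,labelB Labels carried into the result.
#' @return List with `status` (`"ok"` or `"refused"`), `group_a`,
#'   `group_b`, `n_a`, `n_b`, and -- when `status == "ok"` --
#'   `u_statistic` (U of sample `a`), `p_value` and `method`
#'   (`"exact"`/`"normal_approx"`).
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' mannWhitney(c(1, 2), c(3, 4, 5))$status      # "refused"
#' @export
mannWhitney <- function(a, b, alternative = c("two.sided", "less",
                                              "greater"),
                        exactCutoff = 20, labelA = "a", labelB = "b") {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  base <- list(group_a = labelA, group_b = labelB,
               n_a = length(a), n_b = length(b))
  if (length(a) <= 2 || length(b) <= 2)
    return(c(base, list(status = "refused",
                        reason = "<=2 datapoints in a sample")))
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= exactCutoff && length(b) <= exactCutoff
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE))
  c(base, list(status = "ok", u_statistic = unname(ht$statistic),
               p_value = ht$p.value,
               method = if (exact) "exact" else "normal_approx"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; input order
#' is preserved.  Idempotent, never exceeds 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Midrank-based rho with p-value from the t approximation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @examples
#' spearmanCor(1:5, c(2, 1, 4, 3, 5))$rho  # 0.8
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x),
       method = "t_approx")
}

#' Median with range
#'
#' Midpoint-convention median (even n: mean of the two central order
#' statistics) with inclusive min and max.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(median, min, max)`.
#' @examples
#' medianRange(c(114, 264, 265, 414))  # 264.5 114 414
#' @export
medianRange <- function(values) {
  if (!length(values)) stop("empty sample")
  c(median = stats::median(values), min = min(values), max = max(values))
}

#' Significance stars for p-values
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `NS` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
significanceStars <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", "NS"))))
}

#' Pairwise TMB comparisons between groups
#'
#' Runs [mannWhitney()] on TMB for every requested group pair (optionally
#' within each cancer type and/or excluding MSI tumors) and applies
#' [bhFdr()] across the family of performed comparisons.
#'
#' @param cohort A [PoleCohort-class].
#' @param assignments Output of [assignGroups()].
#' @param pairs List of 2-element character vectors of groups; default all
#'   pairs among groups present.
#' @param byCancerType Split comparisons per cancer type (default TRUE).
#' @param excludeMsi Drop MSI-substatus tumors first (default FALSE).
#' @return data.frame: one row per comparison with n's, U, p, BH-adjusted
#'   p (across performed comparisons) and stars; refused comparisons keep
#'   `status = "refused"` and `NA` statistics.
#' @export
groupTmbComparisons <- function(cohort, assignments, pairs = NULL,
                                byCancerType = TRUE, excludeMsi = FALSE) {
  d <- merge(as.data.frame(tumorProfiles(cohort)),
             as.data.frame(assignments), by = "tumor_id")
  if (excludeMsi) d <- d[d$substatus != "MSI", ]
  strata <- if (byCancerType) split(d, d$cancer_type) else list(all = d)
  rows <- list()
  for (ct in names(strata)) {
    s <- strata[[ct]]
    gps <- intersect(paste0("G", 1:4), unique(s$group))
    pp <- if (is.null(pairs)) utils::combn(gps, 2, simplify = FALSE)
          else pairs
    for (pr in pp) {
      if (!all(pr %in% gps)) next
      r <- mannWhitney(s$tmb[s$group == pr[1]], s$tmb[s$group == pr[2]],
                       labelA = pr[1], labelB = pr[2])
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = ct, group_a = r$group_a, group_b = r$group_b,
        n_a = r$n_a, n_b = r$n_b, status = r$status,
        u_statistic = if (r$status == "ok") r$u_statistic else NA_real_,
        p_value = if (r$status == "ok") r$p_value else NA_real_,
        method = if (r$status == "ok") r$method else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ok <- out$status == "ok"
  out$adjusted_p <- NA_real_
  if (any(ok)) out$adjusted_p[ok] <- bhFdr(out$p_value[ok])
  out$stars <- significanceStars(out$adjusted_p)
  out
}
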