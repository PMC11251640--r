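# Method comparison: ratios to complete counts, Wilcoxon tests, and the
# counting-effort arithmetic.

#' Compare abundance estimates against complete counts
#'
#' Joins estimates to complete head counts by site and date and expresses
#' each difference as a ratio of predicted to complete count and as a
#' percent deviation `100 * (predicted - complete) / complete`
#' (equivalently `100 * (ratio - 1)`). Pairs lacking a complete count are
#' listed as uncompared.
#'
#' @param estimates data frame with `site_id`, `survey_date`, `method`,
#'   `point` (e.g. from [estimates_df()]).
#' @param complete_counts data frame with `site_id`, `survey_date`,
#'   `count` (all counts > 0).
#' @return List with `records` (per-pair data frame adding `complete`,
#'   `ratio`, `percent_deviation`), `summary` (mean, median, 2.5% and
#'   97.5% percentiles of percent deviation, per method), and
#'   `uncompared`.
#' @export
compare_to_complete <- function(estimates, complete_counts) {
  stopifnot(all(c("site_id", "survey_date", "method", "point") %in%
                  names(estimates)),
            all(c("site_id", "survey_date", "count") %in%
                  names(complete_counts)))
  if (any(complete_counts$count == 0)) stop("complete count of zero")
  key <- function(d) paste(d$site_id, d$survey_date)
  m <- match(key(estimates), key(complete_counts))
  if (all(is.na(m))) stop("no matched site/date pairs")
  rec <- estimates[!is.na(m), , drop = FALSE]
  rec$complete <- complete_counts$count[m[!is.na(m)]]
  rec$ratio <- rec$point / rec$complete
  rec$percent_deviation <- 100 * (rec$ratio - 1)
  summ <- lapply(split(rec$percent_deviation, rec$method), function(d) {
    q <- quantile(d, c(0.025, 0.975), names = FALSE)
    list(n = length(d), mean = mean(d), median = median(d),
         p2.5 = q[1L], p97.5 = q[2L])
  })
  list(records = rec, summary = summ,
       uncompared = estimates[is.na(m), , drop = FALSE])
}

# Exact two-sided signed-rank p for mid-ranked (possibly tied) absolute
# differences, by dynamic programming over the 2^n equiprobable sign
# assignments. Doubling the mid-ranks makes every rank sum an integer, so
# the null distribution is a polynomial-coefficient table of length
# n(n+1) + 1 — exact for any tie pattern.
signed_rank_exact_p <- function(ranks, V) {
  w <- as.integer(round(2 * ranks))
  total <- sum(w)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (wi in w) {
    shifted <- c(numeric(wi), counts[seq_len(total + 1L - wi)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(w)
  v2 <- as.integer(round(2 * V))
  p_le <- sum(probs[seq_len(v2 + 1L)])
  p_ge <- sum(probs[(v2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed rank test for paired samples
#'
#' Paired two-sided test. Zero differences are dropped (their number is
#' reported) and tied absolute differences are mid-ranked. Up to
#' `exact_limit` effective pairs the exact null distribution of the
#' rank-sum statistic is used (computed by enumeration over sign
#' assignments, so ties are handled exactly); above that,
#' [stats::wilcox.test()]'s normal approximation with continuity and tie
#' correction.
#'
#' @param x,y equal-length paired samples.
#' @param continuity_correction apply continuity correction in the normal
#'   approximation.
#' @param exact_limit largest n for the exact distribution (default 25).
#' @return List with `V` (sum of positive-difference ranks), `p`
#'   (two-sided), `n_effective`, `n_zero_dropped`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y, continuity_correction = TRUE,
                                 exact_limit = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  keep <- d != 0  # drop zero differences before ranking
  nz <- d[keep]
  if (!length(nz)) stop("all differences are zero")
  r <- rank(abs(nz))
  V <- sum(r[nz > 0])
  exact <- length(nz) <= exact_limit
  p <- if (exact) {
    signed_rank_exact_p(r, V)
  } else {
    suppressWarnings(
      wilcox.test(x[keep], y[keep], paired = TRUE, exact = FALSE,
                  correct = continuity_correction)$p.value)
  }
  list(V = V, p = p, n_effective = length(nz),
       n_zero_dropped = sum(d == 0), exact = exact)
}

#' Wilcoxon rank sum test for two independent samples
#'
#' Two-sided comparison of two samples via [stats::wilcox.test()], with
#' mid-ranks for ties; exact p by enumeration when the smaller sample has
#' at most `exact_limit` observations and there are no ties, otherwise
#' the normal approximation with tie and continuity corrections.
#'
#' @param x,y non-empty samples.
#' @param exact_limit largest min(n) for the exact distribution.
#' @return List with `W`, `p`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 10L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- any(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) <= exact_limit && !ties
  ht <- wilcox.test(x, y, exact = exact, correct = TRUE)
  list(W = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Counting time for a complete head count
#'
#' Time to enumerate every animal at a haulout at a fixed counting rate —
#' e.g. 10,000 walruses at one per second take about 2.7 hours.
#'
#' @param n_animals number of animals to count.
#' @param rate_per_second animals counted per second (default 1).
#' @return Hours.
#' @export
counting_time_hours <- function(n_animals, rate_per_second = 1) {
  stopifnot(n_animals >= 0, rate_per_second > 0)
  n_animals / rate_per_second / 3600
}

#' Workload reduction from counting only selected model polygons
#'
#' Percent of animals that do not need to be counted when only the
#' selected model polygons are enumerated instead of the whole haulout:
#' `100 * (1 - walruses in selected cells / total walruses)`. With a 30%
#' cell selection on a homogeneous haulout this is about 70%, a proxy for
#' the counting-time saving of the plot-sampling design.
#'
#' @param cell_counts per-cell true counts.
#' @param selected logical selection flags (same length).
#' @return Percent reduction.
#' @export
workload_reduction <- function(cell_counts, selected) {
  stopifnot(length(cell_counts) == length(selected))
  total <- sum(cell_counts)
  if (total == 0) stop("no animals on the haulout")
  100 * (1 - sum(cell_counts[selected]) / total)
}
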