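# Exact null distribution of the signed-rank statistic by enumeration of
# all 2^n sign assignments via the generating function over doubled ranks
# (doubling makes midranks integer).
signed_rank_tail <- function(ranks, v, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1) # counts[k + 1] = #assignments with 2V = k
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  v2 <- round(2 * v)
  idx <- seq(0, total)
  hit <- if (tail == "ge") idx >= v2 - 1e-9 else idx <= v2 + 1e-9
  sum(counts[hit]) / 2^length(ranks)
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired-sample signed-rank test with the p-value computed exactly by full
#' enumeration of the 2^n sign-flip null (no normal approximation), which
#' remains valid with tied absolute differences (midranks). Zero differences
#' are dropped before ranking; the statistic `V` is the sum of the ranks of
#' the positive differences. The two-sided p-value is twice the smaller tail
#' probability, capped at 1.
#'
#' @param data A data frame of paired observations (one row per subject),
#'   e.g. investigation durations for two simultaneously presented scent
#'   samples.
#' @param a,b Column names (strings) of the two paired measurements;
#'   differences are `a - b`.
#' @param alternative `"two.sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @return A one-row tibble of class `wilcoxon_exact` with `V`, `p`,
#'   `alternative`, `n_effective` (pairs after zero removal) and `n_zero`.
#' @examples
#' d <- data.frame(trt = c(5, 7, 9, 6), ctrl = c(3, 6, 4, 6))
#' exact_wilcoxon_signed_rank(d, "trt", "ctrl", alternative = "greater")
#' @export
exact_wilcoxon_signed_rank <- function(data, a, b,
                                       alternative = c(
                                         "two.sided", "greater", "less"
                                       )) {
  alternative <- match.arg(alternative)
  x <- data[[a]]
  y <- data[[b]]
  if (length(x) != length(y) || anyNA(x) || anyNA(y)) {
    abort("Paired observations must be complete.")
  }
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("All differences are zero; V = 0 and p = 1.")
    out <- tibble(
      V = 0, p = 1, alternative = alternative,
      n_effective = 0L, n_zero = n_zero
    )
    class(out) <- c("wilcoxon_exact", class(out))
    return(out)
  }
  if (n > 20) {
    abort("Exact enumeration is limited to 20 nonzero differences.")
  }
  ranks <- rank(abs(d))
  v <- sum(ranks[d > 0])
  p_ge <- signed_rank_tail(ranks, v, "ge")
  p_le <- signed_rank_tail(ranks, v, "le")
  p <- switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, 2 * min(p_ge, p_le))
  )
  out <- tibble(
    V = v, p = p, alternative = alternative,
    n_effective = as.integer(n), n_zero = as.integer(n_zero)
  )
  class(out) <- c("wilcoxon_exact", class(out))
  out
}

#' Two-way single-measure intraclass correlation
#'
#' Inter-observer reliability from a two-way (subjects x raters) layout,
#' single-measure form, computed from the mean squares of the two-way ANOVA
#' decomposition. The default `"agreement"` variant (absolute agreement,
#' ICC(A,1)) penalises systematic rater offsets; the `"consistency"` variant
#' (ICC(C,1)) is invariant to per-rater additive shifts. The 95% confidence
#' interval is F-based (Satterthwaite degrees of freedom for the agreement
#' variant). Zero between-subject variance yields a nonpositive estimate,
#' not an error.
#'
#' @param data A long data frame with one rating per row.
#' @param subject,rater,rating Column names (strings).
#' @param variant `"agreement"` or `"consistency"`.
#' @param conf_level Confidence level of the interval.
#' @return A one-row tibble of class `icc_result` with `icc`, `lower`,
#'   `upper`, `variant`, `n_subjects`, `n_raters`.
#' @export
icc_two_way_single <- function(data, subject = "subject", rater = "rater",
                               rating = "rating",
                               variant = c("agreement", "consistency"),
                               conf_level = 0.95) {
  variant <- match.arg(variant)
  wide <- data |>
    select(dplyr::all_of(c(subject, rater, rating))) |>
    tidyr::pivot_wider(
      names_from = dplyr::all_of(rater),
      values_from = dplyr::all_of(rating)
    )
  m <- as.matrix(wide[-1])
  if (anyNA(m)) abort("The subjects x raters matrix must be complete.")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) abort("Need at least two subjects and two raters.")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  resid <- m - outer(row_means, rep(1, k)) -
    outer(rep(1, n), col_means) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))

  alpha <- 1 - conf_level
  if (variant == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse == 0) {
      lower <- upper <- icc
    } else {
      f_obs <- msr / mse
      f1 <- qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      f2 <- qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lower <- (f_obs / f1 - 1) / (f_obs / f1 + k - 1)
      upper <- (f_obs * f2 - 1) / (f_obs * f2 + k - 1)
    }
  } else {
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    icc <- if (denom == 0) 0 else (msr - mse) / denom
    if (mse == 0 && msc == 0) {
      lower <- upper <- icc
    } else {
      a <- (k * icc) / (n * (1 - icc))
      b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f1 <- qf(1 - alpha / 2, n - 1, v)
      f2 <- qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - f1 * mse) /
        (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- min(1, n * (f2 * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f2 * mse))
    }
  }
  out <- tibble(
    icc = icc,
    lower = min(lower, upper),
    upper = max(lower, upper),
    variant = variant,
    n_subjects = as.integer(n),
    n_raters = as.integer(k)
  )
  class(out) <- c("icc_result", class(out))
  out
}
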