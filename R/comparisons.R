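#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test for paired participant-level values (e.g.
#' period means of step-start paretic rho_disp under Normal vs Force
#' conditions), with Cohen's d of the paired differences reported
#' alongside. Zero differences are dropped before ranking. For 25 or
#' fewer non-zero differences the p-value comes from the exact null
#' distribution of the signed midrank sum (computed by generating-function
#' enumeration, which remains exact under tied magnitudes); larger samples
#' use the normal approximation with continuity and tie corrections.
#'
#' @param values_a,values_b Paired numeric vectors (same participants, two
#'   conditions); the test is of `values_b - values_a`.
#' @param alpha Significance threshold (default 0.025, i.e. two primary
#'   comparisons at a familywise 0.05).
#' @param contrast Label for the comparison (e.g. `"direct effect"`).
#' @return An `fpm_comparison` object: list with `contrast`, `method`,
#'   `statistic` (signed-rank V), `p_value`, `alpha`, `significant`,
#'   `effect_size_d`, `n`. All-zero differences give an undefined p
#'   (`NA`), reported as non-significant.
#' @export
paired_compare <- function(values_a, values_b, alpha = 0.025,
                           contrast = "paired comparison") {
  if (length(values_a) != length(values_b)) abort("Paired vectors differ in length.")
  ok <- is.finite(values_a) & is.finite(values_b)
  d <- (values_b - values_a)[ok]
  n_pairs <- length(d)
  d_eff <- if (sd(d) > 0) mean(d) / sd(d) else NA_real_
  dz <- d[d != 0]
  n <- length(dz)
  if (n == 0L) {
    res <- list(statistic = NA_real_, p_value = NA_real_,
                method = "signed-rank (all differences zero)")
  } else {
    r <- rank(abs(dz))
    v <- sum(r[dz > 0])
    if (n <= 25L) {
      p <- signed_rank_exact_p(r, v)
      method <- "exact signed-rank"
    } else {
      p <- signed_rank_normal_p(r, v, n)
      method <- "signed-rank, normal approximation"
    }
    res <- list(statistic = v, p_value = p, method = method)
  }
  new_fpm_comparison(
    contrast = contrast, method = res$method, statistic = res$statistic,
    p_value = res$p_value, alpha = alpha,
    effect_size_d = d_eff, n = n_pairs
  )
}

# Exact two-sided p for the signed midrank sum. Midranks are multiples of
# 1/2, so doubling gives integers and the null distribution of the doubled
# positive-rank sum is the coefficient vector of prod_i (1 + x^(2 r_i)).
signed_rank_exact_p <- function(ranks, v) {
  m <- as.integer(round(2 * ranks))
  total <- sum(m)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (mi in m) {
    shifted <- c(numeric(mi), counts[seq_len(total + 1L - mi)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(m)
  w <- as.integer(round(2 * v))
  p_le <- sum(probs[seq_len(w + 1L)])
  p_ge <- sum(probs[(w + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

# Normal approximation with continuity correction and tie correction.
signed_rank_normal_p <- function(ranks, v, n) {
  mu <- n * (n + 1) / 4
  ties <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Independent-group Wilcoxon rank-sum comparison
#'
#' Two-sided rank-sum (Mann-Whitney) test between two independent groups
#' (e.g. Assistive vs Perturbing participants), via [stats::wilcox.test()],
#' with Cohen's d on the raw values reported alongside.
#'
#' @param values_group1,values_group2 Numeric vectors, one per group.
#' @param alpha Significance threshold (default 0.025).
#' @param contrast Label for the comparison.
#' @return An `fpm_comparison` object.
#' @export
group_compare <- function(values_group1, values_group2, alpha = 0.025,
                          contrast = "group comparison") {
  x <- values_group1[is.finite(values_group1)]
  y <- values_group2[is.finite(values_group2)]
  if (length(x) == 0L || length(y) == 0L) abort("Both groups must be non-empty.")
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  d_eff <- if (sp > 0) (mean(x) - mean(y)) / sp else NA_real_
  new_fpm_comparison(
    contrast = contrast, method = "rank-sum",
    statistic = unname(wt$statistic), p_value = wt$p.value, alpha = alpha,
    effect_size_d = d_eff, n = length(x) + length(y)
  )
}

new_fpm_comparison <- function(contrast, method, statistic, p_value, alpha,
                               effect_size_d, n) {
  structure(
    list(contrast = contrast, method = method, statistic = statistic,
         p_value = p_value, alpha = alpha,
         significant = isTRUE(p_value < alpha),
         effect_size_d = effect_size_d, n = n),
    class = "fpm_comparison"
  )
}

#' @export
print.fpm_comparison <- function(x, ...) {
  p_txt <- if (is.na(x$p_value)) "undefined" else format.pval(x$p_value, digits = 3)
  cat(sprintf("<fpm_comparison> %s (%s, n = %d)\n", x$contrast, x$method, x$n))
  cat(sprintf("  statistic = %s, p = %s (alpha = %g) -> %s\n",
              format(x$statistic, digits = 4), p_txt, x$alpha,
              if (x$significant) "significant" else "not significant"))
  cat(sprintf("  Cohen's d (paired differences) = %s\n",
              format(x$effect_size_d, digits = 3)))
  invisible(x)
}

#' Tidy a comparison result
#' @param x An `fpm_comparison`.
#' @param ... Unused.
#' @return One-row tibble with `contrast`, `method`, `statistic`,
#'   `p_value`, `alpha`, `significant`, `effect_size_d`, `n`.
#' @exportS3Method generics::tidy
tidy.fpm_comparison <- function(x, ...) {
  tibble(
    contrast = x$contrast, method = x$method,
    statistic = x$statistic, p_value = x$p_value, alpha = x$alpha,
    significant = x$significant, effect_size_d = x$effect_size_d, n = x$n
  )
}

#' One-row model summary of a comparison result
#' @inheritParams tidy.fpm_comparison
#' @return Same one-row tibble as [tidy.fpm_comparison()].
#' @exportS3Method generics::glance
glance.fpm_comparison <- function(x, ...) tidy.fpm_comparison(x)
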