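#' Compare two samples of gap-junction sizes
#'
#' Runs the standard two-sample battery on gap-junction areas (or
#' diameters): Student's homoscedastic t, Welch's heteroscedastic t, the F
#' variance-ratio test and the two-sample Kolmogorov–Smirnov test, plus the
#' pooled-SD Cohen's d effect size and the post-hoc power of the
#' two-sample t-test at that effect size, computed from the noncentral-t
#' distribution (see [power_two_sample_t()]).
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param alpha Two-sided significance level for the power calculation.
#' @return An object of class `gj_comparison` with elements `tests`
#'   (tibble: method, statistic, p.value), `n1`, `n2`, `mean1`, `mean2`,
#'   `sd1`, `sd2`, `effect_size_d`, `power`, `alpha`. [tidy()] returns the
#'   test table; [glance()] a one-row summary.
#' @export
#' @examples
#' a <- rnorm(13, 0.37, 0.19)
#' b <- rnorm(228, 0.28, 0.18)
#' compare_gap_junction_sizes(a, b)
compare_gap_junction_sizes <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    abort("each sample needs at least 2 observations",
          class = "retcouple_domain_error")
  }
  n1 <- length(sample_a)
  n2 <- length(sample_b)
  tt_h <- t.test(sample_a, sample_b, var.equal = TRUE)
  tt_w <- t.test(sample_a, sample_b, var.equal = FALSE)
  ft <- var.test(sample_a, sample_b)
  ks <- suppressWarnings(ks.test(sample_a, sample_b))

  sp <- sqrt(((n1 - 1) * var(sample_a) + (n2 - 1) * var(sample_b)) /
               (n1 + n2 - 2))
  d <- if (sp > 0) abs(mean(sample_a) - mean(sample_b)) / sp else 0
  pw <- power_two_sample_t(n1, n2, d, alpha)

  tests <- tibble::tibble(
    method = c("t_homoscedastic", "t_welch", "F_ratio", "ks"),
    statistic = c(unname(tt_h$statistic), unname(tt_w$statistic),
                  unname(ft$statistic), unname(ks$statistic)),
    p.value = c(tt_h$p.value, tt_w$p.value, ft$p.value, ks$p.value)
  )
  structure(list(
    tests = tests, n1 = n1, n2 = n2,
    mean1 = mean(sample_a), mean2 = mean(sample_b),
    sd1 = sd(sample_a), sd2 = sd(sample_b),
    effect_size_d = d, power = pw, alpha = alpha
  ), class = "gj_comparison")
}

#' Post-hoc power of the two-sample t-test
#'
#' Power of the two-sided two-sample pooled t-test to detect a
#' standardised mean difference `d` (Cohen's d) with group sizes `n1` and
#' `n2`, from the noncentral-t distribution with noncentrality
#' `d * sqrt(n1 n2 / (n1 + n2))` on `n1 + n2 - 2` degrees of freedom.
#' With a very unequal design the smaller group dominates: power saturates
#' as the larger group grows.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param d Cohen's d (absolute standardised mean difference).
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' power_two_sample_t(13, 228, d = 0.5)
power_two_sample_t <- function(n1, n2, d, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, d >= 0, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp = ncp) + (1 - pt(tcrit, df, ncp = ncp))
}

#' @export
print.gj_comparison <- function(x, ...) {
  cat("<gj_comparison> n1 =", x$n1, " n2 =", x$n2, "\n")
  cat(sprintf("  mean1 = %.4g (sd %.3g), mean2 = %.4g (sd %.3g)\n",
              x$mean1, x$sd1, x$mean2, x$sd2))
  print(x$tests)
  cat(sprintf("  Cohen's d = %.3f, power = %.3f at alpha = %g\n",
              x$effect_size_d, x$power, x$alpha))
  invisible(x)
}

#' @method tidy gj_comparison
#' @export
tidy.gj_comparison <- function(x, ...) x$tests

#' @method glance gj_comparison
#' @export
glance.gj_comparison <- function(x, ...) {
  tibble::tibble(
    n1 = x$n1, n2 = x$n2, mean1 = x$mean1, mean2 = x$mean2,
    sd1 = x$sd1, sd2 = x$sd2, effect_size_d = x$effect_size_d,
    power = x$power, alpha = x$alpha,
    p_t_welch = x$tests$p.value[x$tests$method == "t_welch"],
    p_ks = x$tests$p.value[x$tests$method == "ks"]
  )
}
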