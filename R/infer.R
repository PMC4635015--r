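#' Maximum-likelihood fit of a normal distribution
#'
#' Closed-form MLE: location is the sample mean and scale the
#' maximum-likelihood (1/n) standard deviation. Used for wigwag
#' turn-angle distributions.
#'
#' @param samples Numeric vector, `n >= 2`, finite.
#' @return Object of class `wigwag_fit` with `family`, `location`,
#'   `scale`, `n` and `log_likelihood`.
#' @export
fit_normal_mle <- function(samples) {
  x <- samples
  if (length(x) < 2L) stop_wigwag("need at least 2 samples")
  if (!all(is.finite(x))) stop_wigwag("samples must be finite")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s < 1e-12) stop_wigwag("degenerate fit: sample has zero variance")
  structure(list(family = "normal", location = m, scale = s,
                 n = length(x),
                 log_likelihood = sum(stats::dnorm(x, m, s, log = TRUE))),
            class = "wigwag_fit")
}

#' Maximum-likelihood fit of a lognormal distribution
#'
#' The lognormal MLE is the normal MLE of the log-transformed sample;
#' `location` and `scale` are reported in log space. Used for wigwag
#' interval distributions.
#'
#' @param samples Strictly positive numeric vector, `n >= 2`.
#' @return Object of class `wigwag_fit` (family `"lognormal"`).
#' @export
fit_lognormal_mle <- function(samples) {
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop_wigwag("lognormal fit requires strictly positive finite samples")
  f <- fit_normal_mle(log(samples))
  f$family <- "lognormal"
  f$log_likelihood <- sum(stats::dlnorm(samples, f$location, f$scale, log = TRUE))
  f
}

#' @export
print.wigwag_fit <- function(x, ...) {
  cat(sprintf("<wigwag_fit> %s(location = %.4g, scale = %.4g), n = %d, logLik = %.4g\n",
              x$family, x$location, x$scale, x$n, x$log_likelihood))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin contract over [stats::ks.test()] reporting the D statistic
#' (supremum ECDF distance) and the asymptotic p-value.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop_wigwag("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Hypothesis tests for region preference
#'
#' The assay's two significance contracts: a Wilcoxon signed-rank test on
#' the paired per-animal (wall, central) preference indices, and a
#' chi-squared goodness-of-fit test of the animal counts per region
#' against the null split implied by the equal-area region construction
#' (50/50 by default).
#'
#' @param per_animal Data frame with columns `wall_index` and
#'   `central_index`, at least 5 rows.
#' @param region_counts Length-2 counts `c(wall, central)` of animals per
#'   region.
#' @param expected Null region probabilities (default `c(0.5, 0.5)`).
#' @param alternative Wilcoxon alternative; default `"greater"` (wall
#'   index exceeds central index).
#' @return List with `wilcoxon_p`, `chi2_stat`, `chi2_p`.
#' @export
preference_tests <- function(per_animal, region_counts,
                             expected = c(0.5, 0.5),
                             alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  if (!all(c("wall_index", "central_index") %in% names(per_animal)))
    stop_wigwag("per_animal needs columns wall_index and central_index")
  if (nrow(per_animal) < 5L)
    stop_wigwag("need at least 5 paired index values")
  d <- per_animal$wall_index - per_animal$central_index
  if (all(abs(d) < 1e-12))
    stop_wigwag("Wilcoxon undefined: all paired differences are zero")
  wt <- stats::wilcox.test(per_animal$wall_index, per_animal$central_index,
                           paired = TRUE, alternative = alternative,
                           exact = TRUE)
  if (length(region_counts) != 2L || any(region_counts < 0))
    stop_wigwag("region_counts must be two non-negative counts")
  ct <- suppressWarnings(stats::chisq.test(region_counts, p = expected))
  list(wilcoxon_p = wt$p.value,
       chi2_stat = unname(ct$statistic),
       chi2_p = ct$p.value)
}

#' Two-group comparison of preference indices
#'
#' Thin contract over [stats::t.test()] (Welch by default) for comparing
#' wall-preference indices between conditions, as used for arena-size and
#' curvature contrasts.
#'
#' @param x,y Numeric index samples for the two conditions.
#' @param ... Passed to [stats::t.test()].
#' @return List with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
index_t_test <- function(x, y, ...) {
  tt <- stats::t.test(x, y, ...)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}
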