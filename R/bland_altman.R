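#' Bland-Altman agreement between two measurement methods
#'
#' Computes the classical limits-of-agreement analysis for paired
#' measurements of the same quantity (here, meal energy estimated by a rater
#' versus the weighed reference). Differences are `estimate - reference`;
#' the limits of agreement are the mean difference plus/minus
#' `loa_multiplier` sample standard deviations (default 2), the convention
#' "mean difference +/- 2 SD". The mean difference carries a t-based 95%
#' confidence interval, and the association between differences and pair
#' means is summarized by a Pearson correlation with its p-value (a
#' diagnostic that agreement does not depend on the size of the
#' measurement).
#'
#' @param estimate Numeric vector of test-method values (kcal).
#' @param reference Paired vector of reference-method values (kcal).
#' @param conf_level Confidence level for the mean-difference CI.
#' @param loa_multiplier SD multiplier for the limits of agreement
#'   (default 2).
#' @return An object of class `bland_altman` with components `n`,
#'   `mean_diff`, `sd_diff`, `ci_mean_diff`, `loa`, `n_outside_loa`, and
#'   `corr_diff_vs_mean` (`r`, `p`; `NA` when the differences or means are
#'   constant).
#' @examples
#' ba <- bland_altman(c(103, 97, 100), c(100, 100, 100))
#' ba$loa  # -6, 6
#' @seealso [plot.bland_altman()]
#' @export
bland_altman <- function(estimate, reference, conf_level = 0.95,
                         loa_multiplier = 2) {
  if (length(estimate) != length(reference))
    stop("estimate and reference must be paired")
  if (any(!is.finite(estimate)) || any(!is.finite(reference)))
    stop("values must be finite")
  n <- length(estimate)
  if (n < 3) stop("insufficient pairs: need at least 3")
  d <- estimate - reference
  m <- (estimate + reference) / 2
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  se <- sd_diff / sqrt(n)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  loa <- mean_diff + c(-1, 1) * loa_multiplier * sd_diff
  corr <- if (sd_diff == 0 || stats::sd(m) == 0) {
    list(r = NA_real_, p = NA_real_)
  } else {
    ct <- stats::cor.test(d, m)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  structure(list(n = n, mean_diff = mean_diff, sd_diff = sd_diff,
                 ci_mean_diff = mean_diff + c(-1, 1) * tcrit * se,
                 loa = loa,
                 n_outside_loa = sum(d < loa[1] | d > loa[2]),
                 corr_diff_vs_mean = corr,
                 conf_level = conf_level, loa_multiplier = loa_multiplier,
                 differences = d, means = m),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat("Bland-Altman agreement (n =", x$n, "pairs)\n")
  cat(sprintf("  Mean difference: %s kcal (%d%% CI %s to %s)\n",
              format(x$mean_diff, digits = digits),
              round(100 * x$conf_level),
              format(x$ci_mean_diff[1], digits = digits),
              format(x$ci_mean_diff[2], digits = digits)))
  cat(sprintf("  Limits of agreement (mean +/- %g SD): %s to %s kcal\n",
              x$loa_multiplier,
              format(x$loa[1], digits = digits),
              format(x$loa[2], digits = digits)))
  cat(sprintf("  %d observation(s) outside the limits\n", x$n_outside_loa))
  if (!is.na(x$corr_diff_vs_mean$r))
    cat(sprintf("  Corr(differences, means): r = %s, p = %s\n",
                format(x$corr_diff_vs_mean$r, digits = 2),
                format.pval(x$corr_diff_vs_mean$p, digits = 2)))
  else
    cat("  Corr(differences, means): undefined (zero variance)\n")
  invisible(x)
}

#' @export
summary.bland_altman <- function(object, ...) print(object, ...)

#' Bland-Altman plot
#'
#' Differences plotted against pair means, with the mean difference (solid)
#' and limits of agreement (dotted) as horizontal reference lines.
#'
#' @param x A [bland_altman()] fit.
#' @param xlab,ylab,... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman <- function(x, xlab = "Mean of estimates (kcal)",
                              ylab = "Difference (kcal)", ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab,
                 ylim = range(c(x$differences, x$loa)), ...)
  graphics::abline(h = x$mean_diff, lty = 1)
  graphics::abline(h = x$loa, lty = 3)
  invisible(x)
}
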