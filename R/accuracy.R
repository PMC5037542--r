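#' Accuracy of rater estimates against weighed true values
#'
#' If raters are accurate, estimate = slope x true value + intercept with
#' intercept 0 and slope 1. This fits the linear calibration
#' `estimate ~ true_value` with a random tray intercept (several raters
#' assess the same tray, so records cluster within tray) by REML, and tests
#' the two null hypotheses intercept = 0 and slope = 1. Wald t tests with
#' Satterthwaite degrees of freedom are the default; likelihood-ratio tests
#' (ML refits) are available via `test = "lrt"`.
#'
#' @param records Data.frame of assessment records with columns `tray_id`,
#'   `rater_id`, `estimate`, `true_value` (kcal).
#' @param test `"wald"` (default) or `"lrt"`.
#' @param conf_level Confidence level for the coefficient CIs.
#' @return An object of class `accuracy_fit`: `coefficients` (estimate, SE,
#'   df, CI per term), `p_intercept_vs_0`, `p_slope_vs_1`, `varcomp`
#'   (tray and residual variances), and the underlying `lmerModLmerTest`
#'   fit in `$fit`.
#' @examples
#' set.seed(1)
#' rec <- expand.grid(tray_id = paste0("T", 1:30), rater_id = paste0("R", 1:3))
#' rec$true_value <- rep(stats::runif(30, 200, 800), 3)
#' rec$estimate <- rec$true_value + stats::rnorm(90, 0, 20)
#' accuracy_model(rec)
#' @export
accuracy_model <- function(records, test = c("wald", "lrt"), conf_level = 0.95) {
  test <- match.arg(test)
  req <- c("tray_id", "rater_id", "estimate", "true_value")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(records$true_value)) stop("true values must be present for all records")
  if (length(unique(records$tray_id)) < 2)
    stop("need at least 2 trays")
  per_tray <- table(records$tray_id)
  if (all(per_tray < 2))
    stop("need at least 2 raters per tray for the random tray effect")
  if (stats::var(records$true_value) == 0)
    stop("slope unidentifiable: all true values are equal")
  d <- data.frame(estimate = records$estimate, true_value = records$true_value,
                  tray_id = factor(records$tray_id))
  fs <- fit_lmer_satt(estimate ~ true_value + (1 | tray_id), d)
  fit <- fs$fit
  cs <- fs$coefs  # Satterthwaite df
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = cs[, "df"])
  coefs <- data.frame(term = c("intercept", "slope"),
                      estimate = cs[, "Estimate"],
                      se = cs[, "Std. Error"],
                      df = cs[, "df"],
                      ci_low = cs[, "Estimate"] - tcrit * cs[, "Std. Error"],
                      ci_high = cs[, "Estimate"] + tcrit * cs[, "Std. Error"],
                      row.names = NULL)
  if (test == "wald") {
    t0 <- cs["(Intercept)", "Estimate"] / cs["(Intercept)", "Std. Error"]
    t1 <- (cs["true_value", "Estimate"] - 1) / cs["true_value", "Std. Error"]
    p0 <- 2 * stats::pt(-abs(t0), df = cs["(Intercept)", "df"])
    p1 <- 2 * stats::pt(-abs(t1), df = cs["true_value", "df"])
  } else {
    full <- lme4::lmer(estimate ~ true_value + (1 | tray_id), data = d, REML = FALSE)
    no_int <- lme4::lmer(estimate ~ 0 + true_value + (1 | tray_id), data = d,
                         REML = FALSE)
    slope1 <- lme4::lmer(estimate ~ 1 + (1 | tray_id) + offset(true_value),
                         data = d, REML = FALSE)
    p0 <- stats::anova(no_int, full)[2, "Pr(>Chisq)"]
    p1 <- stats::anova(slope1, full)[2, "Pr(>Chisq)"]
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(tray = vc$vcov[vc$grp == "tray_id"],
               residual = vc$vcov[vc$grp == "Residual"])
  structure(list(coefficients = coefs, p_intercept_vs_0 = p0,
                 p_slope_vs_1 = p1, varcomp = varcomp, test = test,
                 conf_level = conf_level, n = nrow(d),
                 n_trays = nlevels(d$tray_id), fit = fit),
            class = "accuracy_fit")
}

#' @export
print.accuracy_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Rater accuracy calibration (REML): %d records, %d trays\n",
              x$n, x$n_trays))
  cf <- x$coefficients
  cat(sprintf("  Intercept: %s (%d%% CI %s to %s), p vs 0 = %s\n",
              format(cf$estimate[1], digits = digits),
              round(100 * x$conf_level),
              format(cf$ci_low[1], digits = digits),
              format(cf$ci_high[1], digits = digits),
              format.pval(x$p_intercept_vs_0, digits = 2)))
  cat(sprintf("  Slope:     %s (%d%% CI %s to %s), p vs 1 = %s\n",
              format(cf$estimate[2], digits = digits),
              round(100 * x$conf_level),
              format(cf$ci_low[2], digits = digits),
              format(cf$ci_high[2], digits = digits),
              format.pval(x$p_slope_vs_1, digits = 2)))
  cat(sprintf("  Variance components: tray %s, residual %s\n",
              format(x$varcomp[["tray"]], digits = digits),
              format(x$varcomp[["residual"]], digits = digits)))
  invisible(x)
}

#' @export
summary.accuracy_fit <- function(object, ...) {
  print(object, ...)
  cat("\nUnderlying mixed-model summary:\n")
  print(summary(object$fit))
  invisible(object)
}

#' @export
coef.accuracy_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.accuracy_fit <- function(object, ...) {
  m <- as.matrix(object$coefficients[, c("ci_low", "ci_high")])
  rownames(m) <- object$coefficients$term
  m
}

#' @export
residuals.accuracy_fit <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
predict.accuracy_fit <- function(object, ...) stats::predict(object$fit, ...)
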