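# REML fit with Satterthwaite coefficient table, falling back to residual
# degrees of freedom when the data are degenerate (e.g. zero residual
# variance), where the Satterthwaite machinery is undefined.
fit_lmer_satt <- function(form, data) {
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(form, data = data, REML = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cs <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
    if (!is.null(cs) && "df" %in% colnames(cs) && all(is.finite(cs[, "df"])))
      return(list(fit = fit, coefs = cs))
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = data, REML = TRUE)))
  beta <- lme4::fixef(fit)
  se <- tryCatch(
    sqrt(diag(as.matrix(stats::vcov(fit, use.hessian = FALSE)))),
    error = function(e) NULL)
  if (is.null(se)) {
    # zero-variance corner: the mixed fit collapses onto ordinary least
    # squares, whose coefficient table is well defined
    fe_form <- lme4::nobars(form)
    ls <- stats::lm(fe_form, data = data)
    beta <- stats::coef(ls)
    se <- sqrt(diag(stats::vcov(ls)))
  }
  df <- nrow(data) - length(beta)
  tv <- beta / se
  cs <- cbind(Estimate = beta, "Std. Error" = se, df = df,
              "t value" = tv, "Pr(>|t|)" = 2 * stats::pt(-abs(tv), df))
  list(fit = fit, coefs = cs)
}
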