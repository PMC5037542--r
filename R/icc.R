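#' Inter-rater reliability: intraclass correlation from a mixed model
#'
#' Gauges agreement between raters who independently estimated meal energy
#' on the same trays. A linear mixed model with a random intercept per tray
#' (and optional fixed covariates such as day and meal) is fitted by REML;
#' the ICC is the between-tray variance divided by the total
#' (tray + residual) variance after covariate adjustment. Because only tray
#' enters as a random grouping, the estimator applies equally to complete
#' designs (every rater rates every tray) and incomplete ones (each tray
#' rated by a subset of raters), as long as trays carry at least two
#' ratings.
#'
#' The confidence interval is computed by a seeded parametric bootstrap:
#' new responses are simulated from the fitted model, the model is refitted,
#' and percentile limits of the replicate ICCs are reported. (The interval
#' method used in the original SAS analyses of this design is not published,
#' so the bootstrap is the package's documented choice.)
#'
#' @param records Data.frame with columns `tray_id`, `rater_id`, `estimate`,
#'   plus any covariate columns named in `covariates`.
#' @param covariates Character vector of fixed-effect covariate columns
#'   (each treated as a factor; default `c("day", "meal")` when present).
#'   Covariates with fewer than two observed levels are dropped.
#' @param ci `"bootstrap"` (default) or `"none"`.
#' @param nboot Number of parametric bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (required when
#'   `ci = "bootstrap"`).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_fit`: `icc`, `ci`, `varcomp` (tray,
#'   residual), `design` (`"complete"` or `"incomplete"`), and the
#'   underlying fit in `$fit`.
#' @examples
#' set.seed(7)
#' rec <- expand.grid(tray_id = paste0("T", 1:30), rater_id = paste0("R", 1:3))
#' rec$estimate <- rep(stats::rnorm(30, 500, 100), 3) + stats::rnorm(90, 0, 33)
#' icc_model(rec, covariates = NULL, ci = "none")
#' @export
icc_model <- function(records, covariates = intersect(c("day", "meal"), names(records)),
                      ci = c("bootstrap", "none"), nboot = 1000, seed = NULL,
                      conf_level = 0.95) {
  ci <- match.arg(ci)
  req <- c("tray_id", "rater_id", "estimate")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  per_tray <- table(records$tray_id)
  if (max(per_tray) < 2)
    stop("reliability unidentifiable: no tray has 2 or more ratings")
  d <- data.frame(estimate = records$estimate, tray_id = factor(records$tray_id))
  keep <- character()
  for (cv in covariates) {
    f <- factor(records[[cv]])
    if (nlevels(f) >= 2) { d[[cv]] <- f; keep <- c(keep, cv) }
  }
  rhs <- paste(c(if (length(keep)) keep else "1", "(1 | tray_id)"),
               collapse = " + ")
  form <- stats::as.formula(paste("estimate ~", rhs))
  fit <- lme4::lmer(form, data = d, REML = TRUE)
  icc_of <- function(f) {
    vc <- as.data.frame(lme4::VarCorr(f))
    vt <- max(vc$vcov[vc$grp == "tray_id"], 0)
    vr <- vc$vcov[vc$grp == "Residual"]
    c(icc = vt / (vt + vr), tray = vt, residual = vr)
  }
  est <- icc_of(fit)
  # complete design: every rater rated every tray
  inc <- table(records$tray_id, records$rater_id) > 0
  design <- if (all(inc)) "complete" else "incomplete"
  ci_val <- c(NA_real_, NA_real_)
  if (ci == "bootstrap") {
    if (is.null(seed)) stop("a seed is required for the bootstrap CI")
    set.seed(seed)
    sims <- stats::simulate(fit, nsim = nboot)
    reps <- vapply(seq_len(nboot), function(i) {
      di <- d
      di$estimate <- sims[[i]]
      fi <- suppressMessages(suppressWarnings(
        lme4::lmer(form, data = di, REML = TRUE)))
      icc_of(fi)[["icc"]]
    }, numeric(1))
    a <- (1 - conf_level) / 2
    ci_val <- unname(stats::quantile(reps, c(a, 1 - a), na.rm = TRUE))
  }
  structure(list(icc = unname(est[["icc"]]), ci = ci_val,
                 varcomp = c(tray = unname(est[["tray"]]),
                             residual = unname(est[["residual"]])),
                 design = design, covariates = keep, ci_method = ci,
                 nboot = if (ci == "bootstrap") nboot else NA_integer_,
                 seed = seed, conf_level = conf_level,
                 n = nrow(d), n_trays = nlevels(d$tray_id),
                 n_raters = length(unique(records$rater_id)), fit = fit),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Inter-rater reliability (REML mixed model, %s design)\n", x$design))
  cat(sprintf("  %d ratings, %d trays, %d raters", x$n, x$n_trays, x$n_raters))
  if (length(x$covariates))
    cat("; covariates:", paste(x$covariates, collapse = ", "))
  cat("\n")
  if (!anyNA(x$ci))
    cat(sprintf("  ICC = %s (%d%% CI %s to %s, parametric bootstrap n=%d)\n",
                format(x$icc, digits = digits), round(100 * x$conf_level),
                format(x$ci[1], digits = digits),
                format(x$ci[2], digits = digits), x$nboot))
  else
    cat(sprintf("  ICC = %s\n", format(x$icc, digits = digits)))
  cat(sprintf("  Variance components: tray %s, residual %s\n",
              format(x$varcomp[["tray"]], digits = digits),
              format(x$varcomp[["residual"]], digits = digits)))
  invisible(x)
}

#' @export
summary.icc_fit <- function(object, ...) {
  print(object, ...)
  cat("\nUnderlying mixed-model summary:\n")
  print(summary(object$fit))
  invisible(object)
}

#' @export
confint.icc_fit <- function(object, ...) {
  matrix(object$ci, nrow = 1,
         dimnames = list("icc", c("ci_low", "ci_high")))
}
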