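# Thermal tolerance statistics: LT50 dose-response fits, LT50 ratio
# tests, upper thermal limits, and survival decline widths.

#' Fit a logistic dose-response model for worker death
#'
#' Fits a binomial GLM with logit link of death probability on assay
#' temperature for a single species, by maximum likelihood (IRLS,
#' deviance tolerance 1e-8, at most 100 iterations). When the data are
#' completely or quasi-completely separated (every tube all-dead or
#' all-alive, perfectly ordered by temperature), the ML estimate diverges;
#' the model is then refit with Jeffreys-prior (Firth) penalization and
#' the result is flagged `method = "firth"`.
#'
#' The median lethal temperature is `lt50 = -beta0/beta1`; its standard
#' error follows from the delta method with gradient
#' `(-1/beta1, -lt50/beta1)`, and the 95% confidence interval is
#' `lt50 +/- 1.96 * se_lt50`.
#'
#' @param obs a `survival_table` (or data.frame with columns
#'   `temperature`, `n_total`, `n_dead`) for one species.
#' @param tol IRLS deviance convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @return an object of class `dose_response_fit` with elements `beta0`,
#'   `beta1`, `cov`, `lt50`, `se_lt50`, `ci95`, `converged`, `method`,
#'   `n_obs`, `species`.
#' @export
fit_dose_response <- function(obs, tol = 1e-8, maxit = 100L) {
  if (length(unique(obs$temperature)) < 2L)
    stop("dose-response fit needs at least two distinct temperatures")
  if (sum(obs$n_dead) == 0L || sum(obs$n_dead) == sum(obs$n_total))
    stop("dose-response fit needs at least one death and one survival overall")
  fit <- suppressWarnings(
    glm(cbind(n_dead, n_total - n_dead) ~ temperature,
        family = binomial("logit"), data = as.data.frame(obs),
        control = glm.control(epsilon = tol, maxit = maxit)))
  beta <- unname(coef(fit))
  V <- tryCatch(unname(vcov(fit)), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(diag(V))
  separated <- !fit$converged || any(!is.finite(beta)) ||
    any(!is.finite(se)) || abs(beta[2]) > 20 || se[2] > 5
  method <- "ml"
  converged <- fit$converged
  if (separated) {
    ff <- .firth_logistic(cbind(1, obs$temperature), obs$n_dead, obs$n_total)
    beta <- ff$beta
    V <- ff$cov
    method <- "firth"
    converged <- ff$converged
  }
  lt50 <- -beta[1] / beta[2]
  grad <- c(-1 / beta[2], -lt50 / beta[2])
  se_lt50 <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(list(
    beta0 = beta[1], beta1 = beta[2], cov = V,
    lt50 = lt50, se_lt50 = se_lt50,
    ci95 = c(lt50 - 1.96 * se_lt50, lt50 + 1.96 * se_lt50),
    converged = converged, method = method, n_obs = nrow(obs),
    species = if (!is.null(obs$species)) obs$species[1] else NA_character_),
    class = "dose_response_fit")
}

# Firth-penalized logistic regression on aggregated binomial data.
# Modified score: U*(b) = X'(y - m*p + h*(1/2 - p)), h = hat diagonal of
# the weighted least-squares projection.
.firth_logistic <- function(X, y, m, tol = 1e-10, maxit = 200L) {
  beta <- c(qlogis(pmin(pmax(sum(y) / sum(m), 0.05), 0.95)), 0)
  # crude slope start from the temperature spread
  converged <- FALSE
  XtWX <- diag(2)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- m * p * (1 - p)
    XtWX <- crossprod(X, X * w)
    XtWXi <- solve(XtWX)
    h <- w * rowSums((X %*% XtWXi) * X)
    U <- drop(crossprod(X, y - m * p + h * (0.5 - p)))
    step <- drop(XtWXi %*% U)
    # dampen large steps for stability on near-degenerate data
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  XtWX <- crossprod(X, X * (m * p * (1 - p)))
  list(beta = beta, cov = solve(XtWX), converged = converged)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "Dose-response fit (%s%s): LT50 = %.2f C (95%% CI %.2f-%.2f), slope = %.3f/C\n",
    x$method, if (is.na(x$species)) "" else paste0(", ", x$species),
    x$lt50, x$ci95[1], x$ci95[2], x$beta1))
  invisible(x)
}

#' Ratio test comparing two LT50 estimates
#'
#' Tests the null hypothesis that the LT50 ratio between two fitted
#' species equals 1. The log ratio has delta-method standard error
#' `sqrt(se_logA^2 + se_logB^2)` with `se_log = se_lt50 / lt50`; the
#' statistic `z = log(lt50_A/lt50_B) / se` is referred to the standard
#' normal (two-sided), and the 95% CI of the ratio is
#' `exp(log-ratio +/- 1.96 * se)`.
#'
#' @param fit_a,fit_b `dose_response_fit` objects.
#' @return an object of class `ratio_test` with elements `ratio`,
#'   `log_ratio_se`, `ci95`, `z`, `p`.
#' @export
ratio_test <- function(fit_a, fit_b) {
  for (f in list(fit_a, fit_b)) {
    if (!inherits(f, "dose_response_fit"))
      stop("ratio_test expects dose_response_fit objects")
    if (!isTRUE(f$converged) || f$beta1 <= 0)
      stop("ratio_test requires converged fits with positive slope")
    if (f$lt50 <= 0)
      stop("ratio_test undefined for non-positive LT50 (log scale)")
  }
  lr <- log(fit_a$lt50) - log(fit_b$lt50)
  se <- sqrt((fit_a$se_lt50 / fit_a$lt50)^2 + (fit_b$se_lt50 / fit_b$lt50)^2)
  z <- lr / se
  structure(list(
    ratio = fit_a$lt50 / fit_b$lt50,
    log_ratio_se = se,
    ci95 = exp(c(lr - 1.96 * se, lr + 1.96 * se)),
    z = z,
    p = 2 * pnorm(-abs(z)),
    species = c(fit_a$species, fit_b$species)),
    class = "ratio_test")
}

#' @export
print.ratio_test <- function(x, ...) {
  cat(sprintf(
    "LT50 ratio test: ratio = %.4f (95%% CI %.4f-%.4f), z = %.3f, p = %.3g\n",
    x$ratio, x$ci95[1], x$ci95[2], x$z, x$p))
  invisible(x)
}

#' Determine the upper thermal limit (UTL)
#'
#' The UTL is the highest assayed temperature at which survival does not
#' differ significantly from full survival. Per-tube survival proportions
#' are compared across temperature groups by one-way ANOVA; Tukey HSD
#' contrasts every group against the reference group (the temperature with
#' the highest mean survival, ties resolved to the lowest temperature).
#' The UTL is the highest temperature whose adjusted p-value against the
#' reference is at least `alpha`.
#'
#' Degenerate inputs: if every group has zero within-group variance and
#' all group means are identical, the ANOVA is undefined and the UTL is
#' reported as the highest tested temperature with `degenerate = TRUE`.
#' With zero residual variance but differing means, groups identical to
#' the reference are treated as indistinguishable (p 1) and differing
#' groups as different (p 0).
#'
#' @param obs a `survival_table` for one species (>= 2 temperatures,
#'   >= 2 tubes per temperature).
#' @param alpha significance level for the Tukey comparisons.
#' @return an object of class `utl_result` with elements `utl`,
#'   `anova_f`, `anova_p`, `tukey` (adjusted p per temperature vs the
#'   reference), `reference_temperature`, `degenerate`.
#' @export
determine_utl <- function(obs, alpha = 0.05) {
  temps <- sort(unique(obs$temperature))
  if (length(temps) < 2L)
    stop("UTL needs at least two temperatures")
  if (any(table(obs$temperature) < 2L))
    stop("UTL needs at least two tubes per temperature")
  surv <- 1 - obs$n_dead / obs$n_total
  tf <- factor(obs$temperature, levels = temps)
  means <- tapply(surv, tf, mean)
  ref <- levels(tf)[which(means == max(means))[1]]
  wvar <- tapply(surv, tf, var)
  if (all(wvar == 0) && length(unique(means)) == 1L) {
    return(structure(list(
      utl = max(temps), anova_f = NA_real_, anova_p = NA_real_,
      tukey = setNames(rep(NA_real_, length(temps)), temps),
      reference_temperature = as.numeric(ref), alpha = alpha,
      degenerate = TRUE), class = "utl_result"))
  }
  fit <- aov(surv ~ tf)
  an <- summary(fit)[[1]]
  tk <- suppressWarnings(TukeyHSD(fit)$tf)
  padj <- setNames(rep(NA_real_, length(temps)), levels(tf))
  padj[ref] <- 1
  for (rn in rownames(tk)) {
    pair <- strsplit(rn, "-", fixed = TRUE)[[1]]
    if (ref %in% pair) {
      other <- setdiff(pair, ref)
      p <- tk[rn, "p adj"]
      if (is.nan(p)) p <- if (tk[rn, "diff"] == 0) 1 else 0
      padj[other] <- p
    }
  }
  ok <- as.numeric(names(padj)[!is.na(padj) & padj >= alpha])
  structure(list(
    utl = if (length(ok)) max(ok) else NA_real_,
    anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
    tukey = padj, reference_temperature = as.numeric(ref),
    alpha = alpha, degenerate = FALSE), class = "utl_result")
}

#' @export
print.utl_result <- function(x, ...) {
  cat(sprintf("UTL = %s C (reference %.0f C, alpha %.2f%s)\n",
              format(x$utl), x$reference_temperature, x$alpha,
              if (x$degenerate) ", degenerate: no group variation" else ""))
  invisible(x)
}

#' Width of the survival decline
#'
#' Locates `t_high`, the highest tested temperature with mean survival at
#' or above `upper`, and `t_zero`, the lowest tested temperature with mean
#' survival at or below `lower`; the decline width is
#' `t_zero - t_high` (degrees C). Either side may be undefined when the
#' survival curve never crosses the corresponding threshold; a
#' non-monotone curve with `t_zero < t_high` is reported with a warning.
#'
#' @param obs a `survival_table` for one species.
#' @param upper,lower mean-survival thresholds (defaults 0.90 and 0.05)
#'   operationalizing "around 100%" and "0%".
#' @return an object of class `decline_width` with elements `t_high`,
#'   `t_zero`, `width`, `upper`, `lower`, `reason`.
#' @export
decline_width <- function(obs, upper = 0.90, lower = 0.05) {
  temps <- sort(unique(obs$temperature))
  surv <- 1 - obs$n_dead / obs$n_total
  means <- tapply(surv, factor(obs$temperature, levels = temps), mean)
  hi <- temps[means >= upper]
  lo <- temps[means <= lower]
  t_high <- if (length(hi)) max(hi) else NA_real_
  t_zero <- if (length(lo)) min(lo) else NA_real_
  reason <- NULL
  if (is.na(t_high)) reason <- c(reason, "mean survival never reached upper threshold")
  if (is.na(t_zero)) reason <- c(reason, "mean survival never reached lower threshold")
  width <- t_zero - t_high
  if (!is.na(width) && width < 0)
    warning("non-monotone survival: survival crossed the lower threshold below the upper-threshold temperature")
  structure(list(t_high = t_high, t_zero = t_zero, width = width,
                 upper = upper, lower = lower,
                 reason = if (is.null(reason)) NA_character_ else
                   paste(reason, collapse = "; ")),
            class = "decline_width")
}

#' @export
print.decline_width <- function(x, ...) {
  cat(sprintf("Survival decline: %s -> %s C, width %s C\n",
              format(x$t_high), format(x$t_zero), format(x$width)))
  invisible(x)
}
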