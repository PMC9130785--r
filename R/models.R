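#' Fit an MHC-diversity interaction model for one chemical variable
#'
#' Ordinary least squares of a per-individual chemical response (e.g. a PC
#' score) on MHC diversity, sex, breeding status and the two-way
#' interactions diversity x sex and diversity x breeding status. Term
#' p-values come from a Type III ANOVA with sum-to-zero contrasts on sex
#' (the orthodox coding for Type III tests); reference-level (treatment)
#' coefficients are additionally reported because published tables often
#' print that coding without saying so. Simple slopes of the response on
#' diversity are returned per sex (at the mean breeding status) and at
#' breeding status mean and mean +/- 1 s.d. (averaged over sex), matching
#' the early/mid/late presentation convention.
#'
#' @param data Per-individual tibble containing the response, diversity,
#'   `sex` ("F"/"M") and breeding-status columns; no missing values in used
#'   columns.
#' @param response,diversity,status Column names (strings). `status`
#'   defaults to `"breeding_status"`.
#' @param conf_level Confidence level for coefficient intervals.
#' @return An object of class `mhc_lm` with components `fit` (sum-coded lm),
#'   `fit_treatment`, `anova` (Type III), `slopes_by_sex`,
#'   `slopes_by_status` and the model spec; use [tidy.mhc_lm()] /
#'   [glance.mhc_lm()].
#' @export
fit_interaction_model <- function(data, response, diversity,
                                  status = "breeding_status",
                                  conf_level = 0.95) {
  used <- c(response, diversity, "sex", status)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[used]
  if (anyNA(d)) stop("missing values in model columns", call. = FALSE)
  check_sex(d$sex)
  d <- tibble::tibble(
    response = data[[response]],
    diversity = data[[diversity]],
    sex = factor(data$sex, levels = c("F", "M")),
    status = data[[status]]
  )
  n_par <- 6
  if (nrow(d) <= n_par + 1) {
    stop("too few rows (", nrow(d), ") for a ", n_par, "-parameter model",
         call. = FALSE)
  }
  form <- response ~ diversity + sex + status +
    diversity:sex + diversity:status
  fit <- stats::lm(form, data = d, contrasts = list(sex = "contr.sum"))
  alias <- stats::alias(fit)$Complete
  if (!is.null(alias)) {
    stop("rank-deficient model; aliased term(s): ",
         paste(rownames(alias), collapse = ", "), call. = FALSE)
  }
  fit_tr <- stats::lm(form, data = d)
  # a perfect (zero-residual) fit has no error stratum: report the
  # coefficients with undefined Type III p-values instead of failing
  a3 <- tryCatch(
    car::Anova(fit, type = 3),
    error = function(e) {
      if (!grepl("residual sum of squares", conditionMessage(e))) stop(e)
      terms <- c("(Intercept)", "diversity", "sex", "status",
                 "diversity:sex", "diversity:status", "Residuals")
      nas <- rep(NA_real_, length(terms))
      data.frame(`Sum Sq` = nas, Df = nas, `F value` = nas,
                 `Pr(>F)` = nas, row.names = terms, check.names = FALSE)
    }
  )
  # simple slopes of response on diversity
  sl_sex <- emmeans::emtrends(fit, ~sex, var = "diversity")
  m <- mean(d$status)
  s <- stats::sd(d$status)
  sl_status <- emmeans::emtrends(
    fit, ~status, var = "diversity",
    at = list(status = c(early = m - s, mid = m, late = m + s))
  )
  structure(
    list(
      fit = fit, fit_treatment = fit_tr, anova = a3,
      slopes_by_sex = summary(sl_sex, infer = c(TRUE, TRUE)),
      slopes_by_status = summary(sl_status, infer = c(TRUE, TRUE)),
      response = response, diversity = diversity, status = status,
      conf_level = conf_level, n = nrow(d)
    ),
    class = "mhc_lm"
  )
}

type3_p <- function(object) {
  a <- object$anova
  terms <- rownames(a)
  stats::setNames(a[["Pr(>F)"]], terms)
}

#' Tidy an interaction model fit
#'
#' One row per model term with the coefficient estimate, standard error and
#' confidence interval, plus the Type III p-value for the matching ANOVA
#' term (intercept and residuals excluded from p-value matching where not
#' applicable).
#'
#' @param x An `mhc_lm` object.
#' @param coding `"sum"` (sum-to-zero sex contrasts, the coding the Type III
#'   tests use) or `"treatment"` (reference level = female).
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std_error`, `conf_low`, `conf_high`,
#'   `p_type3`.
#' @export
tidy.mhc_lm <- function(x, coding = c("sum", "treatment"), ...) {
  coding <- match.arg(coding)
  fit <- if (coding == "sum") x$fit else x$fit_treatment
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = x$conf_level)
  # map coefficient rows to Type III ANOVA terms
  p3 <- type3_p(x)
  term_of <- function(coef_name) {
    if (coef_name == "(Intercept)") return("(Intercept)")
    base <- gsub("sex[A-Z1-9]*", "sex", coef_name)
    if (base %in% names(p3)) base else NA_character_
  }
  terms <- vapply(rownames(cf), term_of, character(1))
  tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std_error = unname(cf[, "Std. Error"]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2]),
    p_type3 = unname(p3[terms])
  )
}

#' Model-level summary of an interaction model fit
#'
#' @param x An `mhc_lm` object.
#' @param ... Unused.
#' @return One-row tibble: adjusted R-squared, F statistic, numerator /
#'   denominator d.f., overall p-value, n.
#' @export
glance.mhc_lm <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble::tibble(
    adj_r_squared = s$adj.r.squared,
    statistic = unname(f[1]),
    df = unname(f[2]),
    df_residual = unname(f[3]),
    p_value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    n = x$n
  )
}

#' Simple slopes from an interaction model
#'
#' @param x An `mhc_lm` object.
#' @param by `"sex"` (per-sex slope of the response on diversity, at mean
#'   breeding status) or `"status"` (slope at breeding status mean and
#'   mean +/- 1 s.d.).
#' @return Tibble with the group, slope, standard error, CI and p-value.
#' @export
simple_slopes <- function(x, by = c("sex", "status")) {
  by <- match.arg(by)
  s <- if (by == "sex") x$slopes_by_sex else x$slopes_by_status
  out <- tibble::as_tibble(s)
  names(out)[names(out) == "diversity.trend"] <- "slope"
  names(out)[names(out) == "SE"] <- "std_error"
  names(out)[names(out) == "lower.CL"] <- "conf_low"
  names(out)[names(out) == "upper.CL"] <- "conf_high"
  names(out)[names(out) == "p.value"] <- "p_value"
  if (by == "status") {
    out$phase <- c("early", "mid", "late")[order(order(out$status))]
  }
  out
}

#' @export
print.mhc_lm <- function(x, ...) {
  cat("Interaction model:", x$response, "~", x$diversity,
      "* (sex + breeding status)\n")
  g <- glance(x)
  cat(sprintf("adj R^2 = %.3f, F = %.3f (d.f. = %d, %d), p = %s\n",
              g$adj_r_squared, g$statistic, g$df, g$df_residual,
              format.pval(g$p_value, digits = 3)))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Pooled-variance two-sample t test
#'
#' Classic equal-variance two-sample t (d.f. = n1 + n2 - 2), two-sided.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return One-row tibble `t`, `df`, `p_value`, `mean_x`, `mean_y`; `t` and
#'   `p_value` are `NA` with a warning when the pooled variance is zero.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  df <- length(x) + length(y) - 2
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    warning("zero pooled variance: t statistic undefined")
    return(tibble::tibble(t = NA_real_, df = df, p_value = NA_real_,
                          mean_x = mean(x), mean_y = mean(y)))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  tibble::tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_x = mean(x),
    mean_y = mean(y)
  )
}
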