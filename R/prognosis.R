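#' Methylation score of a sample
#'
#' Mean beta-value over the detector's feature windows, a cfDNA
#' tumor-burden surrogate. Missing beta-values are excluded from both the
#' numerator and denominator (zero-filling would deflate scores of shallow
#' samples).
#'
#' @param beta beta vector over windows (named) or window x sample matrix.
#' @param feature_windows window ids of the detection classifier.
#' @return numeric score in `[0, 1]` (per sample for a matrix); `NA` with a
#'   warning when every window is missing.
#' @export
methylation_score <- function(beta, feature_windows) {
  if (is.matrix(beta)) {
    return(apply(beta, 2, methylation_score, feature_windows = feature_windows))
  }
  b <- beta[feature_windows]
  if (all(is.na(b))) {
    warning("all feature windows missing; methylation score undefined")
    return(NA_real_)
  }
  mean(b, na.rm = TRUE)
}

#' Dichotomize scores at the median
#'
#' `low` is score <= median (ties to low), `high` strictly above.
#'
#' @param scores numeric vector (>= 2 values).
#' @return factor with levels `low`, `high`.
#' @export
dichotomize_median <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 scores")
  med <- stats::median(scores, na.rm = TRUE)
  factor(ifelse(scores <= med, "low", "high"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' @param data data.frame with `os_months` and `event`.
#' @param group factor of group labels (both groups non-empty).
#' @return list: `fit` (a [survival::survfit] object), `logrank_p`
#'   (two-sided), `median_os` (named per group, `NA` when the curve never
#'   falls below 0.5), `n` per group.
#' @export
km_logrank <- function(data, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need at least two non-empty groups")
  df <- data.frame(os_months = data$os_months, event = data$event,
                   group = group)
  fit <- survival::survfit(survival::Surv(os_months, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(os_months, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = nlevels(group) - 1, lower.tail = FALSE)
  med <- summary(fit)$table[, "median"]
  names(med) <- sub("^group=", "", rownames(summary(fit)$table))
  list(fit = fit, logrank_p = p, logrank_chisq = sd$chisq, median_os = med,
       n = table(group))
}

fit_cox <- function(formula, data) {
  fit <- tryCatch(survival::coxph(formula, data = data),
                  error = function(e) NULL,
                  warning = function(w) suppressWarnings(
                    survival::coxph(formula, data = data)))
  if (is.null(fit)) return(NULL)
  s <- summary(fit)
  zph <- tryCatch(survival::cox.zph(fit)$table, error = function(e) NULL)
  cf_names <- rownames(s$coefficients)
  # cox.zph reports one row per model term; coefficient names of factor
  # covariates carry level suffixes, so match by prefix
  ph <- rep(NA_real_, length(cf_names))
  if (!is.null(zph)) {
    terms <- setdiff(rownames(zph), "GLOBAL")
    for (i in seq_along(cf_names)) {
      hit <- terms[startsWith(cf_names[i], terms)]
      if (length(hit) > 0) ph[i] <- zph[hit[1], "p"]
    }
  }
  coefs <- data.frame(term = cf_names,
                      coef = s$coefficients[, "coef"],
                      hr = s$coefficients[, "exp(coef)"],
                      ci_lo = s$conf.int[, "lower .95"],
                      ci_hi = s$conf.int[, "upper .95"],
                      p = s$coefficients[, "Pr(>|z|)"],
                      ph_p = ph,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(fit = fit, coefficients = coefs,
       aic = stats::AIC(fit), bic = stats::BIC(fit),
       concordance = unname(s$concordance["C"]),
       n = s$n, n_events = s$nevent)
}

#' Cox proportional-hazards models for the methylation score
#'
#' Fits univariable models for the continuous score, the dichotomized
#' score, age, sex and stage; multivariable models adding either score
#' form to the clinical base model (age + sex + stage); and compares the
#' base and score-augmented models by AIC, BIC and concordance.
#' Proportional hazards are checked per covariate via scaled Schoenfeld
#' residuals.
#'
#' @param data data.frame with `os_months`, `event`, `score`, `age`,
#'   `sex`, `stage`.
#' @return list of model results (each as coefficient table + AIC/BIC/
#'   concordance) plus a `comparison` data.frame.
#' @export
cox_models <- function(data) {
  need <- c("os_months", "event", "score", "age", "sex", "stage")
  if (!all(need %in% names(data)))
    stop("data must contain: ", paste(need, collapse = ", "))
  data$score_group <- dichotomize_median(data$score)
  n_cov <- 4
  if (sum(data$event) < n_cov * 5)
    warning("fewer than 5 events per covariate; multivariable fits may be unstable")
  S <- survival::Surv(data$os_months, data$event)
  models <- list(
    uni_score = fit_cox(S ~ score, data),
    uni_score_group = fit_cox(S ~ score_group, data),
    uni_age = fit_cox(S ~ age, data),
    uni_sex = fit_cox(S ~ sex, data),
    uni_stage = fit_cox(S ~ stage, data),
    base = fit_cox(S ~ age + sex + stage, data),
    multi_score = fit_cox(S ~ score + age + sex + stage, data),
    multi_score_group = fit_cox(S ~ score_group + age + sex + stage, data)
  )
  failed <- names(models)[vapply(models, is.null, logical(1))]
  models <- models[!vapply(models, is.null, logical(1))]
  cmp_names <- intersect(c("base", "multi_score", "multi_score_group"),
                         names(models))
  comparison <- data.frame(
    model = cmp_names,
    aic = vapply(models[cmp_names], `[[`, 0, "aic"),
    bic = vapply(models[cmp_names], `[[`, 0, "bic"),
    concordance = vapply(models[cmp_names], `[[`, 0, "concordance"),
    row.names = NULL)
  c(models, list(comparison = comparison, non_convergent = failed))
}
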