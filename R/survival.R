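#' Construct endpoint (time, event) pairs from survival records
#'
#' Survival time begins at the definitive surgery and ends at death, at the
#' endpoint event, or at the last follow-up. Endpoints:
#' \describe{
#'   \item{primary}{all-cause death.}
#'   \item{composite}{death or heart failure; the event time is the earliest
#'     component event.}
#'   \item{reintervention}{any cardiac reoperation after the definitive
#'     surgery.}
#' }
#' Records with missing or non-positive follow-up time, or with a component
#' event time after the follow-up time, are rejected and reported in the
#' `rejected` attribute rather than silently dropped.
#'
#' @param records data frame with columns `patient_id`, `time_years`
#'   (follow-up time), `death` (0/1; death occurs at `time_years`), `hf` and
#'   `hf_time`, `reint` and `reint_time`.
#' @param endpoint one of `"primary"`, `"composite"`, `"reintervention"`.
#' @return Data frame `patient_id`, `time`, `event` with attribute
#'   `rejected` (data frame of rejected rows and reasons).
#' @export
build_endpoint <- function(records,
                           endpoint = c("primary", "composite",
                                        "reintervention")) {
  endpoint <- match.arg(endpoint)
  req <- c("patient_id", "time_years", "death")
  stopifnot(all(req %in% names(records)))

  bad_time <- is.na(records$time_years) | records$time_years <= 0
  reason <- ifelse(bad_time, "missing or non-positive follow-up time", NA)
  check_comp <- function(flag, tm, what) {
    if (is.null(records[[flag]])) return(NULL)
    bad <- records[[flag]] == 1 &
      (is.na(records[[tm]]) | records[[tm]] <= 0 |
         records[[tm]] > records$time_years + 1e-9)
    ifelse(bad & is.na(reason), paste(what, "event time invalid"), NA)
  }
  for (r in list(check_comp("hf", "hf_time", "heart-failure"),
                 check_comp("reint", "reint_time", "reintervention"))) {
    if (!is.null(r)) reason <- ifelse(is.na(reason), r, reason)
  }
  keep <- is.na(reason)
  rejected <- data.frame(patient_id = records$patient_id[!keep],
                         reason = reason[!keep])
  rec <- records[keep, , drop = FALSE]

  out <- switch(endpoint,
    primary = data.frame(patient_id = rec$patient_id,
                         time = rec$time_years,
                         event = as.integer(rec$death == 1)),
    composite = {
      death_t <- ifelse(rec$death == 1, rec$time_years, Inf)
      hf_t <- ifelse(!is.null(rec$hf) & rec$hf == 1, rec$hf_time, Inf)
      ev <- is.finite(pmin(death_t, hf_t))
      data.frame(patient_id = rec$patient_id,
                 time = ifelse(ev, pmin(death_t, hf_t), rec$time_years),
                 event = as.integer(ev))
    },
    reintervention = {
      ev <- rec$reint == 1
      data.frame(patient_id = rec$patient_id,
                 time = ifelse(ev, rec$reint_time, rec$time_years),
                 event = as.integer(ev))
    })
  attr(out, "rejected") <- rejected
  out
}

#' Kaplan-Meier estimate with Greenwood variance
#'
#' Product-limit estimator with Greenwood standard errors and log-log 95%
#' confidence intervals (guaranteed inside \[0, 1\]), via
#' [survival::survfit()].
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param conf.level confidence level (default 0.95).
#' @return Data frame with one row per distinct follow-up time (plus the
#'   `time = 0, S = 1` anchor): `time`, `n_risk`, `n_event`, `surv`,
#'   `std_err` (of S, Greenwood), `lower`, `upper`.
#' @export
km_estimate <- function(time, event, conf.level = 0.95) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time <= 0)) stop("follow-up times must be positive")
  fit <- survfit(Surv(time, event) ~ 1, conf.type = "log-log",
                 conf.int = conf.level)
  s <- summary(fit, censored = TRUE)
  rbind(
    data.frame(time = 0, n_risk = length(time), n_event = 0L, surv = 1,
               std_err = 0, lower = 1, upper = 1),
    data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
               surv = s$surv, std_err = s$std.err,
               lower = ifelse(is.na(s$lower) & s$surv == 0, 0, s$lower),
               upper = ifelse(is.na(s$upper) & s$surv == 0, 0, s$upper))
  )
}

#' k-sample log-rank test
#'
#' Compares survival between groups with the log-rank (Mantel-Haenszel)
#' chi-square statistic on `k - 1` degrees of freedom, via
#' [survival::survdiff()].
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group group labels (coerced to factor; every level must contain at
#'   least one patient).
#' @return List with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  if (is.factor(group) && any(table(group) == 0L)) {
    stop("a group contains zero patients")
  }
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (sum(event) < 1L) stop("need at least one event overall")
  sd <- survdiff(Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Landmark analysis of group survival
#'
#' Piecewise comparison of group outcomes around a landmark time. The
#' pre-landmark analysis uses all patients with administrative censoring at
#' the landmark; the post-landmark analysis conditions on the risk set at
#' the landmark — patients event-free and still under follow-up at
#' `t_landmark` — and keeps the original time origin (no clock reset).
#'
#' @param time positive follow-up times (years since definitive surgery).
#' @param event 0/1 event indicators for the chosen endpoint.
#' @param group group (cluster) labels.
#' @param t_landmark landmark time in years (default 4).
#' @return List of class `landmark_analysis`: `t_landmark`; `pre` and `post`
#'   each holding `test` (log-rank result or `NULL` if skipped), `km`
#'   (a [survival::survfit()] object by group) and `n` (patients per group);
#'   `post$skipped_reason` explains a skipped post-landmark test.
#' @export
landmark_analysis <- function(time, event, group, t_landmark = 4) {
  if (t_landmark <= 0) stop("t_landmark must be positive")
  group <- factor(group)

  pre_time <- pmin(time, t_landmark)
  pre_event <- as.integer(event == 1 & time <= t_landmark)
  pre <- list(
    test = if (sum(pre_event) >= 1L)
      logrank_test(pre_time, pre_event, group) else NULL,
    km = survfit(Surv(pre_time, pre_event) ~ group, conf.type = "log-log"),
    n = table(group)
  )

  at_risk <- time > t_landmark          # event-free and uncensored at t*
  post <- list(n = table(group[at_risk]), skipped_reason = NULL)
  if (any(post$n == 0L)) {
    post$test <- NULL
    post$km <- NULL
    post$skipped_reason <- paste(
      "empty post-landmark risk set in group(s):",
      paste(names(post$n)[post$n == 0L], collapse = ", "))
  } else if (sum(event[at_risk]) < 1L) {
    post$test <- NULL
    post$km <- survfit(Surv(time[at_risk], event[at_risk]) ~ group[at_risk],
                       conf.type = "log-log")
    post$skipped_reason <- "no post-landmark events"
  } else {
    post$test <- logrank_test(time[at_risk], event[at_risk], group[at_risk])
    post$km <- survfit(Surv(time[at_risk], event[at_risk]) ~ group[at_risk],
                       conf.type = "log-log")
  }
  structure(list(t_landmark = t_landmark, pre = pre, post = post),
            class = "landmark_analysis")
}

#' @export
print.landmark_analysis <- function(x, ...) {
  cat("Landmark analysis at t =", x$t_landmark, "years\n")
  fmt <- function(part, nm) {
    cat(" ", nm, "landmark: n =", paste(part$n, collapse = "/"))
    if (!is.null(part$test)) {
      cat(sprintf(", log-rank chi2 = %.3f (df %d), p = %.4g\n",
                  part$test$statistic, part$test$df, part$test$p))
    } else {
      cat(", test skipped",
          if (!is.null(part$skipped_reason)) paste0("(", part$skipped_reason, ")"),
          "\n")
    }
  }
  fmt(x$pre, "pre-")
  fmt(x$post, "post-")
  invisible(x)
}

# Shared extraction of HR/CI/p rows from a coxph fit; flags monotone
# likelihood (infinite coefficients) as non-estimable.
#' @keywords internal
cox_rows <- function(fit, conf.level = 0.95) {
  s <- summary(fit, conf.int = conf.level)
  coefs <- s$coefficients
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  est <- coefs[, "coef"]
  se <- coefs[, "se(coef)"]
  inf <- !is.finite(est) | !is.finite(se) | abs(est) > 15 | se > 100
  data.frame(
    term = rownames(coefs),
    hr = ifelse(inf, NA_real_, exp(est)),
    lower = ifelse(inf, NA_real_, exp(est - z * se)),
    upper = ifelse(inf, NA_real_, exp(est + z * se)),
    p = ifelse(inf, NA_real_, coefs[, "Pr(>|z|)"]),
    estimable = !inf,
    row.names = NULL
  )
}

#' Univariable Cox proportional-hazards regression
#'
#' Fits a single-covariate Cox model by partial-likelihood maximization
#' (Efron tie handling by default) via [survival::coxph()], returning the
#' hazard ratio with Wald confidence interval and p-value. Covariate levels
#' with monotone likelihood (e.g. zero events in a level) are flagged
#' non-estimable with `NA` in place of the hazard ratio, the analogue of a
#' "/" entry in a results table.
#'
#' @param data data frame containing `time`, `event` and the covariate.
#' @param covariate name of the covariate column.
#' @param time,event names of the time and event columns (defaults `"time"`,
#'   `"event"`).
#' @param ties tie handling, `"efron"` (default) or `"breslow"`.
#' @param conf.level Wald CI level.
#' @return Data frame with one row per estimated coefficient: `covariate`,
#'   `term`, `hr`, `lower`, `upper`, `p`, `estimable`.
#' @export
cox_univariable <- function(data, covariate, time = "time", event = "event",
                            ties = c("efron", "breslow"), conf.level = 0.95) {
  ties <- match.arg(ties)
  x <- data[[covariate]]
  if (is.null(x)) stop("unknown covariate: ", covariate)
  if (length(unique(x[!is.na(x)])) < 2L) {
    stop("covariate ", covariate, " has fewer than two observed levels")
  }
  f <- as.formula(paste0("Surv(", time, ", ", event, ") ~ `", covariate, "`"))
  fit <- suppressWarnings(coxph(f, data = data, ties = ties))
  out <- cox_rows(fit, conf.level)
  cbind(covariate = covariate, out)
}

#' Multivariable Cox regression over univariably significant covariates
#'
#' Entry rule: covariates whose univariable raw p-value (minimum across
#' levels for factors) is below `entry_p` enter a joint Cox model.
#' BH-adjusted p-values are computed across the joint model's coefficients.
#'
#' @param data data frame with `time`, `event` and covariate columns.
#' @param covariates candidate covariate names.
#' @inheritParams cox_univariable
#' @param entry_p univariable entry threshold (default 0.05).
#' @return List with `selected` (covariates entered), `univariable` (stacked
#'   univariable rows with `p_adj` BH-adjusted within the univariable
#'   family) and `table` (joint-model rows with `p_adj`, or `NULL` with
#'   `message = "no multivariable model"` when nothing enters).
#' @export
cox_multivariable <- function(data, covariates, time = "time",
                              event = "event", ties = c("efron", "breslow"),
                              entry_p = 0.05, conf.level = 0.95) {
  ties <- match.arg(ties)
  uni <- do.call(rbind, lapply(covariates, function(cv)
    cox_univariable(data, cv, time, event, ties, conf.level)))
  uni$p_adj <- bh_adjust_na(uni$p)

  minp <- vapply(split(uni$p, uni$covariate), function(p)
    suppressWarnings(min(p, na.rm = TRUE)), 1)
  selected <- covariates[covariates %in% names(minp)[is.finite(minp) & minp < entry_p]]

  if (!length(selected)) {
    return(list(selected = character(0), univariable = uni, table = NULL,
                message = "no multivariable model"))
  }
  f <- as.formula(paste0("Surv(", time, ", ", event, ") ~ ",
                         paste0("`", selected, "`", collapse = " + ")))
  fit <- suppressWarnings(coxph(f, data = data, ties = ties))
  if (any(is.na(stats::coef(fit)))) {
    warning("collinear covariate(s) dropped from the multivariable model: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  }
  tab <- cox_rows(fit, conf.level)
  tab$p_adj <- bh_adjust_na(tab$p)
  list(selected = selected, univariable = uni, table = tab)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

# BH that tolerates NA (non-estimable rows stay NA, family size = observed).
#' @keywords internal
bh_adjust_na <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- bh_adjust(p[ok])
  out
}
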