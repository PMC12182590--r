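#' Weighted stratified Cox proportional-hazards model
#'
#' Thin wrapper around [survival::coxph()] with the conventions used
#' throughout the package: survey weights standardized to mean 1 within the
#' analysis sample, Efron tie handling by default, optional stratification
#' columns, and optional robust (sandwich) variance with clustering by
#' subject for longitudinal records.
#'
#' @param data Data frame with `follow_up_years` and `event` columns.
#' @param formula Right-hand side only, e.g. `~ accelerated + age`.
#' @param strata Character vector of stratification columns (e.g.
#'   `c("sex", "ethnicity")`).
#' @param weights_col Optional column of survey weights (standardized to
#'   mean 1 before fitting).
#' @param cluster_col Optional column defining clusters for the robust
#'   variance (e.g. subject id with time-varying records).
#' @param robust Request robust sandwich standard errors.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return The `survival::coxph` fit.
#' @export
fit_cox <- function(data, formula, strata = NULL, weights_col = NULL,
                    cluster_col = NULL, robust = !is.null(cluster_col),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  rhs <- paste(deparse(formula[[length(formula)]]), collapse = " ")
  if (!is.null(strata))
    rhs <- paste(rhs, "+", paste0("strata(", strata, ")", collapse = " + "))
  if (!is.null(cluster_col)) rhs <- paste(rhs, "+ cluster(", cluster_col, ")")
  f <- stats::as.formula(paste("survival::Surv(follow_up_years, event) ~", rhs))
  w <- NULL
  if (!is.null(weights_col)) {
    w <- data[[weights_col]]
    if (any(w <= 0)) stop("survey weights must be positive")
    w <- w / mean(w)
  }
  data$.w <- w
  fit <- if (is.null(w))
    survival::coxph(f, data = data, ties = ties, robust = robust,
                    x = TRUE, model = TRUE)
  else survival::coxph(f, data = data, weights = .w, ties = ties,
                       robust = robust, x = TRUE, model = TRUE)
  fit
}

#' Tidy hazard-ratio table from a Cox fit
#'
#' @param fit A `coxph` fit.
#' @return Data frame with term, log-HR, HR, SE (robust when available) and
#'   Wald 95% CI on the HR scale.
#' @export
cox_table <- function(fit) {
  s <- summary(fit)
  co <- s$coefficients
  se <- if ("robust se" %in% colnames(co)) co[, "robust se"] else co[, "se(coef)"]
  data.frame(term = rownames(co), coef = co[, "coef"],
             hr = exp(co[, "coef"]), se = se,
             ci_low = exp(co[, "coef"] - 1.96 * se),
             ci_high = exp(co[, "coef"] + 1.96 * se),
             p = 2 * stats::pnorm(-abs(co[, "coef"] / se)),
             n = s$n, row.names = NULL)
}

# censoring-distribution Kaplan-Meier G(t) evaluated at arbitrary times;
# right-continuous step function, G(0) = 1
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
}

#' Uno's inverse-probability-of-censoring-weighted concordance
#'
#' IPCW concordance for right-censored data. Comparable pairs are (i, j)
#' with subject i experiencing an event before `tau` and `t_i < t_j`; each
#' pair is weighted by `G(t_i)^-2` where `G` is the Kaplan-Meier estimate of
#' the censoring distribution on the pooled sample. Ties in the linear
#' predictor count one half. With no censoring and `tau` at the maximum
#' observed time this reduces exactly to Harrell's C.
#'
#' @param lp Linear predictor (higher = higher risk).
#' @param time,event Survival outcome (years).
#' @param tau Truncation time; default the maximum observed time.
#' @param se_boot Number of bootstrap resamples for the standard error
#'   (0 = point estimate only).
#' @param g_min Optional lower truncation for `G` (values below are floored,
#'   with a message); `NULL` disables truncation.
#' @return List (`metric_result`) with `estimate`, `se`, `ci_low`,
#'   `ci_high`, `n_used`, `n_pairs`.
#' @export
uno_c <- function(lp, time, event, tau = max(time), se_boot = 0,
                  g_min = NULL) {
  est <- function(lp, time, event) {
    G <- censoring_km(time, event)
    gi <- G(time)
    if (!is.null(g_min)) {
      nlow <- sum(gi < g_min & event == 1 & time < tau)
      if (nlow) message("uno_c: floored G for ", nlow, " event time(s)")
      gi <- pmax(gi, g_min)
    }
    idx <- which(event == 1 & time < tau)
    if (!length(idx)) return(c(NA_real_, 0))
    num <- 0; den <- 0
    for (i in idx) {
      j <- which(time > time[i])
      if (!length(j)) next
      w <- 1 / gi[i]^2
      num <- num + w * (sum(lp[i] > lp[j]) + 0.5 * sum(lp[i] == lp[j]))
      den <- den + w * length(j)
    }
    c(if (den > 0) num / den else NA_real_, den)
  }
  r <- est(lp, time, event)
  if (r[2] == 0) stop("no comparable pairs before tau")
  se <- NA_real_
  if (se_boot > 0) {
    n <- length(time)
    bs <- vapply(seq_len(se_boot), function(b) {
      s <- sample.int(n, n, replace = TRUE)
      est(lp[s], time[s], event[s])[1]
    }, 0)
    se <- stats::sd(bs, na.rm = TRUE)
  }
  metric_result(r[1], se, n_used = length(time), n_pairs = r[2])
}

metric_result <- function(estimate, se = NA_real_, n_used = NA_integer_, ...) {
  ci <- if (is.na(se)) c(estimate, estimate)
  else estimate + c(-1.96, 1.96) * se
  structure(list(estimate = estimate, se = se,
                 ci_low = min(ci[1], estimate), ci_high = max(ci[2], estimate),
                 n_used = n_used, ...),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("estimate %.4f (se %.4f, 95%% CI %.4f-%.4f, n=%s)\n",
              x$estimate, x$se, x$ci_low, x$ci_high, x$n_used))
  invisible(x)
}

#' Time-dependent (cumulative/dynamic) IPCW AUC
#'
#' At each evaluation time `tau`, cases are subjects with an event at or
#' before `tau` (weighted `1/G(t_i)`) and controls are subjects still under
#' observation beyond `tau` (weighted `1/G(tau)`); the AUC is the weighted
#' probability that a case's linear predictor exceeds a control's, ties
#' counting one half. Times with no cases or no controls are returned as
#' `NA` and flagged.
#'
#' @inheritParams uno_c
#' @param eval_times Evaluation horizons (years).
#' @return Data frame with `time`, `auc`, `n_cases`, `n_controls`,
#'   `missing` (flag).
#' @export
tauc <- function(lp, time, event, eval_times) {
  G <- censoring_km(time, event)
  out <- lapply(eval_times, function(tt) {
    case <- which(time <= tt & event == 1)
    ctrl <- which(time > tt)
    if (!length(case) || !length(ctrl))
      return(data.frame(time = tt, auc = NA_real_, n_cases = length(case),
                        n_controls = length(ctrl), missing = TRUE))
    wc <- 1 / G(time[case])
    num <- 0
    for (k in seq_along(case)) {
      num <- num + wc[k] * (sum(lp[case[k]] > lp[ctrl]) +
                              0.5 * sum(lp[case[k]] == lp[ctrl]))
    }
    den <- sum(wc) * length(ctrl)   # constant control weight 1/G(tt) cancels
    data.frame(time = tt, auc = num / den, n_cases = length(case),
               n_controls = length(ctrl), missing = FALSE)
  })
  do.call(rbind, out)
}

#' Difference in time-dependent AUC between two predictors
#'
#' @param lp_a,lp_b Linear predictors on the same subjects.
#' @inheritParams tauc
#' @return Data frame with `time`, `auc_a`, `auc_b`, `delta` (A - B;
#'   positive favours A).
#' @export
delta_tauc <- function(lp_a, lp_b, time, event, eval_times) {
  a <- tauc(lp_a, time, event, eval_times)
  b <- tauc(lp_b, time, event, eval_times)
  data.frame(time = a$time, auc_a = a$auc, auc_b = b$auc,
             delta = a$auc - b$auc)
}

#' Paired bootstrap comparison of two predictors' AUC at a horizon
#'
#' Resamples subjects with replacement, recomputing the time-dependent AUC
#' of both predictors on each resample; returns the observed difference, its
#' bootstrap standard error and a two-sided normal-approximation p-value.
#' Resamples with no cases or no controls at the horizon are dropped and
#' counted; more than 10% dropped is an error.
#'
#' @param lp_a,lp_b Linear predictors on common subjects.
#' @inheritParams uno_c
#' @param horizon Horizon in years at which AUCs are compared.
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @return List with `delta`, `se`, `p`, `auc_a`, `auc_b`, `B_used`.
#' @export
compare_auc_bootstrap <- function(lp_a, lp_b, time, event, horizon,
                                  B = 1000, seed = 1L) {
  if (B < 100) stop("B must be at least 100")
  if (length(lp_a) != length(lp_b)) stop("predictors must share subjects")
  base_a <- tauc(lp_a, time, event, horizon)$auc
  base_b <- tauc(lp_b, time, event, horizon)$auc
  delta <- base_a - base_b
  n <- length(time)
  set.seed(seed)
  ds <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    s <- sample.int(n, n, replace = TRUE)
    if (!any(time[s] <= horizon & event[s] == 1) || !any(time[s] > horizon))
      next
    ds[b] <- tauc(lp_a[s], time[s], event[s], horizon)$auc -
      tauc(lp_b[s], time[s], event[s], horizon)$auc
  }
  dropped <- sum(is.na(ds))
  if (dropped > 0.10 * B)
    stop("more than 10% of bootstrap resamples were degenerate (",
         dropped, "/", B, ")")
  se <- stats::sd(ds, na.rm = TRUE)
  p <- if (is.na(se) || se == 0) {
    if (isTRUE(all.equal(delta, 0))) 1 else 0
  } else 2 * stats::pnorm(-abs(delta / se))
  list(delta = delta, se = se, p = p, auc_a = base_a, auc_b = base_b,
       B_used = B - dropped)
}

#' Kaplan-Meier survivor curves by group
#'
#' @param time,event Survival outcome.
#' @param group Grouping factor (e.g. accelerated aging x multimorbidity).
#' @param weights Optional case weights.
#' @return Data frame with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
kaplan_meier <- function(time, event, group = rep("all", length(time)),
                         weights = NULL) {
  group <- as.factor(group)
  if (any(table(group) == 0)) stop("empty group")
  d <- data.frame(time = time, event = event, group = group)
  d$w <- if (is.null(weights)) 1 else weights
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d,
                           weights = w)
  st <- summary(fit, censored = TRUE)
  grp <- if (is.null(st$strata)) rep(levels(group)[1], length(st$time))
  else sub("^group=", "", as.character(st$strata))
  data.frame(group = grp, time = st$time, n_risk = st$n.risk,
             n_event = st$n.event, surv = st$surv)
}

#' Log-rank test for equality of survivor curves
#'
#' Observed-minus-expected chi-square over the joint risk set, via
#' [survival::survdiff()]. Supports any number of groups (four in the
#' accelerated-aging-by-multimorbidity analysis).
#'
#' @inheritParams kaplan_meier
#' @return List with `statistic`, `df`, `p`.
#' @export
log_rank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need at least two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = data.frame(time, event, group))
  df <- length(sd$n) - 1
  list(statistic = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Proportional-hazards diagnostic (scaled Schoenfeld residuals)
#'
#' Correlation test of scaled Schoenfeld residuals against time (identity
#' transform by default), plus the residual series for plotting.
#'
#' @param cox_fit A `coxph` fit (fitted with `x = TRUE`).
#' @param transform Time transform passed to [survival::cox.zph()].
#' @return List with `table` (per-covariate and GLOBAL rows: chisq, df, p),
#'   `time` and `residuals` (matrix, one column per covariate).
#' @export
ph_test <- function(cox_fit, transform = "identity") {
  if (sum(cox_fit$nevent) < 2)
    stop("PH test undefined with fewer than 2 events")
  z <- survival::cox.zph(cox_fit, transform = transform)
  list(table = as.data.frame(z$table), time = z$x, residuals = z$y)
}
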