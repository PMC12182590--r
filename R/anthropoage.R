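#' Gompertz cumulative distribution function
#'
#' Probability of death within `t` months under the Gompertz
#' proportional-hazards model: `1 - exp(-exp(xb) * (exp(gamma t) - 1) /
#' gamma)`. Stable for very small `gamma` via `expm1`, approaching the
#' exponential limit `1 - exp(-exp(xb) * t)`.
#'
#' @param gamma Shape parameter per month (> 0), or a `gompertz_fit` (its
#'   first shape is used unless `group` selects one).
#' @param xb Linear predictor (rate included).
#' @param t Horizon in months (default 120, i.e. 10 years).
#' @param group Optional shape-group label when `gamma` is a grouped fit.
#' @return Death probability in (0, 1) for finite `xb`.
#' @examples
#' gompertz_cdf(0.005, -5.2, 120)
#' @export
gompertz_cdf <- function(gamma, xb, t = 120, group = NULL) {
  if (inherits(gamma, "gompertz_fit")) {
    fit <- gamma
    gamma <- if (is.null(group)) fit$gamma[[1]] else fit$gamma[[group]]
  }
  if (any(!is.finite(gamma)) || any(gamma <= 0)) stop("gamma must be > 0")
  if (any(t <= 0)) stop("horizon t must be > 0")
  -expm1(-exp(xb) * expm1(gamma * t) / gamma)
}

#' AnthropoAge: biological age from matched Gompertz CDFs
#'
#' Inverts the chronological-age-only Gompertz model at a given 10-year
#' mortality risk: the returned value is the age at which the CA-only model
#' predicts death probability `M` within `t` months,
#' `(ln(-ln(1 - M) / ((exp(gamma0 t) - 1) / gamma0)) - beta0) / beta1`.
#' When `M` comes from the age + anthropometry model this is the subject's
#' AnthropoAge in years.
#'
#' @param ca_fit `gompertz_fit` of the CA-only model (coefficients `rate`
#'   and `age`), or a list with `gamma`, `beta0`, `beta1`.
#' @param M Predicted death probability, strictly inside (0, 1).
#' @param t Horizon in months (default 120).
#' @param clamp If `TRUE`, values of `M` outside (0, 1) are clamped to
#'   `[eps, 1 - eps]` with `eps = 1e-12` and the number of clamped values is
#'   reported via a message; the default is to error.
#' @return Biological age in years.
#' @export
anthropoage <- function(ca_fit, M, t = 120, clamp = FALSE) {
  p <- ca_params(ca_fit)
  if (any(t <= 0)) stop("horizon t must be > 0")
  if (p$beta1 == 0) stop("beta1 (age coefficient) must be nonzero")
  bad <- M <= 0 | M >= 1 | !is.finite(M)
  if (any(bad)) {
    if (!clamp) stop("M must lie strictly inside (0, 1); ",
                     sum(bad), " value(s) outside")
    message("anthropoage: clamped ", sum(bad), " value(s) of M to (0, 1)")
    eps <- 1e-12
    M <- pmin(pmax(M, eps), 1 - eps)
  }
  B <- expm1(p$gamma * t) / p$gamma
  (log(-log1p(-M) / B) - p$beta0) / p$beta1
}

ca_params <- function(ca_fit) {
  if (inherits(ca_fit, "gompertz_fit")) {
    list(gamma = unname(ca_fit$gamma[[1]]),
         beta0 = unname(ca_fit$coef[["rate"]]),
         beta1 = unname(ca_fit$coef[["age"]]))
  } else {
    stopifnot(all(c("gamma", "beta0", "beta1") %in% names(ca_fit)))
    ca_fit
  }
}

#' Linear predictor of the age + anthropometry Gompertz model
#'
#' `rate + beta_age * age + beta_b1 * ln(BMI) + beta_b2 * ln(BMI)^2 +
#' beta_w * WHtR^(1/3)`. For fits stored on an orthogonalized basis
#' (`basis = "orthogonal"`), centering/scaling constants stored on the fit
#' are applied to each term first.
#'
#' @param fit `gompertz_fit` from [fit_gompertz_anthro()] (or read from a
#'   coefficient file).
#' @param age,bmi,whtr Covariate vectors.
#' @return The linear predictor `xb`.
#' @export
anthro_xb <- function(fit, age, bmi, whtr) {
  terms <- cbind(age = age, log_bmi = log(bmi), log_bmi2 = log(bmi)^2,
                 whtr_cbrt = whtr^(1 / 3))
  if (identical(fit$basis, "orthogonal")) {
    ctr <- fit$basis_center[colnames(terms)]
    scl <- fit$basis_scale[colnames(terms)]
    terms <- sweep(sweep(terms, 2, ctr, "-"), 2, scl, "/")
  }
  need <- c("rate", colnames(terms))
  if (!all(need %in% names(fit$coef)))
    stop("anthropometry fit must carry coefficients: ",
         paste(need, collapse = ", "))
  drop(fit$coef[["rate"]] + terms %*% fit$coef[colnames(terms)])
}

#' Compute AnthropoAge for every row of a panel
#'
#' For each row: the linear predictor of the sex-matching anthropometry model
#' is built with that row's ethnicity-specific shape, converted into a
#' 10-year (or `t`-month) death probability, and inverted through the
#' sex-matching CA-only model.
#'
#' @param panel Data frame with `sex`, `ethnicity`, `age`, `bmi`, `whtr`.
#' @param ca_fits,anthro_fits Lists of `gompertz_fit` objects named by sex
#'   (as appearing in `panel$sex`).
#' @param t Horizon in months (default 120).
#' @param clamp Passed to [anthropoage()].
#' @return Numeric vector of AnthropoAge (years), aligned with `panel` rows.
#' @export
anthropoage_batch <- function(panel, ca_fits, anthro_fits, t = 120,
                              clamp = FALSE) {
  need <- c("sex", "ethnicity", "age", "bmi", "whtr")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- rep(NA_real_, nrow(panel))
  for (s in unique(panel$sex)) {
    if (is.null(ca_fits[[s]]) || is.null(anthro_fits[[s]]))
      stop("no fitted models for sex '", s, "'")
    afit <- anthro_fits[[s]]
    i <- which(panel$sex == s)
    unknown <- setdiff(unique(panel$ethnicity[i]), names(afit$gamma))
    if (length(unknown))
      stop("no fitted shape for ethnicity group(s) ",
           paste(unknown, collapse = ", "), "; known: ",
           paste(names(afit$gamma), collapse = ", "))
    xb <- anthro_xb(afit, panel$age[i], panel$bmi[i], panel$whtr[i])
    g <- afit$gamma[panel$ethnicity[i]]
    M <- gompertz_cdf(g, xb, t)
    out[i] <- anthropoage(ca_fits[[s]], M, t, clamp = clamp)
  }
  out
}

#' AnthropoAgeAccel: residual age acceleration
#'
#' Regresses AnthropoAge on chronological age separately for each sex and
#' returns the residuals. Modes: `"study-intercepts"` (default; ordinary
#' least squares with fixed study intercepts, which absorb between-study
#' offsets), `"pooled"` (plain OLS), and `"mixed"` (lme4 random intercepts:
#' study only for `level = "baseline"`, study plus participant for
#' `level = "longitudinal"`). Accelerated aging is a positive residual;
#' quartiles are unweighted sample quartiles of the residual within sex.
#'
#' @param panel Data frame with `anthropoage`, `age`, `sex`; `study` for
#'   modes beyond pooled; `id` for the longitudinal mixed model.
#' @param mode Residualization mode, see above.
#' @param level `"baseline"` or `"longitudinal"` (mixed mode only).
#' @return A data frame with columns `anthropoage`, `accel`, `accelerated`
#'   (logical, `accel > 0`) and `accel_quartile` (1-4, within sex), row-
#'   aligned with `panel`.
#' @export
anthropoage_accel <- function(panel,
                              mode = c("study-intercepts", "pooled", "mixed"),
                              level = c("baseline", "longitudinal")) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  need <- c("anthropoage", "age", "sex")
  if (mode != "pooled") need <- c(need, "study")
  if (mode == "mixed" && level == "longitudinal") need <- c(need, "id")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel missing column(s): ",
                         paste(miss, collapse = ", "))
  accel <- rep(NA_real_, nrow(panel))
  quart <- rep(NA_integer_, nrow(panel))
  for (s in unique(panel$sex)) {
    i <- which(panel$sex == s)
    if (length(i) < 3) stop("fewer than 3 rows for sex '", s, "'")
    d <- panel[i, , drop = FALSE]
    r <- switch(mode,
      "pooled" = stats::resid(stats::lm(anthropoage ~ age, data = d)),
      "study-intercepts" = {
        f <- if (length(unique(d$study)) > 1)
          anthropoage ~ age + factor(study) else anthropoage ~ age
        stats::resid(stats::lm(f, data = d))
      },
      "mixed" = {
        f <- if (level == "longitudinal")
          anthropoage ~ age + (1 | study) + (1 | id)
        else anthropoage ~ age + (1 | study)
        # a single study level degenerates to pooled OLS
        if (length(unique(d$study)) < 2)
          stats::resid(stats::lm(anthropoage ~ age, data = d))
        else stats::resid(lme4::lmer(f, data = d, REML = TRUE))
      })
    r <- as.numeric(r)
    r[abs(r) < 1e-9] <- 0   # exact fits leave only rounding noise
    accel[i] <- r
    q <- stats::quantile(accel[i], c(0.25, 0.5, 0.75), type = 7)
    quart[i] <- 1L + findInterval(accel[i], q, left.open = TRUE)
  }
  data.frame(anthropoage = panel$anthropoage, accel = accel,
             accelerated = accel > 0, accel_quartile = quart)
}
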