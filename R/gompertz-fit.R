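#' Fit a Gompertz proportional-hazards model by maximum likelihood
#'
#' Fits the survival model with hazard `h(t) = exp(xb) * exp(gamma * t)` for
#' right-censored data, maximizing the log-likelihood
#' `sum_events (xb_i + gamma * t_i) - sum_all exp(xb_i) * (exp(gamma * t_i)
#' - 1) / gamma` (time in months by convention). The shape may be shared or
#' specific to groups (e.g. race/ethnicity) via `shape_groups`. Optional case
#' weights multiply each subject's likelihood contribution.
#'
#' @param formula `survival::Surv(time, event) ~ covariates`; the intercept
#'   is the Gompertz rate parameter.
#' @param data Data frame; times must be positive and on the scale given by
#'   `time_unit`.
#' @param shape_groups Optional column name (or factor) giving the grouping
#'   of the shape parameter.
#' @param weights Optional positive case weights.
#' @param sex Optional stratum label stored on the fit.
#' @param time_unit Label recorded with the fit (default `"months"`); purely
#'   descriptive — the caller supplies times already on this scale.
#' @param init Optional named starting values (`gamma`, plus coefficients).
#' @param control List with `maxit` and `reltol` passed to [stats::optim()].
#'
#' @return An object of class `gompertz_fit` with components `gamma` (named
#'   per group), `coef` (rate intercept named `rate`, then covariates),
#'   `vcov` (observed-information covariance on the natural scale, shapes
#'   first), `loglik`, `n`, `events`, `sex`, `time_unit`, `basis`.
#' @examples
#' d <- data.frame(time = rexp(50, 1 / 60), event = 1, x = rnorm(50))
#' fit <- fit_gompertz(survival::Surv(time, event) ~ x, d)
#' @export
fit_gompertz <- function(formula, data, shape_groups = NULL, weights = NULL,
                         sex = NA_character_, time_unit = "months",
                         init = NULL, control = list(maxit = 500,
                                                     reltol = 1e-12)) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv")) stop("response must be a survival::Surv object")
  time <- y[, 1]; event <- y[, 2]
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  colnames(X)[colnames(X) == "(Intercept)"] <- "rate"
  if (any(time <= 0)) stop("survival times must be > 0")
  if (sum(event) < 1) stop("zero events in this stratum")
  if (is.null(weights)) weights <- rep(1, length(time))
  if (length(weights) != length(time) || any(weights <= 0))
    stop("weights must be positive, one per (complete) row")
  if (!is.null(shape_groups)) {
    grp <- if (is.character(shape_groups) && length(shape_groups) == 1)
      data[[shape_groups]] else shape_groups
    omitted <- attr(mf, "na.action")
    if (!is.null(omitted)) grp <- grp[-omitted]
    grp <- factor(grp)
    if (length(grp) != length(time)) stop("shape_groups length mismatch")
  } else grp <- factor(rep("all", length(time)))
  glev <- levels(grp)
  gi <- as.integer(grp)
  G <- length(glev); p <- ncol(X)

  # theta = (log gamma_1..G, beta_1..p)
  negll <- function(th) {
    gam <- exp(th[seq_len(G)]); beta <- th[G + seq_len(p)]
    xb <- drop(X %*% beta)
    g <- gam[gi]
    cum <- exp(xb) * expm1(g * time) / g
    -sum(weights * (event * (xb + g * time) - cum))
  }
  grad <- function(th) {
    gam <- exp(th[seq_len(G)]); beta <- th[G + seq_len(p)]
    xb <- drop(X %*% beta)
    g <- gam[gi]
    egt <- exp(g * time)
    cum <- exp(xb) * (egt - 1) / g
    db <- drop(crossprod(X, weights * (event - cum)))
    # d/dgamma of (e^(g t)-1)/g = (t e^(gt) g - (e^(gt)-1)) / g^2
    dcum_dg <- exp(xb) * (time * egt * g - (egt - 1)) / g^2
    dg_term <- weights * (event * time - dcum_dg) * g  # chain rule via log
    dg <- vapply(seq_len(G), function(k) sum(dg_term[gi == k]), 0)
    -c(dg, db)
  }

  th0 <- c(rep(log(0.005), G), rep(0, p))
  names(th0) <- c(paste0("log_gamma.", glev), colnames(X))
  # crude rate init from the exponential MLE
  th0[G + 1] <- log(sum(weights * event) / sum(weights * time))
  if (!is.null(init)) {
    if (!is.null(init$gamma)) th0[seq_len(G)] <- log(init$gamma)
    cm <- intersect(names(init), colnames(X))
    th0[G + match(cm, colnames(X))] <- unlist(init[cm])
  }
  opt <- stats::optim(th0, negll, grad, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  if (opt$convergence != 0)
    stop("Gompertz fit did not converge (optim code ", opt$convergence, ")")
  gam <- exp(opt$par[seq_len(G)])
  if (any(gam < 1e-9))
    warning("shape parameter driven to the boundary (gamma < 1e-9)")
  beta <- opt$par[G + seq_len(p)]
  names(gam) <- glev
  names(beta) <- colnames(X)
  # observed information on the (log gamma, beta) scale, mapped to the
  # natural scale by the delta method (keeps the shape off the boundary)
  H <- stats::optimHess(opt$par, negll, grad)
  vc <- tryCatch({
    J <- diag(c(gam, rep(1, p)))
    J %*% solve(H) %*% J
  }, error = function(e) matrix(NA_real_, G + p, G + p))
  dimnames(vc) <- list(c(paste0("gamma.", glev), names(beta)),
                       c(paste0("gamma.", glev), names(beta)))
  structure(list(gamma = gam, coef = beta, vcov = vc,
                 loglik = -opt$value, n = length(time), events = sum(event),
                 sex = sex, time_unit = time_unit, basis = "raw",
                 shape_levels = glev, formula = formula),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz proportional-hazards fit",
      if (!is.na(x$sex)) paste0("(", x$sex, ")"), "\n")
  cat("  time unit:", x$time_unit, " n =", x$n, " events =", x$events, "\n")
  cat("  shape (per", x$time_unit, "):\n")
  print(round(x$gamma, 6))
  cat("  coefficients:\n")
  print(round(x$coef, 6))
  cat("  loglik:", format(x$loglik), "\n")
  invisible(x)
}

#' Gompertz log-likelihood evaluated at given parameters
#'
#' Direct evaluation of the right-censored Gompertz PH log-likelihood; used
#' for verification and unit tests.
#'
#' @param gamma Shape per group (named when grouped), per month.
#' @param beta Coefficient vector (intercept first) matching `X`.
#' @param X Model matrix.
#' @param time,event Survival outcome (time in months).
#' @param group Integer/factor group index for the shape (default all one).
#' @param weights Case weights.
#' @return The log-likelihood value.
#' @export
gompertz_loglik <- function(gamma, beta, X, time, event,
                            group = rep(1L, length(time)),
                            weights = rep(1, length(time))) {
  g <- gamma[as.integer(factor(group))]
  xb <- drop(X %*% beta)
  sum(weights * (event * (xb + g * time) - exp(xb) * expm1(g * time) / g))
}

# ---- the two model fits used by the AnthropoAge pipeline -------------------

#' Fit the chronological-age-only Gompertz model for one sex
#'
#' Time is follow-up in months; age in years is the only covariate.
#'
#' @param panel Baseline rows for one sex with `follow_up_years`, `event`,
#'   `age` columns.
#' @param sex Label stored on the fit.
#' @param weights Optional case weights.
#' @return A `gompertz_fit` with coefficients `rate` and `age`.
#' @export
fit_gompertz_ca <- function(panel, sex = NA_character_, weights = NULL) {
  d <- data.frame(t_mo = panel$follow_up_years * 12, event = panel$event,
                  age = panel$age)
  fit_gompertz(survival::Surv(t_mo, event) ~ age, d, weights = weights,
               sex = sex)
}

#' Fit the age + anthropometry Gompertz model for one sex
#'
#' Covariates: age (years), log BMI, squared log BMI, cube-root WHtR; the
#' shape parameter is specific to each race/ethnicity group.
#'
#' @inheritParams fit_gompertz_ca
#' @return A `gompertz_fit` with coefficients `rate`, `age`, `log_bmi`,
#'   `log_bmi2`, `whtr_cbrt` and one shape per ethnicity group.
#' @export
fit_gompertz_anthro <- function(panel, sex = NA_character_, weights = NULL) {
  d <- data.frame(t_mo = panel$follow_up_years * 12, event = panel$event,
                  age = panel$age, log_bmi = log(panel$bmi),
                  log_bmi2 = log(panel$bmi)^2,
                  whtr_cbrt = panel$whtr^(1 / 3),
                  ethnicity = panel$ethnicity)
  fit_gompertz(survival::Surv(t_mo, event) ~ age + log_bmi + log_bmi2 +
                 whtr_cbrt, d, shape_groups = d$ethnicity, weights = weights,
               sex = sex)
}

# ---- coefficient file round trip -------------------------------------------

#' Write fitted AnthropoAge coefficient sets to a delimited text file
#'
#' Serializes the per-sex CA-only and anthropometry Gompertz fits to a
#' tab-separated file with one row per value: `model`, `sex`, `kind`
#' (`meta`/`shape`/`coef`), `name`, `value`. Values are written with 17
#' significant digits so the file round-trips bit-exactly through
#' [read_gompertz_coefs()].
#'
#' @param ca_fits,anthro_fits Named lists of `gompertz_fit` objects, one per
#'   sex.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gompertz_coefs <- function(ca_fits, anthro_fits, path) {
  row1 <- function(model, sex, kind, name, value)
    data.frame(model = model, sex = sex, kind = kind, name = name,
               value = value, stringsAsFactors = FALSE)
  ser <- function(fit, model, sex) {
    rbind(
      row1(model, sex, "meta", "time_unit", fit$time_unit),
      row1(model, sex, "meta", "basis", fit$basis),
      do.call(rbind, lapply(names(fit$gamma), function(g)
        row1(model, sex, "shape", g, sprintf("%.17g", fit$gamma[[g]])))),
      do.call(rbind, lapply(names(fit$coef), function(b)
        row1(model, sex, "coef", b, sprintf("%.17g", fit$coef[[b]]))))
    )
  }
  tab <- rbind(
    do.call(rbind, lapply(names(ca_fits), function(s)
      ser(ca_fits[[s]], "ca", s))),
    do.call(rbind, lapply(names(anthro_fits), function(s)
      ser(anthro_fits[[s]], "anthro", s)))
  )
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read AnthropoAge coefficient sets from a delimited text file
#'
#' Inverse of [write_gompertz_coefs()]. The returned fits carry coefficients
#' and shapes only (no covariance or likelihood), which is all
#' [anthropoage_batch()] needs.
#'
#' @param path File written by [write_gompertz_coefs()].
#' @return A list with `ca` and `anthro`, each a named-by-sex list of
#'   `gompertz_fit` objects.
#' @export
read_gompertz_coefs <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  build <- function(model, sex) {
    sub <- tab[tab$model == model & tab$sex == sex, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    val <- function(kind) {
      s <- sub[sub$kind == kind, , drop = FALSE]
      stats::setNames(as.numeric(s$value), s$name)
    }
    meta <- stats::setNames(sub$value[sub$kind == "meta"],
                            sub$name[sub$kind == "meta"])
    structure(list(gamma = val("shape"), coef = val("coef"), vcov = NULL,
                   loglik = NA_real_, n = NA_integer_, events = NA_integer_,
                   sex = sex, time_unit = unname(meta["time_unit"]),
                   basis = unname(meta["basis"]),
                   shape_levels = names(val("shape"))),
              class = "gompertz_fit")
  }
  sexes <- unique(tab$sex)
  list(ca = Filter(Negate(is.null),
                   stats::setNames(lapply(sexes, build, model = "ca"), sexes)),
       anthro = Filter(Negate(is.null),
                       stats::setNames(lapply(sexes, build, model = "anthro"),
                                       sexes)))
}
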