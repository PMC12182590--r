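# Independent brute-force oracles used across tests. These are written from
# the definitions, deliberately as plain double loops, and must stay
# independent of the package's vectorized implementations.

# IPCW concordance: literal double loop over all ordered pairs
oracle_uno_c <- function(lp, time, event, tau = max(time)) {
  G <- stats::stepfun(
    survival::survfit(survival::Surv(time, 1 - event) ~ 1)$time,
    c(1, survival::survfit(survival::Surv(time, 1 - event) ~ 1)$surv),
    right = FALSE)
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] >= tau) next
    w <- 1 / G(time[i])^2
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      den <- den + w
      if (lp[i] > lp[j]) num <- num + w
      else if (lp[i] == lp[j]) num <- num + w / 2
    }
  }
  num / den
}

# cumulative/dynamic IPCW AUC at a single time, literal pair sum
oracle_tauc <- function(lp, time, event, tt) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (!(time[i] <= tt && event[i] == 1)) next
    wi <- 1 / G(time[i])
    for (j in seq_len(n)) {
      if (time[j] <= tt) next
      wj <- 1 / G(tt)
      den <- den + wi * wj
      if (lp[i] > lp[j]) num <- num + wi * wj
      else if (lp[i] == lp[j]) num <- num + wi * wj / 2
    }
  }
  num / den
}

# Harrell's C by plain pair counting (no weights, no censoring assumed)
oracle_harrell <- function(lp, time) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] >= time[j]) next
    den <- den + 1
    if (lp[i] > lp[j]) num <- num + 1
    else if (lp[i] == lp[j]) num <- num + 0.5
  }
  num / den
}

# Cox partial log-likelihood (Breslow, no ties in the fixtures used)
oracle_cox_pll <- function(beta, x, time, event) {
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] != 1) next
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# log-rank statistic by hand: sum(O - E)^2 / V over event times, two groups
oracle_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    d <- sum(event == 1 & time == tt)
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d1 <- sum(event == 1 & time == tt & group == g1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + d1 - e1
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# small synthetic panels reused across files
tiny_config <- function(n = 300, seed = 42, ...) {
  synth_config(n_subjects = n, studies = list(A = c(0, 2, 4), B = c(0, 3)),
               seed = seed, ...)
}

# single-study baseline-only config with pure age-driven mortality
ca_only_config <- function(n, seed, gamma = 0.005, beta0 = -10,
                           beta1 = 0.08, censor_time = 12) {
  synth_config(
    n_subjects = n, studies = list(S = 0), seed = seed,
    mortality_params = list(gamma = gamma, beta0 = beta0, beta1 = beta1,
                            c_logbmi = 0, c_logbmi2 = 0, c_whtr_cbrt = 0),
    censor_time = censor_time)
}
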