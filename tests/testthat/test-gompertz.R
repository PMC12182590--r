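# direct evaluation of the Gompertz PH log-likelihood, term by term
hand_loglik <- function(gamma, beta, X, time, event) {
  total <- 0
  for (i in seq_along(time)) {
    xb <- sum(X[i, ] * beta)
    total <- total + event[i] * (xb + gamma * time[i]) -
      exp(xb) * (exp(gamma * time[i]) - 1) / gamma
  }
  total
}

test_that("log-likelihood equals a hand-summed evaluation on 4 subjects", {
  X <- cbind(1, c(60, 70, 80, 55))
  time <- c(24, 60, 10, 120)
  event <- c(1, 0, 1, 0)
  gamma <- 0.005; beta <- c(-10, 0.08)
  expect_equal(gompertz_loglik(gamma, beta, X, time, event),
               hand_loglik(gamma, beta, X, time, event), tolerance = 1e-12)
})

test_that("the MLE agrees with an independent Gompertz fitter", {
  skip_if_not_installed("flexsurv")
  set.seed(8)
  n <- 3000
  age <- runif(n, 50, 94)
  u <- runif(n)
  t_mo <- log1p(-0.005 * log(u) / exp(-10 + 0.08 * age)) / 0.005
  time <- pmin(t_mo, 144)
  ev <- as.integer(t_mo <= 144)
  d <- data.frame(time = time, event = ev, age = age)
  f <- fit_gompertz(survival::Surv(time, event) ~ age, d)
  fs <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ age, data = d,
                              dist = "gompertz",
                              control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(unname(f$gamma), unname(fs$res["shape", "est"]),
               tolerance = 1e-4)
  expect_equal(unname(f$coef[["rate"]]),
               log(unname(fs$res["rate", "est"])), tolerance = 1e-4)
  expect_equal(unname(f$coef[["age"]]), unname(fs$res["age", "est"]),
               tolerance = 1e-4)
  # neither optimizer found a lower maximum
  expect_equal(f$loglik, fs$loglik, tolerance = 1e-7)
  expect_gte(f$loglik, fs$loglik - 1e-4)
})

test_that("group-specific shapes are recovered and degenerate data rejected", {
  set.seed(9)
  n <- 6000
  grp <- sample(c("g1", "g2"), n, TRUE)
  gam <- ifelse(grp == "g1", 0.004, 0.008)
  age <- runif(n, 50, 94)
  u <- runif(n)
  t_mo <- log1p(-gam * log(u) / exp(-10 + 0.08 * age)) / gam
  time <- pmin(t_mo, 144)
  d <- data.frame(time = time, event = as.integer(t_mo <= 144), age = age,
                  grp = grp)
  f <- fit_gompertz(survival::Surv(time, event) ~ age, d, shape_groups = "grp")
  expect_equal(unname(f$gamma["g1"]), 0.004, tolerance = 0.25)
  expect_equal(unname(f$gamma["g2"]), 0.008, tolerance = 0.25)
  d$event <- 0
  expect_error(fit_gompertz(survival::Surv(time, event) ~ age, d),
               "zero events")
})

test_that("CDF matches direct evaluation, limits and the exponential limit", {
  expect_equal(gompertz_cdf(0.005, -5.2, 120), 0.596288298041,
               tolerance = 1e-9)
  expect_equal(gompertz_cdf(0.005, -50, 120), 0, tolerance = 1e-10)
  expect_equal(gompertz_cdf(0.005, 50, 120), 1)
  # gamma -> 0+ approaches 1 - exp(-exp(xb) t)
  expect_equal(gompertz_cdf(1e-8, -5, 120), 1 - exp(-exp(-5) * 120),
               tolerance = 1e-6)
  expect_error(gompertz_cdf(0, -5, 120), "gamma")
  expect_error(gompertz_cdf(0.005, -5, -1), "t must be")
})

test_that("closed-form biological age equals numeric CDF inversion", {
  ca <- list(gamma = 0.005, beta0 = -10, beta1 = 0.08)
  # frozen oracle: uniroot on CDF_CA(120, a) = 0.10
  expect_equal(anthropoage(ca, 0.10), 33.0898209311, tolerance = 1e-8)
  # round-trip identity at age 60
  M <- gompertz_cdf(ca$gamma, ca$beta0 + ca$beta1 * 60, 120)
  expect_equal(anthropoage(ca, M), 60, tolerance = 1e-10)
  # monotone in M
  Ms <- seq(0.01, 0.9, by = 0.01)
  expect_true(all(diff(anthropoage(ca, Ms)) > 0))
  expect_error(anthropoage(ca, 1.2), "strictly inside")
  expect_error(anthropoage(ca, 0), "strictly inside")
  expect_message(anthropoage(ca, c(0.5, 1.5), clamp = TRUE), "clamped 1")
})

test_that("batch computation stratifies by sex and matches scalar calls", {
  cfg <- tiny_config(n = 400, seed = 23)
  g <- generate_panel(cfg)
  b <- apply_eligibility(g$panel)$kept
  b <- b[b$wave == 0, ]
  sexes <- c("female", "male")
  ca <- lapply(sexes, function(s) fit_gompertz_ca(b[b$sex == s, ], s))
  an <- lapply(sexes, function(s) fit_gompertz_anthro(b[b$sex == s, ], s))
  names(ca) <- names(an) <- sexes
  aa <- anthropoage_batch(b, ca, an)
  expect_true(all(is.finite(aa)))
  # batch equals row-by-row scalar computation
  i <- c(1, 25, 100)
  scalar <- vapply(i, function(k) {
    f <- an[[b$sex[k]]]
    M <- gompertz_cdf(f$gamma[[b$ethnicity[k]]],
                      anthro_xb(f, b$age[k], b$bmi[k], b$whtr[k]), 120)
    anthropoage(ca[[b$sex[k]]], M)
  }, 0)
  expect_equal(aa[i], scalar, tolerance = 1e-12)
  # permuting rows permutes results
  perm <- sample(nrow(b))
  expect_equal(anthropoage_batch(b[perm, ], ca, an), aa[perm])
  # relabeling sex changes the result (models differ)
  b2 <- b
  b2$sex <- ifelse(b$sex == "female", "male", "female")
  expect_false(isTRUE(all.equal(anthropoage_batch(b2, ca, an), aa)))
  # unknown ethnicity named in the error
  b3 <- b[1, ]; b3$ethnicity <- "Martian"
  expect_error(anthropoage_batch(b3, ca, an), "Martian")
  # forced identity: anthropometry model == CA model makes AnthropoAge = age
  ca_id <- list(female = ca$female, male = ca$male)
  an_id <- lapply(ca, function(f) {
    f2 <- f
    f2$gamma <- c("White" = unname(f$gamma[1]), "Black" = unname(f$gamma[1]),
                  "Hispanic/Latino" = unname(f$gamma[1]),
                  "Other" = unname(f$gamma[1]))
    f2$coef <- c(rate = unname(f$coef[["rate"]]), age = unname(f$coef[["age"]]),
                 log_bmi = 0, log_bmi2 = 0, whtr_cbrt = 0)
    f2
  })
  expect_equal(anthropoage_batch(b, ca_id, an_id), b$age, tolerance = 1e-8)
})

test_that("residualization modes behave as ordinary least squares promises", {
  set.seed(31)
  n <- 400
  d <- data.frame(age = runif(n, 50, 90), sex = rep(c("female", "male"), n / 2),
                  study = sample(c("A", "B"), n, TRUE))
  d$anthropoage <- d$age + rnorm(n, 0, 3)
  r <- anthropoage_accel(d, mode = "pooled")
  for (s in c("female", "male")) {
    i <- d$sex == s
    expect_lt(abs(sum(r$accel[i])), 1e-9)
    expect_lt(abs(cor(r$accel[i], d$age[i])), 1e-10)
  }
  expect_equal(r$accelerated, r$accel > 0)
  expect_true(all(r$accel_quartile %in% 1:4))
  # identity input: all residuals zero, nobody accelerated
  d0 <- d; d0$anthropoage <- d0$age
  r0 <- anthropoage_accel(d0, mode = "study-intercepts")
  expect_equal(r0$accel, rep(0, n), tolerance = 1e-10)
  expect_false(any(r0$accelerated))
  expect_error(anthropoage_accel(d[1:2, ]), "fewer than 3")
})

test_that("study fixed intercepts absorb a constant between-study offset", {
  set.seed(32)
  n <- 300
  one <- data.frame(age = runif(n, 50, 90), sex = "female", study = "A")
  one$anthropoage <- 0.9 * one$age + rnorm(n, 0, 2)
  two <- one
  two$study <- "B"
  two$anthropoage <- two$anthropoage + 3   # constant offset
  both <- rbind(one, two)
  r_both <- anthropoage_accel(both, mode = "study-intercepts")
  r_one <- anthropoage_accel(one, mode = "study-intercepts")
  expect_equal(r_both$accel[seq_len(n)], r_one$accel, tolerance = 1e-8)
  expect_equal(r_both$accel[n + seq_len(n)], r_one$accel, tolerance = 1e-8)
})

test_that("recovered acceleration tracks the latent truth, more with stronger
           anthropometry effects", {
  run <- function(c_whtr) {
    cfg <- synth_config(n_subjects = 1500, studies = list(S = 0), seed = 77,
                        mortality_params = list(gamma = 0.0045, beta0 = -12.4,
                                                beta1 = 0.085, c_logbmi = 0,
                                                c_logbmi2 = 0,
                                                c_whtr_cbrt = c_whtr))
    g <- generate_panel(cfg)
    b <- apply_eligibility(g$panel)$kept
    sexes <- unique(b$sex)
    # small per-ethnicity strata can push a group shape to the boundary;
    # that is expected at this sample size and harmless for the rank check
    ca <- lapply(sexes, function(s) fit_gompertz_ca(b[b$sex == s, ], s))
    an <- suppressWarnings(
      lapply(sexes, function(s) fit_gompertz_anthro(b[b$sex == s, ], s)))
    names(ca) <- names(an) <- sexes
    b$anthropoage <- anthropoage_batch(b, ca, an, clamp = TRUE)
    b$accel <- anthropoage_accel(b, mode = "pooled")$accel
    m <- merge(b[, c("id", "accel")], g$truth$accel, by = "id")
    cor(m$accel.x, m$accel.y, method = "spearman")
  }
  rho_null <- run(0)
  rho_strong <- run(30)
  expect_gt(rho_strong, 0.2)
  expect_gt(rho_strong, rho_null + 0.1)
})

test_that("coefficient files round-trip bit-exactly", {
  cfg <- tiny_config(n = 300, seed = 53)
  g <- generate_panel(cfg)
  b <- apply_eligibility(g$panel)$kept
  b <- b[b$wave == 0, ]
  sexes <- c("female", "male")
  ca <- lapply(sexes, function(s) fit_gompertz_ca(b[b$sex == s, ], s))
  an <- lapply(sexes, function(s) fit_gompertz_anthro(b[b$sex == s, ], s))
  names(ca) <- names(an) <- sexes
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gompertz_coefs(ca, an, path)
  back <- read_gompertz_coefs(path)
  for (s in sexes) {
    expect_identical(back$ca[[s]]$gamma, ca[[s]]$gamma)
    expect_identical(back$ca[[s]]$coef, ca[[s]]$coef)
    expect_identical(back$anthro[[s]]$gamma, an[[s]]$gamma)
    expect_identical(back$anthro[[s]]$coef, an[[s]]$coef)
    expect_identical(back$anthro[[s]]$time_unit, "months")
  }
  # and computed ages are identical through the file
  expect_identical(anthropoage_batch(b, ca, an),
                   anthropoage_batch(b, back$ca, back$anthro))
})
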