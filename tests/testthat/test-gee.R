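test_that("independence Gaussian GEE equals weighted least squares exactly", {
  set.seed(24)
  n <- 160
  d <- data.frame(id = rep(1:40, each = 4), x = rnorm(n),
                  w = runif(n, 0.5, 2))
  d$y <- 1 + 2 * d$x + rnorm(n)
  f1 <- fit_gee(y ~ x, d, "id", "gaussian", "independence",
                weights_col = "w")
  f2 <- lm(y ~ x, d, weights = w)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("cluster size one reduces to GLM with heteroskedasticity-robust SE", {
  set.seed(25)
  n <- 150
  d <- data.frame(id = 1:n, x = rnorm(n))
  d$y <- rpois(n, exp(0.5 + 0.3 * d$x))
  g1 <- fit_gee(y ~ x, d, "id", "poisson", "independence")
  g2 <- glm(y ~ x, poisson, d)
  expect_equal(coef(g1), coef(g2), tolerance = 1e-8)
  expect_equal(unname(g1$robust_se),
               unname(sqrt(diag(sandwich::vcovHC(g2, type = "HC0")))),
               tolerance = 1e-6)
  # AR(1) working correlation is irrelevant with singleton clusters
  g3 <- fit_gee(y ~ x, d, "id", "poisson", "ar1")
  expect_equal(coef(g3), coef(g1), tolerance = 1e-8)
})

test_that("sandwich covariance is symmetric positive semi-definite", {
  set.seed(26)
  n <- 200
  d <- data.frame(id = rep(1:50, each = 4), x = rnorm(n),
                  t = rep(0:3, 50))
  d$y <- 1 + 0.5 * d$x + rep(rnorm(50), each = 4) + rnorm(n)
  f <- fit_gee(y ~ x + t, d, "id", "gaussian", "ar1", waves_col = "t")
  expect_equal(f$vcov, t(f$vcov))
  expect_true(all(eigen(f$vcov, symmetric = TRUE)$values > -1e-12))
  expect_true(is.finite(f$qic))
  expect_gte(f$n_clusters, 2)
})

test_that("GEE recovers clustered regression parameters with CI coverage", {
  # gaussian slope
  set.seed(27)
  cover_g <- replicate(40, {
    n_cl <- 80
    d <- data.frame(id = rep(seq_len(n_cl), each = 3),
                    x = rnorm(n_cl * 3))
    d$y <- 1 + 1.2 * d$x + rep(rnorm(n_cl, 0, 0.8), each = 3) +
      rnorm(n_cl * 3, 0, 0.5)
    f <- fit_gee(y ~ x, d, "id", "gaussian", "ar1")
    b <- coef(f)[["x"]]; se <- f$robust_se[2]
    b - 1.96 * se < 1.2 && b + 1.96 * se > 1.2
  })
  expect_gte(mean(cover_g), 0.85)
  # binomial log-odds with true OR 1.3
  set.seed(28)
  n_cl <- 2000
  d <- data.frame(id = rep(seq_len(n_cl), each = 3),
                  x = rnorm(n_cl * 3))
  re <- rep(rnorm(n_cl, 0, 0.3), each = 3)
  d$y <- rbinom(n_cl * 3, 1, plogis(-0.5 + log(1.3) * d$x + re))
  f <- fit_gee(y ~ x, d, "id", "binomial", "ar1")
  ci <- exp(coef(f)[["x"]] + c(-1.96, 1.96) * f$robust_se[2])
  expect_lt(ci[1], 1.3)
  expect_gt(ci[2], 1.3)
  expect_error(fit_gee(y ~ x, d[d$id == 1, ], "id", "binomial"),
               "2 clusters")
})

test_that("aging trend slope and verdict behave on constructed panels", {
  cfg <- ca_only_config(400, seed = 61, beta0 = -20)  # essentially no deaths
  cfg$studies <- list(S = c(0, 2, 4, 6))
  g <- generate_panel(cfg)
  p <- g$panel
  # biological age rising 10% faster than chronological age
  p$anthropoage <- p$age + 0.1 * p$visit_years
  tr <- aging_trend(p)
  expect_equal(tr$beta, 1.1, tolerance = 0.02)
  expect_true(tr$ci[1] <= 1.1 + 1e-8 && tr$ci[2] >= 1.1 - 1e-8)
  expect_equal(tr$verdict, "faster")
  # identity aging: slope exactly 1, indeterminate
  p$anthropoage <- p$age
  tr1 <- aging_trend(p)
  expect_equal(tr1$beta, 1, tolerance = 1e-6)
  expect_equal(tr1$verdict, "indeterminate")
  # frozen biological age: slope 0, slower than expected
  p$anthropoage <- 60
  tr0 <- aging_trend(p)
  expect_equal(tr0$beta, 0, tolerance = 1e-8)
  expect_equal(tr0$verdict, "slower")
  expect_error(aging_trend(p[p$wave == 0, ]), "two waves")
})

test_that("QIC comparison penalizes noise and rewards signal", {
  set.seed(29)
  dq <- replicate(50, {
    n_cl <- 60
    d <- data.frame(id = rep(seq_len(n_cl), each = 3),
                    x = rnorm(n_cl * 3), z = rnorm(n_cl * 3))
    d$y <- 1 + 1.5 * d$x + rep(rnorm(n_cl, 0, 0.7), each = 3) + rnorm(n_cl * 3)
    base <- fit_gee(y ~ x, d, "id", "gaussian", "ar1")
    noise <- fit_gee(y ~ x + z, d, "id", "gaussian", "ar1")
    signal_red <- fit_gee(y ~ 1, d, "id", "gaussian", "ar1")
    c(noise = qic_compare(base, noise), signal = qic_compare(signal_red, base))
  })
  # adding pure noise does not improve QIC in expectation
  expect_gte(mean(dq["noise", ]), 0)
  # adding the true data-generating covariate always improves it here
  expect_true(all(dq["signal", ] < 0))
  f <- fit_gee(y ~ x, data.frame(id = rep(1:20, 2), x = rnorm(40),
                                 y = rnorm(40)), "id", "gaussian")
  expect_equal(qic_compare(f, f), 0)
})

test_that("new-onset models exclude the baseline-positive population", {
  # 10 subjects, 3 positive at baseline
  d <- data.frame(id = rep(sprintf("s%02d", 1:10), each = 3),
                  wave = rep(0:2, 10), visit_years = rep(c(0, 2, 4), 10),
                  age = rep(runif(10, 55, 80), each = 3),
                  accel = rep(rnorm(10), each = 3))
  d$accelerated <- d$accel > 0
  d$dx <- 0
  d$dx[d$id %in% c("s01", "s02", "s03")] <- 1
  # a few new-onset cases keep the at-risk fit identified
  d$dx[d$id == "s05" & d$wave > 0] <- 1
  d$dx[d$id == "s07" & d$wave > 1] <- 1
  d$dx[d$id == "s09" & d$wave > 0] <- 1
  m <- new_onset_model(d, "dx", at_risk_exclusion = TRUE)
  expect_equal(m$n_subjects, 7)
  expect_equal(m$n_excluded, 3)
  expect_equal(m$family, "binomial")
  expect_true(all(c("per_year", "interaction", "binary") %in% m$table$model))
  d$dx <- 1
  expect_error(new_onset_model(d, "dx"), "empty at-risk")
})

test_that("new-onset recovery: null and positive acceleration effects", {
  set.seed(30)
  n <- 1200
  waves <- 0:3
  a <- rnorm(n, 0, 3)
  mk_panel <- function(or_per_sd) {
    cur <- rep(0L, n)
    rows <- lapply(waves, function(w) {
      if (w > 0)
        cur <<- pmax(cur, rbinom(n, 1, plogis(-2.2 + log(or_per_sd) * a / 3)))
      data.frame(id = sprintf("s%04d", 1:n), wave = w, visit_years = 2 * w,
                 age = 65, accel = a, accelerated = a > 0, dx = cur)
    })
    do.call(rbind, rows)
  }
  null <- new_onset_model(mk_panel(1), "dx", at_risk_exclusion = FALSE)
  tb <- null$table[null$table$model == "binary", ]
  expect_true(tb$exp_ci_low < 1 && tb$exp_ci_high > 1)
  pos <- new_onset_model(mk_panel(1.42), "dx", at_risk_exclusion = FALSE)
  tb2 <- pos$table[pos$table$model == "binary", ]
  expect_gt(tb2$estimate, 0)
  # QIC favours adding acceleration when it drives the outcome
  expect_lt(pos$delta_qic, 0)
})

test_that("weighted prevalence matches hand-computed weighted proportions", {
  d <- data.frame(id = rep(1:4, 2), wave = rep(c(0, 1), each = 4),
                  visit_years = rep(c(0, 2), each = 4),
                  accelerated = c(1, 0, 1, 1, 0, 0, 1, 0),
                  svy_weight = c(1, 2, 1, 4, 1, 1, 2, 2))
  pr <- weighted_prevalence_over_time(d)
  expect_equal(pr$prevalence, c((1 + 1 + 4) / 8, 2 / 6), tolerance = 1e-12)
  # equal weights reduce to the simple proportion
  d$svy_weight <- 1
  pr1 <- weighted_prevalence_over_time(d)
  expect_equal(pr1$prevalence, c(0.75, 0.25))
  # everyone flagged: prevalence one, CI capped at one
  d$accelerated <- 1
  pr2 <- weighted_prevalence_over_time(d)
  expect_equal(pr2$prevalence, c(1, 1))
  expect_true(all(pr2$ci_high <= 1))
})
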