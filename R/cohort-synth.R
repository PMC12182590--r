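#' Configuration for the synthetic multi-study cohort generator
#'
#' Builds and validates the configuration of [generate_panel()]. The defaults
#' emulate a harmonized multinational aging panel: five studies with 2-3 year
#' wave spacing, baseline ages 50-94 skewed towards the early 60s, sex- and
#' ethnicity-specific anthropometry that drifts with age, Gompertz mortality
#' whose hazard depends on chronological age and on deviations of log-BMI and
#' cube-root WHtR from their age expectation, and self-reported outcome
#' accrual correlated with a per-subject latent age-acceleration deviate.
#'
#' @param n_subjects Subjects per study.
#' @param studies Named list of wave schedules (visit offsets in years,
#'   strictly increasing, starting at 0).
#' @param age_range Baseline age range in years.
#' @param sex_ratio Proportion female.
#' @param ethnicity_mix Named probability vector over ethnicity groups.
#' @param anthro_params Per-sex anthropometry parameters; see Details.
#' @param mortality_params True Gompertz parameters: `gamma` (shape, per
#'   month), `beta0` (rate intercept), `beta1` (per year of age), and effect
#'   sizes `c_logbmi`, `c_logbmi2`, `c_whtr_cbrt` applied to deviations of
#'   the transformed anthropometry from its age/sex expectation.
#' @param outcome_params Baseline prevalences, per-wave incidences and
#'   per-year-of-acceleration log-odds for the self-reported outcomes.
#' @param accel_sd SD (years) of the latent per-subject acceleration.
#' @param censor_time Administrative censoring horizon in years (> 0).
#' @param seed Master RNG seed; each study uses an independent substream.
#'
#' @details `anthro_params` is a list with per-sex entries `female` / `male`,
#'   each containing `logbmi_mean`, `logbmi_sd`, `logbmi_slope` (per year of
#'   age, centred at 70), `whtr_mean`, `whtr_sd`, `whtr_slope`, `height_mean`,
#'   `height_sd`, and loadings `load_logbmi`, `load_whtr` mapping one year of
#'   latent acceleration onto the transformed anthropometry scales.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 1000,
                         studies = list(
                           HRS = seq(0, 12, by = 2),
                           ELSA = c(0, 4, 8),
                           MHAS = c(0, 2, 11),
                           CRELES = c(0, 2, 5),
                           CHARLS = c(0, 2, 4)),
                         age_range = c(50, 94),
                         sex_ratio = 0.55,
                         ethnicity_mix = c("White" = 0.55, "Black" = 0.10,
                                           "Hispanic/Latino" = 0.20,
                                           "Other" = 0.15),
                         anthro_params = default_anthro_params(),
                         mortality_params = list(gamma = 0.0045,
                                                 beta0 = -12.4, beta1 = 0.085,
                                                 c_logbmi = -1.0,
                                                 c_logbmi2 = 4.0,
                                                 c_whtr_cbrt = 25.0),
                         outcome_params = default_outcome_params(),
                         accel_sd = 3,
                         censor_time = 12,
                         seed = 20260101) {
  cfg <- list(n_subjects = n_subjects, studies = studies,
              age_range = age_range, sex_ratio = sex_ratio,
              ethnicity_mix = ethnicity_mix, anthro_params = anthro_params,
              mortality_params = mortality_params,
              outcome_params = outcome_params, accel_sd = accel_sd,
              censor_time = censor_time, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

default_anthro_params <- function() {
  base <- list(logbmi_sd = 0.16, logbmi_slope = -0.0025,
               whtr_sd = 0.05, whtr_slope = 0.0012,
               load_logbmi = -0.008, load_whtr = 0.006)
  list(
    female = c(base, list(logbmi_mean = log(27.8), whtr_mean = 0.595,
                          height_mean = 158, height_sd = 6.5)),
    male = c(base, list(logbmi_mean = log(27.0), whtr_mean = 0.575,
                        height_mean = 171, height_sd = 7.0))
  )
}

default_outcome_params <- function() {
  dx <- c(hypertension = 0.45, diabetes = 0.18, mi = 0.07, stroke = 0.05,
          cancer = 0.12, lung_disease = 0.08, arthritis = 0.35)
  list(
    prevalence = dx,
    incidence = dx / 8,          # per-wave new-report probability
    log_or_accel = 0.08,         # per year of latent acceleration
    poor_srh_prev = 0.10, poor_srh_inc = 0.03,
    adl_item_p = 0.05, iadl_item_p = 0.06,
    adl_age_slope = 0.05,        # logit per year of age over 70
    adl_log_or_accel = 0.10
  )
}

validate_synth_config <- function(cfg) {
  mp <- cfg$mortality_params
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(unlist(mp))) stop("mortality_params must be finite numbers")
  if (mp$gamma <= 0) stop("Gompertz shape gamma must be > 0")
  if (!num_ok(cfg$censor_time) || cfg$censor_time <= 0)
    stop("censor_time must be > 0: no positive follow-up is possible")
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1)
    stop("sex_ratio must be a probability")
  if (any(cfg$ethnicity_mix < 0) || abs(sum(cfg$ethnicity_mix) - 1) > 1e-8)
    stop("ethnicity_mix must be a probability distribution")
  if (!length(cfg$studies)) stop("at least one study is required")
  for (s in names(cfg$studies)) {
    w <- cfg$studies[[s]]
    if (!length(w)) stop("empty wave schedule for study ", s)
    if (w[1] != 0 || any(diff(w) <= 0))
      stop("wave offsets must be strictly increasing and start at 0 (", s, ")")
  }
  pr <- c(cfg$outcome_params$prevalence, cfg$outcome_params$incidence,
          cfg$outcome_params$poor_srh_prev, cfg$outcome_params$adl_item_p)
  if (any(pr < 0 | pr > 1)) stop("outcome probabilities must lie in [0, 1]")
  invisible(cfg)
}

# expected transformed anthropometry at a given age (deviations from these
# enter the true hazard)
anthro_expect <- function(p, age) {
  list(logbmi = p$logbmi_mean + p$logbmi_slope * (age - 70),
       whtr = p$whtr_mean + p$whtr_slope * (age - 70))
}

#' Generate a synthetic multi-study longitudinal panel
#'
#' Draws one long-format panel (one row per participant-visit) plus a ground
#' truth sidecar. Per subject: fixed demographics; a latent Gaussian
#' age-acceleration deviate (years) that loads on anthropometry and on
#' outcome accrual; anthropometry evolving along configured age slopes with
#' visit-level noise, back-transformed and clipped to plausibility ranges;
#' a death time drawn in continuous time from the configured Gompertz hazard
#' (shape per month) with linear predictor
#' `beta0 + beta1 * baseline age + effects of transformed-anthropometry
#' deviations`, reported rounded to the month; administrative censoring at
#' `censor_time` years. Visits after death are dropped; reported diagnoses
#' persist at later waves; survey weights are positive with mean 1.
#'
#' @param config A [synth_config()].
#' @param hr_accel Hazard multiplier applied to subjects whose latent
#'   acceleration is positive (used by [inject_acceleration()]); default 1.
#' @return A list with `panel` (data frame) and `truth` (list with the
#'   config, per-subject latent accelerations, true parameters and the
#'   anthropometry clipping fraction). `truth` is never consumed by any
#'   estimation code path.
#' @export
generate_panel <- function(config, hr_accel = 1) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  if (!is.finite(hr_accel) || hr_accel <= 0) stop("hr_accel must be > 0")
  studies <- names(config$studies)
  pieces <- vector("list", length(studies))
  accel_list <- vector("list", length(studies))
  clipped <- 0L; total_meas <- 0L
  for (k in seq_along(studies)) {
    # independent substream per study: appending a study never perturbs others
    g <- gen_study(config, studies[k], config$studies[[k]],
                   seed = config$seed + 104729L * k, hr_accel = hr_accel)
    pieces[[k]] <- g$panel
    accel_list[[k]] <- g$accel
    clipped <- clipped + g$n_clipped
    total_meas <- total_meas + g$n_meas
  }
  panel <- do.call(rbind, pieces)
  rownames(panel) <- NULL
  truth <- list(config = config,
                accel = do.call(rbind, accel_list),
                params = config$mortality_params,
                hr_accel = hr_accel,
                clip_fraction = clipped / max(total_meas, 1L))
  list(panel = panel, truth = truth)
}

gen_study <- function(cfg, study, waves, seed, hr_accel) {
  set.seed(seed %% .Machine$integer.max)
  n <- cfg$n_subjects
  nw <- length(waves)
  mp <- cfg$mortality_params
  op <- cfg$outcome_params
  # --- subject-level draws (fixed order so the stream is reproducible and
  # independent of death times)
  age0 <- cfg$age_range[1] +
    diff(cfg$age_range) * stats::rbeta(n, 1.5, 3.0)
  sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "female", "male")
  eth <- sample(names(cfg$ethnicity_mix), n, TRUE, prob = cfg$ethnicity_mix)
  accel <- stats::rnorm(n, 0, cfg$accel_sd)
  svy_weight <- stats::rgamma(n, shape = 4, rate = 4)
  education <- sample(c("primary_or_less", "secondary", "tertiary"), n, TRUE,
                      prob = c(0.45, 0.35, 0.20))
  smoking <- sample(c("never", "former", "lt10_day", "ge10_day"), n, TRUE,
                    prob = c(0.50, 0.30, 0.10, 0.10))
  alcohol <- sample(c("never", "lt_weekly", "lt_daily", "daily"), n, TRUE,
                    prob = c(0.40, 0.30, 0.20, 0.10))
  ap <- cfg$anthro_params
  pf <- ap$female; pm <- ap$male
  pick <- function(fe, ma) ifelse(sex == "female", fe, ma)
  height <- stats::rnorm(n, pick(pf$height_mean, pm$height_mean),
                         pick(pf$height_sd, pm$height_sd))
  height <- pmin(pmax(height, 126), 199)
  # subject-level anthropometry deviations: latent-acceleration loading plus
  # an independent stable component
  dev_logbmi <- pick(pf$load_logbmi, pm$load_logbmi) * accel +
    stats::rnorm(n, 0, pick(pf$logbmi_sd, pm$logbmi_sd) * 0.8)
  dev_whtr <- pick(pf$load_whtr, pm$load_whtr) * accel +
    stats::rnorm(n, 0, pick(pf$whtr_sd, pm$whtr_sd) * 0.7)
  # --- visit-level measurement noise, drawn for every scheduled wave
  noise_bmi <- matrix(stats::rnorm(n * nw, 0, 0.03), n, nw)
  noise_whtr <- matrix(stats::rnorm(n * nw, 0, 0.012), n, nw)
  # --- mortality: hazard uses baseline age and baseline transformed-scale
  # deviations from the age expectation
  exp_lb <- pick(anthro_expect(pf, age0)$logbmi, anthro_expect(pm, age0)$logbmi)
  exp_wh <- pick(anthro_expect(pf, age0)$whtr, anthro_expect(pm, age0)$whtr)
  lb0 <- exp_lb + dev_logbmi + noise_bmi[, 1]
  wh0 <- exp_wh + dev_whtr + noise_whtr[, 1]
  d_lb <- lb0 - exp_lb
  d_wc <- wh0^(1 / 3) - exp_wh^(1 / 3)
  xb <- mp$beta0 + mp$beta1 * age0 +
    mp$c_logbmi * d_lb + mp$c_logbmi2 * d_lb^2 + mp$c_whtr_cbrt * d_wc
  xb <- xb + log(hr_accel) * (accel > 0)
  u <- stats::runif(n)
  # inverse-CDF draw from S(t) = exp(-e^xb (e^(g t) - 1)/g), t in months
  t_mo <- log1p(-mp$gamma * log(u) / exp(xb)) / mp$gamma
  death_mo <- pmax(round(t_mo), 1)            # reported to the month
  death_yr <- death_mo / 12
  cens <- cfg$censor_time
  follow_up <- pmin(death_yr, cens)
  event <- as.integer(death_yr <= cens)
  # --- outcomes: draws for every wave regardless of death, then persistence
  dx_names <- names(op$prevalence)
  dx <- array(0L, c(n, nw, length(dx_names)),
              dimnames = list(NULL, NULL, dx_names))
  lo <- op$log_or_accel * accel
  for (j in seq_along(dx_names)) {
    p0 <- stats::plogis(stats::qlogis(op$prevalence[j]) + lo)
    pinc <- stats::plogis(stats::qlogis(op$incidence[j]) + lo)
    cur <- stats::rbinom(n, 1, p0)
    dx[, 1, j] <- cur
    if (nw > 1) for (w in 2:nw) {
      cur <- pmax(cur, stats::rbinom(n, 1, pinc))
      dx[, w, j] <- cur
    }
  }
  srh_poor <- matrix(0L, n, nw)
  cur <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(op$poor_srh_prev) + lo))
  srh_poor[, 1] <- cur
  if (nw > 1) for (w in 2:nw) {
    cur <- pmax(cur, stats::rbinom(n, 1,
                                   stats::plogis(stats::qlogis(op$poor_srh_inc) + lo)))
    srh_poor[, w] <- cur
  }
  adl <- matrix(0L, n, nw); iadl <- matrix(0L, n, nw)
  for (w in seq_len(nw)) {
    eta_a <- stats::qlogis(op$adl_item_p) +
      op$adl_age_slope * (age0 + waves[w] - 70) + op$adl_log_or_accel * accel
    eta_i <- stats::qlogis(op$iadl_item_p) +
      op$adl_age_slope * (age0 + waves[w] - 70) + op$adl_log_or_accel * accel
    adl[, w] <- stats::rbinom(n, 5, stats::plogis(eta_a))
    iadl[, w] <- stats::rbinom(n, 4, stats::plogis(eta_i))
  }
  adl <- t(apply(adl, 1, cummax)); iadl <- t(apply(iadl, 1, cummax))
  if (nw == 1) { adl <- matrix(adl, n, 1); iadl <- matrix(iadl, n, 1) }
  # --- assemble rows: a visit is kept if the subject is alive at its offset
  ids <- sprintf("%s_%05d", study, seq_len(n))
  rows <- vector("list", nw)
  n_clipped <- 0L; n_meas <- 0L
  for (w in seq_len(nw)) {
    alive <- waves[w] == 0 | (follow_up > waves[w])
    i <- which(alive)
    if (!length(i)) next
    agev <- age0[i] + waves[w]
    exp_lb_v <- pick(anthro_expect(pf, agev)$logbmi,
                     anthro_expect(pm, agev)$logbmi)[i]
    exp_wh_v <- pick(anthro_expect(pf, agev)$whtr,
                     anthro_expect(pm, agev)$whtr)[i]
    bmi <- exp(exp_lb_v + dev_logbmi[i] + noise_bmi[i, w])
    whtr <- exp_wh_v + dev_whtr[i] + noise_whtr[i, w]
    n_meas <- n_meas + length(i)
    bclip <- bmi < 10.2 | bmi > 59.5
    wclip <- whtr * height[i] < 51 | whtr * height[i] > 159
    n_clipped <- n_clipped + sum(bclip | wclip)
    bmi <- pmin(pmax(bmi, 10.2), 59.5)
    waist <- pmin(pmax(whtr * height[i], 51), 159)
    rows[[w]] <- data.frame(
      id = ids[i], study = study, wave = w - 1L, visit_years = waves[w],
      age = agev, sex = sex[i], ethnicity = eth[i],
      height_cm = height[i], weight_kg = bmi * (height[i] / 100)^2,
      waist_cm = waist, bmi = bmi, whtr = waist / height[i],
      education = education[i], smoking = smoking[i], alcohol = alcohol[i],
      svy_weight = svy_weight[i],
      follow_up_years = follow_up[i], event = event[i],
      adl = adl[i, w], iadl = iadl[i, w],
      srh = ifelse(srh_poor[i, w] == 1, 5L,
                   1L + (seq_along(i) %% 4L)),   # non-poor levels spread 1-4
      poor_srh = srh_poor[i, w],
      stringsAsFactors = FALSE
    )
    for (j in dx_names) rows[[w]][[j]] <- dx[i, w, j]
    rows[[w]]$comorbidity_count <- rowSums(dx[i, w, , drop = FALSE])
    rows[[w]]$multimorbidity <- as.integer(rows[[w]]$comorbidity_count >= 2)
  }
  panel <- do.call(rbind, rows)
  panel <- panel[order(panel$id, panel$wave), , drop = FALSE]
  list(panel = panel,
       accel = data.frame(id = ids, study = study, accel = accel,
                          stringsAsFactors = FALSE),
       n_clipped = n_clipped, n_meas = n_meas)
}

#' Multiply the hazard of latently accelerated subjects
#'
#' Regenerates the panel from its stored configuration with the hazard of
#' every subject whose latent acceleration is positive multiplied by
#' `hr_accel`. All random draws reuse the original per-study substreams, so
#' `hr_accel = 1` reproduces the input panel exactly and only death and
#' censoring outcomes change otherwise.
#'
#' @param panel Panel data frame from [generate_panel()] (unused except for
#'   interface symmetry; the regeneration is driven by `truth`).
#' @param truth Ground-truth sidecar from [generate_panel()].
#' @param hr_accel Positive hazard ratio.
#' @return A list with the regenerated `panel` and updated `truth`.
#' @export
inject_acceleration <- function(panel, truth, hr_accel) {
  if (!is.numeric(hr_accel) || !is.finite(hr_accel) || hr_accel <= 0)
    stop("hr_accel must be a positive finite number")
  generate_panel(truth$config, hr_accel = hr_accel)
}

#' Write / read a synthetic panel and its truth sidecar
#'
#' The panel is written as plain CSV (one row per visit); the truth sidecar
#' is written as a CSV of per-subject latent accelerations plus a key-value
#' text file of true parameters.
#'
#' @param x Result of [generate_panel()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pp <- file.path(dir, "panel.csv")
  ap <- file.path(dir, "truth_accel.csv")
  tp <- file.path(dir, "truth_params.txt")
  utils::write.csv(x$panel, pp, row.names = FALSE)
  utils::write.csv(x$truth$accel, ap, row.names = FALSE)
  prm <- c(unlist(x$truth$params), hr_accel = x$truth$hr_accel,
           clip_fraction = x$truth$clip_fraction)
  writeLines(sprintf("%s\t%.17g", names(prm), prm), tp)
  invisible(c(panel = pp, accel = ap, params = tp))
}
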