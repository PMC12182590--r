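#' Validate the schema of a panel file or data frame
#'
#' Checks required columns, their types, unit plausibility (age 0-120,
#' height 50-250 cm) and uniqueness of (id, wave) pairs.
#'
#' @param panel A data frame or the path of a delimited (CSV) panel file.
#' @return List with `ok` (logical) and `problems` (data frame of
#'   column/check/detail rows; empty when `ok`).
#' @export
validate_schema <- function(panel) {
  if (is.character(panel)) {
    if (!file.exists(panel)) stop("unreadable file: ", panel)
    panel <- utils::read.csv(panel, stringsAsFactors = FALSE)
  }
  req_num <- c(wave = NA, visit_years = NA, age = NA, height_cm = NA,
               weight_kg = NA, waist_cm = NA, svy_weight = NA,
               follow_up_years = NA, event = NA)
  req_chr <- c("id", "study", "sex", "ethnicity")
  probs <- list()
  add <- function(col, check, detail)
    probs[[length(probs) + 1]] <<- data.frame(column = col, check = check,
                                              detail = detail)
  for (cn in c(names(req_num), req_chr))
    if (!cn %in% names(panel)) add(cn, "presence", "missing column")
  for (cn in intersect(names(req_num), names(panel)))
    if (!is.numeric(panel[[cn]])) add(cn, "type", "not numeric")
  chk_range <- function(cn, lo, hi) {
    if (cn %in% names(panel) && is.numeric(panel[[cn]])) {
      bad <- sum(panel[[cn]] < lo | panel[[cn]] > hi, na.rm = TRUE)
      if (bad) add(cn, "plausibility",
                   sprintf("%d value(s) outside [%g, %g]", bad, lo, hi))
    }
  }
  chk_range("age", 0, 120)
  chk_range("height_cm", 50, 250)
  chk_range("event", 0, 1)
  if (all(c("id", "wave") %in% names(panel))) {
    key <- paste(panel$id, panel$wave)
    dup <- key[duplicated(key)]
    if (length(dup)) add("id/wave", "uniqueness",
                        paste("duplicated:", dup[1]))
  }
  problems <- if (length(probs)) do.call(rbind, probs)
  else data.frame(column = character(), check = character(),
                  detail = character())
  list(ok = nrow(problems) == 0, problems = problems)
}

#' Pipeline configuration
#'
#' Validated configuration of [run_pipeline()].
#'
#' @param panel Data frame or path of the input panel.
#' @param outdir Output directory for the report tables.
#' @param coefs Path of a coefficient file ([read_gompertz_coefs()] format)
#'   or `NULL` to self-fit the Gompertz models on the panel's baseline.
#' @param horizon_months Risk horizon of the CDF matching (default 120).
#' @param accel_mode Residualization mode for [anthropoage_accel()].
#' @param eval_years Horizons (years) of the time-dependent AUC grid.
#' @param dca_thresholds Threshold grid of the decision curves.
#' @param boot_B,seed Bootstrap resamples and master RNG seed.
#' @param truncate_followup Optional follow-up truncation (years): events
#'   after it are censored at it (sensitivity analysis).
#' @param onset_outcomes Outcome columns for the new-onset model grid.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(panel, outdir, coefs = NULL,
                            horizon_months = 120,
                            accel_mode = "study-intercepts",
                            eval_years = c(2, 4, 6, 8, 10),
                            dca_thresholds = seq(0.01, 0.50, 0.01),
                            boot_B = 200, seed = 20260101,
                            truncate_followup = NULL,
                            onset_outcomes = c("adl", "iadl", "poor_srh",
                                               "diabetes", "hypertension")) {
  stopifnot(horizon_months > 0, boot_B >= 100)
  structure(list(panel = panel, outdir = outdir, coefs = coefs,
                 horizon_months = horizon_months, accel_mode = accel_mode,
                 eval_years = eval_years, dca_thresholds = dca_thresholds,
                 boot_B = boot_B, seed = as.integer(seed),
                 truncate_followup = truncate_followup,
                 onset_outcomes = onset_outcomes),
            class = "pipeline_config")
}

write_stage <- function(tab, path, n, seed, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# n=%d seed=%d config=%s", n, seed, hash), con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  path
}

#' Run the end-to-end validation pipeline
#'
#' Stages, each writing a CSV table to `config$outdir`: schema validation;
#' eligibility accounting; Gompertz model fitting (or coefficient loading)
#' on the baseline wave; AnthropoAge / AnthropoAgeAccel computation with
#' per-study distribution summaries; discrimination (Uno's c and
#' time-dependent AUC for age, age + AnthropoAgeAccel and the benchmark
#' body-shape indices, with a paired bootstrap comparison of the first two);
#' decision curves for the two Gompertz risk models; Cox models for
#' accelerated aging with three adjustment tiers and for AnthropoAgeAccel
#' quartiles, plus Kaplan-Meier/log-rank by accelerated aging and
#' multimorbidity; GEE aging trends and weighted prevalence over time per
#' study; and a new-onset outcome grid with QIC differences. Every table
#' header carries the sample size, seed and a hash of the configuration.
#' A stage failure aborts with the stage name; previously written outputs
#' are flagged invalid in `MANIFEST.txt`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all tables and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- file.path(config$outdir, "config.txt")
  cfg_flat <- unlist(config[setdiff(names(config), c("panel", "outdir"))])
  writeLines(sprintf("%s=%s", names(cfg_flat), as.character(cfg_flat)),
             cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  manifest <- file.path(config$outdir, "MANIFEST.txt")
  done <- character()
  out <- list(paths = character())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      writeLines(c(paste("INVALID: pipeline failed at stage", name),
                   paste("completed:", paste(done, collapse = ", "))),
                 manifest)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    done <<- c(done, name)
    message(sprintf("[%s] done (rows in: %d)", name, nrow(panel)))
    res
  }
  emit <- function(tab, file, n) {
    p <- write_stage(tab, file.path(config$outdir, file), n, config$seed, hash)
    out$paths <<- c(out$paths, p)
    tab
  }

  panel <- config$panel
  if (is.character(panel)) panel <- utils::read.csv(panel,
                                                    stringsAsFactors = FALSE)

  stage("schema", {
    v <- validate_schema(panel)
    if (!v$ok) stop("schema validation failed: ",
                    paste(v$problems$column, v$problems$detail,
                          collapse = "; "))
  })

  if (!is.null(config$truncate_followup)) {
    tf <- config$truncate_followup
    panel$event <- ifelse(panel$follow_up_years > tf, 0L, panel$event)
    panel$follow_up_years <- pmin(panel$follow_up_years, tf)
  }

  elig <- stage("eligibility", apply_eligibility(panel))
  acct <- do.call(rbind, lapply(split(seq_len(nrow(panel)), panel$study),
                                function(i) {
    dr <- elig$dropped[elig$dropped$study %in% panel$study[i][1], ]
    data.frame(study = panel$study[i][1], input = length(i),
               kept = sum(elig$kept$study == panel$study[i][1]),
               dropped = nrow(dr))
  }))
  out$eligibility <- emit(acct, "eligibility.csv", nrow(panel))
  out$drop_reasons <- emit(
    as.data.frame(table(reason = elig$dropped$reason)),
    "drop_reasons.csv", nrow(panel))
  panel <- elig$kept
  base <- panel[panel$wave == min(panel$wave), , drop = FALSE]

  fits <- stage("gompertz_fit", {
    if (!is.null(config$coefs)) read_gompertz_coefs(config$coefs)
    else {
      sexes <- unique(base$sex)
      ca <- lapply(sexes, function(s)
        fit_gompertz_ca(base[base$sex == s, ], sex = s))
      an <- lapply(sexes, function(s)
        fit_gompertz_anthro(base[base$sex == s, ], sex = s))
      names(ca) <- names(an) <- sexes
      write_gompertz_coefs(ca, an, file.path(config$outdir, "coefs.tsv"))
      list(ca = ca, anthro = an)
    }
  })

  ba <- stage("anthropoage", {
    panel$anthropoage <- anthropoage_batch(panel, fits$ca, fits$anthro,
                                           t = config$horizon_months,
                                           clamp = TRUE)
    acc <- anthropoage_accel(panel, mode = config$accel_mode)
    panel$accel <- acc$accel
    panel$accelerated <- acc$accelerated
    panel$accel_quartile <- acc$accel_quartile
    panel
  })
  panel <- ba
  base <- panel[panel$wave == min(panel$wave), , drop = FALSE]
  qt <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75))
  summ <- do.call(rbind, lapply(split(base, base$study), function(d)
    data.frame(study = d$study[1], n = nrow(d),
               aa_median = qt(d$anthropoage)[2], aa_q1 = qt(d$anthropoage)[1],
               aa_q3 = qt(d$anthropoage)[3],
               accel_median = qt(d$accel)[2],
               pct_accelerated = 100 * mean(d$accelerated),
               deaths = sum(d$event), row.names = NULL)))
  pooled <- data.frame(study = "pooled", n = nrow(base),
                       aa_median = qt(base$anthropoage)[2],
                       aa_q1 = qt(base$anthropoage)[1],
                       aa_q3 = qt(base$anthropoage)[3],
                       accel_median = qt(base$accel)[2],
                       pct_accelerated = 100 * mean(base$accelerated),
                       deaths = sum(base$event), row.names = NULL)
  out$ba_summary <- emit(rbind(summ, pooled), "ba_summary.csv", nrow(base))

  disc <- stage("discrimination", {
    lps <- list(
      ca = base$age,
      ca_accel = {
        f <- fit_cox(base, ~ age + accel)
        drop(as.matrix(base[, c("age", "accel")]) %*% stats::coef(f))
      },
      bri = body_roundness_index(base$waist_cm, base$height_cm),
      wwi = weight_adjusted_waist_index(base$waist_cm, base$weight_kg),
      absi = a_body_shape_index(base$waist_cm, base$bmi, base$height_cm))
    rows <- lapply(names(lps), function(m) {
      uc <- uno_c(lps[[m]], base$follow_up_years, base$event)
      ta <- tauc(lps[[m]], base$follow_up_years, base$event,
                 config$eval_years)
      data.frame(model = m, metric = c("uno_c", paste0("tauc_", ta$time)),
                 estimate = c(uc$estimate, ta$auc))
    })
    tab <- do.call(rbind, rows)
    cmp <- compare_auc_bootstrap(lps$ca_accel, lps$ca, base$follow_up_years,
                                 base$event,
                                 horizon = max(config$eval_years),
                                 B = config$boot_B, seed = config$seed)
    list(tab = tab, cmp = cmp, lps = lps)
  })
  out$discrimination <- emit(disc$tab, "discrimination.csv", nrow(base))
  out$auc_comparison <- emit(
    data.frame(delta = disc$cmp$delta, se = disc$cmp$se, p = disc$cmp$p,
               auc_ca_accel = disc$cmp$auc_a, auc_ca = disc$cmp$auc_b,
               B_used = disc$cmp$B_used),
    "auc_comparison.csv", nrow(base))

  dca <- stage("decision_curve", {
    horizon_y <- config$horizon_months / 12
    risk_anthro <- vapply(seq_len(nrow(base)), function(i) {
      f <- fits$anthro[[base$sex[i]]]
      gompertz_cdf(f$gamma[[base$ethnicity[i]]],
                   anthro_xb(f, base$age[i], base$bmi[i], base$whtr[i]),
                   config$horizon_months)
    }, 0)
    risk_ca <- vapply(seq_len(nrow(base)), function(i) {
      p <- ca_params(fits$ca[[base$sex[i]]])
      gompertz_cdf(p$gamma, p$beta0 + p$beta1 * base$age[i],
                   config$horizon_months)
    }, 0)
    nb_a <- net_benefit_survival(risk_anthro, base$follow_up_years,
                                 base$event, horizon_y,
                                 config$dca_thresholds,
                                 weights = base$svy_weight)
    nb_c <- net_benefit_survival(risk_ca, base$follow_up_years, base$event,
                                 horizon_y, config$dca_thresholds,
                                 weights = base$svy_weight)
    d <- delta_net_benefit(nb_a, nb_c)
    data.frame(threshold = nb_a$threshold, nb_anthro = nb_a$nb_model,
               nb_ca = nb_c$nb_model, nb_all = nb_a$nb_all, nb_none = 0,
               delta_anthro_vs_ca = d$delta)
  })
  out$decision_curve <- emit(dca, "decision_curve.csv", nrow(base))

  cox <- stage("cox_accelerated", {
    if (sum(base$event) == 0) stop("zero events")
    tiers <- list(unadjusted = ~ accelerated,
                  age_adjusted = ~ accelerated + age,
                  fully_adjusted = ~ accelerated + age + education +
                    smoking + alcohol + hypertension + diabetes + mi +
                    stroke + cancer + lung_disease + arthritis)
    tabs <- lapply(names(tiers), function(tn) {
      f <- fit_cox(base, tiers[[tn]], strata = c("sex", "ethnicity"),
                   weights_col = "svy_weight", robust = TRUE)
      tb <- cox_table(f)
      cbind(tier = tn, tb[tb$term == "acceleratedTRUE", , drop = FALSE])
    })
    bq <- base
    bq$accel_quartile <- factor(bq$accel_quartile)
    fq <- fit_cox(bq, ~ accel_quartile + age, strata = c("sex", "ethnicity"),
                  weights_col = "svy_weight", robust = TRUE)
    tq <- cox_table(fq)
    ph <- ph_test(fit_cox(base, ~ accelerated + age))
    list(hr = do.call(rbind, tabs), quart = tq, ph = ph$table)
  })
  out$cox_hr <- emit(cox$hr, "cox_accelerated.csv", nrow(base))
  out$cox_quartiles <- emit(cox$quart, "cox_quartiles.csv", nrow(base))
  out$ph_test <- emit(cbind(term = rownames(cox$ph), cox$ph),
                      "ph_test.csv", nrow(base))

  km <- stage("kaplan_meier", {
    g <- interaction(base$accelerated, base$multimorbidity >= 1,
                     sep = "_x_mm_")
    lr <- log_rank(base$follow_up_years, base$event, g)
    list(km = kaplan_meier(base$follow_up_years, base$event, g,
                           weights = base$svy_weight),
         lr = data.frame(statistic = lr$statistic, df = lr$df, p = lr$p))
  })
  out$km <- emit(km$km, "km_accel_multimorbidity.csv", nrow(base))
  out$log_rank <- emit(km$lr, "log_rank.csv", nrow(base))

  trends <- stage("gee_trends", {
    per <- lapply(unique(panel$study), function(s) {
      tr <- aging_trend(panel[panel$study == s, ], adjust = "none")
      data.frame(study = s, beta = tr$beta, ci_low = tr$ci[1],
                 ci_high = tr$ci[2], verdict = tr$verdict)
    })
    trp <- aging_trend(panel, adjust = "none")
    rbind(do.call(rbind, per),
          data.frame(study = "pooled", beta = trp$beta,
                     ci_low = trp$ci[1], ci_high = trp$ci[2],
                     verdict = trp$verdict))
  })
  out$trends <- emit(trends, "gee_trends.csv", nrow(panel))
  out$prevalence <- emit(weighted_prevalence_over_time(panel),
                         "accel_prevalence.csv", nrow(panel))

  onset <- stage("new_onset", {
    rows <- lapply(config$onset_outcomes, function(oc) {
      m <- new_onset_model(panel, oc, at_risk_exclusion = TRUE)
      cbind(outcome = oc, m$table, delta_qic = m$delta_qic,
            n_subjects = m$n_subjects, family = m$family)
    })
    do.call(rbind, rows)
  })
  out$new_onset <- emit(onset, "new_onset.csv", nrow(panel))

  writeLines(c("VALID", paste("completed:", paste(done, collapse = ", "))),
             manifest)
  invisible(out)
}
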