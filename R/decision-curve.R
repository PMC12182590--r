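#' Net benefit of a risk model across threshold probabilities
#'
#' Decision curve analysis for a binary outcome. At threshold `p_t` subjects
#' with predicted risk at or above `p_t` are "treated"; the net benefit is
#' `TP/n - (FP/n) * p_t / (1 - p_t)`, with the treat-all curve counting
#' everyone as treated and treat-none identically zero. An optional weight
#' vector replaces counts by weight sums (weights are normalized internally,
#' so equal weights reproduce the unweighted curve exactly).
#'
#' @param risk Predicted event probabilities in \[0, 1\].
#' @param observed Binary outcome (event within the horizon).
#' @param thresholds Threshold grid, strictly inside (0, 1); default
#'   0.01-0.50 in steps of 0.01.
#' @param weights Optional non-negative weights.
#' @return A data frame of class `net_benefit_curve` with columns
#'   `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
net_benefit <- function(risk, observed, thresholds = seq(0.01, 0.50, 0.01),
                        weights = NULL) {
  if (!length(thresholds)) stop("empty threshold grid")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  if (any(risk < 0 | risk > 1, na.rm = TRUE))
    stop("risks must lie in [0, 1]")
  w <- if (is.null(weights)) rep(1, length(risk)) else weights
  if (any(w < 0)) stop("weights must be non-negative")
  n <- sum(w)
  y <- as.numeric(observed)
  prev <- sum(w * y) / n
  nb <- vapply(thresholds, function(p) {
    treat <- risk >= p
    tp <- sum(w[treat] * y[treat])
    fp <- sum(w[treat] * (1 - y[treat]))
    (tp - fp * p / (1 - p)) / n
  }, 0)
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  structure(data.frame(threshold = thresholds, nb_model = nb,
                       nb_all = nb_all, nb_none = 0),
            class = c("net_benefit_curve", "data.frame"))
}

#' Net benefit for a survival outcome at a fixed horizon
#'
#' Converts a right-censored outcome into horizon-binary status with IPCW:
#' events before the horizon weigh `1/G(t_i)`, survivors past it weigh
#' `1/G(tau)`, and subjects censored before the horizon get weight zero
#' (`ipcw = FALSE` instead drops censored-before-horizon subjects and leaves
#' everyone else at weight one — the naive complete-follower variant).
#'
#' @inheritParams net_benefit
#' @param time,event Survival outcome (years).
#' @param horizon_years Risk horizon.
#' @param ipcw Use inverse-probability-of-censoring weights (default).
#' @param weights Optional survey weights, multiplied with the censoring
#'   weights.
#' @return A `net_benefit_curve`.
#' @export
net_benefit_survival <- function(risk, time, event, horizon_years,
                                 thresholds = seq(0.01, 0.50, 0.01),
                                 ipcw = TRUE, weights = NULL) {
  status <- as.numeric(time <= horizon_years & event == 1)
  if (ipcw) {
    G <- censoring_km(time, event)
    wc <- ifelse(status == 1, 1 / G(time),
                 ifelse(time > horizon_years, 1 / G(horizon_years), 0))
  } else {
    keep <- status == 1 | time > horizon_years
    wc <- as.numeric(keep)
  }
  if (!is.null(weights)) wc <- wc * weights
  net_benefit(risk, status, thresholds, weights = wc)
}

#' Per-threshold difference of two net-benefit curves
#'
#' @param curve_a,curve_b `net_benefit_curve` objects on identical grids.
#' @return Data frame with `threshold` and `delta` (A - B).
#' @export
delta_net_benefit <- function(curve_a, curve_b) {
  if (!isTRUE(all.equal(curve_a$threshold, curve_b$threshold)))
    stop("threshold grids differ")
  data.frame(threshold = curve_a$threshold,
             delta = curve_a$nb_model - curve_b$nb_model)
}
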