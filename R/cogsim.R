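# Generative parameter fields, their legal ranges, and whether the shipped
# presets attach a between-person SD taken from the normative SD column.
param_fields <- function() {
  tibble::tribble(
    ~field,                 ~lo,   ~hi,
    "rt_base_ms",            200,   Inf,
    "alerting_ms",          -Inf,   Inf,
    "orienting_ms",         -Inf,   Inf,
    "congruency_ms",        -Inf,   Inf,
    "rt_sigma_ms",             1,   Inf,
    "err_base",                0,     1,
    "err_alerting_delta",     -1,     1,
    "err_orienting_delta",    -1,     1,
    "err_congruency_delta",   -1,     1,
    "anticipation_rate",       0,     1,
    "ev_hit_p1",               0,     1,
    "ev_hit_slope",           -1,     1,
    "fa_p1",                   0,     1,
    "fa_slope",               -1,     1,
    "av_mu1_ms",               1,   Inf,
    "av_mu_slope_ms",       -Inf,   Inf,
    "av_sigma1_ms",            1,   Inf,
    "av_sigma_slope_ms",    -Inf,   Inf,
    "av_lapse_mix",            0,     1
  )
}

#' Generative cognitive parameters of one simulated participant
#'
#' These parameters are, by construction, the quantities the scoring module
#' estimates: additive reaction-time effects of the warning tone, the
#' spatial cue, and flanker congruency; error probabilities and their
#' condition deltas; block-linear executive-vigilance hit and false-alarm
#' probabilities; and block-linear arousal-vigilance RT mean/SD with a
#' slow-tail lapse mixture.
#'
#' @param rt_base_ms Mean correct RT (ms) in the reference cell (warning
#'   tone present, no cue, congruent flankers).
#' @param alerting_ms RT cost of a missing warning tone (no-tone minus tone).
#' @param orienting_ms RT cost of an invalid vs. valid cue; the no-cue cell
#'   sits at the midpoint, so half the effect is added on invalid trials and
#'   half subtracted on valid trials.
#' @param congruency_ms RT cost of incongruent flankers.
#' @param rt_sigma_ms Within-person trial-to-trial RT SD (ms).
#' @param err_base Error probability in the reference cell.
#' @param err_alerting_delta,err_orienting_delta,err_congruency_delta Error
#'   probability deltas paralleling the RT effects.
#' @param anticipation_rate Probability a trial's RT is replaced by an
#'   anticipatory response in 80-199 ms (removed by the RT filter).
#' @param ev_hit_p1 Block-1 probability of detecting a displaced target.
#' @param ev_hit_slope Change in hit probability per block.
#' @param fa_p1 Block-1 probability of a spacebar false alarm on
#'   fa-difficult flanker trials.
#' @param fa_slope Change in false-alarm probability per block.
#' @param av_mu1_ms,av_mu_slope_ms Block-1 mean and per-block drift of the
#'   countdown-stopping RT (ms).
#' @param av_sigma1_ms,av_sigma_slope_ms Block-1 SD and per-block drift of
#'   the countdown-stopping RT (ms).
#' @param av_lapse_mix Mixture weight of a slow uniform 600-1000 ms tail on
#'   arousal-vigilance trials.
#' @return A one-row tibble of class `antivea_params`.
#' @export
participant_params <- function(rt_base_ms = 587.5, alerting_ms = 40,
                               orienting_ms = 40, congruency_ms = 43,
                               rt_sigma_ms = 120,
                               err_base = 0.045, err_alerting_delta = 0.024,
                               err_orienting_delta = 0, err_congruency_delta = 0.008,
                               anticipation_rate = 0.02,
                               ev_hit_p1 = 0.78, ev_hit_slope = -0.019,
                               fa_p1 = 0.07, fa_slope = -0.0027,
                               av_mu1_ms = 481, av_mu_slope_ms = 4,
                               av_sigma1_ms = 80, av_sigma_slope_ms = 4,
                               av_lapse_mix = 0) {
  p <- tibble(
    rt_base_ms = rt_base_ms, alerting_ms = alerting_ms,
    orienting_ms = orienting_ms, congruency_ms = congruency_ms,
    rt_sigma_ms = rt_sigma_ms, err_base = err_base,
    err_alerting_delta = err_alerting_delta,
    err_orienting_delta = err_orienting_delta,
    err_congruency_delta = err_congruency_delta,
    anticipation_rate = anticipation_rate,
    ev_hit_p1 = ev_hit_p1, ev_hit_slope = ev_hit_slope,
    fa_p1 = fa_p1, fa_slope = fa_slope,
    av_mu1_ms = av_mu1_ms, av_mu_slope_ms = av_mu_slope_ms,
    av_sigma1_ms = av_sigma1_ms, av_sigma_slope_ms = av_sigma_slope_ms,
    av_lapse_mix = av_lapse_mix
  )
  validate_params(p)
  class(p) <- c("antivea_params", class(p))
  p
}

validate_params <- function(p) {
  probs <- c("err_base", "anticipation_rate", "ev_hit_p1", "fa_p1",
             "av_lapse_mix")
  for (f in probs) {
    if (any(p[[f]] < 0 | p[[f]] > 1)) {
      abort(sprintf("parameter '%s' must be a probability in [0, 1]", f))
    }
  }
  if (any(p$rt_sigma_ms <= 0)) abort("rt_sigma_ms must be positive")
  if (any(p$av_sigma1_ms <= 0)) abort("av_sigma1_ms must be positive")
  invisible(p)
}

#' Population-level (cohort) parameter distributions
#'
#' A cohort is a per-field population mean and SD for
#' [participant_params()]; participants are drawn field-wise from
#' independent truncated normals. The shipped reference presets are
#' calibrated to published normative results; see [cohort_preset()].
#'
#' @param means Named numeric vector of field means (all fields of
#'   [participant_params()]).
#' @param sds Named numeric vector of field SDs (missing fields default
#'   to 0, i.e. no between-person variation).
#' @param preset Optional preset name to store with the cohort.
#' @return A tibble of class `antivea_cohort` with columns `field`, `mean`,
#'   `sd`, `lo`, `hi`.
#' @export
cohort_params <- function(means, sds = numeric(), preset = "custom") {
  ff <- param_fields()
  missing_fields <- setdiff(ff$field, names(means))
  if (length(missing_fields) > 0) {
    abort(paste0("cohort means missing field(s): ",
                 paste(missing_fields, collapse = ", ")))
  }
  if (any(sds < 0, na.rm = TRUE)) abort("cohort SDs must be >= 0")
  sd_vec <- unname(sds[ff$field])
  sd_vec[is.na(sd_vec)] <- 0
  out <- ff |>
    mutate(mean = unname(means[.data$field]), sd = sd_vec) |>
    select("field", "mean", "sd", "lo", "hi")
  structure(out, preset = preset,
            class = c("antivea_cohort", class(out)))
}

# Mean of a normal(mu, sd) truncated to [lo, hi]. The normalizing mass is
# computed in whichever tail keeps precision when both bounds sit far out.
truncnorm_mean <- function(mu, sd, lo, hi) {
  if (sd == 0) return(mu)
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- if (a > 0) {
    pnorm(a, lower.tail = FALSE) - pnorm(b, lower.tail = FALSE)
  } else {
    pnorm(b) - pnorm(a)
  }
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Quantile function of a normal(mu, sd) truncated to [lo, hi], computed in
# whichever tail keeps precision when both bounds sit far from the mean.
qtruncnorm <- function(u, mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- if (a > 0) {
    pa <- pnorm(a, lower.tail = FALSE)
    pb <- pnorm(b, lower.tail = FALSE)
    qnorm(pa + u * (pb - pa), lower.tail = FALSE)
  } else {
    pa <- pnorm(a)
    pb <- pnorm(b)
    qnorm(pa + u * (pb - pa))
  }
  mu + sd * z
}

# Expected cohort mean and slope of the clipped block path
# p_b = clip01(p1 + s (b - 1)) when p1 ~ truncnorm(mu1, sd1, [0, 1]) and
# s ~ normal(mus, sds); midpoint-quantile quadrature on both margins.
clipped_path_moments <- function(mu1, mus, sd1, sds, n_blocks, m = 161L) {
  u <- (seq_len(m) - 0.5) / m
  p1 <- if (sd1 == 0) mu1 else qtruncnorm(u, mu1, sd1, 0, 1)
  s <- if (sds == 0) mus else mus + sds * qnorm(u)
  b <- seq_len(n_blocks) - 1
  xc <- b - mean(b)
  acc_mean <- 0
  acc_slope <- 0
  for (bi in seq_along(b)) {
    pb_mat <- pmin(pmax(outer(p1, s * b[bi], "+"), 0), 1)
    acc_mean <- acc_mean + mean(pb_mat)
    acc_slope <- acc_slope + xc[bi] * mean(pb_mat)
  }
  c(mean = acc_mean / n_blocks, slope = acc_slope / sum(xc^2))
}

# Solve the underlying (block-1 probability, slope) population means so the
# expected *scored* mean and slope of the clipped path equal the targets
# (fractions, fraction per block). Falls back to the closed-form identity
# when there is no between-person variation.
solve_clipped_pair <- function(target_mean, target_slope, sd1, sds,
                               n_blocks) {
  mid <- (n_blocks - 1) / 2
  naive <- c(target_mean - mid * target_slope, target_slope)
  if (sd1 == 0 && sds == 0) return(naive)
  obj <- function(par) {
    mm <- clipped_path_moments(par[1], par[2], sd1, sds, n_blocks)
    (mm[["mean"]] - target_mean)^2 + (mm[["slope"]] - target_slope)^2
  }
  fit <- stats::optim(naive, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  fit$par
}

# Expected cohort-level overall error rate when the per-cell error
# probability clip01(base + deltas) is averaged over the 12 equally
# weighted flanker cells and over the population; fixed-seed Monte Carlo
# so calibration stays deterministic.
expected_overall_errors <- function(mu_base, sd_base, deltas, delta_sds,
                                    n = 40000L) {
  draws <- withr::with_seed(20230101L, {
    list(base = qtruncnorm(runif(n), mu_base, sd_base, 0, 1),
         alert = rnorm(n, deltas[["alerting"]], delta_sds[["alerting"]]),
         orient = rnorm(n, deltas[["orienting"]], delta_sds[["orienting"]]),
         cong = rnorm(n, deltas[["congruency"]], delta_sds[["congruency"]]))
  })
  cells <- tidyr::crossing(tone = c(TRUE, FALSE),
                           cue = c("valid", "invalid", "none"),
                           congruency = c("congruent", "incongruent"))
  acc <- 0
  for (i in seq_len(nrow(cells))) {
    p <- draws$base +
      draws$alert * as.numeric(!cells$tone[i]) +
      (draws$orient / 2) * ((cells$cue[i] == "invalid") -
                              (cells$cue[i] == "valid")) +
      draws$cong * as.numeric(cells$congruency[i] == "incongruent")
    acc <- acc + mean(pmin(pmax(p, 0), 1))
  }
  acc / nrow(cells)
}

# Underlying normal mean whose [lo, hi]-truncated mean equals `target`.
solve_truncnorm_mu <- function(target, sd, lo, hi) {
  if (sd == 0 || (is.infinite(lo) && is.infinite(hi))) return(target)
  f <- function(mu) truncnorm_mean(mu, sd, lo, hi) - target
  uniroot(f, interval = c(target - 10 * sd, target + 10 * sd),
          extendInt = "yes", tol = 1e-10)$root
}

#' Normative index targets for the standard task
#'
#' Published normative means and between-person SDs of the core indexes for
#' university-student samples that completed the standard six-block task,
#' pooled over several studies: an in-lab column (427 participants) and an
#' online column (522 participants). These tables are the calibration
#' inputs for the shipped cohort presets.
#'
#' @param version `"inlab"` or `"online"`.
#' @return A tibble with columns `index`, `mean`, `sd`. RT indexes are in
#'   ms, error/hit/false-alarm/lapse indexes in percent, slopes per block.
#' @export
#' @examples
#' reference_index_targets("inlab")
reference_index_targets <- function(version = c("inlab", "online")) {
  version <- match.arg(version)
  inlab <- tibble::tribble(
    ~index,              ~mean,   ~sd,
    "overall_rt",          629,    98,
    "overall_errors",     6.10,  4.74,
    "alerting_rt",          40,    26,
    "alerting_errors",    2.42,  4.79,
    "orienting_rt",         40,    27,
    "orienting_errors",  -0.07,  3.76,
    "congruency_rt",        43,    27,
    "congruency_errors",  0.81,  4.70,
    "hits",              73.24, 17.34,
    "hits_slope",        -1.89,  3.64,
    "fa",                 6.35,  5.80,
    "fa_slope",          -0.27,  0.94,
    "av_mean_rt",          491,    62,
    "av_mean_rt_slope",      4,    11,
    "av_sd_rt",             90,    39,
    "av_sd_rt_slope",        4,    11,
    "lapses",            11.35, 14.57,
    "lapses_slope",       1.47,  3.32
  )
  online <- tibble::tribble(
    ~index,              ~mean,   ~sd,
    "overall_rt",          652,    98,
    "overall_errors",     5.95,  4.36,
    "alerting_rt",          37,    43,
    "alerting_errors",    1.46,  4.75,
    "orienting_rt",         46,    27,
    "orienting_errors",   0.44,  3.98,
    "congruency_rt",        41,    33,
    "congruency_errors",  0.36,  3.88,
    "hits",              78.87, 14.04,
    "hits_slope",        -1.93,  3.61,
    "fa",                 6.88,  6.02,
    "fa_slope",          -0.23,  1.23,
    "av_mean_rt",          509,    85,
    "av_mean_rt_slope",      5,    14,
    "av_sd_rt",             83,    32,
    "av_sd_rt_slope",        6,    13,
    "lapses",            13.19, 17.53,
    "lapses_slope",       1.67,  3.73
  )
  if (version == "inlab") inlab else online
}

#' Calibrate a cohort preset from an index-target table
#'
#' Solves the identification equations of the generative model so that the
#' expected scored indexes of a simulated cohort equal the targets. With the
#' additive RT structure, overall RT averages the tone (half of trials) and
#' congruency (half) effects while the orienting contributions cancel, so
#' `rt_base = overall_rt - alerting/2 - congruency/2`; block-1 vigilance
#' probabilities are recovered from the index mean and slope via
#' `p1 = mean - 2.5 * slope` (the mean over blocks 1..6 sits at block 3.5);
#' and the lapse mixture weight is solved from the lapse identity
#' `lapses = (1 - mix) * P(normal RT > 600) + mix`, averaged over blocks.
#' For bounded probability fields with a nonzero population SD, the
#' underlying normal mean is solved numerically so that the
#' truncated-population mean still equals the identified value.
#'
#' @param targets A tibble like [reference_index_targets()] (columns
#'   `index`, `mean`, and optionally `sd`).
#' @param rt_sigma_ms Within-person trial RT SD (ms); a free dial of the
#'   simulator, not identified by the published means.
#' @param anticipation_rate Probability of an anticipatory (<200 ms)
#'   response; also a free dial.
#' @param n_blocks Number of blocks the targets refer to (6 for the
#'   standard session).
#' @param noise Jitter setting the targets refer to (2 in the standard
#'   session); fixes the expected fa-difficult fraction, which links the
#'   false-alarm rate to the overall error rate.
#' @param preset Name to store with the cohort.
#' @return An `antivea_cohort` (see [cohort_params()]).
#' @export
#' @examples
#' calibrate_preset(reference_index_targets("inlab"))
calibrate_preset <- function(targets, rt_sigma_ms = 120,
                             anticipation_rate = 0.02,
                             n_blocks = 6, noise = 2,
                             preset = "calibrated") {
  tg <- function(ix) {
    v <- targets$mean[targets$index == ix]
    if (length(v) != 1) abort(sprintf("targets must contain index '%s'", ix))
    v
  }
  tg_sd <- function(ix) {
    if (!"sd" %in% names(targets)) return(0)
    v <- targets$sd[targets$index == ix]
    if (length(v) != 1 || is.na(v)) 0 else v
  }
  mid <- (n_blocks - 1) / 2  # mean block offset: blocks 1..B average at 1+mid

  means <- c(
    rt_base_ms = tg("overall_rt") - tg("alerting_rt") / 2 - tg("congruency_rt") / 2,
    alerting_ms = tg("alerting_rt"),
    orienting_ms = tg("orienting_rt"),
    congruency_ms = tg("congruency_rt"),
    rt_sigma_ms = rt_sigma_ms,
    err_base = (tg("overall_errors") - tg("alerting_errors") / 2 -
                  tg("congruency_errors") / 2) / 100,
    err_alerting_delta = tg("alerting_errors") / 100,
    err_orienting_delta = tg("orienting_errors") / 100,
    err_congruency_delta = tg("congruency_errors") / 100,
    anticipation_rate = anticipation_rate,
    ev_hit_p1 = (tg("hits") - mid * tg("hits_slope")) / 100,
    ev_hit_slope = tg("hits_slope") / 100,
    fa_p1 = (tg("fa") - mid * tg("fa_slope")) / 100,
    fa_slope = tg("fa_slope") / 100,
    av_mu1_ms = tg("av_mean_rt") - mid * tg("av_mean_rt_slope"),
    av_mu_slope_ms = tg("av_mean_rt_slope"),
    av_sigma1_ms = tg("av_sd_rt") - mid * tg("av_sd_rt_slope"),
    av_sigma_slope_ms = tg("av_sd_rt_slope"),
    av_lapse_mix = 0
  )

  # feasibility: block-wise probabilities must stay in [0, 1]
  blocks <- seq_len(n_blocks) - 1
  check_prob_path <- function(p1, slope, ix) {
    p <- p1 + slope * blocks
    if (any(p < 0 | p > 1)) {
      abort(sprintf(
        "calibration infeasible: index '%s' implies a block probability outside [0, 1]",
        ix), class = "antivea_calibration_error")
    }
  }
  check_prob_path(means[["ev_hit_p1"]], means[["ev_hit_slope"]], "hits")
  check_prob_path(means[["fa_p1"]], means[["fa_slope"]], "false alarms")
  if (any(means[["av_sigma1_ms"]] + means[["av_sigma_slope_ms"]] * blocks <= 0)) {
    abort("calibration infeasible: index 'SD RT' implies a non-positive block SD",
          class = "antivea_calibration_error")
  }
  if (means[["err_base"]] < 0 || means[["err_base"]] > 1) {
    abort("calibration infeasible: index 'overall errors' implies err_base outside [0, 1]",
          class = "antivea_calibration_error")
  }

  # lapse identity: lapses = mean_b[(1 - mix) * tail_b] + mix
  mu_b <- means[["av_mu1_ms"]] + means[["av_mu_slope_ms"]] * blocks
  sg_b <- means[["av_sigma1_ms"]] + means[["av_sigma_slope_ms"]] * blocks
  tail_mean <- mean(1 - pnorm((LAPSE_MS - mu_b) / sg_b))
  mix <- (tg("lapses") / 100 - tail_mean) / (1 - tail_mean)
  if (mix > 1) {
    abort("calibration infeasible: index 'lapses' requires a mixture weight > 1",
          class = "antivea_calibration_error")
  }
  if (mix < 0) {
    inform(sprintf(
      "lapse target (%.2f%%) is below the rate the normal RT drift already produces (%.2f%%); av_lapse_mix clamped to 0",
      tg("lapses"), 100 * tail_mean))
    mix <- 0
  }
  means[["av_lapse_mix"]] <- mix

  # between-person SDs: normative SD columns for fields whose scored index
  # is a linear readout of the parameter; AV fields stay homogeneous (see
  # the methods vignette on Jensen inflation of the lapse rate)
  sds <- c(
    rt_base_ms = tg_sd("overall_rt"),
    alerting_ms = tg_sd("alerting_rt"),
    orienting_ms = tg_sd("orienting_rt"),
    congruency_ms = tg_sd("congruency_rt"),
    err_base = tg_sd("overall_errors") / 100,
    err_alerting_delta = tg_sd("alerting_errors") / 100,
    err_orienting_delta = tg_sd("orienting_errors") / 100,
    err_congruency_delta = tg_sd("congruency_errors") / 100,
    ev_hit_p1 = tg_sd("hits") / 100,
    ev_hit_slope = tg_sd("hits_slope") / 100,
    fa_p1 = tg_sd("fa") / 100,
    fa_slope = tg_sd("fa_slope") / 100
  )

  cohort <- cohort_params(means, sds, preset = preset)
  # invert truncation so that the truncated-population mean hits the target
  for (i in seq_len(nrow(cohort))) {
    if (cohort$sd[i] > 0) {
      cohort$mean[i] <- solve_truncnorm_mu(cohort$mean[i], cohort$sd[i],
                                           cohort$lo[i], cohort$hi[i])
    }
  }
  # the block-1-probability/slope pairs feed a *clipped* block path, which
  # attenuates positive slopes near the ceiling (and negative ones at the
  # floor) across the cohort; solve the pair so the expected scored mean
  # and slope still equal the targets
  set_mean <- function(cohort, field, value) {
    cohort$mean[cohort$field == field] <- value
    cohort
  }
  get_sd <- function(field) cohort$sd[cohort$field == field]
  ev <- solve_clipped_pair(tg("hits") / 100, tg("hits_slope") / 100,
                           get_sd("ev_hit_p1"), get_sd("ev_hit_slope"),
                           n_blocks)
  cohort <- set_mean(cohort, "ev_hit_p1", ev[1])
  cohort <- set_mean(cohort, "ev_hit_slope", ev[2])
  fa <- solve_clipped_pair(tg("fa") / 100, tg("fa_slope") / 100,
                           get_sd("fa_p1"), get_sd("fa_slope"), n_blocks)
  cohort <- set_mean(cohort, "fa_p1", fa[1])
  cohort <- set_mean(cohort, "fa_slope", fa[2])
  # per-cell error probabilities clip at 0 for low-error participants,
  # which would inflate the cohort error rate; solve err_base against the
  # cohort expectation
  # spacebar false alarms also score as flanker errors, so the direction
  # errors only need to make up the remainder of the target error rate
  fad <- fa_difficult_fraction(noise)
  dir_err_target <- (tg("overall_errors") / 100 - fad * tg("fa") / 100) /
    (1 - fad * tg("fa") / 100)
  if (dir_err_target < 0) {
    abort("calibration infeasible: index 'overall errors' is below the error mass implied by the false-alarm rate",
          class = "antivea_calibration_error")
  }
  if (get_sd("err_base") > 0) {
    deltas <- c(alerting = means[["err_alerting_delta"]],
                orienting = means[["err_orienting_delta"]],
                congruency = means[["err_congruency_delta"]])
    delta_sds <- c(alerting = get_sd("err_alerting_delta"),
                   orienting = get_sd("err_orienting_delta"),
                   congruency = get_sd("err_congruency_delta"))
    f <- function(mu) {
      expected_overall_errors(mu, get_sd("err_base"), deltas, delta_sds) -
        dir_err_target
    }
    sol <- uniroot(f, interval = c(-0.5, 0.5), extendInt = "upX",
                   tol = 1e-7)
    cohort <- set_mean(cohort, "err_base", sol$root)
  } else {
    cohort <- set_mean(cohort, "err_base",
                       dir_err_target - means[["err_alerting_delta"]] / 2 -
                         means[["err_congruency_delta"]] / 2)
  }
  attr(cohort, "targets") <- targets
  cohort
}

#' Shipped reference cohort presets
#'
#' `"inlab_reference"` and `"online_reference"` are produced by running
#' [calibrate_preset()] on the corresponding column of
#' [reference_index_targets()].
#'
#' @param preset Preset name.
#' @param ... Passed to [calibrate_preset()] (e.g. `rt_sigma_ms`).
#' @return An `antivea_cohort`.
#' @export
#' @examples
#' cohort_preset("inlab_reference")
cohort_preset <- function(preset = c("inlab_reference", "online_reference"),
                          ...) {
  preset <- match.arg(preset)
  version <- if (preset == "inlab_reference") "inlab" else "online"
  calibrate_preset(reference_index_targets(version), preset = preset, ...)
}

#' Draw participants from a cohort
#'
#' Each parameter field is drawn independently from a normal with the
#' cohort's mean and SD, truncated to the field's legal range (inverse-CDF
#' sampling). A zero SD returns the mean exactly.
#'
#' @param cohort An `antivea_cohort`.
#' @param n Number of participants.
#' @param seed Integer seed.
#' @return A tibble with a `participant` id column and one column per
#'   parameter field; rows validate as [participant_params()].
#' @export
sample_participants <- function(cohort, n, seed) {
  stopifnot(inherits(cohort, "antivea_cohort"), n >= 1)
  draws <- withr::with_seed(as.integer(seed), {
    purrr::pmap(list(cohort$mean, cohort$sd, cohort$lo, cohort$hi),
                function(mu, sd, lo, hi) {
                  if (sd == 0) return(rep(mu, n))
                  qtruncnorm(runif(n), mu, sd, lo, hi)
                })
  })
  names(draws) <- cohort$field
  out <- bind_cols(tibble(participant = sprintf("P%04d", seq_len(n))),
                   as_tibble(draws))
  validate_params(out)
  out
}

# Additive cell mean (ms) for flanker-type trials.
anti_cell_mean <- function(p, tone, cue, congruency) {
  p$rt_base_ms +
    p$alerting_ms * as.numeric(!tone) +
    (p$orienting_ms / 2) * ((cue == "invalid") - (cue == "valid")) +
    p$congruency_ms * as.numeric(congruency == "incongruent")
}

# Shifted-lognormal RT draws with mean m and SD s above a 200 ms shift.
rt_shifted_lognormal <- function(n, m, s) {
  m0 <- m - 200
  if (any(m0 <= 0)) {
    abort("ANTI cell mean RT must exceed the 200 ms lognormal shift")
  }
  sdlog <- sqrt(log1p((s / m0)^2))
  meanlog <- log(m0) - sdlog^2 / 2
  200 + rlnorm(n, meanlog, sdlog)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate one participant's raw session
#'
#' Generates one raw trial record per scheduled trial under the generative
#' model: flanker (ANTI) RTs follow a 200 ms shifted lognormal around the
#' additive cell mean with SD `rt_sigma_ms`; direction errors, anticipations
#' (< 200 ms), and spacebar false alarms on fa-difficult trials occur with
#' their respective probabilities; executive-vigilance hits follow the
#' block-linear hit probability; arousal-vigilance RTs are block-linear
#' normal mixed with a slow 600-1000 ms tail, and draws reaching 1000 ms
#' become omissions (the countdown expires).
#'
#' @param params One row of generative parameters ([participant_params()] or
#'   a row of [sample_participants()]).
#' @param schedule An `antivea_schedule` from [build_session()].
#' @param seed Integer seed.
#' @param subject_id System-style unique subject identifier.
#' @param session_number Session counter for the subject.
#' @param session_date Timestamp string `"yyyy-mm-dd hh:mm:ss"`.
#' @return A tibble of raw trial records in the package's CSV dialect (see
#'   [trial_codebook()]).
#' @export
simulate_session <- function(params, schedule, seed,
                             subject_id = "S00001",
                             session_number = 1L,
                             session_date = "2023-01-01 12:00:00") {
  stopifnot(inherits(schedule, "antivea_schedule"))
  p <- as.list(as_tibble(params)[1, ])
  validate_params(as_tibble(p[param_fields()$field]))
  config <- attr(schedule, "config")
  n <- nrow(schedule)
  if (n == 0) abort("schedule contains no trials: nothing to simulate")

  has_ev_detection <- any(schedule$kind == "EV" &
                            schedule$expected_response == "spacebar")
  if (any(schedule$kind == "EV" & schedule$expected_response == "spacebar") &&
      is.na(p$ev_hit_p1)) {
    abort("EV trials present but EV parameters absent")
  }
  if (any(schedule$kind == "AV" & schedule$expected_response == "any_key") &&
      is.na(p$av_mu1_ms)) {
    abort("AV trials present but AV parameters absent")
  }

  rt <- rep(NA_real_, n)
  resp <- rep("none", n)
  correct <- rep(NA, n)
  rating <- rep(NA_real_, n)
  blk <- schedule$block

  withr::with_seed(as.integer(seed), {
    ## flanker-type stimuli (ANTI; EV shares the draw machinery)
    ia <- which(schedule$kind == "ANTI")
    if (length(ia) > 0) {
      m <- anti_cell_mean(p, schedule$tone[ia], schedule$cue[ia],
                          schedule$congruency[ia])
      rt_a <- rt_shifted_lognormal(length(ia), m, p$rt_sigma_ms)
      perr <- clip01(
        p$err_base +
          p$err_alerting_delta * as.numeric(!schedule$tone[ia]) +
          (p$err_orienting_delta / 2) *
            ((schedule$cue[ia] == "invalid") - (schedule$cue[ia] == "valid")) +
          p$err_congruency_delta *
            as.numeric(schedule$congruency[ia] == "incongruent"))
      ok <- runif(length(ia)) >= perr
      anticipate <- runif(length(ia)) < p$anticipation_rate
      rt_a[anticipate] <- runif(sum(anticipate), 80, 199)
      # spacebar false alarms only arise where the displacement is plausible
      fa_p_b <- clip01(p$fa_p1 + p$fa_slope * (blk[ia] - 1))
      fa <- has_ev_detection &
        !is.na(schedule$fa_difficult[ia]) & schedule$fa_difficult[ia] &
        runif(length(ia)) < fa_p_b
      expd <- schedule$expected_response[ia]
      dir_ok <- ifelse(schedule$target_direction[ia] == "left",
                       "direction_left", "direction_right")
      dir_bad <- ifelse(schedule$target_direction[ia] == "left",
                        "direction_right", "direction_left")
      r <- rep("none", length(ia))
      cc <- rep(NA, length(ia))
      r[expd == "direction_key"] <- ifelse(ok, dir_ok, dir_bad)[expd == "direction_key"]
      cc[expd == "direction_key"] <- ok[expd == "direction_key"]
      r[expd == "any_key"] <- "any_key"
      cc[expd == "any_key"] <- TRUE
      r[fa] <- "spacebar"
      cc[fa] <- FALSE
      rt[ia] <- rt_a
      rt[ia][r == "none"] <- NA_real_
      resp[ia] <- r
      correct[ia] <- cc
    }

    ## executive-vigilance trials
    ie <- which(schedule$kind == "EV")
    if (length(ie) > 0) {
      m <- anti_cell_mean(p, schedule$tone[ie], schedule$cue[ie],
                          schedule$congruency[ie]) + 50
      rt_e <- rt_shifted_lognormal(length(ie), m, p$rt_sigma_ms)
      expd <- schedule$expected_response[ie]
      hit_p <- clip01(p$ev_hit_p1 + p$ev_hit_slope * (blk[ie] - 1))
      hit <- runif(length(ie)) < hit_p
      r <- rep("none", length(ie))
      cc <- rep(NA, length(ie))
      r[expd == "spacebar" & hit] <- "spacebar"
      cc[expd == "spacebar"] <- hit[expd == "spacebar"]
      rt[ie] <- ifelse(r == "spacebar", rt_e, NA_real_)
      resp[ie] <- r
      correct[ie] <- cc
    }

    ## arousal-vigilance trials (stop the countdown)
    iv <- which(schedule$kind == "AV" &
                  schedule$expected_response == "any_key")
    if (length(iv) > 0) {
      mu_b <- p$av_mu1_ms + p$av_mu_slope_ms * (blk[iv] - 1)
      sg_b <- pmax(p$av_sigma1_ms + p$av_sigma_slope_ms * (blk[iv] - 1), 1)
      slow <- runif(length(iv)) < p$av_lapse_mix
      rt_v <- rnorm(length(iv), mu_b, sg_b)
      rt_v[slow] <- runif(sum(slow), LAPSE_MS, 1000)
      rt_v <- pmax(rt_v, 1)
      expired <- rt_v >= 1000
      rt[iv] <- ifelse(expired, NA_real_, rt_v)
      resp[iv] <- ifelse(expired, "none", "any_key")
    }

    ## thought probes (placeholder rating model)
    it <- which(schedule$kind == "TP")
    if (length(it) > 0) {
      rating[it] <- runif(length(it), -1, 1)
      rt[it] <- runif(length(it), 800, 4000)
      resp[it] <- "probe_value"
    }
  })

  bind_cols(
    tibble(
      subject_id = subject_id,
      session_number = as.integer(session_number),
      session_date = session_date,
      participant_code = config$participant_code,
      experiment = config$experiment,
      group = config$group,
      task_type = config$task_type,
      noise = config$noise,
      difficulty = config$difficulty,
      target_duration_ms = config$target_duration_ms,
      n_blocks = config$n_blocks,
      probes_per_block = config$probes_per_block
    ),
    as_tibble(schedule),
    tibble(response_class = resp, rt_ms = rt, correct = correct,
           screen_full = TRUE, probe_rating = rating)
  )
}

#' Simulate a cohort of raw sessions
#'
#' Draws `n` participants from a cohort, builds each one an independent
#' seeded schedule for `config`, and simulates their raw sessions. The
#' returned ground-truth parameter table is the oracle for
#' parameter-recovery tests of the scoring chain.
#'
#' @param cohort An `antivea_cohort` (e.g. [cohort_preset()]).
#' @param config A [task_config()].
#' @param n Number of participants.
#' @param seed Integer master seed; participant draws, schedules, and
#'   sessions all derive from it.
#' @return A list of class `antivea_cohort_sim` with elements `trials`
#'   (all raw trial records), `participants` (ground-truth parameters),
#'   `config`, and `seed`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_cohort(cohort_preset("inlab_reference"),
#'                        task_config(participant_code = "1234", n_blocks = 2),
#'                        n = 5, seed = 42)
#' dplyr::count(sim$trials, kind)
#' }
simulate_cohort <- function(cohort, config, n, seed) {
  if (config$n_blocks == 0 && !config$do_practice) {
    abort("nothing to simulate: 0 experimental blocks and no practice")
  }
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, 2L * n + 1L))
  participants <- sample_participants(cohort, n, seed = seeds[1])
  base_time <- as.POSIXct("2023-01-01 09:00:00", tz = "UTC")
  sessions <- purrr::map(seq_len(n), function(i) {
    # each participant enters their own digit code on the platform
    cfg_i <- config
    cfg_i$participant_code <- paste0(config$participant_code,
                                     sprintf("%03d", i))
    sched <- build_session(cfg_i, seed = seeds[1L + i])
    simulate_session(participants[i, -1], sched, seed = seeds[1L + n + i],
                     subject_id = sprintf("S%05d", i),
                     session_date = format(base_time + (i - 1) * 3600,
                                           "%Y-%m-%d %H:%M:%S"))
  })
  structure(
    list(trials = bind_rows(sessions), participants = participants,
         config = config, seed = as.integer(seed)),
    class = "antivea_cohort_sim"
  )
}

#' @export
print.antivea_cohort_sim <- function(x, ...) {
  cat(sprintf("<antivea_cohort_sim> %d participants, %d trial records (task %s, seed %d)\n",
              nrow(x$participants), nrow(x$trials), x$config$task_type, x$seed))
  invisible(x)
}
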