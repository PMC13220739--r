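#' Default anthropometry parameters
#'
#' Per-sex means and standard deviations of log-BMI and log-WC, the
#' log-scale BMI-WC correlation, and the height distribution.  The
#' log-normal parameters are quantile-matched so that the implied WHO BMI
#' and WC class frequencies reproduce the source cohort's baseline
#' distribution; the log-scale correlation of 0.872 is calibrated so that
#' the *pooled* (both-sex) Pearson correlation between BMI and WC is 0.81
#' (pooling attenuates the within-sex correlation because men and women
#' differ in mean WC).
#'
#' @return Nested list with components `men`, `women` (each with
#'   `log_bmi`, `log_wc`, `height` as `c(mean, sd)`) and `rho`.
#' @export
default_anthro_params <- function() {
  list(
    men = list(log_bmi = c(mean = 3.292487, sd = 0.110680),
               log_wc  = c(mean = 4.601324, sd = 0.092402),
               height  = c(mean = 1.77, sd = 0.065)),
    women = list(log_bmi = c(mean = 3.281900, sd = 0.153818),
                 log_wc  = c(mean = 4.509812, sd = 0.120766),
                 height  = c(mean = 1.65, sd = 0.060)),
    rho = 0.872
  )
}

#' Default covariate and biomarker generating distributions
#'
#' Per-sex category probabilities and score distributions emulating the
#' baseline table of a Dutch population cohort aged 50+.  Biomarker
#' parameters are set so the comorbidity classifiers reproduce the
#' baseline prevalences of hypertension, diabetes, hypercholesterolaemia
#' and low HDL approximately.
#'
#' @return Nested list keyed by sex.
#' @export
default_covariate_mixture <- function() {
  list(
    men = list(
      household_with_others = 0.933,
      education = c(low = 0.109, medium = 0.636, high = 0.255),
      pa_index = c(inactive = 0.142, moderately_inactive = 0.290,
                   moderately_active = 0.259, active = 0.309),
      dhd15 = c(mean = 64.0, sd = 13.0),
      smoking = c(never = 0.228, current = 0.236, former = 0.536),
      cigs_per_day = c(meanlog = log(15), sdlog = 0.55),
      alcohol = c(none = 0.087, occasional = 0.132, low = 0.033,
                  moderate = 0.441, high = 0.307),
      copd = 0.160,
      sbp = c(mean = 136, sd = 19), dbp = c(mean = 83, sd = 10),
      on_htn_meds = 0.142,
      glucose = c(meanlog = log(5.6), sdlog = 0.22),
      self_report_diabetes = 0.045,
      tc = c(mean = 5.75, sd = 0.95), hdl = c(mean = 1.25, sd = 0.21),
      on_lipid_meds = 0.013
    ),
    women = list(
      household_with_others = 0.850,
      education = c(low = 0.128, medium = 0.712, high = 0.160),
      pa_index = c(inactive = 0.119, moderately_inactive = 0.313,
                   moderately_active = 0.296, active = 0.272),
      dhd15 = c(mean = 70.1, sd = 13.0),
      smoking = c(never = 0.452, current = 0.216, former = 0.332),
      cigs_per_day = c(meanlog = log(12), sdlog = 0.55),
      alcohol = c(none = 0.197, occasional = 0.233, low = 0.072,
                  moderate = 0.230, high = 0.268),
      copd = 0.162,
      sbp = c(mean = 133, sd = 20), dbp = c(mean = 81, sd = 10),
      on_htn_meds = 0.175,
      glucose = c(meanlog = log(5.4), sdlog = 0.22),
      self_report_diabetes = 0.032,
      tc = c(mean = 6.1, sd = 1.0), hdl = c(mean = 1.48, sd = 0.11),
      on_lipid_meds = 0.015
    )
  )
}

#' Default Gompertz baseline hazards
#'
#' Reference-category (low adiposity) cause-specific hazards at age 50
#' (`rate50`, events/year) and age slopes (`shape`, 1/year) for the three
#' transitions: `h12` disease-free to CVD, `h13` disease-free to death,
#' `h23` CVD to death.  Calibrated by simulation so a cohort of ~2,323
#' (49% women, entry ages 50-70) followed 22 years yields about 695
#' incident CVD events and 587 deaths under the default hazard ratios.
#'
#' @return Nested list keyed by sex, then transition.
#' @export
default_baseline_hazards <- function() {
  list(
    men = list(h12 = c(rate50 = 0.0040, shape = 0.070),
               h13 = c(rate50 = 0.0008, shape = 0.098),
               h23 = c(rate50 = 0.0045, shape = 0.087)),
    women = list(h12 = c(rate50 = 0.0032, shape = 0.070),
                 h13 = c(rate50 = 0.00072, shape = 0.100),
                 h23 = c(rate50 = 0.0040, shape = 0.087))
  )
}

#' Default true log hazard ratios
#'
#' Per-sex, per-transition log hazard ratios for the composite adiposity
#' categories (reference `low` fixed at 0).  Defaults are the published
#' adjusted estimates for this cohort, so that parameter-recovery
#' experiments target realistic effect sizes.
#'
#' @return Nested list keyed by sex, then transition; each element a named
#'   numeric vector over [adiposity_levels()].
#' @export
default_true_log_hr <- function() {
  lhr <- function(...) {
    v <- log(c(1, ...))
    names(v) <- adiposity_levels()
    v
  }
  list(
    men = list(h12 = lhr(1.07, 1.14, 1.66),
               h13 = lhr(0.90, 1.23, 1.25),
               h23 = lhr(1.21, 1.45, 1.84)),
    women = list(h12 = lhr(0.77, 1.03, 1.02),
                 h13 = lhr(1.13, 1.30, 0.98),
                 h23 = lhr(0.69, 0.91, 0.81))
  )
}

#' Synthetic cohort configuration
#'
#' Assembles and validates the configuration for [generate_cohort()].
#' `n_participants` is the target number of *eligible* participants;
#' `exclusion_counts` extra participants are appended with eligibility
#' flags set (mutually exclusive, so eligible = roster - sum(counts)).
#'
#' @param n_participants Number of eligible participants.
#' @param fraction_women Proportion of women.
#' @param age_range_at_entry Numeric length 2, entry-age bounds in years.
#' @param entry_band_weights Probabilities of entry in ages 50-59, 60-69,
#'   and 70+ (uniform within band, capped at the range maximum).
#' @param n_waves Number of measurement waves per participant.
#' @param wave_spacing Years between waves.
#' @param anthro_params See [default_anthro_params()].
#' @param anthro_walk Per-year drift and innovation SD of the log-scale
#'   random walk that evolves BMI and WC between waves.
#' @param covariate_mixture See [default_covariate_mixture()].
#' @param baseline_hazards See [default_baseline_hazards()].
#' @param true_log_hr See [default_true_log_hr()].
#' @param covariate_log_hr Log hazard ratio per unit of the standardized
#'   lifestyle risk score (smoking + inactivity), applied to all
#'   transitions; 0 disables covariate effects on the hazards.
#' @param confounding Correlation-style knob in `[0, 1)` tying the latent
#'   adiposity propensity to the lifestyle risk score; 0 generates
#'   exposure independent of covariates.
#' @param exclusion_counts Named integer counts of flagged extras:
#'   `cancer_history`, `cancer_unknown`, `pregnant` (women only).
#' @param missing_anthro Named per-sex probabilities that a participant
#'   has no valid anthropometry at any wave (complete-case removal).
#' @param admin_censoring Administrative censoring, years after entry.
#' @param seed Integer root seed.
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_participants = 2323,
                          fraction_women = 0.498,
                          age_range_at_entry = c(50, 72),
                          entry_band_weights = c(0.593, 0.392, 0.015),
                          n_waves = 5,
                          wave_spacing = 5,
                          anthro_params = default_anthro_params(),
                          anthro_walk = c(drift = 0.0015, sd = 0.010),
                          covariate_mixture = default_covariate_mixture(),
                          baseline_hazards = default_baseline_hazards(),
                          true_log_hr = default_true_log_hr(),
                          covariate_log_hr = 0,
                          confounding = 0,
                          exclusion_counts = c(cancer_history = 114,
                                               cancer_unknown = 128,
                                               pregnant = 1),
                          missing_anthro = c(men = 0, women = 0),
                          admin_censoring = 22,
                          seed = 1L) {
  stopifnot(n_participants >= 1,
            fraction_women >= 0, fraction_women <= 1,
            length(age_range_at_entry) == 2,
            age_range_at_entry[1] < age_range_at_entry[2],
            n_waves >= 1, wave_spacing > 0,
            abs(anthro_params$rho) <= 1,
            all(unlist(exclusion_counts) >= 0),
            all(missing_anthro >= 0 & missing_anthro <= 1),
            confounding >= 0, confounding < 1,
            admin_censoring > 0)
  for (sx in c("men", "women")) {
    for (tr in c("h12", "h13", "h23")) {
      h <- baseline_hazards[[sx]][[tr]]
      stopifnot(h["rate50"] >= 0, is.finite(h["shape"]))
      stopifnot(true_log_hr[[sx]][[tr]][1] == 0)
    }
    stopifnot(anthro_params[[sx]]$log_bmi["sd"] > 0,
              anthro_params[[sx]]$log_wc["sd"] > 0)
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Sample a Gompertz event time by inversion
#'
#' Inverts the Gompertz survival function
#' `S(t) = exp(-(lambda/gamma) (exp(gamma t) - 1))` at `u`.  For
#' `gamma < 0` the distribution is defective; draws beyond its mass (and
#' any draw when `lambda = 0`) return `Inf` (no event ever).
#'
#' @param lambda Rate at the reference age (events/year), `>= 0`.
#' @param gamma Age slope (1/year).
#' @param u Uniform(0,1) survival draw(s).
#' @return Event time(s) in years from the reference age.
#' @export
sample_gompertz_time <- function(lambda, gamma, u) {
  if (any(u <= 0 | u >= 1)) stop("u must be in (0, 1)", call. = FALSE)
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  n <- max(length(lambda), length(gamma), length(u))
  lambda <- rep_len(lambda, n); gamma <- rep_len(gamma, n); u <- rep_len(u, n)
  t <- numeric(n)
  z <- lambda == 0
  t[z] <- Inf
  g0 <- !z & abs(gamma) < 1e-12
  t[g0] <- -log(u[g0]) / lambda[g0]
  g <- !z & !g0
  arg <- 1 - gamma[g] * log(u[g]) / lambda[g]
  t[g] <- ifelse(arg > 0, log(arg) / gamma[g], Inf)
  t
}

# Cumulative Gompertz hazard of rate m*lambda*exp(shape*(x - 50)) over
# [a, b) in attained age.
gompertz_cumhaz <- function(lambda, shape, m, a, b) {
  out <- numeric(length(a))
  g0 <- abs(shape) < 1e-12
  out[g0] <- (m * lambda)[g0] * (b - a)[g0]
  gg <- !g0
  out[gg] <- (m * lambda / shape * (exp(shape * (b - 50)) -
                                    exp(shape * (a - 50))))[gg]
  out
}

# Age at which the cumulative hazard from age a reaches e_rem (assumes the
# interval-level cumulative hazard already exceeds e_rem).
gompertz_invert <- function(lambda, shape, m, a, e_rem) {
  g0 <- abs(shape) < 1e-12
  out <- numeric(length(a))
  out[g0] <- a[g0] + (e_rem / (m * lambda))[g0]
  gg <- !g0
  out[gg] <- 50 + log(exp(shape * (a - 50)) +
                      (shape * e_rem / (m * lambda)))[gg] / shape[gg]
  out
}

# Vectorised competing/sequential event simulation over piecewise-constant
# category multipliers. `bounds` is an (n x K+1) matrix of age cuts per
# participant (entry ... censor); `logm12/13/23` are (n x K) log hazard
# multipliers in force on each interval. Returns age_cvd, age_death.
simulate_events_piecewise <- function(bounds, logm12, logm13, logm23,
                                      haz, e12, e13, e23) {
  n <- nrow(bounds); K <- ncol(logm12)
  age_cvd <- rep(NA_real_, n); age_death <- rep(NA_real_, n)
  alive_healthy <- rep(TRUE, n)
  r12 <- haz$h12["rate50"]; s12 <- haz$h12["shape"]
  r13 <- haz$h13["rate50"]; s13 <- haz$h13["shape"]
  r23 <- haz$h23["rate50"]; s23 <- haz$h23["shape"]
  for (k in seq_len(K)) {
    idx <- which(alive_healthy)
    if (!length(idx)) break
    a <- bounds[idx, k]; b <- bounds[idx, k + 1]
    m12 <- exp(logm12[idx, k]); m13 <- exp(logm13[idx, k])
    H12 <- gompertz_cumhaz(r12, s12, m12, a, b)
    H13 <- gompertz_cumhaz(r13, s13, m13, a, b)
    hit12 <- e12[idx] <= H12
    hit13 <- e13[idx] <= H13
    t12 <- rep(Inf, length(idx)); t13 <- rep(Inf, length(idx))
    if (any(hit12))
      t12[hit12] <- gompertz_invert(r12, s12, m12[hit12], a[hit12],
                                    e12[idx][hit12])
    if (any(hit13))
      t13[hit13] <- gompertz_invert(r13, s13, m13[hit13], a[hit13],
                                    e13[idx][hit13])
    cvd_first <- hit12 & t12 <= t13
    death_first <- hit13 & t13 < t12
    age_cvd[idx[cvd_first]] <- t12[cvd_first]
    age_death[idx[death_first]] <- t13[death_first]
    alive_healthy[idx[cvd_first | death_first]] <- FALSE
    surv <- !(cvd_first | death_first)
    e12[idx[surv]] <- e12[idx][surv] - H12[surv]
    e13[idx[surv]] <- e13[idx][surv] - H13[surv]
  }
  # post-CVD mortality, restarted on the attained-age clock at diagnosis
  has_cvd <- which(!is.na(age_cvd))
  if (length(has_cvd)) {
    e <- e23[has_cvd]
    pos <- rep(NA_real_, length(has_cvd))
    for (k in seq_len(K)) {
      a0 <- pmax(bounds[has_cvd, k], age_cvd[has_cvd])
      b0 <- bounds[has_cvd, k + 1]
      act <- which(is.na(pos) & b0 > a0)
      if (!length(act)) next
      m <- exp(logm23[has_cvd, k])[act]
      H <- gompertz_cumhaz(r23, s23, m, a0[act], b0[act])
      hit <- e[act] <= H
      if (any(hit))
        pos[act[hit]] <- gompertz_invert(r23, s23, m[hit], a0[act][hit],
                                         e[act][hit])
      e[act[!hit]] <- e[act][!hit] - H[!hit]
    }
    age_death[has_cvd] <- pos
  }
  list(age_cvd = age_cvd, age_death = age_death)
}

#' Simulate one participant's event history
#'
#' Competing first event from the disease-free state (incident CVD vs
#' death), then, if CVD occurs first, death from the post-CVD hazard on the
#' attained-age (Markov) clock.  Category hazards are baseline x
#' `exp(true_log_hr)`; administrative censoring is applied; by construction
#' no backflow is possible.
#'
#' @param entry_age Entry age in years (within the configured range).
#' @param exposure_category A single category in [adiposity_levels()]
#'   (held constant), or a data.frame with columns `age`, `category`
#'   giving a piecewise-constant exposure path from entry.
#' @param sex `"men"` or `"women"`.
#' @param config A [cohort_config()].
#' @param u Optional named list of uniform draws `u12`, `u13`, `u23` (one
#'   each); drawn from the session RNG when omitted.
#' @return List with `age_cvd`, `age_death` (NA when unobserved) and
#'   `age_censor`.
#' @export
simulate_event_history <- function(entry_age, exposure_category, sex, config,
                                   u = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  sex <- check_sex(sex, 1L)
  if (entry_age < config$age_range_at_entry[1] ||
      entry_age > config$age_range_at_entry[2])
    stop("entry_age outside configured range", call. = FALSE)
  if (is.data.frame(exposure_category)) {
    path_age <- exposure_category$age
    path_cat <- as.character(exposure_category$category)
  } else {
    path_age <- entry_age
    path_cat <- as.character(exposure_category)
  }
  if (!all(path_cat %in% adiposity_levels()))
    stop("unknown exposure category", call. = FALSE)
  censor <- entry_age + config$admin_censoring
  cuts <- sort(unique(c(entry_age, path_age[path_age > entry_age &
                                            path_age < censor], censor)))
  K <- length(cuts) - 1L
  cat_at <- function(a) path_cat[findInterval(a, path_age)]
  cats <- vapply(cuts[-length(cuts)], cat_at, "")
  lhr <- config$true_log_hr[[sex]]
  mk <- function(tr) matrix(lhr[[tr]][cats], nrow = 1)
  if (is.null(u)) u <- list(u12 = runif(1), u13 = runif(1), u23 = runif(1))
  ev <- simulate_events_piecewise(
    bounds = matrix(cuts, nrow = 1),
    logm12 = mk("h12"), logm13 = mk("h13"), logm23 = mk("h23"),
    haz = config$baseline_hazards[[sex]],
    e12 = -log(u$u12), e13 = -log(u$u13), e23 = -log(u$u23))
  list(age_cvd = ev$age_cvd, age_death = ev$age_death, age_censor = censor)
}

#' Generate anthropometry
#'
#' Bivariate log-normal (BMI, WC) with a Gaussian copula on the log scale;
#' height drawn separately per sex and weight back-solved from BMI, so BMI
#' is exactly `weight/height^2`.
#'
#' @param n Number of draws.
#' @param sex `"men"` or `"women"`.
#' @param anthro_params See [default_anthro_params()].
#' @param z Optional n x 2 matrix of standard-normal scores to use for
#'   (log-BMI, log-WC); drawn internally when omitted.
#' @return Data frame with `height` (m), `weight` (kg), `wc` (cm), `bmi`.
#' @export
generate_anthropometry <- function(n, sex, anthro_params = default_anthro_params(),
                                   z = NULL) {
  stopifnot(n >= 1)
  sex <- match.arg(sex, c("men", "women"))
  p <- anthro_params[[sex]]
  rho <- anthro_params$rho
  if (abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  if (p$log_bmi["sd"] <= 0 || p$log_wc["sd"] <= 0)
    stop("log-scale SDs must be positive", call. = FALSE)
  if (is.null(z)) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  } else {
    z1 <- z[, 1]; z2 <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  }
  bmi <- exp(p$log_bmi["mean"] + p$log_bmi["sd"] * z1)
  wc <- exp(p$log_wc["mean"] + p$log_wc["sd"] * z2)
  height <- stats::rnorm(n, p$height["mean"], p$height["sd"])
  height <- pmin(pmax(height, 1.3), 2.2)
  data.frame(height = height, weight = bmi * height^2, wc = wc, bmi = bmi)
}

sample_cat <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

generate_covariates <- function(n, sex, mix) {
  p <- mix[[sex]]
  household <- factor(ifelse(stats::runif(n) < p$household_with_others,
                             "with_others", "alone"),
                      levels = c("with_others", "alone"))
  smoking <- sample_cat(n, p$smoking)
  cigs <- rep(NA_real_, n)
  cur <- smoking == "current"
  cigs[cur] <- pmin(pmax(round(stats::rlnorm(sum(cur), p$cigs_per_day["meanlog"],
                                             p$cigs_per_day["sdlog"])), 1), 60)
  data.frame(
    household = household,
    education = sample_cat(n, p$education),
    pa_index = sample_cat(n, p$pa_index),
    dhd15 = pmin(pmax(stats::rnorm(n, p$dhd15["mean"], p$dhd15["sd"]), 1), 130),
    smoking = smoking,
    cigs_per_day = cigs,
    alcohol = sample_cat(n, p$alcohol),
    copd = stats::runif(n) < p$copd,
    sbp = stats::rnorm(n, p$sbp["mean"], p$sbp["sd"]),
    dbp = stats::rnorm(n, p$dbp["mean"], p$dbp["sd"]),
    on_htn_meds = stats::runif(n) < p$on_htn_meds,
    glucose = stats::rlnorm(n, p$glucose["meanlog"], p$glucose["sdlog"]),
    self_report_diabetes = stats::runif(n) < p$self_report_diabetes,
    tc = stats::rnorm(n, p$tc["mean"], p$tc["sd"]),
    hdl = pmax(stats::rnorm(n, p$hdl["mean"], p$hdl["sd"]), 0.4),
    on_lipid_meds = stats::runif(n) < p$on_lipid_meds
  )
}

# Standardized lifestyle risk score: linear in the smoking and physical
# activity dummies, so a model adjusting for those factors is correctly
# specified when the score enters the hazard.
risk_score <- function(cov) {
  s <- 1.0 * (cov$smoking == "current") + 0.4 * (cov$smoking == "former") +
    1.0 * (cov$pa_index == "inactive") +
    0.6 * (cov$pa_index == "moderately_inactive") +
    0.3 * (cov$pa_index == "moderately_active")
  (s - 1.05) / 0.65
}

#' Generate a synthetic longitudinal cohort
#'
#' Produces a roster of participants (baseline covariates, biomarkers,
#' eligibility flags), a long wave table of repeated anthropometry, and an
#' event table from the configured Gompertz illness-death hazards.  The
#' per-wave anthropometry evolves by a small correlated random walk on the
#' log scale, and the event hazards follow the participant's
#' *current* (wave-updated) composite adiposity category, so
#' last-observation-carried-forward exposure in downstream person-time is
#' exact.  Extra participants carrying the eligibility-exclusion flags are
#' appended so [apply_eligibility()] has work to do.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed` when given.
#' @return Object of class `synthetic_cohort`: list with data frames
#'   `participants`, `waves`, `events`, plus the `config` used.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  n_extra <- sum(config$exclusion_counts)
  N <- config$n_participants + n_extra
  sex <- ifelse(stats::runif(N) < config$fraction_women, "women", "men")
  # entry ages: banded mixture, uniform within band
  lo <- config$age_range_at_entry[1]; hi <- config$age_range_at_entry[2]
  band <- sample.int(3, N, replace = TRUE, prob = config$entry_band_weights)
  b_lo <- c(50, 60, 70)[band]
  b_hi <- pmin(c(60, 70, hi)[band], hi)
  entry_age <- b_lo + stats::runif(N) * (b_hi - b_lo)
  entry_age <- pmin(pmax(entry_age, lo), hi)

  cov <- rbind(generate_covariates(sum(sex == "men"), "men",
                                   config$covariate_mixture),
               generate_covariates(sum(sex == "women"), "women",
                                   config$covariate_mixture))
  ord <- order(c(which(sex == "men"), which(sex == "women")))
  cov <- cov[ord, , drop = FALSE]
  rownames(cov) <- NULL
  score <- risk_score(cov)

  # baseline latent scores, optionally tied to the lifestyle score
  cf <- config$confounding
  zb <- cf * score + sqrt(1 - cf^2) * stats::rnorm(N)
  zw <- stats::rnorm(N)
  W <- config$n_waves; sp <- config$wave_spacing
  ap <- config$anthro_params
  # per-wave log-scale paths
  log_bmi <- matrix(NA_real_, N, W); log_wc <- matrix(NA_real_, N, W)
  rho <- ap$rho
  z2 <- rho * zb + sqrt(1 - rho^2) * zw
  for (sx in c("men", "women")) {
    i <- sex == sx
    log_bmi[i, 1] <- ap[[sx]]$log_bmi["mean"] + ap[[sx]]$log_bmi["sd"] * zb[i]
    log_wc[i, 1] <- ap[[sx]]$log_wc["mean"] + ap[[sx]]$log_wc["sd"] * z2[i]
  }
  drift <- config$anthro_walk["drift"] * sp
  wsd <- config$anthro_walk["sd"] * sqrt(sp)
  if (W > 1) for (k in 2:W) {
    db <- stats::rnorm(N); dw <- rho * db + sqrt(1 - rho^2) * stats::rnorm(N)
    log_bmi[, k] <- log_bmi[, k - 1] + drift + wsd * db
    log_wc[, k] <- log_wc[, k - 1] + drift + wsd * dw
  }
  height <- numeric(N)
  for (sx in c("men", "women")) {
    i <- sex == sx
    height[i] <- stats::rnorm(sum(i), ap[[sx]]$height["mean"],
                              ap[[sx]]$height["sd"])
  }
  height <- pmin(pmax(height, 1.3), 2.2)

  wave_age <- outer(entry_age, (seq_len(W) - 1) * sp, "+")
  # true category path per wave (composite mapping on true anthropometry)
  cats <- matrix("", N, W)
  for (k in seq_len(W)) {
    bc <- classify_bmi(exp(log_bmi[, k]))
    wcc <- classify_wc(exp(log_wc[, k]), sex)
    cats[, k] <- as.character(classify_adiposity(bc, wcc))
  }

  censor <- entry_age + config$admin_censoring
  bounds <- cbind(wave_age, censor)
  lhr <- config$true_log_hr
  lm12 <- matrix(0, N, W); lm13 <- matrix(0, N, W); lm23 <- matrix(0, N, W)
  bscore <- config$covariate_log_hr * score
  for (sx in c("men", "women")) {
    i <- sex == sx
    lm12[i, ] <- matrix(lhr[[sx]]$h12[cats[i, ]], sum(i), W) + bscore[i]
    lm13[i, ] <- matrix(lhr[[sx]]$h13[cats[i, ]], sum(i), W) + bscore[i]
    lm23[i, ] <- matrix(lhr[[sx]]$h23[cats[i, ]], sum(i), W) + bscore[i]
  }
  e12 <- stats::rexp(N); e13 <- stats::rexp(N); e23 <- stats::rexp(N)
  ev <- list(age_cvd = rep(NA_real_, N), age_death = rep(NA_real_, N))
  for (sx in c("men", "women")) {
    i <- which(sex == sx)
    res <- simulate_events_piecewise(bounds[i, , drop = FALSE],
                                     lm12[i, , drop = FALSE],
                                     lm13[i, , drop = FALSE],
                                     lm23[i, , drop = FALSE],
                                     config$baseline_hazards[[sx]],
                                     e12[i], e13[i], e23[i])
    ev$age_cvd[i] <- res$age_cvd
    ev$age_death[i] <- res$age_death
  }

  # participant-level anthropometry missingness (complete-case fodder)
  miss <- stats::runif(N) < config$missing_anthro[sex]

  # eligibility flags on randomly chosen, mutually exclusive extras
  flags <- matrix(FALSE, N, 3,
                  dimnames = list(NULL, c("cancer_history", "cancer_unknown",
                                          "pregnant")))
  cnt <- config$exclusion_counts
  pool <- sample.int(N)
  take <- function(k, from_women = FALSE) {
    if (from_women) {
      cand <- pool[sex[pool] == "women"]
      picked <- cand[seq_len(k)]
    } else picked <- pool[seq_len(k)]
    pool <<- setdiff(pool, picked)
    picked
  }
  if (cnt["cancer_history"] > 0)
    flags[take(cnt["cancer_history"]), "cancer_history"] <- TRUE
  if (cnt["cancer_unknown"] > 0)
    flags[take(cnt["cancer_unknown"]), "cancer_unknown"] <- TRUE
  if (cnt["pregnant"] > 0)
    flags[take(cnt["pregnant"], from_women = TRUE), "pregnant"] <- TRUE

  participants <- data.frame(id = seq_len(N), sex = sex,
                             entry_age = round(entry_age, 2),
                             as.data.frame(flags), cov,
                             stringsAsFactors = FALSE)

  waves <- data.frame(
    id = rep(seq_len(N), each = W),
    wave = rep(seq_len(W), N),
    sex = rep(sex, each = W),
    age = round(as.vector(t(wave_age)), 2),
    height = rep(height, each = W),
    weight = as.vector(t(exp(log_bmi))) * rep(height^2, each = W),
    wc = as.vector(t(exp(log_wc)))
  )
  # waves after death/censoring are never observed
  end_obs <- pmin(ifelse(is.na(ev$age_death), Inf, ev$age_death), censor)
  waves <- waves[waves$age <= rep(end_obs, each = W) + 1e-9, ]
  waves[waves$id %in% which(miss), c("height", "weight", "wc")] <- NA_real_
  rownames(waves) <- NULL

  events <- data.frame(id = seq_len(N),
                       age_cvd = round(ev$age_cvd, 2),
                       age_death = round(ev$age_death, 2),
                       age_censor = round(censor, 2))

  structure(list(participants = participants, waves = waves, events = events,
                 config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic illness-death cohort\n")
  cat("  roster:", nrow(x$participants), "participants (",
      sum(x$participants$sex == "women"), "women )\n")
  cat("  waves: ", nrow(x$waves), "rows\n")
  cat("  events:", sum(!is.na(x$events$age_cvd)), "incident CVD,",
      sum(!is.na(x$events$age_death)), "deaths\n")
  invisible(x)
}
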