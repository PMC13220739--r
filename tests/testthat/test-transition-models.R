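library(data.table)

# Cohort of identical low-category participants entering at exactly 50,
# with event times drawn straight from the Gompertz sampler, so the fit
# can be checked against a direct survival MLE.
gompertz_cohort <- function(n, lambda, gamma, horizon = 30, seed = 1) {
  set.seed(seed)
  t <- sample_gompertz_time(lambda, gamma, runif(n))
  cvd <- ifelse(t < horizon, 50 + t, NA)
  manual_cohort(entry = rep(50, n), age_cvd = cvd,
                age_death = rep(NA_real_, n),
                age_censor = rep(50 + horizon, n))
}

test_that("constant-hazard data recover the exponential occurrence/exposure", {
  ch <- gompertz_cohort(8000, lambda = 0.03, gamma = 0, seed = 30)
  pt <- build_person_time(ch)
  fit <- fit_gompertz(pt, "h12", exposure = FALSE)
  g <- fit$coefficients["age_c"]
  se_g <- sqrt(fit$vcov_robust["age_c", "age_c"])
  expect_lt(abs(g), 3 * se_g)
  d <- sum(pt$event[pt$transition == "h12"])
  T <- sum((pt$tstop - pt$tstart)[pt$transition == "h12"])
  # with gamma ~ 0 the fitted rate is flat and must match d/T
  mean_age <- sum(((pt$tstop + pt$tstart) / 2 *
                     (pt$tstop - pt$tstart))[pt$transition == "h12"]) / T
  expect_equal(unname(gompertz_rate(fit, mean_age)), d / T,
               tolerance = 0.02)
})

test_that("log-likelihood equals a brute-force Poisson evaluation", {
  ch <- generate_cohort(quick_config(600), seed = 31)
  ch$waves <- phenotype_waves(ch$waves)
  pt <- build_person_time(ch)
  fit <- fit_gompertz(pt, "h12", "men", exposure = TRUE)
  seg <- pt[pt$transition == "h12" & pt$sex == "men", ]
  Tt <- seg$tstop - seg$tstart
  lp_cat <- rep(0, nrow(seg))
  for (lv in levels(seg$category)[-1])
    lp_cat <- lp_cat + fit$coefficients[lv] * (seg$category == lv)
  b0 <- fit$coefficients["(Intercept)"]; g <- fit$coefficients["age_c"]
  eta_mid <- b0 + g * ((seg$tstart + seg$tstop) / 2 - 50) + lp_cat
  eta_ev <- b0 + g * (seg$tstop - 50) + lp_cat  # events at their exact age
  ll <- sum(seg$event * (eta_ev + log(Tt))) - sum(Tt * exp(eta_mid))
  expect_equal(fit$loglik, ll, tolerance = 1e-10)
  expect_equal(fit$aic, -2 * ll + 2 * length(fit$coefficients),
               tolerance = 1e-10)
})

test_that("piecewise Poisson fit agrees with the direct Gompertz MLE", {
  skip_if_not_installed("flexsurv")
  ch <- gompertz_cohort(4000, lambda = 0.02, gamma = 0.09, seed = 32)
  pt <- build_person_time(ch, step = 1)
  fit <- fit_gompertz(pt, "h12", exposure = FALSE)
  t <- pmin(ch$events$age_cvd - 50, 30, na.rm = TRUE)
  t[is.na(ch$events$age_cvd)] <- 30
  status <- as.integer(!is.na(ch$events$age_cvd))
  fs <- flexsurv::flexsurvreg(survival::Surv(t, status) ~ 1,
                              dist = "gompertz")
  rate_fs <- exp(fs$coefficients["rate"])
  shape_fs <- fs$coefficients["shape"]
  expect_equal(unname(exp(fit$coefficients["(Intercept)"])),
               unname(rate_fs), tolerance = 1e-3)
  expect_equal(unname(fit$coefficients["age_c"]), unname(shape_fs),
               tolerance = 1e-3)
})

test_that("true Gompertz parameters are recovered within Wald intervals", {
  cfg <- quick_config(20000, true_log_hr = null_log_hr(),
                      anthro_walk = static_walk)
  ch <- generate_cohort(cfg, seed = 33)
  ch$waves <- phenotype_waves(ch$waves)
  pt <- build_person_time(ch)
  fit <- fit_gompertz(pt, "h12", "men", exposure = FALSE)
  h <- cfg$baseline_hazards$men$h12
  b0 <- fit$coefficients[1]; g <- fit$coefficients[2]
  se <- sqrt(diag(fit$vcov_robust)[1:2])
  expect_lt(abs(b0 - log(h["rate50"])), 2.5 * se[1])
  expect_lt(abs(g - h["shape"]), 2.5 * se[2])
})

test_that("merging age-split rows with identical covariates preserves the MLE", {
  ch <- generate_cohort(quick_config(500), seed = 34)
  ch$waves <- phenotype_waves(ch$waves)
  pt <- build_person_time(ch)
  # rows sharing the exact (interval, category) cell have identical
  # covariate vectors, so pooling their events and exposure (carried in
  # an explicit duration column) must not move the MLE
  seg <- pt[pt$transition == "h12", ]
  agg <- seg[, .(id = .GRP, sex = "men", transition = "h12",
                 duration = (tstop[1] - tstart[1]) * .N,
                 event = sum(event)),
             by = .(tstart, tstop, category)]
  fit_raw <- fit_gompertz(seg, "h12", exposure = TRUE)
  fit_agg <- fit_gompertz(agg[, .(id, sex, transition, tstart, tstop,
                                  duration, event, category)], "h12",
                          exposure = TRUE, min_events = 1)
  expect_equal(fit_raw$coefficients, fit_agg$coefficients,
               tolerance = 1e-6)
  # log-likelihoods differ only through the data-dependent d*log(T) term
  off_raw <- sum(seg$event * log(seg$tstop - seg$tstart))
  off_agg <- sum(agg$event * log(agg$duration))
  expect_equal(fit_raw$loglik - off_raw, fit_agg$loglik - off_agg,
               tolerance = 1e-6)
})

test_that("hazard ratios are invariant to shifting the age origin", {
  ch <- generate_cohort(quick_config(1500), seed = 35)
  ch$waves <- phenotype_waves(ch$waves)
  pt <- build_person_time(ch)
  fit1 <- estimate_hrs(pt, "h12", "men", adjust = character())
  pt2 <- data.table::copy(pt)
  pt2[, `:=`(tstart = tstart + 5, tstop = tstop + 5)]
  data.table::setattr(pt2, "participants", attr(pt, "participants"))
  fit2 <- estimate_hrs(pt2, "h12", "men", adjust = character())
  expect_equal(fit1$hr, fit2$hr, tolerance = 1e-6)
  g1 <- attr(fit1, "fit"); g2 <- attr(fit2, "fit")
  expect_equal(g1$coefficients["age_c"], g2$coefficients["age_c"],
               tolerance = 1e-6)
  expect_equal(unname(g2$coefficients[1] - g1$coefficients[1]),
               unname(-5 * g1$coefficients["age_c"]), tolerance = 1e-6)
})

test_that("cluster-robust covariance matches the sandwich package", {
  skip_if_not_installed("sandwich")
  ch <- generate_cohort(quick_config(400), seed = 36)
  ch$waves <- phenotype_waves(ch$waves)
  pt <- build_person_time(ch)
  fit <- fit_gompertz(pt, "h12", "men", exposure = TRUE)
  seg <- pt[pt$transition == "h12" & pt$sex == "men", ]
  # the GLM twin of the fit: event rows are split into a censored
  # exposure piece plus an epsilon-duration event row at the event age
  base <- data.frame(d = 0L, age_c = (seg$tstart + seg$tstop) / 2 - 50,
                     category = seg$category,
                     off = log(seg$tstop - seg$tstart), id = seg$id)
  evr <- seg$event == 1L
  eps <- data.frame(d = 1L, age_c = seg$tstop[evr] - 50,
                    category = seg$category[evr],
                    off = log(1e-9), id = seg$id[evr])
  df <- rbind(base, eps)
  gfit <- glm(d ~ age_c + category + offset(off), poisson(), data = df)
  Vs <- sandwich::vcovCL(gfit, cluster = df$id, type = "HC0",
                         cadjust = TRUE)
  # same estimator, same small-sample factor G/(G-1)
  expect_equal(unname(diag(fit$vcov_robust)), unname(diag(Vs)),
               tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), unname(coef(gfit)),
               tolerance = 1e-6)
})

test_that("robust SEs exceed model SEs under within-cluster correlation", {
  # overdispersed counts with shared per-individual frailty
  set.seed(37)
  n_id <- 400; reps <- 8
  id <- rep(seq_len(n_id), each = reps)
  age <- rep(seq(55, 62), n_id)
  frail <- rep(rgamma(n_id, shape = 1, rate = 1), each = reps)
  rate <- 0.05 * exp(0.05 * (age - 50)) * frail
  d <- rpois(n_id * reps, rate)
  seg <- data.table(id = id, sex = "men", transition = "h12",
                    tstart = age, tstop = age + 1, event = d,
                    category = factor("low", levels = adiposity_levels()))
  fit <- fit_gompertz(seg, "h12", exposure = FALSE)
  expect_gt(sqrt(fit$vcov_robust[1, 1]), sqrt(fit$vcov_model[1, 1]))
})

test_that("zero-event categories are flagged", {
  ch <- gompertz_cohort(300, lambda = 0.02, gamma = 0.05, seed = 38)
  pt <- build_person_time(ch)  # everyone is in the low category
  expect_warning(fit <- fit_gompertz(pt, "h12", exposure = TRUE),
                 "zero events")
  expect_setequal(fit$zero_event_categories,
                  c("increased", "high", "very_high"))
})

test_that("Weibull comparison prefers the true model family", {
  ch <- gompertz_cohort(20000, lambda = 0.02, gamma = 0.09, seed = 39)
  pt <- build_person_time(ch)
  fg <- fit_gompertz(pt, "h12", exposure = FALSE)
  fw <- fit_weibull(pt, "h12", exposure = FALSE)
  expect_lt(fg$aic, fw$aic)
  expect_equal(fw$aic, -2 * fw$loglik + 2 * length(fw$coefficients))
  # exponential data: both families nest it, AICs nearly tie
  ch0 <- gompertz_cohort(8000, lambda = 0.03, gamma = 0, seed = 40)
  pt0 <- build_person_time(ch0)
  a_g <- fit_gompertz(pt0, "h12", exposure = FALSE)$aic
  a_w <- fit_weibull(pt0, "h12", exposure = FALSE)$aic
  expect_lt(abs(a_g - a_w), 2)
})

test_that("age stratification conserves person-time and matches truth", {
  ch <- generate_cohort(quick_config(4000), seed = 41)
  ch$waves <- phenotype_waves(ch$waves)
  pt <- build_person_time(ch)
  strat <- age_stratified_hrs(pt, "h12", "men", cut = 65,
                              adjust = character())
  fy <- attr(strat$younger, "fit"); fo <- attr(strat$older, "fit")
  expect_equal(fy$person_years + fo$person_years,
               sum((pt$tstop - pt$tstart)[pt$transition == "h12" &
                                            pt$sex == "men"]),
               tolerance = 1e-8)
  # homogeneous truth: stratum estimates agree within joint Wald CI
  for (lv in c("high", "very_high")) {
    dy <- log(strat$younger$hr[strat$younger$category == lv])
    do <- log(strat$older$hr[strat$older$category == lv])
    se <- sqrt(strat$younger$se_log[strat$younger$category == lv]^2 +
                 strat$older$se_log[strat$older$category == lv]^2)
    expect_lt(abs(dy - do), 3 * se)
  }
})

test_that("variance inflation factors behave on known designs", {
  set.seed(42)
  X <- matrix(rnorm(300), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  v <- compute_vif(X)
  expect_true(all(v$vif < 1.2))
  expect_equal(v$tolerance, 1 / v$vif)
  X2 <- cbind(X, d = X[, 1])
  v2 <- compute_vif(X2)
  expect_true(is.infinite(v2$vif[v2$variable == "d"]))
  # default synthetic covariate set shows no concerning collinearity
  ch <- generate_cohort(quick_config(2000), seed = 43)
  p <- ch$participants
  p$cigs_per_day[is.na(p$cigs_per_day)] <- 0
  v3 <- compute_vif(p[, default_adjustment()])
  expect_true(all(v3$vif < 5))
  expect_true(all(v3$tolerance > 0.20))
})
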