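#' Estimate the full multistate life-expectancy pipeline
#'
#' Runs the estimation chain on a phenotyped cohort: transition-specific
#' person-time, overall (marginal) Gompertz rates and adjusted hazard
#' ratios per sex and transition, category prevalences by sex, age band
#' and disease status, prevalence-calibrated category rates, and one
#' multistate life table per sex and exposure category.
#'
#' @param cohort A `synthetic_cohort` (or any object of that shape).
#' @param exposure_kind `"composite"`, `"wc_only"` or `"bmi_only"`.
#' @param adjust Covariates for the HR models, see [default_adjustment()].
#' @param start,close,step Life-table age window and interval width.
#' @param init `"observed"` starts each category's table at its observed
#'   disease prevalence in the first age band; `"healthy"` starts everyone
#'   disease-free.
#' @param sensitivity Cohort filter mode, see [sensitivity_filters()].
#' @param min_events Event floor per fitted model.
#' @return Object of class `le_pipeline`: list with `overall` and `hrs`
#'   (nested by sex then transition), `prev`, `tables` (by sex then
#'   category), `le` (data frame of expectancy triples and differences
#'   versus the reference category), plus the settings used.
#' @export
le_pipeline <- function(cohort,
                        exposure_kind = c("composite", "wc_only", "bmi_only"),
                        adjust = default_adjustment(),
                        start = 50, close = 80, step = 1,
                        init = c("observed", "healthy"),
                        sensitivity = c("none", "early_events_2y",
                                        "baseline_comorbidity"),
                        min_events = 10) {
  exposure_kind <- match.arg(exposure_kind)
  init <- match.arg(init)
  sensitivity <- match.arg(sensitivity)
  cohort <- sensitivity_filters(cohort, sensitivity)
  segments <- build_person_time(cohort, exposure_kind)
  prev <- estimate_prevalences(cohort, exposure_kind)
  ages <- seq(start, close - step, by = step)
  sexes <- sort(unique(segments$sex))
  overall <- list(); hrs <- list(); tables <- list()
  for (sx in sexes) {
    overall[[sx]] <- list(); hrs[[sx]] <- list(); tables[[sx]] <- list()
    for (tr in c("h12", "h13", "h23")) {
      overall[[sx]][[tr]] <- fit_gompertz(segments, tr, sx,
                                          exposure = FALSE,
                                          min_events = min_events)
      hrs[[sx]][[tr]] <- estimate_hrs(segments, tr, sx, adjust = adjust,
                                      min_events = min_events)
    }
  }
  state <- list(overall = overall, hrs = hrs, prev = prev,
                exposure_kind = exposure_kind,
                start = start, close = close, step = step, init = init,
                adjust = adjust)
  built <- rebuild_tables(state)
  state$tables <- built$tables
  state$le <- built$le
  class(state) <- "le_pipeline"
  state
}

# Rebuild calibrated rates, life tables and the LE summary from a
# (possibly perturbed) parameter state. Used by both the point estimate
# and every bootstrap draw.
rebuild_tables <- function(state, params = NULL) {
  prev <- if (is.null(params)) state$prev else params$prev
  ages <- seq(state$start, state$close - state$step, by = state$step)
  sexes <- names(state$overall)
  tables <- list(); rows <- list()
  for (sx in sexes) {
    tables[[sx]] <- list()
    rates <- list()
    for (tr in c("h12", "h13", "h23")) {
      if (is.null(params)) {
        ov <- state$overall[[sx]][[tr]]
        hr <- stats::setNames(state$hrs[[sx]][[tr]]$hr,
                              state$hrs[[sx]][[tr]]$category)
      } else {
        g <- params$gompertz[[sx]][[tr]]
        ov <- function(a) exp(g[1] + g[2] * (a - 50))
        hr <- exp(params$log_hr[[sx]][[tr]])
        hr <- c(1, hr)
        names(hr) <- c(as.character(state$hrs[[sx]][[tr]]$category[1]),
                       names(params$log_hr[[sx]][[tr]]))
      }
      rates[[tr]] <- calibrate_category_rates(ov, hr, prev, sx,
                                              cvd = (tr == "h23"),
                                              ages = ages)
    }
    cats <- colnames(rates$h12)
    ref_le <- NULL
    for (cat in cats) {
      ic <- if (state$init == "observed")
        init_cvd_fraction(prev, sx, cat, state$start) else 0
      tab <- build_lifetable(rates$h12[, cat], rates$h13[, cat],
                             rates$h23[, cat],
                             start = state$start, close = state$close,
                             step = state$step, init_cvd = ic)
      tables[[sx]][[cat]] <- tab
      le <- le_decompose(tab)
      if (is.null(ref_le)) ref_le <- le
      rows[[paste(sx, cat)]] <- data.frame(
        sex = sx, category = cat,
        total_le = le["total_le"], cvd_free_le = le["cvd_free_le"],
        with_cvd_le = le["with_cvd_le"],
        d_total_le = le["total_le"] - ref_le["total_le"],
        d_cvd_free_le = le["cvd_free_le"] - ref_le["cvd_free_le"],
        d_with_cvd_le = le["with_cvd_le"] - ref_le["with_cvd_le"],
        row.names = NULL)
    }
  }
  le <- do.call(rbind, rows)
  rownames(le) <- NULL
  list(tables = tables, le = le)
}

# Observed disease prevalence within a category in the band containing
# `age` (Bayes inversion of the category-given-status prevalences).
init_cvd_fraction <- function(prev, sex, category, age) {
  bands <- attr(prev, "bands")
  b <- bands[findInterval(age, c(bands, Inf))]
  n_cvd <- prevalence_counts(prev, sex, b, TRUE)[category]
  n_free <- prevalence_counts(prev, sex, b, FALSE)[category]
  tot <- n_cvd + n_free
  if (is.na(tot) || tot == 0) return(0)
  unname(n_cvd / tot)
}

#' @export
print.le_pipeline <- function(x, ...) {
  cat("Multistate life-expectancy pipeline (", x$exposure_kind,
      " exposure, ages ", x$start, "-", x$close, ")\n", sep = "")
  print(x$le, digits = 3)
  invisible(x)
}

#' Draw one parametric-bootstrap parameter realisation
#'
#' Gompertz intercept/shape pairs and category log-hazard-ratios are drawn
#' from multivariate normals centred at the estimates with the
#' cluster-robust covariances, independently per sex and transition;
#' prevalence vectors are redrawn as Dirichlet with the observed cell
#' counts as parameters (the conjugate equivalent of multinomial
#' resampling).  A non-positive-semidefinite covariance is repaired to the
#' nearest PSD matrix with a warning.
#'
#' @param state An `le_pipeline`.
#' @param include_prevalence Redraw prevalences too?
#' @param scale Multiplier on all covariances (0 collapses the draw onto
#'   the point estimates).
#' @return List with `gompertz` (per sex/transition `c(b0, gamma)`),
#'   `log_hr` (per sex/transition named vectors, non-reference
#'   categories), and `prev` (a `prevalence_table`).
#' @export
draw_parameters <- function(state, include_prevalence = TRUE, scale = 1) {
  stopifnot(inherits(state, "le_pipeline"))
  gom <- list(); lhr <- list()
  for (sx in names(state$overall)) {
    gom[[sx]] <- list(); lhr[[sx]] <- list()
    for (tr in c("h12", "h13", "h23")) {
      ov <- state$overall[[sx]][[tr]]
      V <- ensure_psd(ov$vcov_robust[1:2, 1:2] * scale)
      gom[[sx]][[tr]] <- drop(MASS::mvrnorm(1, ov$coefficients[1:2], V))
      hr <- state$hrs[[sx]][[tr]]
      lv <- as.character(hr$category[-1])
      mu <- log(hr$hr[-1])
      Vh <- ensure_psd(attr(hr, "vcov_loghr") * scale)
      lhr[[sx]][[tr]] <- stats::setNames(drop(MASS::mvrnorm(1, mu, Vh)), lv)
    }
  }
  prev <- state$prev
  if (include_prevalence && scale > 0) {
    for (sx in unique(prev$sex)) for (b in unique(prev$band))
      for (st in c(FALSE, TRUE)) {
        i <- which(prev$sex == sx & prev$band == b & prev$cvd == st)
        n <- prev$n[i]
        if (sum(n) > 0) {
          g <- stats::rgamma(length(n), shape = n)
          if (sum(g) > 0) prev$p[i] <- g / sum(g)
        }
      }
  }
  list(gompertz = gom, log_hr = lhr, prev = prev)
}

ensure_psd <- function(V) {
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (any(ev$values < -1e-10)) {
    warning("covariance not positive semi-definite; repaired", call. = FALSE)
    ev$values <- pmax(ev$values, 0)
    V <- ev$vectors %*% diag(ev$values, nrow = length(ev$values)) %*%
      t(ev$vectors)
  }
  V
}

#' Parametric-bootstrap confidence intervals for life expectancy
#'
#' Redraws the fitted parameters `B` times with [draw_parameters()],
#' rebuilds the calibrated rates and life tables per draw, and returns
#' percentile (2.5/97.5) intervals for each expectancy and each
#' difference versus the reference category.
#'
#' @param state An `le_pipeline`.
#' @param B Bootstrap iterations (1,000 by default).
#' @param seed Integer seed (required for reproducibility).
#' @param include_prevalence Propagate prevalence uncertainty?
#' @param scale Covariance multiplier (for calibration experiments).
#' @return Object of class `bootstrap_result`: `summary` (the pipeline
#'   `le` table with `_lo`/`_hi` percentile bounds appended), `draws`
#'   (B x quantities matrix), `B`, `seed`, and `n_invalid` (draws that
#'   produced an invalid rate set and were redrawn).
#' @export
bootstrap_le <- function(state, B = 1000, seed = 1L,
                         include_prevalence = TRUE, scale = 1) {
  stopifnot(inherits(state, "le_pipeline"), B >= 1)
  set.seed(seed)
  qty <- c("total_le", "cvd_free_le", "with_cvd_le",
           "d_total_le", "d_cvd_free_le", "d_with_cvd_le")
  key <- paste(state$le$sex, state$le$category, sep = ":")
  cols <- as.vector(outer(key, qty, paste, sep = ":"))
  draws <- matrix(NA_real_, B, length(cols), dimnames = list(NULL, cols))
  n_invalid <- 0L
  for (b in seq_len(B)) {
    ok <- FALSE
    while (!ok) {
      par <- draw_parameters(state, include_prevalence, scale)
      res <- tryCatch(rebuild_tables(state, par), error = function(e) NULL)
      if (is.null(res)) n_invalid <- n_invalid + 1L else ok <- TRUE
    }
    for (q in qty)
      draws[b, paste(key, q, sep = ":")] <- res$le[[q]]
  }
  summ <- state$le
  for (q in qty) {
    lo <- apply(draws[, paste(key, q, sep = ":"), drop = FALSE], 2,
                stats::quantile, probs = 0.025, names = FALSE)
    hi <- apply(draws[, paste(key, q, sep = ":"), drop = FALSE], 2,
                stats::quantile, probs = 0.975, names = FALSE)
    summ[[paste0(q, "_lo")]] <- lo
    summ[[paste0(q, "_hi")]] <- hi
  }
  structure(list(summary = summ, draws = draws, B = B, seed = seed,
                 include_prevalence = include_prevalence,
                 n_invalid = n_invalid),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Parametric bootstrap,", x$B, "iterations (seed", x$seed, ")\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Nested coverage experiment for the bootstrap intervals
#'
#' Repeatedly generates a cohort from known parameters (categories held
#' fixed over follow-up), runs the estimation pipeline and the parametric
#' bootstrap, and checks how often the percentile interval for the
#' disease-free life-expectancy difference (very high versus low
#' adiposity) covers the true value.  The truth is computed once by
#' micro-simulation at the generating rates.
#'
#' @param n_reps Outer replicates.
#' @param n Cohort size per replicate (men only).
#' @param B Inner bootstrap iterations.
#' @param seed Root seed.
#' @param n_truth Micro-simulation size for the true difference.
#' @return List with `coverage`, the true difference `truth`, its
#'   Monte-Carlo SE, and the per-replicate interval matrix.
#' @export
coverage_experiment <- function(n_reps = 200, n = 5000, B = 250,
                                seed = 1L, n_truth = 1e6) {
  cfg <- cohort_config(
    n_participants = n, fraction_women = 0,
    exclusion_counts = c(cancer_history = 0, cancer_unknown = 0,
                         pregnant = 0),
    anthro_walk = c(drift = 0, sd = 0))
  h <- cfg$baseline_hazards$men
  lhr <- cfg$true_log_hr$men
  ages <- 0:29
  truth_le <- lapply(c(low = "low", very_high = "very_high"), function(cat) {
    r12 <- h$h12["rate50"] * exp(h$h12["shape"] * ages) *
      exp(lhr$h12[cat])
    r13 <- h$h13["rate50"] * exp(h$h13["shape"] * ages) *
      exp(lhr$h13[cat])
    r23 <- h$h23["rate50"] * exp(h$h23["shape"] * ages) *
      exp(lhr$h23[cat])
    microsimulate_le(r12, r13, r23, n = n_truth, seed = seed + 10)
  })
  truth <- truth_le$very_high$le["cvd_free_le"] -
    truth_le$low$le["cvd_free_le"]
  truth_se <- sqrt(truth_le$very_high$se["cvd_free_le"]^2 +
                     truth_le$low$se["cvd_free_le"]^2)
  ci <- matrix(NA_real_, n_reps, 2, dimnames = list(NULL, c("lo", "hi")))
  for (r in seq_len(n_reps)) {
    ch <- generate_cohort(cfg, seed = seed + r)
    ch$waves <- phenotype_waves(ch$waves)
    st <- le_pipeline(ch, adjust = character(), init = "healthy")
    bt <- bootstrap_le(st, B = B, seed = seed + 100000L + r)
    i <- bt$summary$category == "very_high"
    ci[r, ] <- c(bt$summary$d_cvd_free_le_lo[i],
                 bt$summary$d_cvd_free_le_hi[i])
  }
  covered <- ci[, "lo"] <= truth & truth <= ci[, "hi"]
  list(coverage = mean(covered), truth = unname(truth),
       truth_se = unname(truth_se), ci = ci)
}
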