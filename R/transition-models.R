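#' Default adjustment covariates
#'
#' Baseline confounders used in the adjusted transition models: baseline
#' age, household composition, education, physical activity, diet score,
#' smoking status with cigarettes/day for current smokers, alcohol use,
#' and COPD.
#'
#' @return Character vector of column names in the participant table.
#' @export
default_adjustment <- function() {
  c("entry_age", "household", "education", "pa_index", "dhd15",
    "smoking", "cigs_per_day", "alcohol", "copd")
}

# Build the numeric design matrix for a fit: intercept, centred mid-age,
# exposure dummies, then adjustment covariates (factors expanded to
# treatment dummies; cigs_per_day enters as 0 for non-current smokers so
# it acts as "cigarettes/day among current smokers").
build_design <- function(seg, participants, exposure, adjust) {
  n <- nrow(seg)
  age_mid <- (seg$tstart + seg$tstop) / 2 - 50
  X <- cbind(`(Intercept)` = rep(1, n), age_c = age_mid)
  if (exposure) {
    lv <- levels(seg$category)
    for (l in lv[-1])
      X <- cbind(X, as.numeric(seg$category == l))
    colnames(X)[(ncol(X) - length(lv) + 2):ncol(X)] <- lv[-1]
  }
  if (length(adjust)) {
    p <- participants[match(seg$id, participants$id), , drop = FALSE]
    for (v in adjust) {
      col <- p[[v]]
      if (v == "cigs_per_day") {
        x <- ifelse(is.na(col), 0, col)
        X <- cbind(X, cigs_per_day = x)
      } else if (is.factor(col) || is.character(col)) {
        col <- as.factor(col)
        for (l in levels(col)[-1]) {
          X <- cbind(X, as.numeric(col == l))
          colnames(X)[ncol(X)] <- paste0(v, "_", l)
        }
      } else {
        X <- cbind(X, as.numeric(col))
        colnames(X)[ncol(X)] <- v
      }
    }
  }
  X
}

# Poisson-likelihood Newton fit with log person-time offset.
# The exposure part of each row (`- T * rate`) is evaluated at the row's
# design `X` (midpoint age); the event part (`d * log rate`) at `Xev`,
# which for event rows carries the exact event age.  With Xev = X this is
# ordinary Poisson IRLS; with exit-age evaluation it equals the GLM in
# which every event row is split into a censored exposure piece plus an
# epsilon-duration event row at the event time, and reproduces the direct
# parametric survival likelihood up to midpoint-rectangle integration of
# the cumulative hazard.  Deterministic start at the occurrence/exposure
# exponential fit (intercept = log(d/T), slopes 0).
poisson_fit <- function(X, d, logT, Xev = X, tol = 1e-9, maxit = 200) {
  loglik <- function(beta) {
    sum(d * (drop(Xev %*% beta) + logT)) - sum(exp(drop(X %*% beta) + logT))
  }
  beta <- c(log(sum(d) / sum(exp(logT))), rep(0, ncol(X) - 1))
  ev_part <- drop(crossprod(Xev, d))
  ll_old <- -Inf
  ll_n <- loglik(beta)
  for (it in seq_len(maxit)) {
    mu <- exp(drop(X %*% beta) + logT)
    XtWX <- crossprod(X, X * mu)
    score <- ev_part - drop(crossprod(X, mu))
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) {  # ridge fallback for near-separation
      XtWX <- XtWX + diag(1e-8, ncol(X))
      step <- solve(XtWX, score)
    }
    beta_new <- beta + drop(step)
    # step-halving if the likelihood worsens
    ll <- ll_n
    h <- 0
    while (h < 20) {
      ll_n <- loglik(beta_new)
      if (is.finite(ll_n) && ll_n >= ll - 1e-12) break
      beta_new <- (beta + beta_new) / 2
      h <- h + 1
    }
    beta <- beta_new
    if (is.finite(ll_old) && abs(ll_n - ll_old) <
        tol * (abs(ll_old) + 1e-12)) break
    ll_old <- ll_n
  }
  mu <- exp(drop(X %*% beta) + logT)
  XtWX <- crossprod(X, X * mu)
  vcov_model <- tryCatch(solve(XtWX), error = function(e) {
    solve(XtWX + diag(1e-8, ncol(X)))
  })
  dimnames(vcov_model) <- list(colnames(X), colnames(X))
  grad <- ev_part - drop(crossprod(X, mu))
  list(coefficients = stats::setNames(drop(beta), colnames(X)),
       vcov_model = vcov_model, mu = mu,
       loglik = loglik(beta), iterations = it,
       gradient_norm = sqrt(sum(grad^2)),
       converged = it < maxit)
}

cluster_robust_vcov <- function(X, d, mu, id, bread, Xev = X) {
  U <- Xev * d - X * mu
  Us <- rowsum(U, group = id)
  G <- nrow(Us)
  meat <- crossprod(Us)
  V <- bread %*% meat %*% bread * G / (G - 1)
  dimnames(V) <- dimnames(bread)
  V
}

#' Fit a Gompertz proportional-hazards transition model
#'
#' Maximises the Poisson log-likelihood
#' `sum(d * log(rate) * ... - T * rate)` over age-split person-time rows,
#' with `log rate = b0 + gamma * (age_mid - 50) + x' beta`.  This is the
#' standard piecewise operationalisation of a Gompertz hazard that is
#' log-linear in attained age; with fine age splitting it agrees with the
#' direct Gompertz survival MLE.  Both the model-based and the
#' cluster-robust (per-individual sandwich, small-sample factor
#' `G/(G-1)`) covariances are returned.
#'
#' @param segments A `person_time` table from [build_person_time()].
#' @param transition `"h12"`, `"h13"` or `"h23"`.
#' @param sex Optional `"men"`/`"women"` subset.
#' @param exposure Include exposure-category dummies (reference = first
#'   level)?
#' @param adjust Character vector of baseline covariate names (columns of
#'   the attached participant table); use [default_adjustment()] for the
#'   pre-specified confounder set, or `character()` for none.
#' @param min_events Fit refuses with fewer events than this floor.
#' @return Object of class `gompertz_fit`: coefficients (`(Intercept)` =
#'   log rate at age 50, `age_c` = Gompertz shape, then category and
#'   covariate log-HRs), `vcov_model`, `vcov_robust`, `n_events`,
#'   `person_years`, `loglik`, `aic`, convergence info, and
#'   `zero_event_categories` flagging separation.
#' @export
fit_gompertz <- function(segments, transition, sex = NULL, exposure = TRUE,
                         adjust = character(), min_events = 10) {
  seg <- subset_segments(segments, transition, sex)
  participants <- attr(segments, "participants")
  d <- seg$event
  if (sum(d) < min_events)
    stop("fewer than ", min_events, " events for transition ", transition,
         call. = FALSE)
  zero_cats <- character()
  if (exposure) {
    tab <- tapply(d, seg$category, sum)
    zero_cats <- names(tab)[is.na(tab) | tab == 0]
    if (length(zero_cats))
      warning("categories with zero events (coefficients unreliable): ",
              paste(zero_cats, collapse = ", "), call. = FALSE)
  }
  X <- build_design(seg, participants, exposure, adjust)
  # event parts of the likelihood are evaluated at the exact event age
  # (the row's exit), which makes the age-split fit match the direct
  # parametric survival MLE; exposure uses the interval midpoint
  Xev <- X
  ev_rows <- d > 0
  Xev[ev_rows, "age_c"] <- seg$tstop[ev_rows] - 50
  logT <- log(segment_duration(seg))
  fit <- poisson_fit(X, d, logT, Xev)
  if (!fit$converged)
    warning("IRLS did not converge; gradient norm ",
            format(fit$gradient_norm), call. = FALSE)
  vr <- cluster_robust_vcov(X, d, fit$mu, seg$id, fit$vcov_model, Xev)
  k <- length(fit$coefficients)
  structure(list(
    transition = transition, sex = sex %||% "both",
    coefficients = fit$coefficients,
    vcov_model = fit$vcov_model, vcov_robust = vr,
    n_events = sum(d), person_years = sum(exp(logT)),
    loglik = fit$loglik, aic = -2 * fit$loglik + 2 * k,
    iterations = fit$iterations, converged = fit$converged,
    gradient_norm = fit$gradient_norm,
    exposure = exposure, adjust = adjust,
    categories = if (exposure) levels(seg$category) else NULL,
    zero_event_categories = zero_cats,
    timescale = "gompertz"
  ), class = "gompertz_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row exposure: an explicit `duration` column (aggregated rows) wins over
# the interval width.
segment_duration <- function(seg) {
  if ("duration" %in% names(seg)) seg$duration else seg$tstop - seg$tstart
}

subset_segments <- function(segments, transition, sex) {
  stopifnot(transition %in% c("h12", "h13", "h23"))
  keep <- segments$transition == transition
  if (!is.null(sex)) keep <- keep & segments$sex == sex
  seg <- segments[keep, ]
  if (nrow(seg) == 0L) stop("no person-time rows selected", call. = FALSE)
  seg
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz PH fit (", x$timescale, " timescale), transition ",
      x$transition, ", sex ", x$sex, "\n", sep = "")
  cat("  events:", x$n_events, " person-years:",
      format(round(x$person_years, 1)), "\n")
  cat("  rate at 50:", format(exp(x$coefficients[1]), digits = 4),
      " shape:", format(x$coefficients[2], digits = 4), "\n")
  cat("  loglik:", format(x$loglik), " AIC:", format(x$aic), "\n")
  invisible(x)
}

#' Predict the overall Gompertz rate at given ages
#'
#' Evaluates `exp(b0 + gamma * (age - 50))` from an exposure-free fit
#' (covariates at reference levels).
#'
#' @param fit A `gompertz_fit`.
#' @param age Ages in years.
#' @return Rates (events/year).
#' @export
gompertz_rate <- function(fit, age) {
  exp(fit$coefficients[1] + fit$coefficients[2] * (age - 50))
}

#' Adjusted hazard ratios per exposure category
#'
#' Fits the adjusted Poisson-Gompertz model and extracts the exposure
#' category coefficients with cluster-robust Wald 95% CIs
#' (`exp(logHR +/- 1.96 se)`), reference category HR fixed at 1.
#'
#' @inheritParams fit_gompertz
#' @return Object of class `hr_set`: data frame with `transition`, `sex`,
#'   `category`, `hr`, `lcl`, `ucl`, `se_log`; the underlying fit is
#'   attached as attribute `"fit"` and the robust covariance block of the
#'   category log-HRs as attribute `"vcov_loghr"`.
#' @export
estimate_hrs <- function(segments, transition, sex = NULL,
                         adjust = default_adjustment(), min_events = 10) {
  fit <- fit_gompertz(segments, transition, sex, exposure = TRUE,
                      adjust = adjust, min_events = min_events)
  lv <- fit$categories
  idx <- match(lv[-1], names(fit$coefficients))
  se <- sqrt(diag(fit$vcov_robust)[idx])
  lhr <- fit$coefficients[idx]
  out <- data.frame(
    transition = transition, sex = fit$sex,
    category = factor(lv, levels = lv),
    hr = c(1, exp(lhr)),
    lcl = c(NA, exp(lhr - 1.96 * se)),
    ucl = c(NA, exp(lhr + 1.96 * se)),
    se_log = c(NA, se),
    row.names = NULL
  )
  attr(out, "fit") <- fit
  attr(out, "vcov_loghr") <- fit$vcov_robust[idx, idx, drop = FALSE]
  class(out) <- c("hr_set", "data.frame")
  out
}

#' Weibull proportional-hazards comparison fit
#'
#' Same Poisson person-time likelihood with `log(age_mid)` replacing the
#' linear age term, i.e. a Weibull hazard `p * lambda * age^(p-1)` on the
#' attained-age timescale, for model-fit (AIC) comparison against the
#' Gompertz specification.
#'
#' @inheritParams fit_gompertz
#' @return A `gompertz_fit`-shaped object with `timescale = "weibull"`;
#'   the `age_c` coefficient is `p - 1` on the log-age scale.
#' @export
fit_weibull <- function(segments, transition, sex = NULL, exposure = FALSE,
                        adjust = character(), min_events = 10) {
  seg <- subset_segments(segments, transition, sex)
  participants <- attr(segments, "participants")
  d <- seg$event
  if (sum(d) < min_events)
    stop("fewer than ", min_events, " events", call. = FALSE)
  X <- build_design(seg, participants, exposure, adjust)
  X[, "age_c"] <- log((seg$tstart + seg$tstop) / 2)
  colnames(X)[2] <- "log_age"
  Xev <- X
  ev_rows <- d > 0
  Xev[ev_rows, "log_age"] <- log(seg$tstop[ev_rows])
  logT <- log(segment_duration(seg))
  fit <- poisson_fit(X, d, logT, Xev)
  vr <- cluster_robust_vcov(X, d, fit$mu, seg$id, fit$vcov_model, Xev)
  k <- length(fit$coefficients)
  structure(list(
    transition = transition, sex = sex %||% "both",
    coefficients = fit$coefficients,
    vcov_model = fit$vcov_model, vcov_robust = vr,
    n_events = sum(d), person_years = sum(exp(logT)),
    loglik = fit$loglik, aic = -2 * fit$loglik + 2 * k,
    iterations = fit$iterations, converged = fit$converged,
    gradient_norm = fit$gradient_norm,
    exposure = exposure, adjust = adjust,
    categories = if (exposure) levels(seg$category) else NULL,
    zero_event_categories = character(),
    timescale = "weibull"
  ), class = "gompertz_fit")
}

#' Attained-age stratified hazard ratios
#'
#' Splits the person-time at the cut age (rows straddling the cut are
#' subdivided) and fits independent adjusted models per stratum.
#'
#' @inheritParams estimate_hrs
#' @param cut Stratification age in years (default 65).
#' @return Named list of two `hr_set`s (`younger`, `older`).
#' @export
age_stratified_hrs <- function(segments, transition, sex = NULL, cut = 65,
                               adjust = default_adjustment(),
                               min_events = 10) {
  seg <- data.table::copy(segments)
  straddle <- seg$tstart < cut & seg$tstop > cut
  if (any(straddle)) {
    lower <- seg[straddle]
    lower[, `:=`(tstop = cut, event = 0L)]
    upper <- seg[straddle]
    upper[, tstart := cut]
    seg <- data.table::rbindlist(list(seg[!straddle], lower, upper))
  }
  for (a in c("participants", "complete_case", "exposure_kind"))
    data.table::setattr(seg, a, attr(segments, a))
  young <- seg[seg$tstop <= cut + 1e-9, ]
  old <- seg[seg$tstart >= cut - 1e-9, ]
  for (s in list(young, old))
    data.table::setattr(s, "participants", attr(segments, "participants"))
  list(younger = estimate_hrs(young, transition, sex, adjust, min_events),
       older = estimate_hrs(old, transition, sex, adjust, min_events))
}

#' Variance inflation factors of a covariate design
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing each (non-intercept) column
#' of the numeric design matrix on all others; tolerance is `1/VIF`.
#'
#' @param x A numeric matrix or a data frame (factors expanded to
#'   treatment dummies).
#' @return Data frame with `variable`, `vif`, `tolerance`; duplicated or
#'   collinear columns get `vif = Inf`.
#' @export
compute_vif <- function(x) {
  if (is.data.frame(x))
    x <- stats::model.matrix(~ ., data = x)[, -1, drop = FALSE]
  x <- as.matrix(x)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  out <- data.frame(variable = colnames(x), vif = NA_real_,
                    tolerance = NA_real_)
  ones <- rep(1, nrow(x))
  for (j in seq_len(ncol(x))) {
    y <- x[, j]
    Z <- cbind(ones, x[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss == 0) 1 else 1 - rss / tss
    out$vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    out$tolerance[j] <- 1 / out$vif[j]
  }
  out
}
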