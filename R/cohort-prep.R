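#' Apply eligibility criteria
#'
#' Removes, in order: participants younger than 50 at the index wave,
#' those with a self-reported cancer history, those with unknown cancer
#' status, and women pregnant at assessment.  A participant matching
#' several criteria is removed once and counted under the first matching
#' rule.
#'
#' @param cohort A `synthetic_cohort` or a roster data frame with columns
#'   `id`, `entry_age`, `cancer_history`, `cancer_unknown`, `pregnant`.
#' @return List with the filtered `cohort` (same class as the input) and
#'   an `exclusion_log` data frame (`step`, `n_removed`, `n_remaining`).
#' @export
apply_eligibility <- function(cohort) {
  roster <- if (inherits(cohort, "synthetic_cohort")) cohort$participants
            else cohort
  stopifnot(all(c("id", "entry_age", "cancer_history", "cancer_unknown",
                  "pregnant") %in% names(roster)))
  steps <- list(
    age_under_50 = roster$entry_age < 50,
    cancer_history = roster$cancer_history,
    cancer_unknown = roster$cancer_unknown,
    pregnant = roster$pregnant
  )
  removed <- rep(FALSE, nrow(roster))
  log <- data.frame(step = names(steps), n_removed = NA_integer_,
                    n_remaining = NA_integer_)
  for (i in seq_along(steps)) {
    hit <- steps[[i]] & !removed
    removed <- removed | hit
    log$n_removed[i] <- sum(hit)
    log$n_remaining[i] <- sum(!removed)
  }
  keep <- roster$id[!removed]
  if (inherits(cohort, "synthetic_cohort")) {
    cohort$participants <- cohort$participants[!removed, , drop = FALSE]
    cohort$waves <- cohort$waves[cohort$waves$id %in% keep, , drop = FALSE]
    cohort$events <- cohort$events[cohort$events$id %in% keep, , drop = FALSE]
    rownames(cohort$participants) <- rownames(cohort$waves) <-
      rownames(cohort$events) <- NULL
    list(cohort = cohort, exclusion_log = log)
  } else {
    list(cohort = roster[!removed, , drop = FALSE], exclusion_log = log)
  }
}

#' Sensitivity-analysis cohort filters
#'
#' `early_events_2y` drops participants with incident CVD or death within
#' two years of entry (reverse-causation guard); `baseline_comorbidity`
#' drops participants with baseline hypertension, diabetes,
#' hypercholesterolaemia or low HDL, classified from the baseline
#' biomarkers with the package's clinical definitions.
#'
#' @param cohort A `synthetic_cohort`.
#' @param mode One of `"none"`, `"early_events_2y"`,
#'   `"baseline_comorbidity"`.
#' @return The filtered `synthetic_cohort`.
#' @export
sensitivity_filters <- function(cohort,
                                mode = c("none", "early_events_2y",
                                         "baseline_comorbidity")) {
  mode <- match.arg(mode)
  if (mode == "none") return(cohort)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  p <- cohort$participants
  ev <- cohort$events[match(p$id, cohort$events$id), ]
  if (mode == "early_events_2y") {
    cut <- p$entry_age + 2
    drop <- (!is.na(ev$age_cvd) & ev$age_cvd < cut) |
      (!is.na(ev$age_death) & ev$age_death < cut)
  } else {
    lip <- classify_lipids(p$tc, p$hdl, p$on_lipid_meds, p$sex)
    drop <- classify_hypertension(p$sbp, p$dbp, p$on_htn_meds) |
      classify_diabetes(p$glucose, p$self_report_diabetes) |
      lip$hypercholesterolaemia | lip$low_hdl
  }
  keep <- p$id[!drop]
  cohort$participants <- p[!drop, , drop = FALSE]
  cohort$waves <- cohort$waves[cohort$waves$id %in% keep, , drop = FALSE]
  cohort$events <- cohort$events[cohort$events$id %in% keep, , drop = FALSE]
  cohort
}

# Split intervals [s, e) at multiples of `step`; returns expanded vectors.
split_at_grid <- function(id, s, e, step) {
  f <- floor(s / step); l <- ceiling(e / step - 1e-9)
  k <- pmax(1L, as.integer(l - f))
  idx <- rep.int(seq_along(s), k)
  j <- sequence(k) - 1L
  t0 <- pmax(s[idx], (f[idx] + j) * step)
  t1 <- pmin(e[idx], (f[idx] + j + 1) * step)
  keep <- t1 - t0 > 1e-9
  list(idx = idx[keep], t0 = t0[keep], t1 = t1[keep])
}

#' Build transition-specific person-time
#'
#' Converts a phenotyped cohort into the estimation rows of the
#' illness-death model.  Disease-free person-time contributes
#' simultaneously to the CVD-incidence (`h12`) and disease-free-mortality
#' (`h13`) transitions (the event flag set on the realised one); post-CVD
#' person-time contributes to `h23`.  Exposure is carried forward from the
#' most recent valid measurement wave, segments are split at every wave
#' where exposure updates and into `step`-year attained-age intervals, and
#' participants without any valid exposure measurement are dropped
#' (complete-case).  Same-age CVD and death is handled as CVD followed by
#' death after a one-day diseased sojourn, so fatal first events count as
#' both incidence and post-CVD death.
#'
#' @param cohort A `synthetic_cohort` (phenotyped internally if needed).
#' @param exposure_kind `"composite"`, `"wc_only"` or `"bmi_only"`.
#' @param step Age-splitting granularity in years (default 1).
#' @param age_window Optional `c(min, max)`: person-time is clipped to
#'   this attained-age window.
#' @param mapping Composite mapping, see [classify_adiposity()].
#' @return A `data.table` of class `person_time` with columns `id`, `sex`,
#'   `transition`, `tstart`, `tstop`, `event`, `category`; the cohort's
#'   baseline covariate table is attached as attribute `"participants"`,
#'   and complete-case exclusions as attribute `"complete_case"`.
#' @export
build_person_time <- function(cohort,
                              exposure_kind = c("composite", "wc_only",
                                                "bmi_only"),
                              step = 1, age_window = NULL,
                              mapping = adiposity_mapping()) {
  exposure_kind <- match.arg(exposure_kind)
  stopifnot(inherits(cohort, "synthetic_cohort"), step > 0)
  waves <- cohort$waves
  if (!"adiposity" %in% names(waves)) waves <- phenotype_waves(waves, mapping)
  expo_col <- switch(exposure_kind, composite = "adiposity",
                     wc_only = "wc_cat", bmi_only = "bmi_cat")
  levs <- switch(exposure_kind, composite = adiposity_levels(),
                 wc_only = wc_levels(), bmi_only = bmi_levels())

  wv <- data.table::as.data.table(
    waves[!is.na(waves[[expo_col]]), c("id", "age", expo_col)])
  data.table::setnames(wv, expo_col, "category")
  data.table::setkey(wv, id, age)

  ev <- data.table::as.data.table(cohort$events)
  p <- cohort$participants
  n_by_sex <- table(p$sex)
  cc_drop <- setdiff(p$id, unique(wv$id))
  cc <- data.frame(
    sex = names(n_by_sex),
    n = as.integer(n_by_sex),
    n_dropped = as.integer(table(factor(p$sex[p$id %in% cc_drop],
                                        levels = names(n_by_sex)))))
  cc$fraction <- cc$n_dropped / cc$n

  first_valid <- wv[, .(start = min(age)), by = id]
  ev <- merge(ev, first_valid, by = "id")  # drops complete-case exclusions
  if (any(!is.na(ev$age_cvd) & !is.na(ev$age_death) &
          ev$age_cvd > ev$age_death))
    stop("CVD after death in event table", call. = FALSE)
  # one-day diseased sojourn when CVD and death are recorded at the same age
  tie <- !is.na(ev$age_cvd) & !is.na(ev$age_death) &
    ev$age_cvd >= ev$age_death
  ev$age_death[tie] <- ev$age_cvd[tie] + 1 / 365.25

  end_death <- pmin(ifelse(is.na(ev$age_death), Inf, ev$age_death),
                    ev$age_censor)
  has_cvd <- !is.na(ev$age_cvd) & ev$age_cvd <= ev$age_censor
  end_healthy <- pmin(ifelse(has_cvd, ev$age_cvd, Inf), end_death)
  died <- !is.na(ev$age_death) & ev$age_death <= ev$age_censor

  spans <- rbind(
    data.table::data.table(id = ev$id, s = ev$start, e = end_healthy,
                           state = "healthy",
                           ev12 = has_cvd & ev$age_cvd >= ev$start,
                           ev23 = FALSE,
                           ev13 = !has_cvd & died),
    data.table::data.table(id = ev$id,
                           s = pmax(ifelse(has_cvd, ev$age_cvd, Inf),
                                    ev$start),
                           e = end_death, state = "cvd",
                           ev12 = FALSE, ev23 = died, ev13 = FALSE)
  )
  if (!is.null(age_window)) {
    spans[, `:=`(s = pmax(s, age_window[1]), e = pmin(e, age_window[2]))]
    # events beyond the window are not observed within it
    spans[e < ifelse(state == "healthy", end_healthy[match(id, ev$id)],
                     end_death[match(id, ev$id)]) - 1e-9,
          c("ev12", "ev13", "ev23") := FALSE]
  }
  spans <- spans[e - s > 1e-9]
  if (nrow(spans) == 0L) stop("no person-time to build", call. = FALSE)
  spans[, span_id := .I]

  # cut at exposure-update ages strictly inside each span
  cuts <- wv[spans, on = "id", allow.cartesian = TRUE][age > s & age < e,
             .(span_id = span_id, b = age)]
  bounds <- rbind(spans[, .(span_id, b = s)], cuts,
                  spans[, .(span_id, b = e)])
  data.table::setorder(bounds, span_id, b)
  pieces <- bounds[, .(t0 = b[-.N], t1 = b[-1]), by = span_id]
  pieces <- pieces[t1 - t0 > 1e-9]

  g <- split_at_grid(pieces$span_id, pieces$t0, pieces$t1, step)
  seg <- data.table::data.table(span_id = pieces$span_id[g$idx],
                                tstart = g$t0, tstop = g$t1)
  seg <- merge(seg, spans[, .(span_id, id, state, e, ev12, ev13, ev23)],
               by = "span_id", sort = FALSE)
  # LOCF category at segment start
  seg[, category := wv[seg, on = .(id, age = tstart), roll = Inf, x.category]]
  last <- abs(seg$tstop - seg$e) < 1e-9

  healthy <- seg[state == "healthy"]
  lh <- last[seg$state == "healthy"]
  cvd <- seg[state == "cvd"]
  lc <- last[seg$state == "cvd"]
  out <- data.table::rbindlist(list(
    healthy[, .(id, transition = "h12", tstart, tstop,
                event = ev12 & lh, category)],
    healthy[, .(id, transition = "h13", tstart, tstop,
                event = ev13 & lh, category)],
    cvd[, .(id, transition = "h23", tstart, tstop,
            event = ev23 & lc, category)]
  ))
  out[, event := as.integer(event)]
  out[, category := factor(as.character(category), levels = levs)]
  out[, sex := p$sex[match(id, p$id)]]
  data.table::setcolorder(out, c("id", "sex", "transition", "tstart",
                                 "tstop", "event", "category"))
  data.table::setattr(out, "participants", p)
  data.table::setattr(out, "complete_case", cc)
  data.table::setattr(out, "exposure_kind", exposure_kind)
  data.table::setattr(out, "class", c("person_time", class(out)))
  out[]
}
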