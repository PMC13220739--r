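# Shared fixtures built in code.

# A minimal hand-built cohort object for deterministic person-time tests.
# Anthropometry is constant within participant unless overridden, so each
# participant has a single known exposure category.
manual_cohort <- function(entry, age_cvd, age_death, age_censor,
                          sex = "men", weight = 70, height = 1.75, wc = 85,
                          waves_at = NULL) {
  n <- length(entry)
  sex <- rep_len(sex, n)
  weight <- rep_len(weight, n); height <- rep_len(height, n)
  wc <- rep_len(wc, n)
  if (is.null(waves_at)) waves_at <- lapply(entry, function(a) a)
  wv <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(id = i, wave = seq_along(waves_at[[i]]), sex = sex[i],
               age = waves_at[[i]], height = height[i], weight = weight[i],
               wc = wc[i])
  }))
  participants <- data.frame(id = seq_len(n), sex = sex, entry_age = entry,
                             cancer_history = FALSE, cancer_unknown = FALSE,
                             pregnant = FALSE)
  events <- data.frame(id = seq_len(n), age_cvd = age_cvd,
                       age_death = age_death, age_censor = age_censor)
  structure(list(participants = participants, waves = wv, events = events,
                 config = NULL, seed = NA),
            class = "synthetic_cohort")
}

# Config shortcuts: no exclusion extras, single sex, frozen hazards.
quick_config <- function(n, sex = "men", ...) {
  cohort_config(
    n_participants = n,
    fraction_women = if (sex == "women") 1 else 0,
    exclusion_counts = c(cancer_history = 0, cancer_unknown = 0,
                         pregnant = 0),
    ...
  )
}

# Null-effect hazard ratios (all categories exchangeable).
null_log_hr <- function() {
  z <- stats::setNames(rep(0, 4), adiposity_levels())
  list(men = list(h12 = z, h13 = z, h23 = z),
       women = list(h12 = z, h13 = z, h23 = z))
}

# Frozen static anthropometry (no drift/random walk between waves).
static_walk <- c(drift = 0, sd = 0)
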