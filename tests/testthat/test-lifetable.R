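test_that("prevalence tables cross-tabulate correctly", {
  # 50-person fixture, checked against a brute-force cross-tabulation
  set.seed(50)
  n <- 50
  entry <- runif(n, 50, 70)
  cvd <- ifelse(runif(n) < 0.3, entry + runif(n, 0, 5), NA)
  ch <- manual_cohort(entry = entry, age_cvd = cvd,
                      age_death = rep(NA_real_, n),
                      age_censor = entry + 22,
                      weight = runif(n, 55, 110),
                      height = runif(n, 1.5, 1.95),
                      wc = runif(n, 70, 120))
  prev <- suppressWarnings(estimate_prevalences(ch))  # sparse cells borrow
  wv <- phenotype_waves(ch$waves)
  has_cvd <- !is.na(cvd) & wv$age >= cvd
  band <- ifelse(wv$age < 60, 50, ifelse(wv$age < 70, 60, 70))
  for (b in unique(band)) for (st in c(FALSE, TRUE)) {
    i <- band == b & has_cvd == st & wv$age < 80
    if (!sum(i)) next
    expected <- table(factor(as.character(wv$adiposity[i]),
                             levels = adiposity_levels()))
    got <- prev[prev$band == b & prev$cvd == st & !prev$borrowed, ]
    if (nrow(got) == 0) next
    expect_equal(got$n, as.integer(expected))
    expect_equal(got$p, as.numeric(expected / sum(expected)))
  }
  # probability vectors sum to one in every cell
  agg <- aggregate(p ~ sex + band + cvd, data = prev, sum)
  expect_true(all(abs(agg$p - 1) < 1e-12))
})

test_that("degenerate single-category cohorts give degenerate prevalences", {
  ch <- manual_cohort(entry = rep(55, 20), age_cvd = rep(NA_real_, 20),
                      age_death = rep(NA_real_, 20),
                      age_censor = rep(77, 20),
                      weight = 70, height = 1.75, wc = 85)  # all "low"
  suppressWarnings(expect_warning(prev <- estimate_prevalences(ch),
                                  "borrowing"))
  cell <- prev[prev$band == 50 & prev$cvd == FALSE, ]
  expect_equal(cell$p, c(1, 0, 0, 0))
})

test_that("rate calibration solves the prevalence-weighting identity", {
  # two-category hand oracle: p = (1/2, 1/2), HR = (1, 3), overall 0.02
  prev2 <- structure(
    data.frame(sex = "men", band = 50, cvd = FALSE,
               category = c("a", "b"), n = c(5, 5), p = c(0.5, 0.5),
               borrowed = FALSE),
    class = c("prevalence_table", "data.frame"), bands = 50)
  r <- calibrate_category_rates(0.02, c(a = 1, b = 3), prev2, "men",
                                cvd = FALSE, ages = 50)
  expect_equal(unname(r[1, ]), c(0.01, 0.03))
  # all HR = 1 reduces to the overall rate
  r1 <- calibrate_category_rates(0.02, c(a = 1, b = 1), prev2, "men",
                                 cvd = FALSE, ages = 50)
  expect_equal(unname(r1[1, ]), c(0.02, 0.02))
  expect_error(calibrate_category_rates(0.02, c(a = 0, b = 0), prev2,
                                        "men", FALSE, 50), "positive")
})

test_that("calibration identity holds to 1e-12 on an estimated pipeline", {
  ch <- generate_cohort(quick_config(2500), seed = 51)
  ch$waves <- phenotype_waves(ch$waves)
  st <- le_pipeline(ch, adjust = character())
  prev <- st$prev
  for (tr in c("h12", "h23")) {
    ov <- st$overall$men[[tr]]
    hr <- stats::setNames(st$hrs$men[[tr]]$hr, st$hrs$men[[tr]]$category)
    rates <- calibrate_category_rates(ov, hr, prev, "men",
                                      cvd = (tr == "h23"))
    for (a in c(50, 57, 63, 79)) {
      p <- prev$p[prev$sex == "men" & prev$cvd == (tr == "h23") &
                    prev$band == ifelse(a < 60, 50, ifelse(a < 70, 60, 70))]
      lhs <- sum(p * rates[as.character(a), ])
      expect_equal(lhs, unname(gompertz_rate(ov, a + 0.5)),
                   tolerance = 1e-12)
    }
  }
})

test_that("zero hazards yield exactly 30 disease-free years", {
  lt <- build_lifetable(0, 0, 0)
  le <- le_decompose(lt)
  expect_identical(unname(le["cvd_free_le"]), 30)
  expect_identical(unname(le["with_cvd_le"]), 0)
  expect_identical(unname(le["total_le"]), 30)
  expect_true(all(lt$l_healthy == 1))
})

test_that("single-decrement table matches the closed-form expectancy", {
  # only background mortality at constant rate m: temporary LE over 30y
  for (m in c(0.01, 0.03, 0.08)) {
    lt <- build_lifetable(0, m, 0)
    le <- le_decompose(lt)
    closed <- (1 - exp(-30 * m)) / m
    expect_lt(abs(le["total_le"] - closed), 0.05)
    expect_equal(unname(le["with_cvd_le"]), 0)
  }
})

test_that("occupancies conserve mass and are monotone", {
  set.seed(52)
  for (rep in 1:5) {
    r12 <- runif(30, 0, 0.05); r13 <- runif(30, 0, 0.04)
    r23 <- runif(30, 0, 0.1)
    lt <- build_lifetable(r12, r13, r23, init_cvd = runif(1, 0, 0.2))
    tot <- lt$l_healthy + lt$l_cvd + lt$l_dead
    expect_true(all(abs(tot - 1) < 1e-12))
    expect_true(all(diff(lt$l_healthy) <= 1e-15))
    expect_true(all(diff(lt$l_dead) >= -1e-15))
    expect_true(all(lt$q12 >= 0 & lt$q12 <= 1))
    expect_true(all(1 - lt$q12 - lt$q13 >= 0))
  }
  expect_error(build_lifetable(-0.01, 0, 0), "negative")
  expect_error(build_lifetable(c(0.01, NA), 0.01, 0.01), "finite|missing")
})

test_that("halving the interval step moves LE by less than 0.02 years", {
  # cohort-scale hazards (the calibrated generator defaults)
  r12 <- 0.0040 * exp(0.070 * (0:29)); r13 <- 0.0008 * exp(0.098 * (0:29))
  r23 <- 0.0045 * exp(0.087 * (0:29))
  le1 <- le_decompose(build_lifetable(r12, r13, r23, step = 1))
  half <- rep(seq_len(30), each = 2)
  le2 <- le_decompose(build_lifetable(r12[half], r13[half], r23[half],
                                      step = 0.5))
  expect_true(all(abs(le1 - le2) < 0.02))
})

test_that("discrete-flow accounting stays close to the exact kernel", {
  r12 <- 0.0040 * exp(0.070 * (0:29)); r13 <- 0.0008 * exp(0.098 * (0:29))
  r23 <- 0.0045 * exp(0.087 * (0:29))
  ex <- build_lifetable(r12, r13, r23, init_cvd = 0.03)
  di <- build_lifetable(r12, r13, r23, init_cvd = 0.03,
                        method = "discrete")
  expect_identical(ex$q12, di$q12)  # reported q's share one definition
  expect_true(all(abs(di$l_healthy + di$l_cvd + di$l_dead - 1) < 1e-12))
  expect_true(all(abs(le_decompose(ex) - le_decompose(di)) < 0.05))
})

test_that("life table agrees with an independent microsimulation", {
  r12 <- 0.0040 * exp(0.070 * (0:29)); r13 <- 0.0008 * exp(0.098 * (0:29))
  r23 <- 0.0045 * exp(0.087 * (0:29))
  lt <- le_decompose(build_lifetable(r12, r13, r23, init_cvd = 0.05))
  ms <- microsimulate_le(r12, r13, r23, n = 2e5, init_cvd = 0.05,
                         seed = 53)
  for (q in names(lt))
    expect_lt(abs(lt[q] - ms$le[q]), 3 * ms$se[q] + 0.01)
})

test_that("identical hazards give identical triples across categories", {
  prev4 <- structure(
    data.frame(sex = "men", band = rep(c(50, 60, 70), each = 4),
               cvd = FALSE,
               category = rep(adiposity_levels(), 3),
               n = 25, p = 0.25, borrowed = FALSE),
    class = c("prevalence_table", "data.frame"), bands = c(50, 60, 70))
  prev4 <- rbind(prev4, transform(prev4, cvd = TRUE))
  attr(prev4, "bands") <- c(50, 60, 70)
  class(prev4) <- c("prevalence_table", "data.frame")
  hr1 <- stats::setNames(rep(1, 4), adiposity_levels())
  les <- sapply(adiposity_levels(), function(cat) {
    r12 <- calibrate_category_rates(function(a) 0.01 * exp(0.06 * (a - 50)),
                                    hr1, prev4, "men", FALSE)[, cat]
    r13 <- calibrate_category_rates(function(a) 0.005 * exp(0.09 * (a - 50)),
                                    hr1, prev4, "men", FALSE)[, cat]
    r23 <- calibrate_category_rates(function(a) 0.02 * exp(0.08 * (a - 50)),
                                    hr1, prev4, "men", TRUE)[, cat]
    le_decompose(build_lifetable(r12, r13, r23))
  })
  for (j in 2:4) expect_equal(les[, j], les[, 1], tolerance = 1e-12)
})

test_that("raising the incidence hazard monotonically erodes disease-free LE", {
  r13 <- 0.005 * exp(0.09 * (0:29)); r23 <- 0.03 * exp(0.07 * (0:29))
  base12 <- 0.01 * exp(0.06 * (0:29))
  free <- sapply(c(0.5, 1, 1.5, 2, 3), function(hr)
    le_decompose(build_lifetable(base12 * hr, r13, r23))["cvd_free_le"])
  expect_true(all(diff(free) < 0))
  # difference helpers
  le <- le_decompose(build_lifetable(base12, r13, r23))
  expect_equal(unname(le_difference(le, le)), c(0, 0, 0))
  expect_equal(unname(le["total_le"]),
               unname(le["cvd_free_le"] + le["with_cvd_le"]))
})
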