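# biomarkers: incremental AUC, post-meal steps, HbA1c mapper,
# elevated/normal classification.

test_that("mgr_3h handles zero and negative excursions", {
  m <- seq(0, 180, by = 15)
  expect_equal(mgr_3h(m, rep(100, length(m)), 100), 0)
  expect_equal(mgr_3h(m, rep(80, length(m)), 100), 0)   # clipped below baseline
  expect_error(mgr_3h(0, 100, 100), "at least 2")
  expect_error(mgr_3h(c(0, 200), c(100, 100), 100), "0-180")
})

test_that("mgr_3h is exact on piecewise-linear traces sampled at nodes", {
  # triangle: baseline 100, peak 160 at 90 min, back to 100 at 180 min
  m <- seq(0, 180, by = 15)
  v <- ifelse(m <= 90, 100 + 60 * m / 90, 160 - 60 * (m - 90) / 90)
  got <- mgr_3h(m, v, 100)
  expect_equal(got, 0.5 * 180 * 60)                     # triangle area
  expect_equal(got, oracle_iauc_samples(m, v, 100), tolerance = 1e-12)
})

test_that("mgr_3h tracks a 1-min Riemann oracle within 2% on smooth bells", {
  set.seed(7)
  for (i in 1:20) {
    amp <- runif(1, 30, 120); tp <- runif(1, 30, 70); s <- runif(1, 0.3, 0.7)
    base <- runif(1, 80, 110)
    f <- function(u) base + amp * exp(-(log(pmax(u, 1e-9) / tp))^2 / (2 * s^2))
    m <- seq(0, 180, by = 15)
    got <- mgr_3h(m, f(m), base)
    oracle <- oracle_iauc_fun(f, base)
    expect_lt(abs(got - oracle) / oracle, 0.02)
  }
})

test_that("mgr_3h is monotone under pointwise increase of the segment", {
  set.seed(8)
  m <- seq(0, 180, by = 15)
  for (i in 1:20) {
    v <- 100 + cumsum(rnorm(length(m), 0, 8))
    bump <- abs(rnorm(length(m), 2, 2))
    expect_gte(mgr_3h(m, v + bump, 100), mgr_3h(m, v, 100))
  }
})

test_that("post-meal steps sum the half-open hour and respect wear", {
  st <- mk_steps(rep(0L, 1440))
  t0 <- T0("2024-03-05T12:00")
  expect_equal(post_meal_steps(st, t0), 0L)
  st2 <- mk_steps(rep(100L, 1440))
  expect_equal(post_meal_steps(st2, t0), 6000L)         # 100/min for 60 min
  # boundary: minute at +60 is excluded
  st3 <- mk_steps(c(rep(0L, 780), rep(1L, 660)))        # steps from 13:00
  expect_equal(post_meal_steps(st3, t0), 0L)
  # unworn hour -> absent
  wear <- rep(TRUE, 1440); wear[721:781] <- FALSE
  st4 <- mk_steps(rep(5L, 1440), wear = wear)
  expect_true(is.na(post_meal_steps(st4, t0)))
})

mk_cohort_mgr <- function(mean_mgrs, hba1c, status = NULL) {
  pids <- sprintf("P%02d", seq_along(mean_mgrs))
  list(events = data.frame(participant_id = pids, mgr_3h = mean_mgrs,
                           stringsAsFactors = FALSE),
       participants = data.frame(participant_id = pids, hba1c = hba1c,
                                 status = status %||%
                                   rep("prediabetes", length(pids)),
                                 stringsAsFactors = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mapper recovers a noise-free linear relation exactly", {
  mgr <- c(1000, 2000, 3000, 4000, 5500, 7000)
  cc <- mk_cohort_mgr(mgr, 4.6 + 4e-4 * mgr)
  mp <- fit_hba1c_mapper(cc$events, cc$participants)
  expect_equal(mp$coefficients[1], 4.6, tolerance = 1e-6)
  expect_equal(mp$coefficients[2], 4e-4, tolerance = 1e-6)
  expect_true(mp$monotone)
  expect_equal(mp$diagnostics$pearson_r, 1, tolerance = 1e-9)
})

test_that("Huber fit resists an extreme outlier better than least squares", {
  set.seed(12)
  mgr <- runif(30, 500, 7000)
  h <- 4.6 + 4e-4 * mgr + rnorm(30, 0, 0.1)
  clean <- mk_cohort_mgr(mgr, h)
  slope_clean <- fit_hba1c_mapper(clean$events, clean$participants)$coefficients[2]
  mgr2 <- c(mgr, 6500); h2 <- c(h, 13)                  # wild outlier
  dirty <- mk_cohort_mgr(mgr2, h2)
  slope_huber <- fit_hba1c_mapper(dirty$events, dirty$participants)$coefficients[2]
  slope_ols_clean <- coef(lm(h ~ mgr))[2]
  slope_ols_dirty <- coef(lm(h2 ~ mgr2))[2]
  expect_lt(abs(slope_huber - slope_clean),
            abs(slope_ols_dirty - slope_ols_clean))
})

test_that("degenerate mapper inputs error", {
  cc <- mk_cohort_mgr(rep(3000, 5), runif(5, 5, 7))
  expect_error(fit_hba1c_mapper(cc$events, cc$participants), "zero variance")
  cc2 <- mk_cohort_mgr(c(100, 200), c(5, 6))
  expect_error(fit_hba1c_mapper(cc2$events, cc2$participants), ">= 3")
})

test_that("classification thresholds follow diabetes status, boundaries inclusive", {
  mgr <- c(1000, 3000, 5000)
  cc <- mk_cohort_mgr(mgr, 4.6 + 4e-4 * mgr)
  mp <- fit_hba1c_mapper(cc$events, cc$participants)
  # worked example: mapped HbA1c 6.0 is elevated for prediabetes
  mgr_60 <- (6.0 - mp$coefficients[1]) / mp$coefficients[2]
  expect_equal(classify_event(mgr_60, mp, "prediabetes")$label, "elevated")
  # the same meal is normal for a T2D participant (6.0 < 6.5)
  expect_equal(classify_event(mgr_60, mp, "t2d")$label, "normal")
  # boundary 5.7 exactly: elevated for at-risk
  mgr_57 <- (5.7 - mp$coefficients[1]) / mp$coefficients[2]
  expect_equal(classify_event(mgr_57, mp, "at_risk")$label, "elevated")
  just_below <- classify_event(mgr_57 - 1, mp, "at_risk")$label
  expect_equal(just_below, "normal")
  # boundary 6.5 for T2D
  mgr_65 <- (6.5 - mp$coefficients[1]) / mp$coefficients[2]
  expect_equal(classify_event(mgr_65, mp, "t2d")$label, "elevated")
  expect_error(classify_event(1000, mp, "diabetic"), "status")
  expect_error(classify_event(1000, structure(list(), class = "list"),
                              "t2d"), "not fitted")
})

test_that("classification is monotone in MGR for a monotone mapper", {
  mgr <- c(1000, 3000, 5000)
  cc <- mk_cohort_mgr(mgr, 4.6 + 4e-4 * mgr)
  mp <- fit_hba1c_mapper(cc$events, cc$participants)
  xs <- seq(0, 9000, by = 250)
  for (st in c("at_risk", "prediabetes", "t2d")) {
    lab <- classify_event(xs, mp, st)$label
    expect_true(all(diff(lab == "elevated") >= 0), info = st)
  }
})

test_that("compute_meal_biomarkers assembles steps, labels and the mapper", {
  sim <- quick_cohort(seed = 41, n_participants = 5, n_days = 4)
  seg <- segment_meal_events(sim$bundle)
  bm <- compute_meal_biomarkers(seg$events, sim$bundle$steps,
                                sim$bundle$participants)
  expect_s3_class(bm$mapper, "hba1c_mapper")
  expect_true(all(bm$biomarkers$label %in% c("elevated", "normal")))
  expect_true(all(bm$biomarkers$mgr_3h >= 0))
  expect_true(all(bm$biomarkers$post_meal_steps >= 0, na.rm = TRUE))
})
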