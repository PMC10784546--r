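# causal: propensity weights, balance, doubly robust estimation.

daily_task <- function(outcome = "tir")
  causal_task("daily_steps_k",
              c("baseline_glucose", "elevated_count", "duration"), outcome)

cat_task <- function(outcome = "tir")
  causal_task("elevated_count",
              c("baseline_glucose", "duration", "daily_steps_k"), outcome,
              treatment_type = "categorical")

test_that("task validation catches treatment/covariate overlap and columns", {
  expect_error(causal_task("x", c("x", "y"), "z"), "must not appear")
  d <- data.frame(a = 1, participant_id = "P")
  expect_error(estimate_effect(d, causal_task("t", "c", "y")), "missing")
})

test_that("stabilized continuous weights are near 1 when treatment is independent of X", {
  cvs <- vapply(1:10, function(s) {
    set.seed(s + 700)
    d <- simulate_daily_outcome_cohort(confounding_strength = 0,
                                       sd_participant_trt = 0)
    w <- propensity_weights_continuous(d$data, daily_task())
    expect_true(all(w > 0))
    sd(w) / mean(w)
  }, 0)
  expect_lt(median(cvs), 0.1)                           # cv < 0.1 at n ~ 400
})

test_that("perfectly predicted treatment is caught by the density floor and truncation", {
  set.seed(72)
  d <- simulate_daily_outcome_cohort()
  dd <- d$data
  dd$daily_steps_k <- 2 + 0.1 * dd$baseline_glucose     # deterministic in X
  w <- suppressWarnings(propensity_weights_continuous(dd, daily_task()))
  expect_true(all(is.finite(w) & w > 0))
})

test_that("weights are deterministic given the data", {
  set.seed(73)
  d <- simulate_daily_outcome_cohort()
  w1 <- propensity_weights_continuous(d$data, daily_task())
  w2 <- propensity_weights_continuous(d$data, daily_task())
  expect_identical(as.numeric(w1), as.numeric(w2))
  wc1 <- propensity_weights_categorical(d$data, cat_task())
  wc2 <- propensity_weights_categorical(d$data, cat_task())
  expect_identical(as.numeric(wc1), as.numeric(wc2))
})

test_that("categorical weights approach 1/share under uninformative covariates", {
  set.seed(74)
  d <- simulate_daily_outcome_cohort(n_participants = 72,
                                     confounding_strength = 0,
                                     sd_participant_trt = 0)
  w <- propensity_weights_categorical(d$data, cat_task(), stabilize = FALSE,
                                      truncate = NULL, mixed = FALSE)
  shares <- prop.table(table(d$data$elevated_count))
  for (lv in names(shares)) {
    wl <- as.numeric(w)[d$data$elevated_count == lv]
    expect_equal(mean(wl), 1 / shares[[lv]], tolerance = 0.12, info = lv)
    expect_lt(sd(wl) / mean(wl), 0.35)                  # near-equal in category
  }
})

test_that("weighted SMD matches hand arithmetic on a 6-row table", {
  d <- data.frame(participant_id = rep(c("A", "B"), 3),
                  t = factor(c("0", "0", "0", "1", "1", "1")),
                  x = c(1, 2, 3, 4, 5, 9),
                  y = rnorm(6))
  task <- causal_task("t", "x", "y", treatment_type = "categorical")
  w <- c(1, 1, 2, 1, 2, 1)
  b <- check_balance(d, task, w)
  # weighted means: g0 = (1+2+6)/4 = 2.25, g1 = (4+10+9)/4 = 5.75
  # weighted vars:  g0 = (1*1.5625 + 1*0.0625 + 2*0.5625)/4 = 0.6875
  #                 g1 = (1*3.0625 + 2*0.5625 + 1*10.5625)/4 = 3.6875
  # |smd| = 3.5/sqrt((0.6875+3.6875)/2) = 3.5/sqrt(2.1875)
  expect_equal(b$weighted, 3.5 / sqrt(2.1875), tolerance = 1e-9)
})

test_that("balance fails before weighting and passes after in the default scenario", {
  set.seed(75)
  d <- simulate_daily_outcome_cohort()
  task <- daily_task()
  before <- check_balance(d$data, task, NULL)
  expect_false(all(before$pass))
  w <- propensity_weights_continuous(d$data, task)
  after <- check_balance(d$data, task, w)
  expect_true(all(after$pass))
  expect_lt(max(abs(after$weighted)), max(abs(before$unweighted)))
})

test_that("zero-variance covariates are excluded from the balance report", {
  set.seed(76)
  d <- simulate_daily_outcome_cohort()
  dd <- d$data; dd$const <- 1
  task <- causal_task("daily_steps_k", c("baseline_glucose", "const"), "tir")
  b <- check_balance(dd, task, NULL)
  expect_false("const" %in% b$covariate)
  expect_match(attr(b, "notes"), "zero variance")
})

test_that("noise-free planted model is recovered exactly", {
  set.seed(77)
  d <- simulate_daily_outcome_cohort(confounding_strength = 0, sd_tir = 0,
                                     sd_participant_out = 0)
  e <- estimate_effect(d$data, daily_task(), doubly_robust = TRUE)
  expect_equal(e$estimate, d$truth$b_steps_tir, tolerance = 1e-6)
  e2 <- estimate_effect(d$data, cat_task(), doubly_robust = TRUE)
  expect_equal(e2$estimate, d$truth$b_cat_tir[2:4], tolerance = 1e-6)
  expect_equal(e2$term, c("0 vs 1", "0 vs 2", "0 vs 3+"))
})

test_that("unit weights reproduce the ordinary mixed-model fit exactly", {
  set.seed(78)
  d <- simulate_daily_outcome_cohort()
  task <- daily_task()
  e_null <- estimate_effect(d$data, task, weights = NULL,
                            doubly_robust = TRUE)
  e_one <- estimate_effect(d$data, task, weights = rep(1, nrow(d$data)),
                           doubly_robust = TRUE, se_type = "model")
  expect_equal(e_one$estimate, e_null$estimate, tolerance = 1e-10)
  expect_equal(e_one$se, e_null$se, tolerance = 1e-10)
  # and matches a direct lme4 fit
  ref <- lme4::lmer(tir ~ daily_steps_k + baseline_glucose + elevated_count +
                      duration + (1 | participant_id), data = d$data)
  expect_equal(e_null$estimate,
               unname(lme4::fixef(ref)["daily_steps_k"]), tolerance = 1e-6)
})

test_that("coefficients are scale-equivariant in treatment units", {
  set.seed(79)
  d <- simulate_daily_outcome_cohort()
  dd <- d$data
  task <- daily_task()
  w <- propensity_weights_continuous(dd, task)
  e1 <- estimate_effect(dd, task, w, doubly_robust = TRUE)
  dd2 <- dd; dd2$daily_steps_k <- dd2$daily_steps_k * 2   # steps in 500s
  e2 <- estimate_effect(dd2, task, w, doubly_robust = TRUE)
  expect_equal(e2$estimate, e1$estimate / 2, tolerance = 1e-8)
})

test_that("doubly robust estimation tolerates single-model misspecification", {
  # propensity misspecified (weights from noise), outcome model correct
  res <- vapply(1:8, function(s) {
    set.seed(s + 900)
    d <- simulate_daily_outcome_cohort()
    n <- nrow(d$data)
    junk <- exp(rnorm(n, 0, 0.3))                        # useless weights
    estimate_effect(d$data, daily_task(), junk,
                    doubly_robust = TRUE)$estimate
  }, 0)
  expect_lt(abs(mean(res) - 0.07), 0.25)
  # outcome model misspecified (no covariates), propensity correct
  res2 <- vapply(1:8, function(s) {
    set.seed(s + 900)
    d <- simulate_daily_outcome_cohort()
    w <- propensity_weights_continuous(d$data, daily_task())
    estimate_effect(d$data, daily_task(), w,
                    doubly_robust = FALSE)$estimate
  }, 0)
  naive <- vapply(1:8, function(s) {
    set.seed(s + 900)
    d <- simulate_daily_outcome_cohort()
    estimate_effect(d$data, daily_task(), NULL,
                    doubly_robust = FALSE)$estimate
  }, 0)
  expect_lt(abs(mean(res2) - 0.07), abs(mean(naive) - 0.07))
})

test_that("p-values live in (0, 1] and drive the significance flag at 0.01", {
  set.seed(80)
  d <- simulate_daily_outcome_cohort()
  e <- estimate_effect(d$data, cat_task(), doubly_robust = TRUE)
  expect_true(all(e$p_value > 0 & e$p_value <= 1))
  expect_equal(e$significant, e$p_value < 0.01)
})

test_that("run_study_analyses handles degenerate and standard inputs", {
  sim <- quick_cohort(seed = 91, n_participants = 6, n_days = 6)
  seg <- segment_meal_events(sim$bundle)
  bm <- compute_meal_biomarkers(seg$events, sim$bundle$steps,
                                sim$bundle$participants)
  days <- build_day_records(bm$biomarkers, sim$bundle$glucose,
                            sim$bundle$steps)
  res <- run_study_analyses(days, bm$biomarkers, mixed_propensity = FALSE)
  expect_named(res, c("elevated_count", "daily_steps", "post_meal_steps",
                      "calories"))
  # degenerate: force a single elevated-count category
  days0 <- days
  days0$elevated_count_category <- factor("0", levels = cgmeal:::ELEVATED_LEVELS)
  res0 <- run_study_analyses(days0, bm$biomarkers, mixed_propensity = FALSE)
  expect_false(res0$elevated_count$estimable)
  expect_match(res0$elevated_count$reason, "categories")
  # degenerate: no qualifying meal rows
  bm0 <- bm$biomarkers; bm0$high_agreement <- FALSE
  resm <- run_study_analyses(days, bm0, mixed_propensity = FALSE)
  expect_false(resm$post_meal_steps$estimable)
})
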