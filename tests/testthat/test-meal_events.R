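# meal_events: log merging, DBSCAN aggregation, start-time selection,
# qualification, inter-annotator agreement.

mk_logs <- function(times, occasions, pid = "P01", calories = 100) {
  data.frame(participant_id = pid, log_time = T0(times),
             occasion = occasions, item_name = "item",
             calories = calories, carbs_g = 10, protein_g = 5, fat_g = 3,
             stringsAsFactors = FALSE)
}

test_that("staged breakfast items merge into one meal timed at the first log", {
  # oatmeal 10:00, orange juice 10:15 -> one meal at 10:00
  m <- merge_food_logs(mk_logs(c("2024-03-05T10:00", "2024-03-05T10:15"),
                               c("breakfast", "breakfast"),
                               calories = c(150, 110)))
  expect_equal(nrow(m), 1)
  expect_equal(cgmeal:::mt_format(m$merged_time), "2024-03-05T10:00")
  expect_equal(m$total_calories, 260)
})

test_that("different occasions never merge even within the window", {
  m <- merge_food_logs(mk_logs(c("2024-03-05T08:00", "2024-03-05T08:30"),
                               c("breakfast", "lunch")))
  expect_equal(nrow(m), 2)
})

test_that("merging is anchored at each group's first log, not chained", {
  m <- merge_food_logs(mk_logs(
    c("2024-03-05T10:00", "2024-03-05T10:59", "2024-03-05T11:30"),
    rep("breakfast", 3)))
  expect_equal(nrow(m), 2)
  expect_equal(sort(m$n_logs), c(1L, 2L))
  expect_equal(sort(cgmeal:::mt_format(m$merged_time)),
               c("2024-03-05T10:00", "2024-03-05T11:30"))
})

test_that("dbscan_1d matches a brute-force reference on random inputs", {
  # independent reference implementation (naive, quadratic)
  ref_dbscan <- function(x, eps, min_pts) {
    n <- length(x)
    nb <- lapply(seq_len(n), function(i) which(abs(x - x[i]) <= eps))
    core <- sapply(nb, length) >= min_pts
    lab <- rep(0L, n); cl <- 0L
    repeat {
      seed <- which(core & lab == 0L)[1]
      if (is.na(seed)) break
      cl <- cl + 1L
      members <- seed
      repeat {
        grow <- unique(unlist(nb[members[core[members]]]))
        grow <- setdiff(grow, members)
        if (!length(grow)) break
        members <- c(members, grow)
      }
      lab[members[lab[members] == 0L]] <- cl
      core[members] <- core[members] & TRUE
      lab[seed] <- cl
    }
    lab
  }
  same_partition <- function(a, b) {
    identical(a == 0L, b == 0L) &&
      all(tapply(b[a != 0], a[a != 0], function(v) length(unique(v))) == 1) &&
      all(tapply(a[b != 0], b[b != 0], function(v) length(unique(v))) == 1)
  }
  set.seed(42)
  for (rep in 1:30) {
    x <- sort(round(runif(sample(1:12, 1), 0, 24), 2))
    eps <- runif(1, 0.3, 3)
    mp <- sample(2:3, 1)
    expect_true(same_partition(dbscan_1d(x, eps, mp), ref_dbscan(x, eps, mp)),
                info = paste("rep", rep))
  }
})

test_that("aggregation applies minimum support and 1.5-h separation", {
  mk_ann <- function(times, ann = "A1", src = "added") {
    data.frame(participant_id = "P01", annotator_id = ann, source = src,
               log_key = NA_character_, time = T0(times),
               stringsAsFactors = FALSE)
  }
  # a lone timing is DBSCAN noise
  expect_equal(nrow(aggregate_annotations(mk_ann("2024-03-05T08:00"))), 0)
  # four timings within 10 min form one group of 4
  g <- aggregate_annotations(mk_ann(paste0("2024-03-05T08:0", c(0, 3, 6, 9)),
                                    ann = paste0("A", 1:4)))
  expect_equal(nrow(g), 4)
  expect_equal(length(unique(g$group_id)), 1)
  # two pairs 3 h apart stay separate
  g2 <- aggregate_annotations(mk_ann(c("2024-03-05T08:00", "2024-03-05T08:10",
                                       "2024-03-05T11:00", "2024-03-05T11:10"),
                                     ann = c("A1", "A2", "A1", "A2")))
  expect_equal(length(unique(g2$group_id)), 2)
  # permutation invariance in annotator/row order
  an <- mk_ann(c("2024-03-05T08:00", "2024-03-05T08:10", "2024-03-05T12:00",
                 "2024-03-05T12:05"), ann = c("A1", "A2", "A3", "A4"))
  g3 <- aggregate_annotations(an)
  g4 <- aggregate_annotations(an[sample(nrow(an)), ])
  key <- function(g) sort(vapply(split(g, g$group_id), function(s)
    paste(sort(cgmeal:::mt_format(s$time)), collapse = ","), ""))
  expect_equal(unname(key(g3)), unname(key(g4)))
})

test_that("select_start_time picks the timing with the largest 3-h iAUC", {
  # two bumps: candidate A (09:00) precedes a large excursion, candidate B
  # (12:00) sits after it, before a small one
  grid <- seq(0, 1439, by = 15)
  f <- function(m) 100 + 80 * exp(-((m - 600) / 40)^2) +
    15 * exp(-((m - 800) / 40)^2)
  trace <- mk_glucose(grid, f(grid))
  cand <- T0(c("2024-03-05T09:00", "2024-03-05T12:00"))
  sel <- select_start_time(cand, trace)
  # brute-force oracle over both candidates
  ia <- vapply(c(540, 720), function(s)
    oracle_iauc_fun(function(u) f(s + u), f(s)), 0)
  expect_gt(ia[1], ia[2])
  expect_equal(sel$start_time, cand[1])

  # identical timings: that timing; exact ties: earliest
  sel2 <- select_start_time(T0(rep("2024-03-05T09:00", 3)), trace)
  expect_equal(sel2$start_time, T0("2024-03-05T09:00"))
  flat <- mk_glucose(grid, rep(100, length(grid)))
  sel3 <- select_start_time(T0(c("2024-03-05T10:00", "2024-03-05T07:00")),
                            flat)
  expect_equal(sel3$start_time, T0("2024-03-05T07:00"))
})

test_that("qualification enforces the 18.6 mg/dL rise threshold inclusively", {
  grid <- seq(0, 1439, by = 15)
  mk_case <- function(amp) {
    vals <- rep(100, length(grid))
    vals[grid >= 600 & grid <= 720] <- 100 + amp
    trace <- mk_glucose(grid, vals)
    an <- data.frame(participant_id = "P01", annotator_id = c("A1", "A2"),
                     source = "added", log_key = NA_character_,
                     time = T0(rep("2024-03-05T09:44", 2)),
                     stringsAsFactors = FALSE)
    qualify_events(aggregate_annotations(an), trace,
                   merge_food_logs(empty_food_logs()))
  }
  expect_equal(nrow(mk_case(18.6)), 1)    # boundary inclusive
  expect_equal(nrow(mk_case(18.5)), 0)
  expect_equal(nrow(mk_case(0)), 0)       # flat trace: no events
  ev <- mk_case(50)
  expect_true(all(ev$max_rise >= 18.6))
})

test_that("events link to the majority log and flag high agreement", {
  sim <- quick_cohort(seed = 21, n_participants = 3, n_days = 3,
                      p_missing_log = 0, p_batch_day = 0)
  seg <- segment_meal_events(sim$bundle)
  ev <- seg$events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$max_rise >= 18.6))
  expect_true(all(cgmeal:::mt_minute_of_day(ev$start_time) >= 240))
  expect_gt(mean(ev$high_agreement), 0.5)
  expect_true(all(ev$merged_id[!is.na(ev$merged_id)] %in%
                    seg$merged_logs$merged_id))
})

test_that("synthetic meals are recovered with small start-time error", {
  sim <- quick_cohort(seed = 31, n_participants = 4, n_days = 4,
                      p_missing_log = 0, p_batch_day = 0, snack_prob = 0)
  set.seed(32)
  sim$bundle$annotations <- simulate_annotators(sim$bundle, sim$truth,
                                                jitter_sd = 5, p_unknown = 0)
  seg <- segment_meal_events(sim$bundle)
  cfg <- attr(sim$truth, "config")
  # qualifying = clearly above the rise threshold AND observable: meals on
  # the sensor-free parts of the first/last day have no excursion to find
  traces <- split(sim$bundle$glucose, sim$bundle$glucose$participant_id)
  observable <- vapply(seq_len(nrow(sim$truth)), function(i) {
    ev <- cgmeal:::eval_candidate(traces[[sim$truth$participant_id[i]]],
                                  sim$truth$start_time[i],
                                  cfg$cgm_interval_min)
    isTRUE(ev$ok)
  }, TRUE)
  qualifying <- sim$truth[true_amplitude(sim$truth, cfg) >= 25 & observable, ]
  err <- vapply(seq_len(nrow(qualifying)), function(i) {
    ev <- seg$events[seg$events$participant_id ==
                       qualifying$participant_id[i], ]
    if (!nrow(ev)) return(Inf)
    min(abs(as.numeric(difftime(ev$start_time, qualifying$start_time[i],
                                units = "mins"))))
  }, 0)
  expect_gt(nrow(qualifying), 20)
  expect_gte(mean(err <= 15), 0.95)
})

test_that("ICC(2,1) matches hand-derived values", {
  # perfect agreement
  M <- cbind(1:10, 1:10, 1:10)
  expect_equal(intraclass_correlation(M), 1)
  # worked 3x3 matrix; oracle from two-way ANOVA mean squares computed
  # independently (MSR 25.52778, MSC 3.527778, MSE 0.0277778)
  W <- rbind(c(9, 10, 11), c(6, 7, 8), c(3, 4, 5.5))
  expect_equal(intraclass_correlation(W), 0.876790830945559, tolerance = 1e-9)
  # independently shuffled large-n columns: ICC near 0
  set.seed(99)
  base <- rnorm(500)
  S <- cbind(sample(base), sample(base), sample(base), sample(base))
  expect_lt(abs(intraclass_correlation(S)), 0.1)
  expect_error(intraclass_correlation(matrix(1:2, 1)), "at least 2")
  expect_error(intraclass_correlation(cbind(c(1, NA), 1:2)), "NA")
})
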