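grid_r <- build_grid("right")

test_that("a noiseless flat field is recovered within the termination spread", {
  obs <- flat_observer(20)
  res <- run_session(obs, session_config(), seed = 101)
  loc <- res$locations
  tp <- loc$role == "test"
  expect_true(all(loc$terminated))
  expect_false(any(loc$unmeasured))
  # every non-capped location honours the dynamic termination bound
  dyn <- loc$n_presentations < 20
  expect_true(all(loc$posterior_sd_db[dyn] <= 1.5))
  # recovery: mean error within the termination spread, no systematic bias
  err <- loc$dls_db[tp] - 20
  expect_lte(mean(abs(err)), 1.5)
  expect_lte(abs(mean(err)), 0.5)
  # blind-spot estimates collapse towards zero sensitivity
  expect_true(all(loc$dls_db[loc$role == "blind_spot"] < 6))
})

test_that("blind spots end far below all their 6-degree neighbours", {
  obs <- flat_observer(20)
  res <- run_session(obs, session_config(), seed = 55)
  loc <- res$locations
  for (b in which(loc$role == "blind_spot")) {
    nb <- which(loc$role == "test" &
                  pmax(abs(loc$x_deg - loc$x_deg[b]),
                       abs(loc$y_deg - loc$y_deg[b])) <= 6)
    expect_true(all(loc$dls_db[b] < loc$dls_db[nb] - 5))
  }
})

test_that("sessions are bit-identical under the same seed", {
  obs <- flat_observer(19, seed = 12)
  a <- run_session(obs, session_config(), seed = 77)
  b <- run_session(obs, session_config(), seed = 77)
  expect_identical(a, b)
  c <- run_session(obs, session_config(), seed = 78)
  expect_false(identical(a$trial_log, c$trial_log))
})

test_that("catch trials follow the schedule and never touch thresholds", {
  obs <- flat_observer(20)
  # no catch trials at probability zero
  none <- run_session(obs, session_config(catch_rate = 0), seed = 5)
  expect_equal(unname(none$n_trials["catch_blank"] +
                        none$n_trials["catch_supra"]), 0)
  # presentations per location equal its test trials in the log: catch and
  # refixation trials leave every ZEST state untouched
  res <- run_session(obs, session_config(catch_rate = 0.2), seed = 5)
  tl <- res$trial_log[res$trial_log$type == "test", ]
  counts <- table(paste(tl$x_deg, tl$y_deg))
  loc <- res$locations
  expect_equal(unname(loc$n_presentations),
               unname(as.integer(counts[paste(loc$x_deg, loc$y_deg)])))
  # blank and suprathreshold catches occur about equally often
  nb <- unname(res$n_trials["catch_blank"]); ns <- unname(res$n_trials["catch_supra"])
  expect_gt(stats::binom.test(nb, nb + ns, 0.5)$p.value, 1e-4)
  # the per-trial insertion rate is Bernoulli(catch_rate)
  sched <- sum(res$n_trials[c("test", "catch_blank", "catch_supra")])
  expect_gt(stats::binom.test(nb + ns, sched, 0.2)$p.value, 1e-4)
})

test_that("growth stages run strictly in order, blind spots throughout", {
  obs <- flat_observer(20)
  res <- run_session(obs, session_config(), seed = 31)
  tl <- res$trial_log[res$trial_log$type == "test", ]
  key <- paste(res$locations$x_deg, res$locations$y_deg)
  tl$group <- res$locations$group[match(paste(tl$x_deg, tl$y_deg), key)]
  for (g in sort(unique(tl$group[tl$group > 1]))) {
    first_g <- min(tl$index[tl$group == g])
    last_prev <- max(tl$index[tl$group == g - 1])
    expect_gt(first_g, last_prev)
  }
  # blind spots are scheduled from the start, outside the stage order
  bs <- tl$index[tl$group == 0]
  expect_gt(length(bs), 0)
  expect_lt(min(bs), max(tl$index[tl$group == 1]))
})

test_that("an untrackable region leaves locations unmeasured, not hung", {
  obs <- flat_observer(20)
  sc <- session_config(trackbox_deg = c(10, 10), max_total_trials = 1500)
  res <- run_session(obs, sc, seed = 9)
  loc <- res$locations
  expect_true(any(loc$unmeasured))
  expect_gt(res$n_trials["refixation"], 0)
  # locations inside the reachable region still get measured
  near <- sqrt(loc$x_deg^2 + loc$y_deg^2) <= 8
  expect_true(all(loc$n_presentations[near & loc$role == "test"] > 0))
})

test_that("catch-trial error rates are ratios of the catch log", {
  log1 <- data.frame(type = c(rep("catch_blank", 10), rep("catch_supra", 10)),
                     outcome = c(rep("miss", 10), rep("miss", 1),
                                 rep("hit", 9)))
  er <- estimate_error_rates(log1)
  expect_equal(unname(er), c(0, 0.1))
  # no catch trials: undefined, never zero
  er2 <- estimate_error_rates(data.frame(type = "test", outcome = "hit"))
  expect_true(all(is.na(er2)))
})

test_that("test-retest repeatability of MS lands in a plausible band", {
  co <- sample_cohort(12, hill_model(), build_grid("right"), seed = 5)
  sc <- session_config()
  ms <- t(vapply(seq_along(co), function(i) {
    r1 <- run_session(co[[i]], sc, seed = 2 * i)
    r2 <- run_session(co[[i]], sc, seed = 2 * i + 1)
    c(mean_sensitivity(r1), mean_sensitivity(r2))
  }, numeric(2)))
  ba <- bland_altman(ms[, 1], ms[, 2])
  expect_gt(ba$cor95, 0.5)
  expect_lt(ba$cor95, 3)
  # and the cohort sits in a normal-adult sensitivity regime
  expect_gt(mean(ms), 15)
  expect_lt(mean(ms), 25)
})
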