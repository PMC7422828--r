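test_that("bimodal prior is a normalised mixture on the domain", {
  cfg <- zest_config()
  p <- make_prior(prior_spec(), cfg)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  # w = 0: unimodal healthy component, mode at its mean
  p0 <- make_prior(prior_spec(healthy_mean = 25, abnormal_weight = 0), cfg)
  expect_equal(cfg$db_domain[which.max(p0)], 25)
  # w = 1: pure abnormal component, mode at 5 dB
  p1 <- make_prior(prior_spec(abnormal_mean = 5, abnormal_weight = 1), cfg)
  expect_equal(cfg$db_domain[which.max(p1)], 5)
})

test_that("likelihood is a cumulative Gaussian centred on threshold", {
  expect_equal(p_seen(20, 20, 1.25), 0.5)
  expect_equal(p_seen(15, 20, 1.25), pnorm(4))
  expect_equal(p_seen(20 - 2, 20, 1.25) + p_seen(20 + 2, 20, 1.25), 1)
  # guess/lapse compress the curve into [gamma, 1 - lambda]
  expect_equal(p_seen(40, 20, 1.25, gamma = 0.03), 0.03, tolerance = 1e-6)
  expect_equal(p_seen(0, 20, 1.25, lambda = 0.05), 0.95, tolerance = 1e-6)
})

test_that("a single update matches the two-outcome closed form", {
  cfg <- zest_config(db_domain = c(10, 20), min_presentations = 1,
                     prior = prior_spec())
  st <- zest_state(cfg)
  st$pmf <- c(0.5, 0.5)
  up <- zest_update(st, 15, seen = TRUE, cfg)
  expect_equal(up$pmf[2], pnorm(4) / (pnorm(4) + pnorm(-4)), tolerance = 1e-12)
  st$pmf <- c(0.5, 0.5)
  dn <- zest_update(st, 15, seen = FALSE, cfg)
  expect_equal(dn$pmf[1], pnorm(4) / (pnorm(4) + pnorm(-4)), tolerance = 1e-12)
})

test_that("alternating hit/miss at one level keeps the pmf symmetric", {
  cfg <- zest_config(db_domain = 13:21, min_presentations = 1,
                     termination_sd = 1e-4, max_presentations = 100)
  st <- zest_state(cfg)
  st$pmf <- rep(1 / 9, 9)
  for (r in c(TRUE, FALSE, TRUE, FALSE)) st <- zest_update(st, 17, r, cfg)
  expect_equal(st$pmf, rev(st$pmf), tolerance = 1e-12)
  expect_equal(zest_estimate(st, cfg), 17, tolerance = 1e-9)
})

test_that("sequential updates equal the brute-force product posterior", {
  # every hit/miss sequence of length <= 6, stimuli chosen adaptively,
  # on a 5-point domain with a uniform prior
  domain <- c(10, 12, 14, 16, 18)
  cfg <- zest_config(db_domain = domain, min_presentations = 1,
                     termination_sd = 1e-6, max_presentations = 100)
  worst <- 0
  for (len in 1:6) {
    for (code in 0:(2^len - 1)) {
      responses <- as.logical(bitwAnd(bitwShiftR(code, 0:(len - 1)), 1L))
      st <- zest_state(cfg)
      st$pmf <- rep(0.2, 5)
      stimuli <- numeric(0)
      for (r in responses) {
        if (st$terminated) break
        s <- next_stimulus(st, cfg)
        stimuli <- c(stimuli, s)
        st <- zest_update(st, s, r, cfg)
      }
      oracle <- brute_posterior(rep(0.2, 5), domain, stimuli,
                                responses[seq_along(stimuli)], 1.25)
      worst <- max(worst, max(abs(st$pmf - oracle)))
    }
  }
  expect_lte(worst, 1e-12)
})

test_that("stimulus placement is the posterior mean, ties rounding down", {
  cfg <- zest_config(min_presentations = 1)
  st <- zest_state(cfg)
  # symmetric pmf about 17 -> 17
  st$pmf <- rep(0, 35); st$pmf[17 + 1] <- 0.4
  st$pmf[c(16, 18) + 1] <- 0.3
  expect_equal(next_stimulus(st, cfg), 17)
  # point mass at 3 -> 3
  st$pmf <- rep(0, 35); st$pmf[3 + 1] <- 1
  expect_equal(next_stimulus(st, cfg), 3)
  # mean exactly 16.5 -> 16 (brighter)
  st$pmf <- rep(0, 35); st$pmf[c(16, 17) + 1] <- 0.5
  expect_equal(next_stimulus(st, cfg), 16)
})

test_that("termination triggers on posterior spread or presentation cap", {
  cfg <- zest_config(min_presentations = 1)
  st <- zest_state(cfg)
  st$n_presentations <- 1L
  # point mass: SD 0
  st$pmf <- rep(0, 35); st$pmf[23] <- 1
  expect_true(is_terminated(st, cfg))
  # uniform on 0..34: SD ~ 10.1
  st$pmf <- rep(1 / 35, 35)
  expect_equal(posterior_sd(st, cfg), sqrt((35^2 - 1) / 12), tolerance = 1e-12)
  expect_false(is_terminated(st, cfg))
  # SD exactly 1.5 terminates (inclusive bound)
  cfg2 <- zest_config(db_domain = c(10, 13), min_presentations = 1)
  st2 <- zest_state(cfg2); st2$pmf <- c(0.5, 0.5); st2$n_presentations <- 1L
  expect_equal(posterior_sd(st2, cfg2), 1.5)
  expect_true(is_terminated(st2, cfg2))
  # the floor postpones dynamic termination, the cap overrides it
  cfg3 <- zest_config(db_domain = c(10, 13), min_presentations = 5,
                      max_presentations = 6)
  st3 <- st2
  expect_false(is_terminated(st3, cfg3))
  st3$n_presentations <- 6L
  st3$pmf <- c(1 / 2, 1 / 2)
  expect_true(is_terminated(st3, cfg3))
})

test_that("the estimate is the clamped continuous posterior mean", {
  cfg <- zest_config()
  st <- zest_state(cfg)
  st$pmf <- rep(0, 35); st$pmf[22 + 1] <- 1
  expect_equal(zest_estimate(st, cfg), 22)
  st$pmf <- rep(0, 35); st$pmf[c(10, 20) + 1] <- 0.5
  expect_equal(zest_estimate(st, cfg), 15)
  for (i in 1:5) {
    st$pmf <- stats::runif(35); st$pmf <- st$pmf / sum(st$pmf)
    e <- zest_estimate(st, cfg)
    expect_true(e >= 0 && e <= 34)
  }
})

test_that("neighbour seeding shifts the prior by the mean deviation", {
  base <- prior_spec()
  done <- data.frame(x_deg = c(9, 15), y_deg = c(9, 9),
                     estimate_db = c(16, 14), normative_db = c(20, 18))
  # both neighbours 4 dB below normative -> healthy mean lowered by 4
  sp <- seed_from_neighbors(c(9, 15), done, normative_db = 19, spec = base)
  expect_equal(sp$healthy_mean, 15)
  # neighbours exactly normative -> unshifted
  done2 <- transform(done, estimate_db = normative_db)
  expect_equal(seed_from_neighbors(c(9, 15), done2, 19, base)$healthy_mean, 19)
  # no completed neighbour in range -> identity at the normative mean
  expect_equal(seed_from_neighbors(c(-21, -9), done, 19, base)$healthy_mean, 19)
  expect_equal(seed_from_neighbors(c(9, 15), NULL, 19, base)$healthy_mean, 19)
})

test_that("posterior spread shrinks in expectation for a consistent observer", {
  cfg <- zest_config(min_presentations = 1, termination_sd = 1e-9,
                     max_presentations = 8)
  set.seed(11)
  sds <- replicate(60, {
    st <- zest_state(cfg, prior = prior_spec(healthy_mean = 18))
    thr <- 18
    path <- numeric(8)
    for (k in 1:8) {
      s <- next_stimulus(st, cfg)
      seen <- stats::runif(1) < p_seen(s, thr, 1.25)
      st <- zest_update(st, s, seen, cfg)
      path[k] <- posterior_sd(st, cfg)
    }
    path
  })
  mean_path <- rowMeans(sds)
  expect_true(all(diff(mean_path) < 0.05))
  expect_lt(mean_path[8], mean_path[1])
})
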