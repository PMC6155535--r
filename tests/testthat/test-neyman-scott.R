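# Neyman-Scott clustered alternatives: parent domains, offspring
# truncation, detection contracts and mu_p calibration.

test_that("parent domains follow their variant definitions", {
  d <- probe_design("c", c(100, 200, 300))
  anchored <- build_parent_domain(d, "probe-anchored", h = 300)
  expect_equal(anchored$sites, c(100, 200, 300))
  expect_equal(anchored$total_size, 3)

  nb <- build_parent_domain(probe_design("c", c(100, 200)),
                            "probe-neighborhood", h = 300, h_p = 60)
  expect_equal(nb$starts, 40)
  expect_equal(nb$ends, 260)
  expect_equal(nb$total_size, 221)

  # disjoint neighborhoods stay disjoint
  nb2 <- build_parent_domain(probe_design("c", c(100, 1000)),
                             "probe-neighborhood", h = 300, h_p = 60)
  expect_equal(nb2$starts, c(40, 940))
  expect_equal(nb2$total_size, 242)

  free <- build_parent_domain(probe_design("c", seq(100, 1000, 100)),
                              "free", h = 300)
  expect_equal(free$starts, -200)   # parents below coordinate 1 are allowed
  expect_equal(free$ends, 1300)
  expect_equal(free$total_size, 1501)
})

test_that("domain sampling stays inside the domain with near-uniform mass", {
  set.seed(41)
  d <- probe_design("c", c(100, 1000))
  dom <- build_parent_domain(d, "probe-neighborhood", h = 300, h_p = 60)
  draws <- snpcluster:::.sample_domain(dom, 20000)
  expect_true(all((draws >= 40 & draws <= 160) | (draws >= 940 & draws <= 1060)))
  # each disjoint block holds half the sites
  expect_lt(abs(mean(draws <= 160) - 0.5), 0.02)
})

test_that("every offspring lies within h of its parent and on a probe locus", {
  set.seed(43)
  d <- make_design(300, 3e5, seed = 9)
  cfg <- ns_config("probe-anchored", mu_o = 40, sigma = 500, mu_p = 5)
  for (r in 1:30) {
    sim <- make_clustered_events(d, cfg)
    X <- sim$events$positions
    expect_true(all(X %in% d$positions))
    if (length(X) > 0) {
      mind <- vapply(X, function(x) min(abs(x - sim$parents)), numeric(1))
      expect_true(all(mind <= cfg$h + 0.5))   # rounding can add half a bp
    }
  }
})

test_that("zero-parent realizations yield empty event sets", {
  set.seed(47)
  d <- make_design(50, 5e4, seed = 10)
  cfg <- ns_config("free", mu_o = 10, sigma = 200, mu_p = 1e-9)
  ev <- simulate_ns_events(d, cfg)
  expect_length(ev$positions, 0)
  expect_error(simulate_ns_events(d, ns_config("free", mu_o = 1, sigma = 1)),
               "mu_p")
})

test_that("as sigma shrinks, anchored parents contribute at most one event", {
  set.seed(53)
  d <- make_design(100, 1e5, seed = 11)
  cfg <- ns_config("probe-anchored", mu_o = 50, sigma = 0, h = 1, mu_p = 8)
  for (r in 1:20) {
    sim <- make_clustered_events(d, cfg)
    expect_lte(length(sim$events$positions), length(unique(sim$parents)))
    expect_true(all(sim$events$positions %in% sim$parents))
  }
})

test_that("calibration matches the target detected count within Monte Carlo error", {
  set.seed(59)
  d <- make_design(400, 2e6, seed = 12)
  eta <- 30
  cfg <- calibrate_parent_mean(d, ns_config("probe-anchored", mu_o = 100,
                                            sigma = 1000), eta,
                               pilot_reps = 800)
  n <- replicate(800, length(simulate_ns_events(d, cfg)$positions))
  se <- stats::sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - eta), 3 * se + 0.02 * eta)
})

test_that("raising mu_o never raises the calibrated mu_p", {
  set.seed(61)
  d <- make_design(400, 2e6, seed = 13)
  r_low <- expected_detected_per_parent(
    d, ns_config("probe-anchored", mu_o = 50, sigma = 1000),
    pilot_reps = 600)
  r_high <- expected_detected_per_parent(
    d, ns_config("probe-anchored", mu_o = 200, sigma = 1000),
    pilot_reps = 600)
  expect_gte(r_high, r_low * 0.98)   # detection per parent is nondecreasing
})

test_that("pilot and analytic detection-per-parent estimates agree", {
  set.seed(67)
  d <- make_design(120, 1.2e5, seed = 14)
  cfg <- ns_config("probe-anchored", mu_o = 30, sigma = 800)
  pilot <- expected_detected_per_parent(d, cfg, "pilot", pilot_reps = 2000)
  analytic <- expected_detected_per_parent(d, cfg, "analytic")
  expect_lt(abs(pilot - analytic) / analytic, 0.1)
})

test_that("clustered detected counts are overdispersed relative to Poisson", {
  set.seed(71)
  d <- make_design(400, 4e5, seed = 15)   # dense probes near anchored parents
  cfg <- ns_config("probe-anchored", mu_o = 1000, sigma = 500, mu_p = 4)
  n <- replicate(1000, length(simulate_ns_events(d, cfg)$positions))
  expect_gt(stats::var(n) / mean(n), 1.5)
})
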