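# Homogeneous Poisson null: calibration arithmetic, simulator contracts,
# equivalence of the two generators, and the Monte Carlo null reference.

test_that("null calibration follows the detected-count contract", {
  d <- probe_design("c", seq(100, 1000, length.out = 5))  # span 901 sites
  cal <- calibrate_null(d, 3)
  expect_equal(cal$per_site_prob, 0.6)
  expect_equal(cal$underlying_mean, 3 * 901 / 5)
  expect_equal(calibrate_null(d, 5)$per_site_prob, 1)
  expect_equal(calibrate_null(d, 1e-6)$underlying_mean, 1e-6 * 901 / 5)
  expect_error(calibrate_null(d, 0), "positive")
  expect_warning(calibrate_null(d, 10), "exceeds")
  # adjusted mode solves |S|(1 - e^-nu) = eta exactly
  adj <- calibrate_null(d, 3, adjust = TRUE)
  expect_equal(5 * (1 - exp(-adj$per_site_mean)), 3)
})

test_that("simulated null events are always probe loci within the span", {
  set.seed(101)
  d <- make_design(60, 1e5)
  cal <- calibrate_null(d, 10)
  for (method in c("thinned", "multiset")) {
    for (r in 1:20) {
      ev <- simulate_null_events(d, cal$underlying_mean, method = method)
      expect_true(all(ev$positions %in% d$positions))
      expect_true(all(ev$positions >= d$s_f & ev$positions <= d$s_l))
      expect_false(is.unsorted(ev$positions, strictly = TRUE))
    }
  }
  ev0 <- simulate_null_events(d, 1e-12, method = "multiset")
  expect_length(ev0$positions, 0)
})

test_that("mean detected count matches the set-collapse closed form", {
  # independent oracle: E|X0| = |S| * (1 - exp(-eta/|S|)) under both
  # generators; with the adjusted calibration E|X0| = eta exactly
  set.seed(202)
  d <- make_design(40, 2e4, "regular")
  eta <- 12
  expected <- 40 * (1 - exp(-eta / 40))
  for (method in c("thinned", "multiset")) {
    cal <- calibrate_null(d, eta)
    n <- replicate(4000, length(simulate_null_events(d, cal$underlying_mean,
                                                     method = method)$positions))
    se <- stats::sd(n) / sqrt(length(n))
    expect_lt(abs(mean(n) - expected), 3 * se)
  }
  cal_adj <- calibrate_null(d, eta, adjust = TRUE)
  n <- replicate(4000, length(simulate_null_events(d, cal_adj$underlying_mean)$positions))
  expect_lt(abs(mean(n) - eta), 3 * stats::sd(n) / sqrt(length(n)))
})

test_that("probe-site inclusion is marginally uniform under the literal generator", {
  set.seed(303)
  d <- probe_design("c", sort(sample.int(2000, 20)))
  cal <- calibrate_null(d, 6)
  M <- 20000
  hits <- numeric(20)
  for (m in seq_len(M)) {
    ev <- simulate_null_events(d, cal$underlying_mean, method = "multiset")
    hits <- hits + (d$positions %in% ev$positions)
  }
  gof <- stats::chisq.test(hits, p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 0.01)
})

test_that("null reference is reproducible and has coherent structure", {
  d <- make_design(150, 8e5, seed = 7)
  nr1 <- build_null_reference(d, eta = 15, M = 40, seed = 99)
  nr2 <- build_null_reference(d, eta = 15, M = 40, seed = 99)
  expect_identical(nr1$ghat_star, nr2$ghat_star)
  expect_identical(nr1$null_cvm, nr2$null_cvm)
  for (f in nr1$families) {
    expect_length(nr1$null_ks[[f]], 40)
    expect_length(nr1$null_cvm[[f]], 40)
    expect_equal(dim(nr1$null_curves[[f]]), c(40, nr1$grids[[f]]$k))
    expect_equal(nr1$ghat_star[[f]]$values,
                 colMeans(nr1$null_curves[[f]], na.rm = TRUE))
    expect_true(all(nr1$null_ks[[f]] >= 0) && all(nr1$null_cvm[[f]] >= 0))
  }
})

test_that("with a single replicate the lone curve is its own reference", {
  d <- make_design(150, 8e5, seed = 8)
  nr <- build_null_reference(d, eta = 15, M = 1, seed = 1,
                             families = "pooled-ratio")
  expect_equal(nr$null_ks[["pooled-ratio"]], 0)
  expect_equal(nr$null_cvm[["pooled-ratio"]], 0)
})

test_that("regular lattice yields a flat pooled-ratio reference beyond the spacing", {
  # on an equal-spacing design the uniform null treats every probe alike,
  # so Ghat* for the pooled ratio is near-constant across d >> spacing
  d <- make_design(200, 2e5, "regular", seed = 3)   # spacing ~1000
  nr <- build_null_reference(d, eta = 30, M = 800, seed = 11,
                             families = "pooled-ratio",
                             d_grid = stat_grid("distance", c(10000, 20000, 40000)))
  g <- nr$ghat_star[["pooled-ratio"]]$values
  expect_lt(max(g) - min(g), 0.02)
})

test_that("a mostly-undefined grid point raises a hard error", {
  d <- make_design(100, 1e6, seed = 12)
  # eta ~ 1 event: a 1 bp neighborhood has no probes, pooled ratio undefined
  expect_error(
    build_null_reference(d, eta = 1.5, M = 60, seed = 5,
                         families = "pooled-ratio",
                         d_grid = stat_grid("distance", c(1, 2))),
    "undefined in more than half")
})
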