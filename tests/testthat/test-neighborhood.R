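# The five neighborhood/gap statistics: hand-enumerated values, boundary
# conventions, oracle equivalence and monotonicity properties.

test_that("neighbor_count matches direct enumeration and excludes the center", {
  A <- c(100, 200, 300, 400, 1000)
  expect_equal(neighbor_count(A, 100, 150), 1L)
  expect_equal(neighbor_count(A, 200, 100), 2L)
  expect_equal(neighbor_count(c(100, 200, 1000), 1000, 100), 0L)
  # boundary |z - x| = d counts; the center never does
  expect_equal(neighbor_count(A, 200, 200), 3L)
  expect_error(neighbor_count(A, 200, 0), "positive")

  set.seed(7)
  for (r in 1:50) {
    pos <- sort(sample.int(5000, 40))
    x <- sample(pos, 1); d <- sample.int(2000, 1)
    expect_equal(neighbor_count(pos, x, d), neighbor_count_brute(pos, x, d))
  }
})

test_that("detection ratios match hand enumeration and the zero-denominator policy", {
  S <- tiny_design(); X <- tiny_events()
  r100 <- mean_detection_ratio(S, X, 100)
  expect_equal(as.numeric(r100), 0.75)          # (1/1 + 1/2)/2, x=1000 excluded
  expect_equal(attr(r100, "n_excluded"), 1L)
  expect_equal(as.numeric(mean_detection_ratio(S, X, 900)), 0.5)
  expect_equal(pooled_detection_ratio(S, X, 100), 2 / 3)
  expect_equal(pooled_detection_ratio(S, X, 900), 0.5)

  # X = S: every ratio is exactly 1 wherever defined
  allx <- event_set("chr19", S$positions)
  expect_equal(as.numeric(mean_detection_ratio(S, allx, 150)), 1)
  expect_equal(pooled_detection_ratio(S, allx, 150), 1)

  empty <- event_set("chr19")
  expect_true(is.na(mean_detection_ratio(S, empty, 100)))
  expect_true(is.na(pooled_detection_ratio(S, empty, 100)))
})

test_that("ratios stay in [0,1] because events are a subset of probes", {
  set.seed(11)
  for (r in 1:30) {
    d <- make_design(80, 5e4)
    X <- event_set(d$chromosome, sample(d$positions, 15))
    for (dd in c(500, 2000, 10000)) {
      p <- pooled_detection_ratio(d, X, dd)
      m <- as.numeric(mean_detection_ratio(d, X, dd))
      if (!is.na(p)) expect_true(p >= 0 && p <= 1)
      if (!is.na(m)) expect_true(m >= 0 && m <= 1)
    }
  }
})

test_that("dmin agrees with the brute-force oracle on random small event sets", {
  X <- tiny_events()
  expect_equal(dmin(X, 2), 100)
  expect_equal(dmin(X, 3), 800)
  expect_error(dmin(X, 1), "integer >= 2")

  set.seed(23)
  for (r in 1:200) {
    ev <- random_event_set()
    ns <- seq(2L, min(8L, length(ev$positions)))
    n <- ns[sample.int(length(ns), 1)]
    expect_equal(dmin(ev, n), dmin_brute(ev$positions, n))
  }
})

test_that("dmin below n events returns the flagged chromosome-span sentinel", {
  d <- tiny_design()
  one <- event_set("chr19", 100)
  s <- dmin(one, 2, design = d)
  expect_equal(as.numeric(s), 900)
  expect_true(attr(s, "sentinel"))
  expect_true(is.na(dmin(one, 2)))   # no design, no sentinel
})

test_that("nmax and gap_count follow their boundary conventions", {
  X <- tiny_events()
  expect_equal(nmax(X, 100), 1L)
  expect_equal(nmax(X, 800), 2L)                 # |1000 - 200| = 800 counts
  expect_equal(nmax(event_set("c", 500), 5000), 0L)
  expect_true(is.na(nmax(event_set("c"), 100)))

  expect_equal(as.integer(gap_count(X, 800)), 1L)   # strict <: gap 800 excluded
  expect_equal(as.integer(gap_count(X, 801)), 2L)
  single <- gap_count(event_set("c", 42), 100)
  expect_equal(as.integer(single), 0L)
  expect_true(attr(single, "flagged"))
})

test_that("gap_count and nmax are nondecreasing in d; dmin nondecreasing in n", {
  set.seed(31)
  for (r in 1:20) {
    ev <- random_event_set()
    K <- length(ev$positions)
    dgrid <- sort(sample.int(5e4, 10))
    gc <- vapply(dgrid, function(d) as.integer(gap_count(ev, d)), integer(1))
    nm <- vapply(dgrid, function(d) nmax(ev, d), integer(1))
    expect_true(all(diff(gc) >= 0))
    expect_true(all(diff(nm) >= 0))
    expect_true(all(gc <= K - 1))
    expect_equal(gc[dgrid > max(diff(ev$positions))],
                 rep(K - 1L, sum(dgrid > max(diff(ev$positions)))))
    ns <- 2:min(8, K)
    dm <- vapply(ns, function(n) dmin(ev, n), numeric(1))
    expect_true(all(diff(dm) >= 0))
  }
})

test_that("stat_curve evaluates families on grids and checks grid kinds", {
  S <- tiny_design(); X <- tiny_events()
  gc_curve <- stat_curve("gap-count", S, X, stat_grid("distance", c(800, 801)))
  expect_equal(gc_curve$values, c(1, 2))
  dm_curve <- stat_curve("dmin", S, X, stat_grid("count", 2:3))
  expect_equal(dm_curve$values, c(100, 800))

  allx <- event_set("chr19", S$positions)
  pr <- stat_curve("pooled-ratio", S, allx, stat_grid("distance", c(300, 600, 900)))
  expect_equal(pr$values, c(1, 1, 1))
  expect_true(all(pr$defined))

  expect_error(stat_curve("dmin", S, X, stat_grid("distance", c(10, 20))),
               "count grid")
  expect_error(stat_curve("pooled-ratio", S, X, stat_grid("count", 2:4)),
               "distance grid")
  expect_error(stat_grid("distance", c(10, 10)), "strictly increasing")
})
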