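# Shared miniature fixtures. The "study-scale" design mirrors the package's
# default synthetic chromosome: 1,200 probes over 6 Mb, mean gap 5 kb.

tiny_design <- function() probe_design("chr19", c(100, 200, 300, 400, 1000))

tiny_events <- function() event_set("chr19", c(100, 200, 1000))

study_design <- function(seed = 42L)
  make_design(1200, 6e6, "lognormal-gap", seed = seed)

# brute-force D(x0, n) / Dmin oracle: nth smallest |x0 - x| over x in X
# (x0 itself included), minimized over all x0
dmin_brute <- function(X, n) {
  if (length(X) < n) return(NA_real_)
  min(vapply(X, function(x0) sort(abs(x0 - X))[n], numeric(1)))
}

# O(n^2) neighbor-count oracle
neighbor_count_brute <- function(positions, center, d)
  sum(abs(positions - center) <= d & positions != center)

random_event_set <- function(max_n = 30, span = 1e5) {
  n <- sample(2:max_n, 1)
  event_set("chrR", sample.int(span, n))
}
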