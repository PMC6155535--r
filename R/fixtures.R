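# Synthetic probe designs and event sets with known structure, so the full
# pipeline builds and tests without any array download.

#' Generate a synthetic probe design
#'
#' Emulates the salient features of a real array design on a miniature
#' chromosome: nonuniform inter-probe spacing (lognormal gaps, matching the
#' right-skewed spacing of genotyping arrays) and, optionally, probe
#' deserts -- a chosen number of gaps inflated beyond a minimum length.
#' The default test scale used throughout the package is 1,200 probes over
#' 6 Mb (mean gap 5 kb).
#'
#' @param n_probes Number of probe loci (`>= 2`).
#' @param span Chromosome span in bp (`> n_probes`).
#' @param spacing `"regular"`, `"lognormal-gap"` or `"with-deserts"`.
#' @param n_deserts,min_desert_gap Desert specification for
#'   `"with-deserts"`: how many gaps to inflate and the minimum inflated
#'   gap length in bp.
#' @param sdlog Lognormal gap shape parameter (spread of inter-probe
#'   spacing). The default 1.5 reproduces the clustered spacing of real
#'   genotyping arrays: with a 5 kb mean gap about 37% of inter-probe gaps
#'   fall below 1 kb, comparable to the sub-kilobase spacing mass reported
#'   for the MDGA design. Because the gaps are drawn independently (real
#'   designs have correlated runs of tight probes), the per-locus
#'   nearest-neighbor fraction comes out somewhat higher than on a real
#'   array.
#' @param chromosome Chromosome label for the design.
#' @param seed Optional integer; if given, the design is reproducible and
#'   the caller's RNG state is untouched.
#' @return A [probe_design()].
#' @export
make_design <- function(n_probes, span,
                        spacing = c("lognormal-gap", "regular", "with-deserts"),
                        n_deserts = 0L, min_desert_gap = 0,
                        sdlog = 1.5, chromosome = "chrS", seed = NULL) {
  spacing <- match.arg(spacing)
  stopifnot(n_probes >= 2L, span > n_probes)
  if (spacing == "with-deserts") {
    stopifnot(n_deserts >= 1L, min_desert_gap > 0)
    if (n_deserts * min_desert_gap * 1.1 >= span - n_probes)
      stop("desert gaps exceed the chromosome span", call. = FALSE)
  }
  .with_seed(seed, {
    if (spacing == "regular") {
      pos <- round(seq(1, span, length.out = n_probes))
    } else {
      gaps <- stats::rlnorm(n_probes - 1L, meanlog = 0, sdlog = sdlog)
      if (spacing == "with-deserts") {
        idx <- sample.int(n_probes - 1L, n_deserts)
        desert <- min_desert_gap * (1 + stats::runif(n_deserts, 0, 0.1))
        budget <- (span - 1) - sum(desert)
        if (budget <= n_probes)
          stop("desert gaps exceed the chromosome span", call. = FALSE)
        gaps[idx] <- 0
        gaps <- gaps / sum(gaps) * budget
        gaps[idx] <- desert
      } else {
        gaps <- gaps / sum(gaps) * (span - 1)
      }
      pos <- round(1 + cumsum(c(0, gaps)))
    }
    pos <- .make_strictly_increasing(pos)
    probe_design(chromosome, pos)
  })
}

# bump ties upward minimally after rounding; keeps order and rough scale
.make_strictly_increasing <- function(pos) {
  pos <- cummax(pos)
  d <- diff(pos)
  while (any(d == 0)) {
    pos[-1L][d == 0] <- pos[-1L][d == 0] + 1
    pos <- cummax(pos)
    d <- diff(pos)
  }
  pos
}

#' Generate clustered events with retained truth
#'
#' Wraps [simulate_ns_events()] keeping the realized parent positions, so
#' recovery tests can assert that every detected event lies within the
#' truncation half-width `h` of some parent.
#'
#' @param design A [probe_design()].
#' @param config A calibrated [ns_config()].
#' @param seed Optional integer seed (caller's RNG state preserved).
#' @return List with `events` (an [event_set()]) and `parents` (numeric
#'   vector of realized parent positions, possibly empty).
#' @export
make_clustered_events <- function(design, config, seed = NULL) {
  .with_seed(seed, {
    ev <- simulate_ns_events(design, config, keep_parents = TRUE)
    parents <- attr(ev, "parents")
    attr(ev, "parents") <- NULL
    list(events = ev, parents = parents)
  })
}
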