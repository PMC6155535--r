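# Neyman-Scott clustered alternatives: Poisson parents on one of three
# domains, truncated-normal offspring, probe-filtered detection.

NS_VARIANTS <- c("free", "probe-anchored", "probe-neighborhood")

#' Neyman-Scott alternative configuration
#'
#' The clustered alternative is a parent-offspring process: an unobserved
#' Poisson number of parents (mean `mu_p`) falls on a parent domain, each
#' parent spawns a Poisson number of offspring (mean `mu_o`) scattered as
#' truncated normals (sd `sigma`, truncation half-width `h`) around it, and
#' the detected events are the distinct offspring positions that are probe
#' loci. The three `variant`s differ only in the parent domain:
#'
#' * `"free"` -- anywhere in `[s_f - h, s_l + h]` (parents beyond that
#'   range cannot yield detectable offspring);
#' * `"probe-anchored"` -- exactly the probe loci (the highest-power
#'   setting, since parents sit where events are detectable);
#' * `"probe-neighborhood"` -- within `h_p` of some probe locus.
#'
#' @param variant One of `"free"`, `"probe-anchored"`,
#'   `"probe-neighborhood"`.
#' @param mu_o Expected offspring per parent.
#' @param sigma Offspring standard deviation in bp.
#' @param mu_p Expected number of parents; may be `NULL` until set by
#'   [calibrate_parent_mean()].
#' @param h Truncation half-width in bp; default `3 * sigma`.
#' @param h_p Parent-neighborhood half-width in bp (only used by
#'   `"probe-neighborhood"`); default `sigma`.
#' @return An `ns_config` object.
#' @export
ns_config <- function(variant = NS_VARIANTS, mu_o, sigma, mu_p = NULL,
                      h = 3 * sigma, h_p = sigma) {
  variant <- match.arg(variant)
  stopifnot(mu_o > 0, sigma >= 0, h > 0, h_p >= 0)
  if (!is.null(mu_p)) stopifnot(mu_p > 0)
  structure(list(variant = variant, mu_p = mu_p, mu_o = mu_o,
                 sigma = sigma, h = h, h_p = h_p),
            class = "ns_config")
}

#' @export
print.ns_config <- function(x, ...) {
  cat(sprintf("Neyman-Scott config: %s, mu_p = %s, mu_o = %g, sigma = %g bp, h = %g bp\n",
              x$variant, if (is.null(x$mu_p)) "(uncalibrated)" else format(x$mu_p),
              x$mu_o, x$sigma, x$h))
  invisible(x)
}

#' Build the parent domain for a Neyman-Scott variant
#'
#' @param design A [probe_design()].
#' @param variant Parent-domain variant, see [ns_config()].
#' @param h Truncation half-width (defines the `"free"` domain
#'   `[s_f - h, s_l + h]`; the lower end may be non-positive -- such
#'   parents can still scatter offspring onto the chromosome).
#' @param h_p Neighborhood half-width for `"probe-neighborhood"`.
#' @return A `parent_domain` object: either explicit `sites`
#'   (probe-anchored) or merged disjoint integer intervals
#'   (`starts`/`ends`), plus `total_size`, the number of admissible
#'   integer sites.
#' @export
build_parent_domain <- function(design, variant = NS_VARIANTS, h, h_p = 0) {
  variant <- match.arg(variant)
  stopifnot(inherits(design, "probe_design"))
  S <- design$positions
  if (variant == "probe-anchored") {
    return(structure(list(variant = variant, sites = S,
                          starts = S, ends = S, total_size = length(S)),
                     class = "parent_domain"))
  }
  if (variant == "free") {
    starts <- design$s_f - h; ends <- design$s_l + h
  } else {
    s <- S - h_p; e <- S + h_p
    # merge overlapping or touching integer intervals
    starts <- s[1L]; ends <- e[1L]
    for (i in seq_along(s)[-1L]) {
      j <- length(ends)
      if (s[i] <= ends[j] + 1) ends[j] <- max(ends[j], e[i])
      else { starts <- c(starts, s[i]); ends <- c(ends, e[i]) }
    }
  }
  structure(list(variant = variant, sites = NULL,
                 starts = starts, ends = ends,
                 total_size = sum(ends - starts + 1)),
            class = "parent_domain")
}

# n iid discrete-uniform draws from a parent domain
.sample_domain <- function(domain, n) {
  if (n == 0L) return(numeric(0))
  if (!is.null(domain$sites))
    return(domain$sites[sample.int(length(domain$sites), n, replace = TRUE)])
  sizes <- domain$ends - domain$starts + 1
  cum <- cumsum(sizes)
  i <- sample.int(domain$total_size, n, replace = TRUE)
  j <- findInterval(i - 1, cum) + 1L
  offsets <- c(0, cum[-length(cum)])
  domain$starts[j] + (i - offsets[j] - 1)
}

# round half-away-from-zero (the bridge from continuous offspring to bp)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# truncated-normal offspring around parent centers, via inverse CDF
.rtnorm_offspring <- function(centers, sigma, h) {
  n <- length(centers)
  if (n == 0L) return(numeric(0))
  if (sigma == 0) return(centers)
  a <- stats::pnorm(-h / sigma)
  b <- stats::pnorm(h / sigma)
  centers + sigma * stats::qnorm(stats::runif(n, a, b))
}

#' Simulate detected events from a Neyman-Scott process
#'
#' Draws `N_p ~ Poisson(mu_p)` parents iid uniform on the parent domain;
#' each parent spawns `Poisson(mu_o)` offspring from a normal centered at
#' the parent (sd `sigma`) truncated to `[parent - h, parent + h]` and
#' rounded to integer bp; the detected event set is the union of offspring
#' positions intersected with the probe design.
#'
#' @param design A [probe_design()].
#' @param config An [ns_config()] with `mu_p` set.
#' @param keep_parents Logical; if `TRUE` the realized parent positions are
#'   attached as `attr(, "parents")` (used for truth-retention fixtures).
#' @return An [event_set()] of detected SNP genotype differences.
#' @export
simulate_ns_events <- function(design, config, keep_parents = FALSE) {
  stopifnot(inherits(config, "ns_config"))
  if (is.null(config$mu_p))
    stop("config$mu_p is not set; calibrate it first (calibrate_parent_mean)",
         call. = FALSE)
  domain <- build_parent_domain(design, config$variant, config$h, config$h_p)
  n_p <- stats::rpois(1L, config$mu_p)
  parents <- .sample_domain(domain, n_p)
  pos <- numeric(0)
  if (n_p > 0L) {
    n_o <- stats::rpois(n_p, config$mu_o)
    centers <- rep(parents, n_o)
    off <- .round_half_away(.rtnorm_offspring(centers, config$sigma, config$h))
    pos <- unique(off[.is_member(off, design$positions)])
  }
  ev <- structure(list(chromosome = design$chromosome, positions = sort(pos)),
                  class = "event_set")
  if (keep_parents) attr(ev, "parents") <- parents
  ev
}

#' Expected detected events per parent
#'
#' The calibration kernel: the mean number of distinct probe loci hit by
#' one parent's offspring cloud. `"pilot"` estimates it by Monte Carlo
#' (parents and detection simulated jointly, total detected over total
#' parents). `"analytic"` computes, for each candidate parent position z,
#' \eqn{\sum_{s \in S} (1 - e^{-\mu_o p_s(z)})} where \eqn{p_s(z)} is the
#' truncated-normal mass rounding to probe site s, averaged over parents
#' uniform on the domain; exact up to the site-rounding convention and
#' intended for small designs (the domain is subsampled beyond
#' `max_parents` positions).
#'
#' @param design A [probe_design()].
#' @param config An [ns_config()]; `mu_p` is not needed (`"pilot"` uses a
#'   provisional value).
#' @param method `"pilot"` or `"analytic"`.
#' @param pilot_reps Pilot replications for `"pilot"`.
#' @param pilot_mu_p Provisional parent mean for the pilot.
#' @param max_parents Cap on the number of candidate parent positions
#'   enumerated by `"analytic"`.
#' @return Expected detected count per parent (positive real).
#' @export
expected_detected_per_parent <- function(design, config,
                                         method = c("pilot", "analytic"),
                                         pilot_reps = 1000L, pilot_mu_p = 20,
                                         max_parents = 2000L) {
  method <- match.arg(method)
  stopifnot(inherits(config, "ns_config"))
  if (method == "pilot") {
    cfg <- config
    cfg$mu_p <- pilot_mu_p
    tot_detected <- 0; tot_parents <- 0
    for (r in seq_len(pilot_reps)) {
      ev <- simulate_ns_events(design, cfg, keep_parents = TRUE)
      tot_detected <- tot_detected + length(ev$positions)
      tot_parents <- tot_parents + length(attr(ev, "parents"))
    }
    if (tot_detected == 0)
      stop("pilot simulation detected no events; offspring never reach ",
           "probe loci under this configuration", call. = FALSE)
    return(tot_detected / tot_parents)
  }
  domain <- build_parent_domain(design, config$variant, config$h, config$h_p)
  z <- if (!is.null(domain$sites)) domain$sites
       else .sample_domain(domain, min(domain$total_size, max_parents))
  if (length(z) > max_parents) z <- sample(z, max_parents)
  S <- design$positions
  sigma <- config$sigma; h <- config$h
  if (sigma == 0) {   # offspring collapse onto the parent
    hit <- .is_member(.round_half_away(z), S)
    return(mean(hit) * (1 - exp(-config$mu_o)))
  }
  trunc_mass <- stats::pnorm(h / sigma) - stats::pnorm(-h / sigma)
  per_parent <- vapply(z, function(zi) {
    lo <- findInterval(zi - h - 1, S) + 1L
    hi <- findInterval(zi + h, S)
    if (hi < lo) return(0)
    s <- S[lo:hi]
    p <- (stats::pnorm((s + 0.5 - zi) / sigma) -
          stats::pnorm((s - 0.5 - zi) / sigma)) / trunc_mass
    sum(-expm1(-config$mu_o * p))
  }, numeric(1))
  mean(per_parent)
}

#' Calibrate the parent mean to an expected detected count
#'
#' Sets `mu_p = eta / r` where `r` is the expected number of detected
#' events per parent estimated by pilot Monte Carlo (see
#' [expected_detected_per_parent()]), so that the alternative process
#' yields on average `eta` detected SNP genotype differences -- matching
#' the null calibration, as a power study requires.
#'
#' @param design A [probe_design()].
#' @param config An [ns_config()] (its `mu_p` is ignored).
#' @param eta Target expected detected count.
#' @param pilot_reps Pilot replications (at least 100).
#' @param pilot_mu_p Provisional parent mean used in the pilot.
#' @return The input `config` with `mu_p` set; the per-parent detection
#'   estimate is attached as `attr(, "detected_per_parent")`.
#' @export
calibrate_parent_mean <- function(design, config, eta,
                                  pilot_reps = 1000L, pilot_mu_p = 20) {
  stopifnot(eta > 0, pilot_reps >= 100L)
  r <- expected_detected_per_parent(design, config, "pilot",
                                    pilot_reps = pilot_reps,
                                    pilot_mu_p = pilot_mu_p)
  out <- config
  out$mu_p <- eta / r
  attr(out, "detected_per_parent") <- r
  out
}
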