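# Homogeneous Poisson null conditional on the probe design: calibration,
# event simulation, and the Monte Carlo null reference used by all tests.

#' Calibrate the homogeneous Poisson null to an expected detected count
#'
#' Under the null, underlying mutations fall as a homogeneous Poisson
#' process on the integer sites of `[s_f, s_l]` and only those landing on
#' probe loci are detected. The calibration makes the *expected number of
#' underlying hits on probe loci* equal `eta`: each site carries Poisson
#' mean `eta / |S|`, so the total underlying mean is
#' `eta * (s_l - s_f + 1) / |S|`.
#'
#' Because multiple underlying hits on one probe site collapse to a single
#' detected difference, the expected number of *distinct* detected loci is
#' `|S| * (1 - exp(-eta/|S|))`, slightly below `eta` (about 2% low at
#' `eta = 50`, `|S| = 1200`, and negligible at array scale). With
#' `adjust = TRUE` the per-site mean is instead solved from
#' `|S| * (1 - exp(-nu)) = eta` so the expected detected count is exactly
#' `eta`.
#'
#' @param design A [probe_design()].
#' @param eta Expected number of detected SNP genotype differences
#'   (typically the observed count `|X|`).
#' @param adjust Logical; correct for set-collapse so that the expected
#'   *detected* count equals `eta` exactly. Default `FALSE`.
#' @return List with `underlying_mean` (total Poisson mean on the span),
#'   `per_site_prob` (`eta / |S|`, the per-site underlying mean), `eta`
#'   and `adjust`.
#' @export
calibrate_null <- function(design, eta, adjust = FALSE) {
  stopifnot(inherits(design, "probe_design"))
  if (length(eta) != 1L || is.na(eta) || eta <= 0)
    stop("eta must be a single positive number", call. = FALSE)
  n_s <- length(design$positions)
  if (eta > n_s)
    warning("eta exceeds the number of probe loci (", n_s, ")")
  nu <- eta / n_s
  if (adjust) {
    if (eta >= n_s)
      stop("adjusted calibration requires eta < |S|", call. = FALSE)
    nu <- -log(1 - eta / n_s)
  }
  span_sites <- design$s_l - design$s_f + 1
  list(underlying_mean = nu * span_sites,
       per_site_prob = eta / n_s,
       per_site_mean = nu,
       eta = eta, adjust = adjust)
}

#' Simulate detected events under the homogeneous Poisson null
#'
#' Two exactly equivalent generators are provided. `"multiset"` is the
#' literal construction: draw `N ~ Poisson(underlying_mean)` underlying
#' positions iid discrete-uniform on the integer sites of `[s_f, s_l]` and
#' keep the distinct ones that are probe loci. `"thinned"` uses the
#' Poissonization identity -- per-site underlying hit counts are independent
#' Poisson with mean `underlying_mean / (s_l - s_f + 1)`, so each probe
#' locus is detected independently with probability
#' `1 - exp(-per-site mean)` -- and is much faster at genome scale.
#'
#' @param design A [probe_design()].
#' @param underlying_mean Total Poisson mean for underlying events on the
#'   span (see [calibrate_null()]).
#' @param method `"thinned"` (default) or `"multiset"`.
#' @return An [event_set()]; positions are always probe loci in
#'   `[s_f, s_l]`.
#' @export
simulate_null_events <- function(design, underlying_mean,
                                 method = c("thinned", "multiset")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "probe_design"))
  span_sites <- design$s_l - design$s_f + 1
  nu <- underlying_mean / span_sites      # per-site Poisson mean
  S <- design$positions
  if (method == "thinned") {
    keep <- stats::runif(length(S)) < -expm1(-nu)
    pos <- S[keep]
  } else {
    n <- stats::rpois(1L, underlying_mean)
    if (n == 0L) {
      pos <- numeric(0)
    } else {
      u <- design$s_f + sample.int(span_sites, n, replace = TRUE) - 1
      pos <- unique(u[.is_member(u, S)])
    }
  }
  structure(list(chromosome = design$chromosome, positions = sort(pos)),
            class = "event_set")
}

# membership of x in sorted table (hash-free exact match on integers)
.is_member <- function(x, table_sorted) {
  i <- findInterval(x, table_sorted)
  i > 0L & table_sorted[pmax(i, 1L)] == x
}

#' Build a Monte Carlo null reference
#'
#' Simulates `M` replicate event sets under the calibrated homogeneous
#' Poisson null, evaluates every tracked statistic family on its grid,
#' stores the pointwise mean curves \eqn{\hat G^*} and, per family, the
#' empirical null samples of the KS and CvM distances of each replicate
#' curve to \eqn{\hat G^*} (the fixed-argument null samples are the stored
#' per-replicate curve values themselves).
#'
#' Replicate grid points where a statistic is undefined are excluded
#' pointwise from the mean (counts recorded in `n_undefined`); a grid point
#' undefined in more than half the replicates is an error -- use a coarser
#' grid or a larger `eta`.
#'
#' @param design A [probe_design()].
#' @param eta Expected detected count under the null (see
#'   [calibrate_null()]).
#' @param M Number of null replications.
#' @param families Statistic families to track.
#' @param d_grid,n_grid [stat_grid()]s for the distance and count families.
#' @param seed Optional integer; if given the build is reproducible and the
#'   caller's RNG state is restored afterwards.
#' @param method Null simulator passed to [simulate_null_events()].
#' @param adjust Passed to [calibrate_null()].
#' @return A `null_reference` object.
#' @export
build_null_reference <- function(design, eta, M,
                                 families = FAMILIES,
                                 d_grid = default_d_grid(),
                                 n_grid = default_n_grid(),
                                 seed = NULL,
                                 method = c("thinned", "multiset"),
                                 adjust = FALSE) {
  method <- match.arg(method)
  families <- match.arg(families, FAMILIES, several.ok = TRUE)
  if (length(M) != 1L || M < 1) stop("M must be a positive integer", call. = FALSE)
  M <- as.integer(M)
  cal <- calibrate_null(design, eta, adjust = adjust)
  span <- design$s_l - design$s_f
  grids <- lapply(families, function(f) if (f == "dmin") n_grid else d_grid)
  names(grids) <- families

  .with_seed(seed, {
    curves <- lapply(families, function(f)
      matrix(NA_real_, nrow = M, ncol = grids[[f]]$k))
    names(curves) <- families
    for (m in seq_len(M)) {
      ev <- simulate_null_events(design, cal$underlying_mean, method = method)
      for (f in families)
        curves[[f]][m, ] <- .family_curve(f, design$positions, ev$positions,
                                          grids[[f]]$values, span)$values
    }

    ghat <- list(); null_ks <- list(); null_cvm <- list(); n_undef <- list()
    for (f in families) {
      cm <- curves[[f]]
      undef <- colSums(is.na(cm))
      if (any(undef > M / 2))
        stop("family '", f, "': grid point(s) ",
             paste(grids[[f]]$values[undef > M / 2], collapse = ", "),
             " undefined in more than half the null replicates; ",
             "use a coarser grid or a larger eta", call. = FALSE)
      gstar <- colMeans(cm, na.rm = TRUE)
      e <- sweep(cm, 2L, gstar)
      w <- .cvm_weights(grids[[f]]$values)
      ks <- apply(abs(e), 1L, max, na.rm = TRUE)
      e2 <- e^2
      cvm <- as.vector(e2 %*% w)
      bad <- which(is.na(cvm))
      for (r in bad) {
        ok <- !is.na(e2[r, ])
        cvm[r] <- sum((e2[r, ] * w)[ok])
      }
      ghat[[f]] <- reference_curve(grids[[f]], gstar, "monte-carlo")
      null_ks[[f]] <- ks
      null_cvm[[f]] <- cvm
      n_undef[[f]] <- undef
    }

    structure(list(chromosome = design$chromosome,
                   n_probes = length(design$positions),
                   eta = eta, M = M,
                   families = families, grids = grids,
                   calibration = cal, method = method, seed = seed,
                   ghat_star = ghat,
                   null_curves = curves,
                   null_ks = null_ks, null_cvm = null_cvm,
                   n_undefined = n_undef),
              class = "null_reference")
  })
}

#' @export
print.null_reference <- function(x, ...) {
  cat(sprintf(paste0("Monte Carlo null reference: %s (%d probes), eta = %g, ",
                     "M = %d\n  families: %s\n"),
              x$chromosome, x$n_probes, x$eta, x$M,
              paste(x$families, collapse = ", ")))
  invisible(x)
}

# run code under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
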