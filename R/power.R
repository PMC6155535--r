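# Monte Carlo power estimation against a shared null reference, and the
# full-factorial power-study driver.

# per-statistic rejection thresholds from the null samples so each
# alternative replicate is scored in O(1); reject <=> mc_pvalue <= alpha.
# upper tail: p <= alpha <=> #{null >= obs} <= kmax <=> obs > sorted[M - kmax]
.reject_threshold <- function(null_sample, alpha, tail) {
  null_sample <- sort(null_sample[!is.na(null_sample)])
  M <- length(null_sample)
  kmax <- floor(alpha * (1 + M) - 1 + 1e-9)
  if (kmax < 0) return(if (tail == "upper") Inf else -Inf)
  if (tail == "upper") null_sample[M - kmax] else null_sample[kmax + 1L]
}

#' Estimate rejection power against a null reference
#'
#' Simulates `M_prime` event sets from an alternative process, scores every
#' tracked statistic (fixed-argument and KS/CvM functional forms) against
#' the null reference's empirical distributions with the clustering-
#' direction tails, and returns the rejection fraction of each statistic
#' with its binomial Monte Carlo standard error. With `alt = NULL` the
#' "alternative" is the calibrated null process itself, so every power
#' estimate should sit near `alpha` -- the calibration identity used to
#' validate type-I error control.
#'
#' @param nullref A [build_null_reference()] result.
#' @param design The [probe_design()] the reference was built on.
#' @param alt A calibrated [ns_config()], or `NULL` for the null process.
#' @param M_prime Number of alternative replications.
#' @param alpha Significance level.
#' @return Data frame: `statistic`, `family`, `form`, `arg`, `power`,
#'   `mc_se`, `M_prime`, `alpha`, plus the mean detected count as
#'   `attr(, "mean_detected")`. Warns when the alternative's mean detected
#'   count drifts more than 10% from the reference's `eta`.
#' @export
estimate_power <- function(nullref, design, alt = NULL, M_prime, alpha = 0.05) {
  stopifnot(inherits(nullref, "null_reference"),
            inherits(design, "probe_design"))
  M_prime <- as.integer(M_prime)
  span <- design$s_l - design$s_f
  fams <- nullref$families

  # thresholds and bookkeeping per statistic column
  thr <- list(); meta <- list()
  for (f in fams) {
    grid <- nullref$grids[[f]]
    tailf <- .family_tail(f)
    argname <- if (f == "dmin") "n" else "d"
    thr[[f]] <- list(
      fixed = vapply(seq_len(grid$k), function(i)
        .reject_threshold(nullref$null_curves[[f]][, i], alpha, tailf),
        numeric(1)),
      ks = .reject_threshold(nullref$null_ks[[f]], alpha, "upper"),
      cvm = .reject_threshold(nullref$null_cvm[[f]], alpha, "upper"))
    meta[[f]] <- data.frame(
      statistic = c(sprintf("%s(%s=%g)", f, argname, grid$values),
                    sprintf(c("KS~%s", "CvM~%s"), f)),
      family = f,
      form = c(rep("fixed", grid$k), "ks", "cvm"),
      arg = c(grid$values, NA_real_, NA_real_),
      stringsAsFactors = FALSE)
  }

  rej <- lapply(fams, function(f) matrix(0L, M_prime, nullref$grids[[f]]$k + 2L))
  names(rej) <- fams
  n_detected <- numeric(M_prime)
  cal <- calibrate_null(design, nullref$eta, adjust = nullref$calibration$adjust)
  for (m in seq_len(M_prime)) {
    ev <- if (is.null(alt))
      simulate_null_events(design, cal$underlying_mean, method = nullref$method)
    else simulate_ns_events(design, alt)
    n_detected[m] <- length(ev$positions)
    for (f in fams) {
      grid <- nullref$grids[[f]]
      cv <- .family_curve(f, design$positions, ev$positions, grid$values, span)
      gstar <- nullref$ghat_star[[f]]$values
      e <- cv$values - gstar
      ks <- max(abs(e), na.rm = TRUE)
      w <- .cvm_weights(grid$values)
      ok <- !is.na(e)
      cvm <- sum((e^2 * w)[ok])
      fx <- if (.family_tail(f) == "upper") cv$values > thr[[f]]$fixed
            else cv$values < thr[[f]]$fixed
      fx[is.na(fx)] <- FALSE      # undefined replicate point: count as retain
      rej[[f]][m, ] <- c(as.integer(fx),
                         as.integer(ks > thr[[f]]$ks),
                         as.integer(cvm > thr[[f]]$cvm))
    }
  }
  mean_detected <- mean(n_detected)
  if (!is.null(alt) &&
      abs(mean_detected - nullref$eta) / nullref$eta > 0.1)
    warning(sprintf("alternative mean detected count %.1f is off the reference's eta = %g by more than 10%%; recalibrate mu_p",
                    mean_detected, nullref$eta))
  out <- do.call(rbind, lapply(fams, function(f) {
    pw <- colMeans(rej[[f]])
    cbind(meta[[f]],
          power = pw,
          mc_se = sqrt(pw * (1 - pw) / M_prime),
          M_prime = M_prime, alpha = alpha)
  }))
  rownames(out) <- NULL
  attr(out, "mean_detected") <- mean_detected
  out
}

#' Full-factorial power study
#'
#' Builds (or reuses) one Monte Carlo null reference, then for every
#' combination of parent-domain variant, `mu_o` level and `sigma` level:
#' calibrates `mu_p` so the alternative matches the null's expected
#' detected count `eta`, and estimates the power of every tracked
#' statistic. Mirrors the long-format layout of a power table, one row per
#' (variant, mu_o, sigma, statistic).
#'
#' @param design A [probe_design()].
#' @param eta Expected detected count for both null and alternatives.
#' @param variants Parent-domain variants to include.
#' @param mu_o_levels,sigma_levels Numeric vectors of factor levels.
#' @param M Null replications (for the shared reference).
#' @param M_prime Alternative replications per cell.
#' @param alpha Significance level.
#' @param families Statistic families to track.
#' @param seed Optional integer seed for the whole study.
#' @param nullref Optionally, a prebuilt [build_null_reference()] to reuse.
#' @param pilot_reps Pilot replications for each `mu_p` calibration.
#' @return Data frame with columns `variant`, `mu_o`, `sigma`, `mu_p`,
#'   `statistic`, `family`, `form`, `arg`, `power`, `mc_se`, `M_prime`,
#'   `alpha`.
#' @export
run_factorial <- function(design, eta, variants = NS_VARIANTS,
                          mu_o_levels = c(375, 1125),
                          sigma_levels = c(500, seq(1000, 10000, by = 1000)),
                          M = 2000, M_prime = 2000, alpha = 0.05,
                          families = FAMILIES, seed = NULL,
                          nullref = NULL, pilot_reps = 1000L) {
  stopifnot(length(mu_o_levels) >= 1L, length(sigma_levels) >= 1L)
  .with_seed(seed, {
    if (is.null(nullref))
      nullref <- build_null_reference(design, eta, M, families = families)
    rows <- list()
    for (variant in variants) for (mu_o in mu_o_levels) for (sigma in sigma_levels) {
      cfg <- ns_config(variant, mu_o = mu_o, sigma = sigma)
      cfg <- calibrate_parent_mean(design, cfg, eta, pilot_reps = pilot_reps)
      pw <- estimate_power(nullref, design, cfg, M_prime, alpha)
      rows[[length(rows) + 1L]] <-
        cbind(variant = variant, mu_o = mu_o, sigma = sigma,
              mu_p = cfg$mu_p, pw)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Optimal fixed arguments from a power table
#'
#' For each (variant, mu_o, sigma, family) cell of a [run_factorial()]
#' table, the fixed argument d or n attaining the highest power -- the
#' companion summary to the maximum-power table.
#'
#' @param power_table A [run_factorial()] result.
#' @return Data frame with one row per cell: the best `arg` and its
#'   `power`.
#' @export
optimal_arguments <- function(power_table) {
  fixed <- power_table[power_table$form == "fixed", ]
  key <- interaction(fixed$variant, fixed$mu_o, fixed$sigma, fixed$family,
                     drop = TRUE)
  picks <- lapply(split(fixed, key), function(df) {
    df[which.max(df$power), c("variant", "mu_o", "sigma", "family",
                              "arg", "power", "mc_se")]
  })
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out[order(out$variant, out$mu_o, out$sigma, out$family), ]
}
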