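# Monte Carlo p-values, per-chromosome testing against a null reference,
# and multiple-testing adjustment.

#' Monte Carlo p-value
#'
#' The add-one estimator \eqn{(1 + \#\{null \ge obs\}) / (1 + M)} (upper
#' tail; `<=` for the lower tail), which has exact type-I error control
#' under the simulated null. Ties count toward the extreme tail. The
#' smallest achievable value is `1 / (1 + M)`; the p-value is never 0.
#'
#' @param observed Observed statistic value.
#' @param null_sample Numeric vector of M simulated null values.
#' @param tail `"upper"` (large values indicate clustering) or `"lower"`.
#' @return A p-value in `(0, 1]`.
#' @examples
#' mc_pvalue(10, 1:9)        # 0.1
#' @export
mc_pvalue <- function(observed, null_sample, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  null_sample <- null_sample[!is.na(null_sample)]
  if (length(null_sample) == 0L)
    stop("empty null sample", call. = FALSE)
  count <- if (tail == "upper") sum(null_sample >= observed)
           else sum(null_sample <= observed)
  (1 + count) / (1 + length(null_sample))
}

# one-sided tail per statistic family (clustering direction)
.family_tail <- function(family) if (family == "dmin") "lower" else "upper"

#' Test one chromosome against a Monte Carlo null reference
#'
#' Computes the observed statistic curves on the reference's grids, their
#' KS and CvM distances to the stored \eqn{\hat G^*} (the same estimate the
#' null samples were scored against), and Monte Carlo p-values for both the
#' functional forms and every fixed-argument statistic. The clustering-
#' direction tail is used throughout: upper for the detection ratios,
#' `nmax` and `gap-count`, lower for `dmin`. Rejection is `p <= alpha`.
#'
#' @param design A [probe_design()] (must be the design the reference was
#'   built on).
#' @param events An [event_set()] of observed SNP genotype differences.
#' @param nullref A [build_null_reference()] result.
#' @param alpha Significance level in `(0, 1)`; `alpha = 0` never rejects.
#' @param statistics `"all"`, `"functional"` (KS/CvM forms only) or
#'   `"fixed"` (fixed-argument statistics only).
#' @return A data frame with one row per statistic: `chromosome`,
#'   `statistic`, `family`, `form` (`"ks"`, `"cvm"` or `"fixed"`), `arg`
#'   (grid argument, `NA` for functional forms), `observed`, `p_value`,
#'   `alpha`, `reject`, `M`, `eta`.
#' @export
test_chromosome <- function(design, events, nullref, alpha = 0.05,
                            statistics = c("all", "functional", "fixed")) {
  statistics <- match.arg(statistics)
  stopifnot(inherits(nullref, "null_reference"),
            inherits(design, "probe_design"), inherits(events, "event_set"))
  if (length(design$positions) != nullref$n_probes)
    warning("design has ", length(design$positions),
            " probes but the null reference was built on ", nullref$n_probes)
  nx <- length(events$positions)
  if (abs(nx - nullref$eta) > 3 * sqrt(nullref$eta))   # beyond Poisson noise
    warning(sprintf("observed |X| = %d is incompatible with the reference's eta = %g (beyond 3 * sqrt(eta)); rebuild the null reference with eta = |X|",
                    nx, nullref$eta))
  span <- design$s_l - design$s_f
  rows <- list()
  for (f in nullref$families) {
    grid <- nullref$grids[[f]]
    cv <- .family_curve(f, design$positions, events$positions,
                        grid$values, span)
    if (!all(cv$defined))
      stop("observed '", f, "' curve undefined at grid point(s) ",
           paste(grid$values[!cv$defined], collapse = ", "), call. = FALSE)
    if (statistics != "fixed") {
      gstar <- nullref$ghat_star[[f]]$values
      e <- cv$values - gstar
      obs_ks <- max(abs(e))
      obs_cvm <- sum(.cvm_weights(grid$values) * e^2)
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = sprintf(c("KS~%s", "CvM~%s"), f),
        family = f, form = c("ks", "cvm"), arg = NA_real_,
        observed = c(obs_ks, obs_cvm),
        p_value = c(mc_pvalue(obs_ks, nullref$null_ks[[f]]),
                    mc_pvalue(obs_cvm, nullref$null_cvm[[f]])),
        stringsAsFactors = FALSE)
    }
    if (statistics != "functional") {
      tail <- .family_tail(f)
      argname <- if (f == "dmin") "n" else "d"
      p <- vapply(seq_len(grid$k), function(i)
        mc_pvalue(cv$values[i], nullref$null_curves[[f]][, i], tail),
        numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = sprintf("%s(%s=%g)", f, argname, grid$values),
        family = f, form = "fixed", arg = grid$values,
        observed = cv$values, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(chromosome = events$chromosome, out,
               alpha = alpha, reject = out$p_value <= alpha,
               M = nullref$M, eta = nullref$eta)
  rownames(out) <- NULL
  out
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni or Benjamini-Hochberg adjustment, as used when testing many
#' chromosomes or samples; thin wrapper over [stats::p.adjust()].
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Enumerate the evaluated statistic suite
#'
#' Lists every statistic implied by a pair of evaluation grids: all five
#' families at each of their fixed arguments plus the KS and CvM functional
#' form of each family. With the default grids (20 distances, 7 cluster
#' sizes) the suite has 20 + 20 + 7 + 20 + 20 fixed-argument statistics and
#' 10 functional forms: 97 statistics in total.
#'
#' @param d_grid,n_grid [stat_grid()]s.
#' @return Data frame with columns `statistic`, `family`, `form`, `arg`.
#' @export
enumerate_statistics <- function(d_grid = default_d_grid(),
                                 n_grid = default_n_grid()) {
  rows <- list()
  for (f in FAMILIES) {
    grid <- if (f == "dmin") n_grid else d_grid
    argname <- if (f == "dmin") "n" else "d"
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = sprintf("%s(%s=%g)", f, argname, grid$values),
      family = f, form = "fixed", arg = grid$values, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = sprintf(c("KS~%s", "CvM~%s"), f),
      family = f, form = c("ks", "cvm"), arg = NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
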