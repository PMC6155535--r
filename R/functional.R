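# Discretized Kolmogorov-Smirnov and Cramer-von Mises distances between an
# observed statistic curve G(.) and a reference curve G*(.) on a shared grid.

#' Reference curve for a statistic family
#'
#' Holds \eqn{\hat G^*(y_i)}, the (usually Monte Carlo) estimate of the
#' null expectation of a statistic curve, aligned to an evaluation grid.
#'
#' @param grid A [stat_grid()].
#' @param values Finite numeric vector aligned to the grid.
#' @param provenance `"monte-carlo"`, `"analytic"` or `"fixture"`.
#' @return A `reference_curve` object.
#' @export
reference_curve <- function(grid, values,
                            provenance = c("monte-carlo", "analytic", "fixture")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(grid, "stat_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$k || any(!is.finite(values)))
    stop("reference values must be finite and aligned to the grid", call. = FALSE)
  structure(list(grid = grid, values = values, provenance = provenance),
            class = "reference_curve")
}

.check_curve_pair <- function(curve, ref) {
  stopifnot(inherits(curve, "stat_curve"), inherits(ref, "reference_curve"))
  if (curve$grid$kind != ref$grid$kind ||
      !identical(curve$grid$values, ref$grid$values))
    stop("curve and reference grids differ", call. = FALSE)
  if (!all(curve$defined))
    stop("curve undefined at grid point(s) ",
         paste(curve$grid$values[!curve$defined], collapse = ", "),
         "; choose a grid where the statistic is defined", call. = FALSE)
}

#' Kolmogorov-Smirnov distance between curve and reference
#'
#' \eqn{\widetilde{KS} = \max_i |G(y_i) - G^*(y_i)|}.
#'
#' @param curve A fully defined [stat_curve()].
#' @param ref A [reference_curve()] on the identical grid.
#' @return Non-negative real.
#' @export
ks_distance <- function(curve, ref) {
  .check_curve_pair(curve, ref)
  max(abs(curve$values - ref$values))
}

#' Cramer-von Mises distance between curve and reference
#'
#' The trapezoid discretization
#' \deqn{\widetilde{CvM} = \frac12 \sum_{i=1}^{k-1}
#'   \{[G(y_i)-G^*(y_i)]^2 + [G(y_{i+1})-G^*(y_{i+1})]^2\}(y_{i+1}-y_i),}
#' implemented verbatim (including the 1/2 factor and squared endpoint sum).
#' Converges to the integrated squared difference as the grid refines.
#' Requires at least 2 grid points.
#'
#' @inheritParams ks_distance
#' @return Non-negative real (units: squared statistic times bp or counts).
#' @export
cvm_distance <- function(curve, ref) {
  .check_curve_pair(curve, ref)
  if (curve$grid$k < 2L)
    stop("CvM needs a grid of at least 2 points", call. = FALSE)
  e2 <- (curve$values - ref$values)^2
  y <- curve$grid$values
  k <- length(y)
  0.5 * sum((e2[-k] + e2[-1L]) * diff(y))
}

# per-grid-point trapezoid weights: CvM = sum(w * e^2) for a fixed grid
.cvm_weights <- function(y) {
  k <- length(y)
  dy <- diff(y)
  w <- numeric(k)
  w[1L] <- dy[1L] / 2
  w[k] <- dy[k - 1L] / 2
  if (k > 2L) w[2:(k - 1L)] <- (dy[-(k - 1L)] + dy[-1L]) / 2
  w
}
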