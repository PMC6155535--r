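# The five neighborhood / gap statistics for a (probe design, event set)
# pair, at fixed arguments and as curves over a grid.
#
# Notation used throughout: S is the sorted probe design, X <= S the sorted
# event positions, N_A(x, d) the number of members of A within distance d of
# x excluding x itself. Distances are integer bp and boundary handling at
# |z - x| = d is exact (no floating point in the counts).

FAMILIES <- c("mean-ratio", "pooled-ratio", "dmin", "nmax", "gap-count")

# counts of `table_pos` members z with 0 < |z - center| <= d, per center;
# table_pos sorted. Binary search via findInterval, O(log n) per query.
.neighbor_counts <- function(table_pos, centers, d) {
  hi <- findInterval(centers + d, table_pos)
  lo <- findInterval(centers - d - 1, table_pos)
  self <- findInterval(centers, table_pos) - findInterval(centers - 1, table_pos)
  hi - lo - self
}

#' Count neighbors within distance d
#'
#' The indicator sum \eqn{N_A(x, d) = \sum_{z \in A} I(0 < |z - x| \le d)}:
#' how many members of a sorted position set lie within `d` bp of `center`,
#' never counting the center position itself.
#'
#' @param positions Sorted numeric vector of positions (the set A).
#' @param center Position(s) to count around (vectorized).
#' @param d Positive distance in bp; the boundary `|z - center| == d` counts.
#' @return Integer count(s), one per center.
#' @examples
#' neighbor_count(c(100, 200, 300, 400, 1000), 100, 150)  # 1
#' @export
neighbor_count <- function(positions, center, d) {
  if (length(d) != 1L || is.na(d) || d <= 0)
    stop("d must be a single positive distance", call. = FALSE)
  if (is.unsorted(positions)) positions <- sort(positions)
  as.integer(.neighbor_counts(positions, center, d))
}

#' Mean detection ratio
#'
#' \eqn{\bar R(d)}: the mean over events x of \eqn{N_X(x,d) / N_S(x,d)} --
#' the fraction of probes near each event that themselves carry events,
#' adjusting for local probe density. Events with no probe within `d`
#' (zero denominator) are excluded from the mean; the exclusion count is
#' attached as `attr(, "n_excluded")`. If every term is excluded (or the
#' event set is empty) the value is `NA`.
#'
#' @param design A [probe_design()].
#' @param events An [event_set()] bound to the design.
#' @param d Positive distance in bp.
#' @return A value in \[0, 1\], or `NA` when undefined.
#' @export
mean_detection_ratio <- function(design, events, d) {
  if (length(d) != 1L || d <= 0) stop("d must be a single positive distance", call. = FALSE)
  X <- events$positions
  if (length(X) == 0L) return(structure(NA_real_, n_excluded = 0L))
  nS <- .neighbor_counts(design$positions, X, d)
  nX <- .neighbor_counts(X, X, d)
  ok <- nS > 0
  val <- if (any(ok)) mean(nX[ok] / nS[ok]) else NA_real_
  structure(val, n_excluded = sum(!ok))
}

#' Pooled mean detection ratio
#'
#' \eqn{\tilde R(d) = \sum_x N_X(x,d) / \sum_x N_S(x,d)}: the recommended
#' base statistic of the package. `NA` when the pooled denominator is zero.
#'
#' @inheritParams mean_detection_ratio
#' @return A value in \[0, 1\], or `NA` when undefined.
#' @export
pooled_detection_ratio <- function(design, events, d) {
  if (length(d) != 1L || d <= 0) stop("d must be a single positive distance", call. = FALSE)
  X <- events$positions
  if (length(X) == 0L) return(NA_real_)
  den <- sum(.neighbor_counts(design$positions, X, d))
  if (den == 0) return(NA_real_)
  sum(.neighbor_counts(X, X, d)) / den
}

# D_min(n) over sorted positions X; `span` is the chromosome span returned
# as a finite sentinel when fewer than n events exist.
.dmin_sorted <- function(X, n, span = NULL) {
  K <- length(X)
  if (K < n) {
    if (is.null(span)) return(NA_real_)
    return(structure(as.numeric(span), sentinel = TRUE))
  }
  l <- seq_len(K - n + 1L)
  best <- X[l + n - 1L] - X[l]           # window width: distance from either endpoint
  if (n >= 3L) {
    for (m in seq_len(n - 2L)) {         # interior members of each window
      cand <- pmax(X[l + m] - X[l], X[l + n - 1L] - X[l + m])
      best <- pmin(best, cand)
    }
  }
  min(best)
}

#' Minimum radius containing n events
#'
#' \eqn{D_{min}(n)}: the smallest distance d such that some event has n
#' events (itself included) within d. Computed by the consecutive-window
#' algorithm: for each run of n consecutive events the best center is the
#' interior member minimizing the larger one-sided reach, and the statistic
#' is the minimum over runs. For `n = 2` this is the minimum adjacent gap.
#'
#' When fewer than `n` events exist, the chromosome span `s_l - s_f` is
#' returned as a finite "no cluster possible" sentinel (flagged with
#' `attr(, "sentinel")`) so that functional forms remain computable;
#' without a `design` the value is `NA`.
#'
#' @param events An [event_set()].
#' @param n Cluster size, integer `>= 2`.
#' @param design Optional [probe_design()] supplying the sentinel span.
#' @return Distance in bp.
#' @examples
#' dmin(event_set("c", c(100, 200, 1000)), 3)  # 800
#' @export
dmin <- function(events, n, design = NULL) {
  if (length(n) != 1L || is.na(n) || n < 2 || n != round(n))
    stop("n must be a single integer >= 2", call. = FALSE)
  span <- if (!is.null(design)) design$s_l - design$s_f else NULL
  .dmin_sorted(events$positions, as.integer(n), span)
}

#' Maximum neighbor count among events
#'
#' \eqn{N_{max}(d) = \max_x N_X(x, d)}: the size (minus the center) of the
#' densest event neighborhood of radius `d`. `NA` for an empty event set;
#' 0 for a singleton.
#'
#' @inheritParams mean_detection_ratio
#' @return Non-negative integer, or `NA`.
#' @export
nmax <- function(events, d) {
  if (length(d) != 1L || d <= 0) stop("d must be a single positive distance", call. = FALSE)
  X <- events$positions
  if (length(X) == 0L) return(NA_integer_)
  max(as.integer(.neighbor_counts(X, X, d)))
}

#' Count of small inter-event gaps
#'
#' \eqn{C(d)}: the number of adjacent inter-event distances strictly less
#' than `d` -- the rainfall-plot statistic. Note the strict inequality
#' (`gap < d`), unlike the `<= d` boundary of the other statistics; this is
#' deliberate and matches the statistic's definition. Returns 0 (flagged)
#' when fewer than 2 events exist.
#'
#' @inheritParams mean_detection_ratio
#' @return Non-negative integer, at most `|X| - 1`.
#' @export
gap_count <- function(events, d) {
  if (length(d) != 1L || d <= 0) stop("d must be a single positive distance", call. = FALSE)
  X <- events$positions
  if (length(X) < 2L) return(structure(0L, flagged = TRUE))
  sum(diff(X) < d)
}

## ---- curves over grids ------------------------------------------------

#' Evaluation grid for statistic curves
#'
#' @param kind `"distance"` (a grid of d values in bp) or `"count"` (a grid
#'   of cluster sizes n, integers `>= 2`; only valid for the `dmin` family).
#' @param values Strictly increasing numeric vector.
#' @return A `stat_grid` object.
#' @export
stat_grid <- function(kind = c("distance", "count"), values) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) || is.unsorted(values, strictly = TRUE))
    stop("grid values must be strictly increasing", call. = FALSE)
  if (kind == "count" && any(values < 2 | values != round(values)))
    stop("count grids need integers >= 2", call. = FALSE)
  if (kind == "distance" && any(values <= 0))
    stop("distance grids need positive values", call. = FALSE)
  structure(list(kind = kind, values = values, k = length(values)),
            class = "stat_grid")
}

#' Default distance grid: 5 kb to 100 kb in 5 kb steps
#' @return A `stat_grid` of 20 distances.
#' @export
default_d_grid <- function() stat_grid("distance", seq(5000, 100000, by = 5000))

#' Default cluster-size grid: n = 2, ..., 8
#' @return A `stat_grid` of 7 counts.
#' @export
default_n_grid <- function() stat_grid("count", 2:8)

# raw curve values for one family; returns list(values, defined)
.family_curve <- function(family, S, X, grid_values, span) {
  k <- length(grid_values)
  vals <- rep(NA_real_, k)
  if (family %in% c("mean-ratio", "pooled-ratio", "nmax")) {
    if (length(X) > 0L) {
      for (i in seq_len(k)) {
        d <- grid_values[i]
        nX <- .neighbor_counts(X, X, d)
        if (family == "nmax") {
          vals[i] <- max(nX)
        } else {
          nS <- .neighbor_counts(S, X, d)
          if (family == "pooled-ratio") {
            den <- sum(nS)
            if (den > 0) vals[i] <- sum(nX) / den
          } else {
            ok <- nS > 0
            if (any(ok)) vals[i] <- mean(nX[ok] / nS[ok])
          }
        }
      }
    }
  } else if (family == "gap-count") {
    g <- if (length(X) >= 2L) diff(X) else numeric(0)
    vals <- vapply(grid_values, function(d) as.numeric(sum(g < d)), numeric(1))
  } else if (family == "dmin") {
    vals <- vapply(grid_values,
                   function(n) as.numeric(.dmin_sorted(X, as.integer(n), span)),
                   numeric(1))
  } else stop("unknown family: ", family, call. = FALSE)
  list(values = vals, defined = !is.na(vals))
}

#' Evaluate a statistic family on a grid
#'
#' @param family One of `"mean-ratio"`, `"pooled-ratio"`, `"dmin"`,
#'   `"nmax"`, `"gap-count"`.
#' @param design A [probe_design()].
#' @param events An [event_set()].
#' @param grid A [stat_grid()]; must be a count grid for `"dmin"` and a
#'   distance grid otherwise.
#' @return A `stat_curve` object: `family`, `grid`, `values` and a logical
#'   `defined` mask marking grid points where the statistic is well defined.
#' @export
stat_curve <- function(family, design, events, grid) {
  family <- match.arg(family, FAMILIES)
  stopifnot(inherits(grid, "stat_grid"))
  needed <- if (family == "dmin") "count" else "distance"
  if (grid$kind != needed)
    stop(sprintf("family '%s' needs a %s grid, got a %s grid",
                 family, needed, grid$kind), call. = FALSE)
  cv <- .family_curve(family, design$positions, events$positions,
                      grid$values, design$s_l - design$s_f)
  structure(list(family = family, grid = grid,
                 values = cv$values, defined = cv$defined),
            class = "stat_curve")
}

#' @export
print.stat_curve <- function(x, ...) {
  cat(sprintf("Statistic curve '%s' on %d %s grid point(s)\n",
              x$family, x$grid$k, x$grid$kind))
  print(stats::setNames(x$values, x$grid$values))
  invisible(x)
}
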