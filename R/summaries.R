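# Descriptive summaries of a probe design and of an event landscape:
# inter-locus distances, probe deserts, nearest-neighbor coverage, and
# rainfall points.

.as_design_list <- function(x) {
  if (inherits(x, "probe_design")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, logical(1), "probe_design"))) x
  else stop("expected a probe_design or a list of them", call. = FALSE)
}

#' Inter-locus distances of a probe design
#'
#' Adjacent differences of the sorted probe positions, pooled over the
#' supplied chromosomes, with the usual location summaries. The distances
#' sum to `s_l - s_f` per chromosome.
#'
#' @param x A [probe_design()] or list of them.
#' @return List with `distances` (the pooled multiset), `mean`, `min`,
#'   `max` and `quartiles`.
#' @export
inter_locus_distances <- function(x) {
  designs <- .as_design_list(x)
  if (any(vapply(designs, function(d) length(d$positions) < 2L, logical(1))))
    stop("every chromosome needs at least 2 probes", call. = FALSE)
  dist <- unlist(lapply(designs, function(d) diff(d$positions)),
                 use.names = FALSE)
  list(distances = dist,
       mean = mean(dist), min = min(dist), max = max(dist),
       quartiles = stats::quantile(dist, c(0.25, 0.5, 0.75)))
}

#' Probe deserts
#'
#' Runs between adjacent probe loci strictly longer than `threshold`
#' (default 1 Mb) where no SNP genotype difference is detectable by design.
#'
#' @param x A [probe_design()] or list of them.
#' @param threshold Gap threshold in bp; the comparison is strict
#'   (`gap > threshold`).
#' @return Data frame sorted by decreasing gap: `chromosome`,
#'   `left_probe`, `right_probe`, `gap`.
#' @export
probe_deserts <- function(x, threshold = 1e6) {
  designs <- .as_design_list(x)
  rows <- lapply(designs, function(d) {
    g <- diff(d$positions)
    i <- which(g > threshold)
    data.frame(chromosome = rep(d$chromosome, length(i)),
               left_probe = d$positions[i],
               right_probe = d$positions[i + 1L],
               gap = g[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$gap), ]
  rownames(out) <- NULL
  out
}

#' Fraction of loci with a near neighbor
#'
#' The count and fraction of probe loci whose nearest same-chromosome
#' neighbor lies within `d` bp, pooled over the supplied chromosomes.
#' Chromosome-end loci have a one-sided neighbor.
#'
#' @param x A [probe_design()] or list of them.
#' @param d Distance in bp (inclusive boundary).
#' @return List with `count`, `total` and `fraction`.
#' @export
neighbor_fraction <- function(x, d) {
  designs <- .as_design_list(x)
  counts <- vapply(designs, function(des) {
    p <- des$positions
    g <- diff(p)
    nn <- pmin(c(Inf, g), c(g, Inf))   # nearest-neighbor distance per locus
    sum(nn <= d)
  }, numeric(1))
  total <- sum(vapply(designs, function(des) length(des$positions), numeric(1)))
  list(count = sum(counts), total = total, fraction = sum(counts) / total)
}

#' Rainfall points for an event set
#'
#' For each event after the first, its position and distance to the
#' previous event -- the coordinates of a rainfall plot (log-scaling of
#' the distance axis is left to the renderer). The distances are exactly
#' the multiset of adjacent inter-event gaps that [gap_count()] thresholds.
#'
#' @param events An [event_set()].
#' @return Data frame with columns `position` and `distance_to_previous`;
#'   empty (with a warning) when fewer than 2 events exist.
#' @export
rainfall_points <- function(events) {
  X <- events$positions
  if (length(X) < 2L) {
    warning("fewer than 2 events; no rainfall points")
    return(data.frame(position = numeric(0),
                      distance_to_previous = numeric(0)))
  }
  data.frame(position = X[-1L], distance_to_previous = diff(X))
}
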