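# S3 containers for a probe design (the array's target loci on one chromosome)
# and an event set (the loci where SNP genotype differences were called).

#' Probe design for one chromosome
#'
#' A probe design is the fixed, sorted set of genomic positions (1-based bp)
#' assayed by the array on one chromosome. Only events at these sites are
#' observable; every statistic in this package is conditional on the design.
#'
#' @param chromosome Chromosome label, e.g. `"chr19"`.
#' @param positions Numeric vector of positive integer bp positions.
#'   Duplicates are collapsed (a probe design is a set) and positions are
#'   sorted.
#'
#' @return An object of class `probe_design` with elements `chromosome`,
#'   `positions` (strictly increasing), `s_f` (first probe) and `s_l`
#'   (last probe).
#' @examples
#' probe_design("chr19", c(100, 300, 200))
#' @export
probe_design <- function(chromosome, positions) {
  positions <- .validate_positions(positions, "probe design")
  if (length(positions) < 2L)
    stop("a probe design needs at least 2 distinct positions", call. = FALSE)
  structure(
    list(chromosome = as.character(chromosome)[1L],
         positions = positions,
         s_f = positions[1L],
         s_l = positions[length(positions)]),
    class = "probe_design")
}

#' Set of detected SNP genotype differences on one chromosome
#'
#' Event positions are the loci where a SNP genotype difference was called
#' when contrasting two samples. When bound to a [probe_design()] via
#' [bind_events()] every position must be a probe target locus.
#'
#' @param chromosome Chromosome label.
#' @param positions Numeric vector of positive integer bp positions; may be
#'   empty. Duplicates collapse, positions are sorted.
#' @return An object of class `event_set` with elements `chromosome` and
#'   `positions`.
#' @examples
#' event_set("chr6", c(500, 120))
#' @export
event_set <- function(chromosome, positions = numeric(0)) {
  positions <- .validate_positions(positions, "event set", allow_empty = TRUE)
  structure(
    list(chromosome = as.character(chromosome)[1L], positions = positions),
    class = "event_set")
}

.validate_positions <- function(positions, what, allow_empty = FALSE) {
  positions <- as.numeric(positions)
  if (length(positions) == 0L) {
    if (allow_empty) return(numeric(0))
    stop(what, " has no positions", call. = FALSE)
  }
  if (anyNA(positions) || any(positions != round(positions)) ||
      any(positions < 1))
    stop(what, " positions must be positive integers (1-based bp)",
         call. = FALSE)
  ndup <- length(positions) - length(unique(positions))
  if (ndup > 0L)
    message(ndup, " duplicate position(s) collapsed in ", what)
  sort(unique(positions))
}

#' @export
print.probe_design <- function(x, ...) {
  cat(sprintf("Probe design: %s, %d loci spanning [%s, %s] bp\n",
              x$chromosome, length(x$positions),
              format(x$s_f, big.mark = ",", scientific = FALSE),
              format(x$s_l, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("Event set: %s, %d SNP genotype difference(s)\n",
              x$chromosome, length(x$positions)))
  invisible(x)
}

#' @export
length.probe_design <- function(x) length(x$positions)

#' @export
length.event_set <- function(x) length(x$positions)
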