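# CSV/BED readers and writers for probe designs and event sets.
#
# The CSV dialect is a header `chromosome,position` (names remappable via
# `columns`); extra columns are ignored. BED3 input (0-based half-open,
# width-1 intervals) is converted to 1-based positions on read.

.read_position_table <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(columns), names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  chrom <- as.character(df[[columns[["chromosome"]]]])
  pos_raw <- df[[columns[["position"]]]]
  pos <- suppressWarnings(as.numeric(pos_raw))
  bad <- which(is.na(pos) | pos != round(pos) | pos < 1)
  if (length(bad))
    stop("non-integer or non-positive position at data line ",
         paste(utils::head(bad, 5L), collapse = ", "), " of ", path,
         call. = FALSE)
  data.frame(chromosome = chrom, position = pos, stringsAsFactors = FALSE)
}

#' Read a probe design from CSV or BED
#'
#' @param path Path to a CSV file with columns `chromosome,position`
#'   (1-based bp) or a BED3 file (0-based half-open intervals of width 1;
#'   converted to 1-based on read).
#' @param dialect `"csv"` or `"bed"`.
#' @param columns Named character vector remapping the CSV column names,
#'   e.g. `c(chromosome = "chr", position = "bp")`.
#' @return A named list of [probe_design()] objects, one per chromosome.
#' @export
read_probe_design <- function(path, dialect = c("csv", "bed"),
                              columns = c(chromosome = "chromosome",
                                          position = "position")) {
  dialect <- match.arg(dialect)
  tab <- if (dialect == "csv") {
    .read_position_table(path, columns)
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    bed <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 3L) stop("BED input needs at least 3 columns", call. = FALSE)
    if (any(bed[[3L]] - bed[[2L]] != 1L))
      warning("BED intervals wider than 1 bp; using start + 1 as the locus")
    data.frame(chromosome = as.character(bed[[1L]]),
               position = as.numeric(bed[[2L]]) + 1,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (ch in unique(tab$chromosome))
    out[[ch]] <- probe_design(ch, tab$position[tab$chromosome == ch])
  out
}

#' Read event positions from CSV
#'
#' @inheritParams read_probe_design
#' @return A named list of [event_set()] objects keyed by chromosome; empty
#'   list for an empty file.
#' @export
read_event_positions <- function(path,
                                 columns = c(chromosome = "chromosome",
                                             position = "position")) {
  tab <- .read_position_table(path, columns)
  if (nrow(tab) == 0L) return(structure(list(), names = character(0)))
  out <- list()
  for (ch in unique(tab$chromosome))
    out[[ch]] <- event_set(ch, tab$position[tab$chromosome == ch])
  out
}

#' Write positions back to CSV
#'
#' Round-trips exactly with [read_probe_design()] / [read_event_positions()].
#'
#' @param x A `probe_design` or `event_set` (or list of them).
#' @param path Output CSV path.
#' @export
write_positions <- function(x, path) {
  if (inherits(x, c("probe_design", "event_set"))) x <- list(x)
  df <- do.call(rbind, lapply(x, function(obj)
    data.frame(chromosome = obj$chromosome,
               position = format(obj$positions, scientific = FALSE, trim = TRUE),
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an event set against a probe design
#'
#' Detected SNP genotype differences are by construction a subset of the
#' probe target loci; this enforces (or repairs) that contract.
#'
#' @param events An [event_set()].
#' @param design A [probe_design()] on the same chromosome.
#' @param policy `"strict"` errors if any event is off-design;
#'   `"drop"` removes off-design events and records how many.
#' @return The validated `event_set`; under `"drop"` the number of removed
#'   positions is attached as `attr(, "n_dropped")`.
#' @export
bind_events <- function(events, design, policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  stopifnot(inherits(events, "event_set"), inherits(design, "probe_design"))
  if (events$chromosome != design$chromosome)
    stop("chromosome mismatch: events on ", events$chromosome,
         ", design on ", design$chromosome, call. = FALSE)
  off <- setdiff(events$positions, design$positions)
  if (length(off) == 0L) {
    attr(events, "n_dropped") <- 0L
    return(events)
  }
  if (policy == "strict")
    stop("event position(s) not in probe design: ",
         paste(utils::head(off, 10L), collapse = ", "), call. = FALSE)
  kept <- event_set(events$chromosome,
                    intersect(events$positions, design$positions))
  attr(kept, "n_dropped") <- length(off)
  kept
}
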