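# Genomic interval bookkeeping. All intervals are 1-based with inclusive
# ends inside the package; BED I/O converts to/from 0-based half-open at the
# boundary and nowhere else.

#' Construct a set of genomic intervals
#'
#' Builds the interval data frame used throughout the package (callability
#' masks, RoH segments, truth tracts): one row per interval with 1-based
#' inclusive coordinates.
#'
#' @param scaffold character vector of scaffold identifiers.
#' @param start,end integer vectors, 1-based inclusive; `end >= start`.
#' @return A `data.frame` with columns `scaffold`, `start`, `end`.
#' @export
genomic_intervals <- function(scaffold = character(), start = integer(),
                              end = integer()) {
  if (length(scaffold) == 1 && length(start) > 1)
    scaffold <- rep(scaffold, length(start))
  stopifnot(length(scaffold) == length(start), length(start) == length(end))
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 1)) stop("interval start must be >= 1")
  if (any(end < start)) stop("interval end must be >= start")
  data.frame(scaffold = as.character(scaffold), start = start, end = end,
             stringsAsFactors = FALSE)
}

# split an interval data.frame into a named list of IRanges per scaffold
.as_iranges_list <- function(x) {
  if (nrow(x) == 0) return(list())
  sp <- split(seq_len(nrow(x)), x$scaffold)
  lapply(sp, function(i) IRanges::IRanges(start = x$start[i], end = x$end[i]))
}

.from_iranges <- function(ir, scaffold) {
  if (length(ir) == 0) return(genomic_intervals())
  genomic_intervals(rep(scaffold, length(ir)), IRanges::start(ir),
                    IRanges::end(ir))
}

#' Merge overlapping or adjacent intervals
#'
#' @param x interval data frame (`scaffold`, `start`, `end`).
#' @return Merged, sorted interval data frame.
#' @export
merge_intervals <- function(x) {
  irl <- .as_iranges_list(x)
  out <- lapply(names(irl), function(s) .from_iranges(IRanges::reduce(irl[[s]]), s))
  if (length(out) == 0) return(genomic_intervals())
  out <- do.call(rbind, out)
  out[order(out$scaffold, out$start), , drop = FALSE]
}

#' Intersect two interval sets
#'
#' @param a,b interval data frames.
#' @return Interval data frame of the base pairs present in both sets.
#' @export
intersect_intervals <- function(a, b) {
  ia <- .as_iranges_list(merge_intervals(a))
  ib <- .as_iranges_list(merge_intervals(b))
  common <- intersect(names(ia), names(ib))
  out <- lapply(common, function(s)
    .from_iranges(IRanges::intersect(ia[[s]], ib[[s]]), s))
  if (length(out) == 0) return(genomic_intervals())
  out <- do.call(rbind, out)
  out[order(out$scaffold, out$start), , drop = FALSE]
}

#' Subtract one interval set from another
#'
#' @param a,b interval data frames; returns `a` minus `b`.
#' @return Interval data frame.
#' @export
setdiff_intervals <- function(a, b) {
  a <- merge_intervals(a)
  ia <- .as_iranges_list(a)
  ib <- .as_iranges_list(merge_intervals(b))
  out <- lapply(names(ia), function(s) {
    if (is.null(ib[[s]])) return(.from_iranges(ia[[s]], s))
    .from_iranges(IRanges::setdiff(ia[[s]], ib[[s]]), s)
  })
  if (length(out) == 0) return(genomic_intervals())
  out <- do.call(rbind, out)
  out[order(out$scaffold, out$start), , drop = FALSE]
}

#' Total base pairs covered by an interval set
#'
#' @param x interval data frame.
#' @param merged set `TRUE` when `x` is already non-overlapping to skip the
#'   merge.
#' @return numeric, total bp.
#' @export
intervals_bp <- function(x, merged = FALSE) {
  if (!merged) x <- merge_intervals(x)
  if (nrow(x) == 0) return(0)
  sum(x$end - x$start + 1)
}

#' Read a BED3 file as 1-based inclusive intervals
#'
#' @param path BED file (0-based half-open on disk).
#' @return interval data frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(genomic_intervals())
  f <- strsplit(lines, "\t")
  genomic_intervals(vapply(f, `[`, "", 1L),
                    as.numeric(vapply(f, `[`, "", 2L)) + 1,
                    as.numeric(vapply(f, `[`, "", 3L)))
}

#' Write intervals as BED3
#'
#' @param x interval data frame (1-based inclusive in memory).
#' @param path output path.
#' @param header optional comment lines (each prefixed with `#`).
#' @export
write_bed <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  if (nrow(x) > 0) {
    writeLines(sprintf("%s\t%d\t%d", x$scaffold, as.integer(x$start - 1),
                       as.integer(x$end)), con)
  }
  invisible(path)
}

#' Read a genome index (scaffold lengths)
#'
#' Two-column TSV: scaffold identifier and length in bp. The scaffold that
#' aligns to the X chromosome, if any, is flagged so coverage-based
#' exclusion can apply its stricter threshold.
#'
#' @param path TSV path.
#' @param x_scaffold identifier of the X-aligned scaffold, or `NULL`.
#' @return `data.frame` with columns `scaffold`, `length`, `is_x`.
#' @export
read_genome_index <- function(path, x_scaffold = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("scaffold", "length"),
                           colClasses = c("character", "numeric"))
  genome_index(tab$scaffold, tab$length, x_scaffold)
}

#' Construct a genome index in memory
#'
#' @param scaffold character scaffold names (unique).
#' @param length numeric lengths in bp (> 0).
#' @param x_scaffold identifier of the X-aligned scaffold, or `NULL`.
#' @return `data.frame` with columns `scaffold`, `length`, `is_x`.
#' @export
genome_index <- function(scaffold, length, x_scaffold = NULL) {
  if (anyDuplicated(scaffold)) stop("scaffold identifiers must be unique")
  if (any(length <= 0)) stop("scaffold lengths must be > 0")
  data.frame(scaffold = as.character(scaffold), length = as.numeric(length),
             is_x = as.character(scaffold) %in% x_scaffold,
             stringsAsFactors = FALSE)
}
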