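# Overlapping-window heterozygosity tracks: the observation sequence of the
# segmentation HMM. Default geometry is 150-kb windows advancing by 50 kb
# (100-kb overlap), anchored at position 1 of each scaffold.

#' Build a per-sample window heterozygosity track
#'
#' Tiles each retained scaffold with overlapping windows and computes, per
#' window, the callable bp and the heterozygous-site count, giving the
#' window heterozygosity ratio `het_count / callable_bp`. Windows start on
#' the grid `1, 1+step, 1+2*step, ...` with `step = width - overlap`; a
#' trailing window running past the scaffold end is truncated there, and
#' grid windows that would add no new sequence beyond the previous window's
#' end are not emitted. Windows with zero callable bp carry an undefined
#' (NA) ratio and are flagged; they are excluded from fitting and decoding
#' and break state runs.
#'
#' @param het_sites `data.frame` with columns `scaffold`, `pos`: positions of
#'   the sample's heterozygous genotypes (already restricted to the mask).
#' @param mask callability mask (interval data frame).
#' @param index genome index; only its scaffolds are tiled.
#' @param width window width in bp (default 150,000).
#' @param overlap overlap between consecutive windows in bp (default
#'   100,000); `step = width - overlap`.
#' @param sample sample identifier stored in the track.
#' @return A `window_track`: data frame with columns `sample`, `scaffold`,
#'   `start`, `end`, `callable_bp`, `het_count`, `het_ratio`,
#'   `noncallable_bp`, plus attributes `width` and `step`.
#' @export
build_window_track <- function(het_sites, mask, index, width = 150000L,
                               overlap = 100000L, sample = "sample") {
  if (width <= 0) stop("width must be > 0")
  if (overlap >= width || overlap < 0) stop("overlap must be in [0, width)")
  step <- width - overlap
  mask <- merge_intervals(mask)
  mask_irl <- .as_iranges_list(mask)
  out <- vector("list", nrow(index))
  for (k in seq_len(nrow(index))) {
    scaf <- index$scaffold[k]
    L <- index$length[k]
    starts <- seq(1, L, by = step)
    ends <- pmin(starts + width - 1, L)
    keep <- !duplicated(ends)          # drop trailing windows adding no bp
    starts <- starts[keep]; ends <- ends[keep]
    n <- length(starts)
    callable <- numeric(n)
    hets <- integer(n)
    if (!is.null(mask_irl[[scaf]])) {
      cov <- IRanges::coverage(mask_irl[[scaf]], width = as.integer(L))
      v <- IRanges::Views(cov, start = as.integer(starts), end = as.integer(ends))
      callable <- as.numeric(IRanges::viewSums(v))
    }
    pos <- het_sites$pos[het_sites$scaffold == scaf]
    if (length(pos) > 0) {
      w <- IRanges::IRanges(start = as.integer(starts), end = as.integer(ends))
      hets <- IRanges::countOverlaps(w, IRanges::IRanges(as.integer(pos), width = 1))
    }
    out[[k]] <- data.frame(sample = sample, scaffold = scaf, start = starts,
                           end = ends, callable_bp = callable,
                           het_count = as.integer(hets),
                           stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, out)
  track$het_ratio <- ifelse(track$callable_bp > 0,
                            track$het_count / track$callable_bp, NA_real_)
  track$noncallable_bp <- (track$end - track$start + 1) - track$callable_bp
  structure(track, width = width, step = step, class = c("window_track",
                                                         "data.frame"))
}

#' Build a window track directly from a ratio sequence
#'
#' Constructs a fully-callable single-sample track on the standard window
#' grid from a given heterozygosity-ratio sequence (NA entries become
#' undefined windows). Convenient for constructing controlled observation
#' sequences when the object of interest is the segmentation itself rather
#' than the windowing.
#'
#' @param ratios numeric vector of window het ratios (NA = undefined); a
#'   named list of vectors gives one scaffold per element.
#' @param width,overlap window geometry (defaults 150,000 / 100,000).
#' @param sample sample identifier.
#' @return A `window_track`.
#' @export
synthetic_window_track <- function(ratios, width = 150000L,
                                   overlap = 100000L, sample = "synthetic") {
  if (!is.list(ratios)) ratios <- list(s1 = ratios)
  step <- width - overlap
  out <- lapply(names(ratios), function(scaf) {
    r <- ratios[[scaf]]
    starts <- 1 + (seq_along(r) - 1) * step
    data.frame(sample = sample, scaffold = scaf, start = starts,
               end = starts + width - 1,
               callable_bp = ifelse(is.na(r), 0, width),
               het_count = as.integer(round(ifelse(is.na(r), 0, r) * width)),
               het_ratio = r, noncallable_bp = ifelse(is.na(r), width, 0),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), width = as.integer(width),
            step = as.integer(step),
            class = c("window_track", "data.frame"))
}

#' Window ratios eligible for emission-prior initialization
#'
#' Returns the heterozygosity ratios of windows whose noncallable bp is
#' strictly below `max_noncallable`, in track order. Gappy windows carry
#' noisy ratios and are kept out of the k-means initialization.
#'
#' @param track a `window_track`.
#' @param max_noncallable exclusive upper bound on noncallable bp
#'   (default 60,000).
#' @return Numeric vector of ratios.
#' @export
filter_windows_for_init <- function(track, max_noncallable = 60000) {
  keep <- track$noncallable_bp < max_noncallable & !is.na(track$het_ratio)
  ratios <- track$het_ratio[keep]
  if (length(ratios) < 3)
    stop("fewer than 3 windows survive the noncallable filter; cannot seed k-means")
  ratios
}

#' Write / read a window track as TSV
#'
#' @param track a `window_track`.
#' @param path file path.
#' @param header optional comment lines (prefixed `#`).
#' @export
write_window_track <- function(track, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  writeLines(sprintf("#width=%d\tstep=%d", attr(track, "width"),
                     attr(track, "step")), con)
  utils::write.table(track, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_track
#' @export
read_window_track <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^#width=", lines)]
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  width <- as.integer(sub("^#width=(\\d+).*", "\\1", meta[1]))
  step <- as.integer(sub(".*step=(\\d+)$", "\\1", meta[1]))
  structure(tab, width = width, step = step,
            class = c("window_track", "data.frame"))
}
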