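# RoH colocalization across samples: pairwise Jaccard coefficients on base
# pairs and the sharing spectrum (bp by carrier count).

#' Jaccard coefficient between two RoH sets
#'
#' Shared RoH base pairs divided by the union of the two samples' RoH base
#' pairs: `|A n B| / (|A| + |B| - |A n B|)`. When both sets are empty the
#' coefficient is defined as 0 and flagged via attribute `degenerate`.
#'
#' @param a,b interval data frames (or `roh_segments`) per sample.
#' @return numeric in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- merge_intervals(genomic_intervals(a$scaffold, a$start, a$end))
  b <- merge_intervals(genomic_intervals(b$scaffold, b$start, b$end))
  bp_a <- intervals_bp(a, merged = TRUE)
  bp_b <- intervals_bp(b, merged = TRUE)
  if (bp_a + bp_b == 0) return(structure(0, degenerate = TRUE))
  shared <- intervals_bp(intersect_intervals(a, b))
  shared / (bp_a + bp_b - shared)
}

#' Pairwise Jaccard matrix over all samples
#'
#' @param sets named list of per-sample interval data frames.
#' @return symmetric numeric matrix with entries in `[0, 1]`; the diagonal
#'   is 1 for samples with at least one RoH bp, 0 otherwise.
#' @export
jaccard_matrix <- function(sets) {
  n <- length(sets)
  out <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      out[i, j] <- out[j, i] <- as.numeric(jaccard(sets[[i]], sets[[j]]))
    }
  }
  out
}

#' RoH sharing spectrum
#'
#' For every genomic base pair, the number of samples whose RoH covers it,
#' computed by an interval sweep (never per-bp loops). Returns the total bp
#' at each carrier count 0..n plus each sample's private RoH bp (bp covered
#' by that sample alone).
#'
#' @param sets named list of per-sample interval data frames.
#' @param index genome index (defines total genome size for count 0).
#' @return list with `spectrum` (`data.frame`: `carriers`, `bp`) and
#'   `private_bp` (named numeric per sample).
#' @export
sharing_spectrum <- function(sets, index) {
  if (length(sets) < 2) stop("need at least 2 samples")
  n <- length(sets)
  merged <- lapply(sets, function(s)
    .as_iranges_list(merge_intervals(genomic_intervals(s$scaffold, s$start, s$end))))
  bp_at <- numeric(n + 1)         # carriers 0..n
  names(bp_at) <- 0:n
  private <- stats::setNames(numeric(n), names(sets))
  for (k in seq_len(nrow(index))) {
    scaf <- index$scaffold[k]
    L <- as.integer(index$length[k])
    covs <- lapply(merged, function(m)
      if (is.null(m[[scaf]])) S4Vectors::Rle(0L, L)
      else IRanges::coverage(m[[scaf]], width = L))
    total <- Reduce(`+`, covs)
    tab <- tapply(S4Vectors::runLength(total), S4Vectors::runValue(total), sum)
    bp_at[names(tab)] <- bp_at[names(tab)] + tab
    single <- total == 1L
    for (s in names(sets)) {
      priv <- single & (covs[[s]] == 1L)
      private[s] <- private[s] + sum(S4Vectors::runLength(priv)[S4Vectors::runValue(priv)])
    }
  }
  list(spectrum = data.frame(carriers = 0:n, bp = as.numeric(bp_at)),
       private_bp = private)
}
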