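# Variant input and site filtering.
#
# A variant table holds the filtered biallelic SNVs that every downstream
# heterozygosity computation consumes: per-site metadata plus per-sample
# genotype and depth matrices. Genotypes are coded 0 (hom-ref), 1 (het),
# 2 (hom-alt), NA (missing); any genotype containing a missing allele is
# missing, and phased separators are treated as unphased.

.GT_CODES <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)

.parse_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt <- sub(":.*$", "", gt)
  out <- .GT_CODES[gt]
  matrix(out, nrow = NROW(gt), dimnames = dimnames(gt))
}

#' Construct a variant table
#'
#' @param site `data.frame` with columns `scaffold`, `pos`, `ref`, `alt`,
#'   `qual` (one row per site, input order preserved).
#' @param gt integer matrix, sites x samples, values 0/1/2/NA.
#' @param dp numeric matrix of read depths, same shape as `gt`.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(site, gt, dp) {
  stopifnot(nrow(site) == nrow(gt), all(dim(gt) == dim(dp)))
  if (is.null(colnames(gt))) stop("gt matrix must carry sample names")
  structure(list(site = site, gt = gt, dp = dp,
                 samples = colnames(gt)), class = "variant_table")
}

#' @describeIn variant_table compact summary.
#' @param x a `variant_table`.
#' @param ... ignored.
#' @method print variant_table
#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples on %d scaffold(s)\n",
              nrow(x$site), length(x$samples),
              length(unique(x$site$scaffold))))
  invisible(x)
}

#' Read a multi-sample VCF into a variant table
#'
#' Reads a VCF v4.2 file (plain or bgzipped), keeping only biallelic SNVs.
#' Records with more than one ALT allele or non-SNV alleles are rejected and
#' counted in a warning; they are not decomposed.
#'
#' @param path VCF path.
#' @return A `variant_table`; the number of rejected records is attached as
#'   attribute `n_rejected`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  snv <- !is.na(alt) & !grepl(",", alt) & nchar(alt) == 1 & nchar(ref) == 1
  n_rejected <- sum(!snv)
  if (n_rejected > 0)
    warning(sprintf("%d multi-allelic or non-SNV record(s) rejected", n_rejected))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dp_raw)) dp_raw <- matrix(NA_real_, nrow(gt_raw), ncol(gt_raw),
                                        dimnames = dimnames(gt_raw))
  site <- data.frame(scaffold = fix[, "CHROM"],
                     pos = as.numeric(fix[, "POS"]),
                     ref = ref, alt = alt,
                     qual = as.numeric(fix[, "QUAL"]),
                     stringsAsFactors = FALSE)
  gt_mat <- .parse_gt(gt_raw)[snv, , drop = FALSE]
  dp_mat <- dp_raw[snv, , drop = FALSE]
  rownames(gt_mat) <- NULL
  rownames(dp_mat) <- NULL
  rownames(site) <- NULL
  vt <- variant_table(site[snv, , drop = FALSE], gt_mat, dp_mat)
  attr(vt, "n_rejected") <- n_rejected
  vt
}

#' Apply site and genotype filters to a variant table
#'
#' Mirrors a VCFtools-style post-calling filter chain. Depth is applied per
#' genotype: a genotype covered by fewer than `depth_min` or more than
#' `depth_max` reads is set to missing at that sample only. Site quality,
#' missingness and minor allele frequency then drop whole sites; the
#' missingness and MAF tests both use the depth-masked genotypes. Input
#' order is preserved.
#'
#' @param vt `variant_table`.
#' @param depth_min,depth_max inclusive per-genotype depth bounds
#'   (defaults 3 and 30 reads).
#' @param qual_min minimum phred-scaled site quality (default 30).
#' @param max_missing_frac drop sites missing in more than this fraction of
#'   samples (default 0.20).
#' @param maf_min minimum minor allele frequency computed from non-missing
#'   genotypes (default 0.02).
#' @return Filtered `variant_table` with a `filter_stats` attribute counting
#'   sites dropped per test and genotypes masked.
#' @export
filter_variants <- function(vt, depth_min = 3, depth_max = 30, qual_min = 30,
                            max_missing_frac = 0.20, maf_min = 0.02) {
  gt <- vt$gt
  dp <- vt$dp
  bad_depth <- !is.na(dp) & (dp < depth_min | dp > depth_max)
  n_masked <- sum(bad_depth & !is.na(gt))
  gt[bad_depth] <- NA_integer_

  n <- ncol(gt)
  nonmiss <- rowSums(!is.na(gt))
  miss_frac <- (n - nonmiss) / n
  alt_count <- rowSums(gt, na.rm = TRUE)
  p <- ifelse(nonmiss > 0, alt_count / (2 * nonmiss), NA_real_)
  maf <- pmin(p, 1 - p)

  fail_qual <- !is.na(vt$site$qual) & vt$site$qual < qual_min
  fail_empty <- nonmiss == 0
  fail_miss <- miss_frac > max_missing_frac
  fail_maf <- !fail_empty & maf < maf_min
  keep <- !(fail_qual | fail_empty | fail_miss | fail_maf)

  out <- variant_table(vt$site[keep, , drop = FALSE],
                       gt[keep, , drop = FALSE],
                       dp[keep, , drop = FALSE])
  # a site can fail several tests; attribute it to the first in the order
  # quality -> zero non-missing -> missingness -> MAF
  attr(out, "filter_stats") <- list(
    n_in = nrow(vt$site), n_out = sum(keep), genotypes_masked = n_masked,
    dropped_qual = sum(fail_qual),
    dropped_empty = sum(fail_empty & !fail_qual),
    dropped_missing = sum(fail_miss & !fail_qual & !fail_empty),
    dropped_maf = sum(fail_maf & !fail_qual & !fail_empty & !fail_miss))
  out
}

#' Select scaffolds by minimum length
#'
#' Keeps scaffolds strictly longer than `min_len`; the analysis is restricted
#' to these large autosome-scale scaffolds.
#'
#' @param index genome index (`genome_index()`).
#' @param min_len minimum length in bp, exclusive (default 45 Mb).
#' @return Character vector of retained scaffold identifiers, with the
#'   retained fraction of assembly bp as attribute `retained_frac`.
#' @export
select_scaffolds <- function(index, min_len = 45e6) {
  stopifnot(min_len > 0)
  keep <- index$length > min_len
  if (!any(keep)) stop("no scaffold exceeds min_len; pipeline cannot proceed")
  out <- index$scaffold[keep]
  attr(out, "retained_frac") <- sum(index$length[keep]) / sum(index$length)
  out
}

#' Flag coverage-outlier windows for exclusion
#'
#' Windows whose mean depth deviates from the genome-wide mean by more than
#' `sd_x` standard deviations on the X-aligned scaffold, or `sd_auto`
#' elsewhere, are returned as intervals to subtract from the callability
#' mask. The asymmetric thresholds remove sex-linked regions, where coverage
#' in the heterogametic sex is systematically shifted.
#'
#' @param coverage_windows `data.frame` with `scaffold`, `start`, `end`,
#'   `mean_depth` per window.
#' @param index genome index carrying the `is_x` flag.
#' @param sd_x,sd_auto SD multipliers (defaults 1 and 2).
#' @return Interval data frame of excluded regions (merged).
#' @export
exclude_coverage_outliers <- function(coverage_windows, index,
                                      sd_x = 1, sd_auto = 2) {
  mu <- mean(coverage_windows$mean_depth)
  sdv <- stats::sd(coverage_windows$mean_depth)
  if (is.na(sdv) || sdv == 0) {
    warning("coverage is constant; no windows excluded")
    return(genomic_intervals())
  }
  is_x <- coverage_windows$scaffold %in% index$scaffold[index$is_x]
  k <- ifelse(is_x, sd_x, sd_auto)
  out <- abs(coverage_windows$mean_depth - mu) > k * sdv
  merge_intervals(genomic_intervals(coverage_windows$scaffold[out],
                                    coverage_windows$start[out],
                                    coverage_windows$end[out]))
}

#' Heterozygous-site positions of one sample within the mask
#'
#' @param vt a `variant_table`.
#' @param mask callability mask (interval data frame).
#' @param sample sample identifier.
#' @return `data.frame` with columns `scaffold`, `pos`.
#' @export
het_sites <- function(vt, mask, sample) {
  g <- vt$gt[, sample]
  het <- !is.na(g) & g == 1L
  sites <- vt$site[het, c("scaffold", "pos")]
  if (nrow(sites) == 0) return(sites)
  irl <- .as_iranges_list(merge_intervals(mask))
  keep <- logical(nrow(sites))
  for (s in unique(sites$scaffold)) {
    i <- sites$scaffold == s
    if (is.null(irl[[s]])) next
    q <- IRanges::IRanges(sites$pos[i], width = 1)
    keep[i] <- IRanges::countOverlaps(q, irl[[s]]) > 0
  }
  sites[keep, , drop = FALSE]
}

#' Genome-wide heterozygosity of one sample
#'
#' Heterozygous genotypes per base pair of the callable genome, with a
#' per-scaffold breakdown.
#'
#' @param vt filtered `variant_table`.
#' @param mask callability mask (interval data frame).
#' @param sample sample identifier.
#' @return A list: `rate` (het sites / callable bp), `het_count`,
#'   `callable_bp`, and `per_scaffold` data frame.
#' @export
genome_wide_heterozygosity <- function(vt, mask, sample) {
  mask <- merge_intervals(mask)
  callable <- intervals_bp(mask, merged = TRUE)
  if (callable <= 0) stop("zero callable bp")
  sites <- het_sites(vt, mask, sample)
  per_scaf_bp <- tapply(mask$end - mask$start + 1, mask$scaffold, sum)
  counts <- table(factor(sites$scaffold, levels = names(per_scaf_bp)))
  per_scaffold <- data.frame(scaffold = names(per_scaf_bp),
                             het_count = as.integer(counts),
                             callable_bp = as.numeric(per_scaf_bp),
                             stringsAsFactors = FALSE)
  per_scaffold$rate <- per_scaffold$het_count / per_scaffold$callable_bp
  list(rate = nrow(sites) / callable, het_count = nrow(sites),
       callable_bp = callable, per_scaffold = per_scaffold)
}
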