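# Genomic inbreeding coefficients and their comparison across estimators
# and cohorts.

#' RoH-based inbreeding coefficient
#'
#' Fraction of the autosomal genome lying inside RoH: total merged segment
#' length divided by the total length of the retained autosomal scaffolds.
#'
#' @param segments a `roh_segments` data frame (one sample).
#' @param autosome_len total bp of the retained autosomal scaffolds.
#' @return numeric in `[0, 1]`.
#' @export
f_roh <- function(segments, autosome_len) {
  if (autosome_len <= 0) stop("autosome_len must be > 0")
  if (nrow(segments) == 0) return(0)
  intervals_bp(genomic_intervals(segments$scaffold, segments$start,
                                 segments$end)) / autosome_len
}

#' Method-of-moments inbreeding coefficient from homozygote counts
#'
#' Wright-style F from observed versus expected homozygous genotype counts,
#' the convention of VCFtools' `--het`: `F = (O - E) / (N - E)` where `O` is
#' the sample's observed homozygous site count, `N` its genotyped site
#' count, and `E = sum_i (1 - 2 p_i (1 - p_i) * n_i / (n_i - 1))` the
#' expected homozygous count under Hardy-Weinberg with the unbiased
#' finite-sample correction (`n_i` = non-missing allele count at site `i`,
#' `p_i` = alt allele frequency over all non-missing genotypes). Sites where
#' the sample is missing, or with fewer than 2 non-missing alleles, are
#' excluded for that sample. Can be negative (excess heterozygosity).
#'
#' @param vt filtered `variant_table`.
#' @param sample sample identifier.
#' @return numeric coefficient, or `NA` when `N - E = 0`.
#' @export
f_hom <- function(vt, sample) {
  g <- vt$gt[, sample]
  nonmiss <- rowSums(!is.na(vt$gt))
  n_alleles <- 2 * nonmiss
  p <- rowSums(vt$gt, na.rm = TRUE) / n_alleles
  use <- !is.na(g) & n_alleles >= 2
  exp_hom <- 1 - 2 * p[use] * (1 - p[use]) * n_alleles[use] / (n_alleles[use] - 1)
  E <- sum(exp_hom)
  N <- sum(use)
  O <- sum(g[use] != 1L)
  if (abs(N - E) < .Machine$double.eps * N) return(NA_real_)
  (O - E) / (N - E)
}

#' Assemble the per-sample inbreeding table
#'
#' @param samples character vector of sample identifiers.
#' @param groups group label per sample (e.g. cohort).
#' @param f_roh1 HMM-caller F_ROH per sample.
#' @param f_roh2 baseline-caller F_ROH per sample.
#' @param f_hom F_HOM per sample.
#' @param f_ped pedigree F per sample (NA where the sample has no studbook
#'   match).
#' @return `data.frame` with one row per sample.
#' @export
inbreeding_table <- function(samples, groups, f_roh1, f_roh2 = NA_real_,
                             f_hom = NA_real_, f_ped = NA_real_) {
  data.frame(sample = samples, group = groups, F_ROH1 = f_roh1,
             F_ROH2 = f_roh2, F_HOM = f_hom, F_PED = f_ped,
             stringsAsFactors = FALSE)
}

#' Spearman correlation matrix of inbreeding estimators
#'
#' Rank correlations for all estimator pairs with two-sided p-values,
#' pairwise-complete: a pair involving F_PED automatically restricts to the
#' samples that have pedigree data.
#'
#' @param table inbreeding table ([inbreeding_table()]).
#' @param columns estimator columns to correlate.
#' @return list with `rho` and `p` matrices (unit diagonal / zero p on the
#'   diagonal) and `n` matrix of complete-pair counts; entries with fewer
#'   than 3 complete pairs are NA.
#' @export
correlation_matrix <- function(table,
                               columns = c("F_ROH1", "F_ROH2", "F_HOM", "F_PED")) {
  columns <- columns[columns %in% names(table)]
  m <- length(columns)
  rho <- matrix(NA_real_, m, m, dimnames = list(columns, columns))
  pmat <- rho
  nmat <- matrix(0L, m, m, dimnames = list(columns, columns))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      x <- table[[columns[i]]]
      y <- table[[columns[j]]]
      ok <- !is.na(x) & !is.na(y)
      nmat[i, j] <- sum(ok)
      if (i == j) { rho[i, j] <- 1; pmat[i, j] <- 0; next }
      if (sum(ok) < 3) next
      ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                             exact = FALSE))
      rho[i, j] <- unname(ct$estimate)
      pmat[i, j] <- ct$p.value
    }
  }
  list(rho = rho, p = pmat, n = nmat)
}

#' Pairwise group comparisons of an inbreeding or heterozygosity metric
#'
#' Either pairwise two-sided Wilcoxon rank-sum tests with Benjamini-Hochberg
#' adjustment, or one-way ANOVA followed by Tukey's HSD. Groups with fewer
#' than 2 members are excluded with a warning.
#'
#' @param values numeric metric per sample.
#' @param groups group label per sample.
#' @param test `"wilcoxon_bh"` or `"anova_tukey"`.
#' @return `data.frame` of group pairs with the adjusted p-value (and, for
#'   Tukey, the estimated difference and 95% interval). For `anova_tukey`
#'   the ANOVA p-value is attached as attribute `anova_p`.
#' @export
compare_groups <- function(values, groups, test = c("wilcoxon_bh", "anova_tukey")) {
  test <- match.arg(test)
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding group(s) of size < 2: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need at least 2 groups of size >= 2")
  if (test == "wilcoxon_bh") {
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(values, groups, p.adjust.method = "BH",
                                  exact = FALSE))
    m <- pw$p.value
    out <- data.frame(group1 = rownames(m)[row(m)[!is.na(m)]],
                      group2 = colnames(m)[col(m)[!is.na(m)]],
                      p_adj = m[!is.na(m)], stringsAsFactors = FALSE)
    return(out[order(out$group1, out$group2), , drop = FALSE])
  }
  g <- factor(groups)
  fit <- stats::aov(values ~ g)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(group1 = vapply(pairs, `[`, "", 1L),
                    group2 = vapply(pairs, `[`, "", 2L),
                    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "anova_p") <- anova_p
  out
}
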