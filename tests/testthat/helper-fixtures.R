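# Fixture builders; everything is generated in code at test time.

# 200-site variant table with known per-filter failures, 30 samples.
# Layout (1-based site indices):
#   1-150   pass everything
#   151-160 QUAL 20                    -> dropped (quality)
#   161-170 8/30 genotypes missing     -> dropped (missingness > 20%)
#   171-180 singleton alt (MAF 1/60)   -> dropped (MAF < 0.02)
#   181-190 one genotype at depth 2    -> genotype masked, site retained
#   191-200 every genotype at depth 1  -> dropped (zero non-missing)
# Hand count of survivors: 150 + 10 = 160.
make_filter_fixture <- function() {
  n_sites <- 200L
  n_samp <- 30L
  samples <- sprintf("G%02d", seq_len(n_samp))
  set.seed(42)
  gt <- matrix(0L, n_sites, n_samp, dimnames = list(NULL, samples))
  # common variation so MAF passes: 10 alt carriers (hets) per ordinary site
  for (i in seq_len(n_sites)) gt[i, sample.int(n_samp, 10)] <- 1L
  qual <- rep(60, n_sites)
  dp <- matrix(10, n_sites, n_samp, dimnames = list(NULL, samples))
  qual[151:160] <- 20
  for (i in 161:170) gt[i, 1:8] <- NA_integer_
  for (i in 171:180) { gt[i, ] <- 0L; gt[i, 5] <- 1L }
  dp[181:190, 3] <- 2
  dp[191:200, ] <- 1
  site <- data.frame(scaffold = "s1", pos = seq_len(n_sites) * 1000,
                     ref = "A", alt = "T", qual = qual,
                     stringsAsFactors = FALSE)
  variant_table(site, gt, dp)
}

# the 5-site worked F_HOM fixture (values hand-computed in test-inbreeding)
make_fhom_fixture <- function() {
  gt <- rbind(c(0L, 1L, 2L),
              c(0L, 0L, 0L),
              c(1L, 1L, 1L),
              c(2L, 2L, 1L),
              c(0L, NA, 2L))
  colnames(gt) <- c("A", "B", "C")
  site <- data.frame(scaffold = "s1", pos = 1:5 * 100, ref = "A", alt = "G",
                     qual = 60, stringsAsFactors = FALSE)
  variant_table(site, gt, matrix(7, 5, 3, dimnames = dimnames(gt)))
}

# track with noisy background ratios and planted low-het runs; runs is a
# list of c(first_window, n_windows)
make_two_regime_track <- function(n_windows, runs, bg = 2.5e-4, low = 1e-5,
                                  seed = 1, width = 150000, overlap = 100000) {
  set.seed(seed)
  rate <- rep(bg, n_windows)
  for (r in runs) rate[r[1]:(r[1] + r[2] - 1)] <- low
  ratios <- rpois(n_windows, rate * width) / width
  synthetic_window_track(ratios, width = width, overlap = overlap)
}

# small fixture pedigrees (all <= 12 individuals) used for the
# tabular-vs-path-counting oracle checks
fixture_pedigrees <- function() {
  list(
    founders_only = pedigree(id = c("A", "B", "C"), sire = 0, dam = 0),
    trio = pedigree(id = c("A", "B", "X"), sire = c(0, 0, "A"),
                    dam = c(0, 0, "B")),
    full_sibs_child = pedigree(
      id = c("A", "B", "S1", "S2", "X"),
      sire = c(0, 0, "A", "A", "S1"),
      dam = c(0, 0, "B", "B", "S2")),
    half_sibs_child = pedigree(
      id = c("A", "B", "C", "H1", "H2", "X"),
      sire = c(0, 0, 0, "A", "A", "H1"),
      dam = c(0, 0, 0, "B", "C", "H2")),
    # 4 founders, 3 generations: a small managed-programme genealogy
    three_gen = pedigree(
      id = c("F1", "F2", "F3", "F4", "C1", "C2", "C3", "G1", "G2", "H1"),
      sire = c(0, 0, 0, 0, "F1", "F1", "F3", "C1", "C3", "G1"),
      dam = c(0, 0, 0, 0, "F2", "F4", "F2", "C2", "C2", "G2")),
    unknown_parent = pedigree(
      id = c("A", "B", "X", "Y"),
      sire = c(0, 0, "A", "X"),
      dam = c(0, 0, 0, "B"))
  )
}

random_hmm_params <- function(k = 3) {
  means <- sort(runif(k, 0, 5e-4))
  vars <- runif(k, 1e-10, 5e-9)
  pi0 <- rgamma(k, 1); pi0 <- pi0 / sum(pi0)
  A <- matrix(rgamma(k * k, 1), k, k); A <- A / rowSums(A)
  list(means = means, vars = vars, pi0 = pi0, A = A)
}
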