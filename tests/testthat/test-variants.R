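test_that("filter chain reproduces the hand count on the 200-site fixture", {
  vt <- make_filter_fixture()
  out <- filter_variants(vt)
  st <- attr(out, "filter_stats")
  expect_equal(st$n_out, 160)
  expect_equal(st$dropped_qual, 10)
  expect_equal(st$dropped_missing, 10)
  expect_equal(st$dropped_maf, 10)
  expect_equal(st$dropped_empty, 10)
  # depth-masked genotype is missing but its site survives
  expect_true(all(is.na(out$gt[out$site$pos %in% (181:190 * 1000), "G03"])))
  expect_true(all((181:190 * 1000) %in% out$site$pos))
  # input order preserved
  expect_true(!is.unsorted(out$site$pos))
})

test_that("MAF and missingness thresholds sit exactly where stated", {
  # 30 samples; singleton het -> MAF 1/60 < 0.02 -> dropped;
  # doubleton -> 2/60 = 0.033 -> kept
  gt <- matrix(0L, 2, 30, dimnames = list(NULL, sprintf("G%02d", 1:30)))
  gt[1, 1] <- 1L
  gt[2, 1:2] <- 1L
  site <- data.frame(scaffold = "s1", pos = c(100, 200), ref = "A", alt = "T",
                     qual = 60, stringsAsFactors = FALSE)
  vt <- variant_table(site, gt, matrix(10, 2, 30, dimnames = dimnames(gt)))
  out <- filter_variants(vt)
  expect_equal(out$site$pos, 200)
  # exactly 20% missing is kept (threshold is "more than")
  gt2 <- matrix(1L, 1, 30, dimnames = list(NULL, sprintf("G%02d", 1:30)))
  gt2[1, 1:6] <- NA_integer_
  vt2 <- variant_table(site[1, ], gt2, matrix(10, 1, 30, dimnames = dimnames(gt2)))
  expect_equal(attr(filter_variants(vt2), "filter_stats")$n_out, 1)
  gt2[1, 7] <- NA_integer_   # 7/30 = 23% missing
  vt3 <- variant_table(site[1, ], gt2, matrix(10, 1, 30, dimnames = dimnames(gt2)))
  expect_equal(attr(filter_variants(vt3), "filter_stats")$n_out, 0)
})

test_that("filtering is idempotent", {
  vt <- make_filter_fixture()
  once <- filter_variants(vt)
  twice <- filter_variants(once)
  expect_equal(twice$site, once$site)
  expect_equal(twice$gt, once$gt)
})

test_that("VCF write/read round trip preserves the table", {
  cfg <- sim_config(scaffold_lengths = c(s1 = 2e6, s2 = 1e6), n_samples = 3,
                    target_fraction = 0.2, seed = 5)
  ds <- emit_dataset(plant_tracts(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(ds$vt, path, contigs = cfg$scaffold_lengths)
  back <- read_variants(path)
  expect_equal(back$site$pos, ds$vt$site$pos)
  expect_equal(back$gt, ds$vt$gt)
  expect_equal(back$dp, ds$vt$dp, ignore_attr = TRUE)
  expect_equal(back$site$qual, ds$vt$site$qual)
})

test_that("multi-allelic records are rejected with a counted warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "A", "B"), collapse = "\t"),
               "s1\t100\t.\tA\tT\t60\t.\t.\tGT:DP\t0/1:8\t0/0:9",
               "s1\t200\t.\tA\tT,G\t60\t.\t.\tGT:DP\t1/2:8\t0/0:9",
               "s1\t300\t.\tA\tTTG\t60\t.\t.\tGT:DP\t0/1:8\t0/0:9"), path)
  expect_warning(vt <- read_variants(path), "2 multi-allelic")
  expect_equal(nrow(vt$site), 1)
  expect_equal(attr(vt, "n_rejected"), 2)
})

test_that("scaffold selection is strictly greater-than", {
  gi <- genome_index(c("s1", "s2", "s3"), c(46e6, 45e6, 10e6))
  expect_equal(as.character(select_scaffolds(gi)), "s1")
  gi2 <- genome_index("s1", 45000001)
  expect_equal(as.character(select_scaffolds(gi2)), "s1")
  expect_equal(attr(select_scaffolds(gi), "retained_frac"), 46 / 101)
  expect_error(select_scaffolds(genome_index("s1", 1e6)), "cannot proceed")
})

test_that("coverage outliers use 1 SD on X and 2 SD on autosomes", {
  gi <- genome_index(c("auto", "chrX"), c(1e6, 1e6), x_scaffold = "chrX")
  # 100 windows at exactly mean 7 sd 1 by construction
  set.seed(3)
  base <- rep(c(6, 8), 50)
  cw <- data.frame(scaffold = rep(c("auto", "chrX"), each = 50),
                   start = rep(seq(1, 50 * 1e4, by = 1e4), 2),
                   end = rep(seq(1e4, 50 * 1e4, by = 1e4), 2),
                   mean_depth = base)
  cw$mean_depth[1] <- 8.5    # auto, 1.5 SD -> retained
  cw$mean_depth[51] <- 8.5   # X, 1.5 SD -> excluded
  mu <- mean(cw$mean_depth); sdv <- sd(cw$mean_depth)
  exc <- exclude_coverage_outliers(cw, gi)
  expect_true(all(exc$scaffold == "chrX"))
  expect_true(any(exc$start == cw$start[51]))
  expect_false(any(exc$scaffold == "auto" & exc$start == cw$start[1] &
                     abs(8.5 - mu) < 2 * sdv))
  expect_warning(
    exclude_coverage_outliers(data.frame(scaffold = "auto", start = 1,
                                         end = 10, mean_depth = c(7, 7)),
                              gi), "constant")
})

test_that("coverage exclusion recovers spiked windows in simulation", {
  set.seed(9)
  n <- 500
  cw <- data.frame(scaffold = "auto", start = seq(1, n * 1e4, by = 1e4),
                   end = seq(1e4, n * 1e4, by = 1e4),
                   mean_depth = rnorm(n, 7, 1))
  spiked <- sample.int(n, 10)
  cw$mean_depth[spiked] <- 15
  gi <- genome_index("auto", n * 1e4)
  exc <- exclude_coverage_outliers(cw, gi)
  expect_true(all(cw$start[spiked] %in%
                    unlist(Map(seq, exc$start, exc$end, by = 1e4))))
})

test_that("genome-wide heterozygosity is count over callable bp", {
  samples <- "S"
  n <- 240
  gt <- matrix(1L, n, 1, dimnames = list(NULL, samples))
  site <- data.frame(scaffold = "s1", pos = seq_len(n) * 4000, ref = "A",
                     alt = "T", qual = 60, stringsAsFactors = FALSE)
  vt <- variant_table(site, gt, matrix(10, n, 1, dimnames = dimnames(gt)))
  mask <- genomic_intervals("s1", 1, 1e6)
  h <- genome_wide_heterozygosity(vt, mask, "S")
  expect_equal(h$rate, 2.4e-4)
  expect_equal(h$per_scaffold$het_count, 240)
  # no het sites -> 0
  gt0 <- matrix(0L, n, 1, dimnames = list(NULL, samples))
  vt0 <- variant_table(site, gt0, matrix(10, n, 1, dimnames = dimnames(gt0)))
  expect_equal(genome_wide_heterozygosity(vt0, mask, "S")$rate, 0)
  expect_error(genome_wide_heterozygosity(vt, genomic_intervals(), "S"),
               "callable")
})

test_that("shrinking the mask never increases the het count", {
  cfg <- sim_config(scaffold_lengths = c(s1 = 5e6), n_samples = 2,
                    target_fraction = 0.2, seed = 21)
  ds <- emit_dataset(plant_tracts(cfg), cfg)
  vt <- filter_variants(ds$vt)
  full <- genome_wide_heterozygosity(vt, ds$mask, "S01")
  shrunk_mask <- intersect_intervals(ds$mask, genomic_intervals("s1", 1, 2.5e6))
  shrunk <- genome_wide_heterozygosity(vt, shrunk_mask, "S01")
  expect_lte(shrunk$het_count, full$het_count)
  expect_lte(shrunk$callable_bp, full$callable_bp)
})
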