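test_that("k-means init recovers perfectly separated clusters exactly", {
  ratios <- rep(c(1e-4, 3e-4, 9e-4), each = 10)
  init <- kmeans3_init(ratios, seed = 1)
  expect_equal(init$means, c(1e-4, 3e-4, 9e-4))
  expect_equal(init$weights, rep(1 / 3, 3))
  expect_error(kmeans3_init(rep(2e-4, 30), seed = 1), "distinct")
})

test_that("k-means init recovers mixture component means within 5%", {
  set.seed(31)
  x <- c(rnorm(1000, 1e-5, 2e-6), rnorm(1000, 2.5e-4, 2e-5),
         rnorm(1000, 6e-4, 4e-5))
  init <- kmeans3_init(x, seed = 7)
  expect_equal(init$means[1], 1e-5, tolerance = 0.05)
  expect_equal(init$means[2], 2.5e-4, tolerance = 0.05)
  expect_equal(init$means[3], 6e-4, tolerance = 0.05)
  expect_equal(init$weights, rep(1 / 3, 3), tolerance = 0.05)
  # deterministic given the seed
  expect_identical(init, kmeans3_init(x, seed = 7))
})

test_that("Baum-Welch raises likelihood above the init and stays monotone", {
  tr <- make_two_regime_track(60, list(c(20, 10)), seed = 3)
  init <- kmeans3_init(filter_windows_for_init(tr), seed = 1)
  m <- fit_baum_welch(tr, init, seed = 1)
  expect_gte(m$log_likelihood, m$ll_history[1])
  expect_true(all(diff(m$ll_history) >= -1e-8 * abs(m$log_likelihood)))
  expect_equal(rowSums(m$transition), rep(1, 3), tolerance = 1e-9)
  expect_true(all(m$variances >= m$var_floor))
  expect_equal(m$roh_state, which.min(m$means))
})

test_that("a constant-dominated input converges one state to the constant", {
  set.seed(5)
  ratios <- c(rep(2e-4, 50), rpois(10, 37.5) / 150000)
  tr <- synthetic_window_track(ratios)
  init <- list(means = c(1e-4, 2e-4, 3e-4), variances = rep(1e-9, 3),
               weights = c(0.2, 0.6, 0.2))
  m <- fit_baum_welch(tr, init, seed = 2)
  expect_true(any(abs(m$means - 2e-4) < 1e-6))
  expect_true(all(diff(m$ll_history) >= -1e-8 * abs(m$log_likelihood)))
})

test_that("two-regime fit puts the RoH state mean within 20% of truth", {
  tr <- make_two_regime_track(400, list(c(50, 40), c(200, 60), c(320, 30)),
                              bg = 2.5e-4, low = 1e-5, seed = 11)
  init <- kmeans3_init(filter_windows_for_init(tr), seed = 4)
  m <- fit_baum_welch(tr, init, seed = 4)
  expect_equal(m$means[m$roh_state], 1e-5, tolerance = 0.2)
})

test_that("posterior columns sum to one along the sequence", {
  set.seed(41)
  p <- random_hmm_params()
  x <- rnorm(50, sample(p$means, 50, replace = TRUE), 1e-5)
  fb <- rohmm:::.forward_backward(x, p$pi0, p$A, p$means, p$vars)
  expect_equal(rowSums(fb$gamma), rep(1, 50), tolerance = 1e-9)
})

test_that("Viterbi equals exhaustive enumeration on short random instances", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    p <- random_hmm_params()
    x <- abs(rnorm(n, sample(p$means, n, replace = TRUE), 3e-5))
    tr <- synthetic_window_track(x)
    model <- structure(list(means = p$means, variances = p$vars,
                            weights = p$pi0, transition = p$A,
                            start_probs = p$pi0,
                            roh_state = which.min(p$means)),
                       class = "hmm_model")
    got <- as.integer(decode_states(tr, model))
    oracle <- viterbi_brute(x, p$pi0, p$A, p$means, p$vars)
    expect_equal(got, oracle$path)
  }
})

test_that("equidistant observations break ties toward the lower state", {
  # unit-scale parameters so the two distances are bit-identical
  model <- structure(list(means = c(1, 3, 9), variances = rep(1, 3),
                          weights = rep(1 / 3, 3),
                          transition = matrix(1 / 3, 3, 3),
                          start_probs = rep(1 / 3, 3), roh_state = 1L),
                     class = "hmm_model")
  tr <- synthetic_window_track(rep(2, 5))     # equidistant from states 1 and 2
  expect_equal(as.integer(decode_states(tr, model)), rep(1L, 5))
})

test_that("segment coordinates follow the run-length convention", {
  # 3-window run -> 150,001 bp; 2-window run -> nothing; 5-window -> 250,001
  ratios <- rep(2.5e-4, 30)
  for (case in list(list(at = 10, n = 3, len = 150001),
                    list(at = 10, n = 2, len = NULL),
                    list(at = 10, n = 5, len = 250001))) {
    r <- ratios
    r[case$at:(case$at + case$n - 1)] <- 1e-6
    tr <- synthetic_window_track(r)
    segs <- baseline_threshold_caller(tr, ratio_cutoff = 1e-4)
    if (is.null(case$len)) {
      expect_equal(nrow(segs), 0)
    } else {
      expect_equal(nrow(segs), 1)
      expect_equal(segs$length, case$len)
      expect_equal(segs$start, tr$start[case$at])
      expect_equal(segs$n_windows, case$n)
    }
  }
})

test_that("undefined windows break runs and runs stop at scaffold ends", {
  r <- rep(2.5e-4, 40)
  r[10:16] <- 1e-6
  r[13] <- NA          # break inside the low run: two short runs of 3
  tr <- synthetic_window_track(r)
  segs <- baseline_threshold_caller(tr, ratio_cutoff = 1e-4)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$length, c(150001, 150001))
  # a run reaching the last window still follows the n * step + 1 rule:
  # with 150-kb windows on a 50-kb step the window span always extends
  # beyond the segment end, so no truncation is needed
  r2 <- c(rep(2.5e-4, 10), rep(1e-6, 5))
  tr2 <- synthetic_window_track(r2)
  segs2 <- baseline_threshold_caller(tr2, ratio_cutoff = 1e-4)
  expect_equal(segs2$end, tr2$start[11] + 5 * 50000)
  expect_equal(segs2$length, 250001)
  expect_lte(segs2$end, max(tr2$end))
})

test_that("permuting the init labels leaves the called RoH unchanged", {
  tr <- make_two_regime_track(200, list(c(40, 20), c(120, 30)), seed = 13)
  init <- kmeans3_init(filter_windows_for_init(tr), seed = 9)
  A0 <- matrix(c(.8, .1, .1, .1, .8, .1, .1, .1, .8), 3, 3, byrow = TRUE)
  perm <- c(3, 1, 2)
  init_p <- list(means = init$means[perm], variances = init$variances[perm],
                 weights = init$weights[perm])
  m1 <- fit_baum_welch(tr, init, seed = 9, trans_init = A0)
  m2 <- fit_baum_welch(tr, init_p, seed = 9,
                       trans_init = A0[perm, perm])
  r1 <- call_roh(decode_states(tr, m1), tr)
  r2 <- call_roh(decode_states(tr, m2), tr)
  expect_equal(r1$start, r2$start)
  expect_equal(r1$end, r2$end)
})

test_that("no called segment is ever shorter than min_windows * step + 1", {
  set.seed(71)
  step <- 50000
  for (rep in 1:15) {
    r <- rpois(150, runif(1, 10, 50)) / 150000
    r[sample.int(150, 5)] <- NA
    tr <- synthetic_window_track(r)
    segs <- baseline_threshold_caller(tr, ratio_cutoff = runif(1, 5e-5, 3e-4))
    if (nrow(segs) > 0) expect_true(all(segs$length >= 3 * step + 1))
  }
})

test_that("HMM and threshold callers agree on per-sample RoH fractions", {
  set.seed(83)
  genome_bp <- 400 * 50000
  froh_hmm <- froh_base <- numeric(20)
  for (i in 1:20) {
    # per-sample autozygous load varies so the correlation is meaningful
    n_runs <- sample(2:8, 1)
    at <- sort(sample(seq(5, 380, by = 15), n_runs))
    runs <- lapply(at, function(a) c(a, sample(4:12, 1)))
    tr <- make_two_regime_track(400, runs, seed = 1000 + i)
    init <- kmeans3_init(filter_windows_for_init(tr), seed = i)
    m <- fit_baum_welch(tr, init, seed = i)
    segs <- call_roh(decode_states(tr, m), tr)
    froh_hmm[i] <- f_roh(segs, genome_bp)
    froh_base[i] <- f_roh(baseline_threshold_caller(tr), genome_bp)
  }
  expect_gt(cor(froh_hmm, froh_base), 0.9)
})

test_that("model YAML round trip preserves the fitted parameters", {
  tr <- make_two_regime_track(60, list(c(20, 8)), seed = 19)
  init <- kmeans3_init(filter_windows_for_init(tr), seed = 3)
  m <- fit_baum_welch(tr, init, seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_hmm_model(m, path)
  back <- read_hmm_model(path)
  expect_equal(back$means, m$means)
  expect_equal(back$transition, m$transition, ignore_attr = TRUE)
  expect_equal(back$roh_state, m$roh_state)
  expect_equal(back$log_likelihood, m$log_likelihood)
})

test_that("fit errors on too-few decodable windows", {
  tr <- synthetic_window_track(c(1e-4, 2e-4, 3e-4, NA, 2e-4))
  init <- list(means = c(1e-4, 2e-4, 3e-4), variances = rep(1e-10, 3),
               weights = rep(1 / 3, 3))
  expect_error(fit_baum_welch(tr, init, seed = 1), "fewer than 10")
})
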