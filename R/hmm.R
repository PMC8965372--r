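# 3-state Gaussian-emission HMM over window heterozygosity ratios.
#
# The state with the lowest emission mean is interpreted as putative RoH;
# the other two states absorb the remaining heterozygosity fluctuations.
# Emission priors come from 1-D k-means on clean windows, transition priors
# are Dirichlet-random, both are then refined by Baum-Welch (EM on scaled
# forward-backward statistics), and segmentation is Viterbi by default.

# split a track into decodable observation sequences: runs of windows with a
# defined ratio, per scaffold. Undefined windows break sequences.
.track_sequences <- function(track) {
  seqs <- list()
  for (scaf in unique(track$scaffold)) {
    idx <- which(track$scaffold == scaf)
    ok <- !is.na(track$het_ratio[idx])
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      rows <- idx[starts[j]:ends[j]]
      seqs[[length(seqs) + 1]] <- list(scaffold = scaf, rows = rows,
                                       x = track$het_ratio[rows])
    }
  }
  seqs
}

# deterministic k-means++ seeding
.kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  for (j in 2:k) {
    d2 <- Reduce(pmin, lapply(centers[seq_len(j - 1)], function(cc) (x - cc)^2))
    if (sum(d2) == 0) {
      centers[j] <- x[sample.int(length(x), 1)]
    } else {
      centers[j] <- x[sample.int(length(x), 1, prob = d2)]
    }
  }
  centers
}

#' k-means initialization of the emission priors
#'
#' Partitions the window heterozygosity ratios into three clusters by 1-D
#' k-means (deterministic k-means++ seeding under `seed`, then Lloyd
#' iterations) and returns the empirical means, variances and weights of the
#' clusters, sorted by ascending mean, as Gaussian emission priors.
#'
#' @param ratios numeric vector of window heterozygosity ratios (from
#'   [filter_windows_for_init()]).
#' @param seed integer RNG seed.
#' @param k number of clusters (default 3).
#' @param var_floor minimum emission variance in ratio^2 units
#'   (default 1e-12); also applied to clusters of size < 2.
#' @return A list with `means`, `variances`, `weights` (each length `k`,
#'   sorted by mean) and `sizes`.
#' @export
kmeans3_init <- function(ratios, seed = 1L, k = 3L, var_floor = 1e-12) {
  if (length(unique(ratios)) < k)
    stop("need at least ", k, " distinct ratio values for k-means")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  centers <- unique(.kmeanspp_centers(ratios, k))
  if (length(centers) < k)
    centers <- stats::quantile(unique(ratios), probs = seq(0, 1, length.out = k),
                               names = FALSE)
  km <- suppressWarnings(stats::kmeans(ratios, centers = matrix(centers),
                                       algorithm = "Lloyd", iter.max = 200))
  ord <- order(km$centers[, 1])
  means <- as.numeric(km$centers[ord, 1])
  sizes <- km$size[ord]
  vars <- numeric(k)
  for (j in seq_len(k)) {
    pts <- ratios[km$cluster == ord[j]]
    if (length(pts) < 2) {
      warning("k-means cluster of size < 2; variance set to the floor")
      vars[j] <- var_floor
    } else {
      vars[j] <- max(stats::var(pts) * (length(pts) - 1) / length(pts), var_floor)
    }
  }
  list(means = means, variances = vars, weights = sizes / length(ratios),
       sizes = sizes)
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# emission density matrix (T x k), floored to keep scaled recursions finite
.emission_matrix <- function(x, means, vars) {
  k <- length(means)
  B <- vapply(seq_len(k),
              function(j) stats::dnorm(x, means[j], sqrt(vars[j])),
              numeric(length(x)))
  B <- matrix(B, ncol = k)
  pmax(B, 1e-300)
}

# scaled forward-backward for one sequence; returns loglik and EM statistics
.forward_backward <- function(x, pi0, A, means, vars) {
  Tn <- length(x)
  k <- length(pi0)
  B <- .emission_matrix(x, means, vars)
  alpha <- matrix(0, Tn, k)
  cvec <- numeric(Tn)
  a <- pi0 * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (Tn > 1) {
    for (t in 2:Tn) {
      a <- (alpha[t - 1, ] %*% A)[1, ] * B[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
  }
  beta <- matrix(0, Tn, k)
  beta[Tn, ] <- 1
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ]))[, 1] / cvec[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, k, k)
  if (Tn > 1) {
    for (t in seq_len(Tn - 1)) {
      xi <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A / cvec[t + 1]
      xi_sum <- xi_sum + xi
    }
  }
  list(loglik = sum(log(cvec)), gamma = gamma, xi_sum = xi_sum, B = B)
}

#' Fit the 3-state Gaussian HMM by Baum-Welch
#'
#' Runs expectation-maximization on the window heterozygosity sequences of
#' one sample. Scaffolds (and stretches separated by undefined windows) are
#' treated as independent observation sequences sharing one parameter set.
#' Emission means/variances, transition matrix and start probabilities are
#' all re-estimated. The forward-backward recursions use per-step scaling,
#' so likelihoods remain finite at any sequence length.
#'
#' @param track a `window_track` for one sample.
#' @param init emission priors from [kmeans3_init()].
#' @param seed integer seed for the Dirichlet(1,1,1) random initialization of
#'   the transition rows.
#' @param tol stop when the log-likelihood improves by less than this
#'   (default 1e-6).
#' @param max_iter maximum EM iterations (default 1000).
#' @param var_floor minimum emission variance (default 1e-12).
#' @param trans_init optional row-stochastic matrix overriding the random
#'   transition initialization.
#' @return An `hmm_model`: list with `means`, `variances`, `weights`,
#'   `transition`, `start_probs`, `roh_state` (index of the lowest-mean
#'   state), `log_likelihood`, `ll_history`, `n_iterations`, `seed`.
#' @export
fit_baum_welch <- function(track, init, seed = 1L, tol = 1e-6,
                           max_iter = 1000L, var_floor = 1e-12,
                           trans_init = NULL) {
  seqs <- .track_sequences(track)
  n_obs <- sum(lengths(lapply(seqs, `[[`, "x")))
  if (n_obs < 10) stop("fewer than 10 decodable windows; cannot fit HMM")
  k <- length(init$means)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  A <- if (is.null(trans_init)) {
    matrix(stats::rgamma(k * k, shape = 1), k, k)      # Dirichlet(1,..,1) rows
  } else {
    stopifnot(all(dim(trans_init) == k))
    trans_init
  }
  A <- A / rowSums(A)
  pi0 <- init$weights / sum(init$weights)
  means <- init$means
  vars <- pmax(init$variances, var_floor)

  ll_history <- numeric(0)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    pi_acc <- numeric(k)
    A_num <- matrix(0, k, k)
    g_sum <- numeric(k)
    gx <- numeric(k)
    gxx <- numeric(k)
    ll <- 0
    for (s in seqs) {
      fb <- .forward_backward(s$x, pi0, A, means, vars)
      ll <- ll + fb$loglik
      pi_acc <- pi_acc + fb$gamma[1, ]
      A_num <- A_num + fb$xi_sum
      g_sum <- g_sum + colSums(fb$gamma)
      gx <- gx + colSums(fb$gamma * s$x)
      gxx <- gxx + colSums(fb$gamma * s$x^2)
    }
    if (!is.finite(ll))
      stop("non-finite log-likelihood at iteration ", iter,
           "; means=", paste(signif(means, 4), collapse = ","),
           " vars=", paste(signif(vars, 4), collapse = ","))
    if (ll < ll_prev - 1e-8 * max(1, abs(ll_prev)))
      stop("log-likelihood decreased at iteration ", iter,
           " (", ll_prev, " -> ", ll, ")")
    ll_history <- c(ll_history, ll)
    converged <- (ll - ll_prev) < tol
    ll_prev <- ll
    # M-step
    pi0 <- pi_acc / sum(pi_acc)
    rs <- rowSums(A_num)
    A <- A_num / ifelse(rs > 0, rs, 1)
    A[rs == 0, ] <- 1 / k
    means <- gx / g_sum
    vars <- pmax(gxx / g_sum - means^2, var_floor)
    if (converged) break
  }
  structure(list(means = means, variances = vars,
                 weights = g_sum / sum(g_sum), transition = A,
                 start_probs = pi0, roh_state = which.min(means),
                 log_likelihood = ll_prev, ll_history = ll_history,
                 n_iterations = length(ll_history), seed = seed,
                 var_floor = var_floor),
            class = "hmm_model")
}

#' @describeIn fit_baum_welch compact summary of a fitted model.
#' @param x an `hmm_model`.
#' @param ... ignored.
#' @method print hmm_model
#' @export
print.hmm_model <- function(x, ...) {
  cat("3-state Gaussian HMM\n")
  cat("  means:    ", paste(signif(x$means, 4), collapse = "  "), "\n")
  cat("  variances:", paste(signif(x$variances, 4), collapse = "  "), "\n")
  cat(sprintf("  RoH state: %d (lowest mean); logLik %.3f after %d iterations\n",
              x$roh_state, x$log_likelihood, x$n_iterations))
  invisible(x)
}

#' Decode the most likely state path
#'
#' Viterbi decoding (log-space) of the window sequence under a fitted model;
#' undefined-ratio windows are skipped and recorded as path breaks (NA).
#' Ties are broken toward the lower state index. Posterior (per-window
#' argmax) decoding is available as an alternative.
#'
#' @param track a `window_track`.
#' @param model an `hmm_model`.
#' @param method `"viterbi"` (default) or `"posterior"`.
#' @return Integer vector of state indices (1..3) aligned to the track rows,
#'   NA at undefined windows, with attribute `roh_state`.
#' @export
decode_states <- function(track, model, method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  path <- rep(NA_integer_, nrow(track))
  k <- length(model$means)
  logA <- log(model$transition)
  logpi <- log(model$start_probs)
  for (s in .track_sequences(track)) {
    Tn <- length(s$x)
    if (method == "posterior") {
      fb <- .forward_backward(s$x, model$start_probs, model$transition,
                              model$means, model$variances)
      path[s$rows] <- max.col(fb$gamma, ties.method = "first")
      next
    }
    logB <- log(.emission_matrix(s$x, model$means, model$variances))
    delta <- matrix(-Inf, Tn, k)
    psi <- matrix(0L, Tn, k)
    delta[1, ] <- logpi + logB[1, ]
    if (Tn > 1) {
      for (t in 2:Tn) {
        cand <- delta[t - 1, ] + logA        # k x k: from i (row) to j (col)
        psi[t, ] <- apply(cand, 2, which.max)  # first max = lower index
        delta[t, ] <- cand[cbind(psi[t, ], seq_len(k))] + logB[t, ]
      }
    }
    states <- integer(Tn)
    states[Tn] <- which.max(delta[Tn, ])
    if (Tn > 1) for (t in (Tn - 1):1) states[t] <- psi[t + 1, states[t + 1]]
    path[s$rows] <- states
  }
  attr(path, "roh_state") <- model$roh_state
  path
}

# shared run-to-segment conversion: maximal runs of `flag` windows, broken at
# scaffold changes and NA flags, become segments under the fixed coordinate
# convention (start of first window to start + n*step, truncated at the
# scaffold end).
.call_runs <- function(track, flag, min_windows) {
  step <- attr(track, "step")
  segs <- list()
  for (scaf in unique(track$scaffold)) {
    idx <- which(track$scaffold == scaf)
    scaf_end <- max(track$end[idx])
    f <- flag[idx]
    f[is.na(f)] <- FALSE
    r <- rle(f)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$values)) {
      if (!r$values[j] || r$lengths[j] < min_windows) next
      rows <- idx[starts[j]:ends[j]]
      n <- length(rows)
      seg_start <- track$start[rows[1]]
      seg_end <- min(seg_start + n * step, scaf_end)
      segs[[length(segs) + 1]] <- data.frame(
        sample = track$sample[rows[1]], scaffold = scaf, start = seg_start,
        end = seg_end, length = seg_end - seg_start + 1, n_windows = n,
        mean_ratio = mean(track$het_ratio[rows], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  if (length(segs) == 0) {
    out <- data.frame(sample = character(), scaffold = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      n_windows = integer(), mean_ratio = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, segs)
  }
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' Call RoH segments from a decoded state path
#'
#' Each maximal run of at least `min_windows` consecutive RoH-state windows
#' becomes one segment spanning from the start of its first window to that
#' start plus `n_windows * step` (inclusive), truncated at the scaffold end.
#' An untruncated run of `n` windows therefore has length `n * step + 1`;
#' with the default geometry the shortest callable segment (3 windows,
#' step 50 kb) is 150,001 bp. Runs cannot span scaffold boundaries or
#' undefined-window breaks.
#'
#' @param path state path from [decode_states()].
#' @param track the `window_track` the path was decoded from.
#' @param min_windows minimum run length in windows (default 3).
#' @return A `roh_segments` data frame: `sample`, `scaffold`, `start`,
#'   `end`, `length`, `n_windows`, `mean_ratio`.
#' @export
call_roh <- function(path, track, min_windows = 3L) {
  roh_state <- attr(path, "roh_state")
  if (is.null(roh_state)) stop("path carries no roh_state attribute")
  .call_runs(track, path == roh_state, min_windows)
}

#' Threshold-run baseline RoH caller
#'
#' A deliberately simple comparator for the HMM caller: a window is in the
#' low-heterozygosity state when its ratio falls strictly below
#' `ratio_cutoff`, and runs are converted to segments under exactly the same
#' conventions as [call_roh()].
#'
#' @param track a `window_track`.
#' @param ratio_cutoff het-ratio cutoff (> 0); default 1e-4, midway (log
#'   scale) between typical background and autozygous-tract rates.
#' @param min_windows minimum run length (default 3).
#' @return A `roh_segments` data frame.
#' @export
baseline_threshold_caller <- function(track, ratio_cutoff = 1e-4,
                                      min_windows = 3L) {
  stopifnot(ratio_cutoff > 0)
  .call_runs(track, track$het_ratio < ratio_cutoff, min_windows)
}

#' Serialize / read a fitted model as YAML
#'
#' @param model an `hmm_model`.
#' @param path YAML file path.
#' @export
write_hmm_model <- function(model, path) {
  yaml::write_yaml(list(
    n_states = length(model$means), means = model$means,
    variances = model$variances, weights = as.numeric(model$weights),
    transition = apply(model$transition, 1, as.numeric, simplify = FALSE),
    start_probs = as.numeric(model$start_probs), roh_state = model$roh_state,
    log_likelihood = model$log_likelihood,
    n_iterations = model$n_iterations, seed = model$seed), path,
    precision = 15)
  invisible(path)
}

#' @rdname write_hmm_model
#' @export
read_hmm_model <- function(path) {
  y <- yaml::read_yaml(path)
  structure(list(means = as.numeric(y$means),
                 variances = as.numeric(y$variances),
                 weights = as.numeric(y$weights),
                 transition = do.call(rbind, lapply(y$transition, as.numeric)),
                 start_probs = as.numeric(y$start_probs),
                 roh_state = y$roh_state, log_likelihood = y$log_likelihood,
                 ll_history = numeric(0), n_iterations = y$n_iterations,
                 seed = y$seed), class = "hmm_model")
}

#' Write RoH segments as BED and TSV
#'
#' @param segments a `roh_segments` data frame.
#' @param bed_path,tsv_path output paths (either may be `NULL`).
#' @param header optional comment lines.
#' @export
write_roh <- function(segments, bed_path = NULL, tsv_path = NULL,
                      header = NULL) {
  if (!is.null(bed_path))
    write_bed(genomic_intervals(segments$scaffold, segments$start,
                                segments$end), bed_path, header = header)
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    if (!is.null(header)) writeLines(paste0("#", header), con)
    utils::write.table(segments, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(segments)
}
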