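# Independent oracles: brute-force references that share no code with the
# implementation paths they check.

# exhaustive Viterbi: score every state sequence of length n (vectorized
# over the 3^n path matrix) and return the best one
viterbi_brute <- function(x, pi0, A, means, vars) {
  k <- length(pi0)
  Tn <- length(x)
  logB <- matrix(log(pmax(vapply(seq_len(k), function(j)
    dnorm(x, means[j], sqrt(vars[j])), numeric(Tn)), 1e-300)), ncol = k)
  logA <- log(A)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), Tn)))
  sc <- log(pi0)[paths[, 1]]
  for (t in seq_len(Tn)) sc <- sc + logB[t, ][paths[, t]]
  if (Tn > 1) {
    for (t in 2:Tn) sc <- sc + logA[cbind(paths[, t - 1], paths[, t])]
  }
  list(path = as.integer(paths[which.max(sc), ]), score = max(sc))
}

# Wright path-counting kinship: enumerate ancestral paths; a pair of paths
# from x and y meeting only at a common ancestor A contributes
# (1/2)^(n_x + n_y + 1) * (1 + F_A). F_A is itself computed by path
# counting on A's parents. Independent of the tabular recursion.
kinship_paths <- function(ped) {
  ids <- ped$id
  parents <- function(i) {
    p <- c(ped$sire[match(i, ids)], ped$dam[match(i, ids)])
    p[!is.na(p)]
  }
  paths_up <- function(i) {
    out <- list(i)
    for (p in parents(i)) {
      out <- c(out, lapply(paths_up(p), function(q) c(i, q)))
    }
    out
  }
  f_pc <- new.env()
  theta_pc <- function(x, y) {
    px <- paths_up(x)
    py <- paths_up(y)
    tot <- 0
    for (a in px) {
      for (b in py) {
        A <- a[length(a)]
        if (A != b[length(b)]) next
        # paths must be disjoint except at the common ancestor
        if (length(intersect(a[-length(a)], b[-length(b)])) > 0) next
        if (A %in% a[-length(a)] || A %in% b[-length(b)]) next
        tot <- tot + 0.5^(length(a) - 1 + length(b) - 1 + 1) * (1 + f_of(A))
      }
    }
    tot
  }
  f_of <- function(i) {
    if (!is.null(f_pc[[i]])) return(f_pc[[i]])
    p <- c(ped$sire[match(i, ids)], ped$dam[match(i, ids)])
    f <- if (any(is.na(p))) 0 else theta_pc(p[1], p[2])
    f_pc[[i]] <- f
    f
  }
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- if (i == j) 0.5 * (1 + f_of(ids[i])) else theta_pc(ids[i], ids[j])
    }
  }
  K
}

# per-bp carrier counts on a toy genome (only sane for <= ~10 kb)
spectrum_brute <- function(sets, index) {
  n <- length(sets)
  bp_at <- setNames(numeric(n + 1), 0:n)
  private <- setNames(numeric(n), names(sets))
  for (k in seq_len(nrow(index))) {
    scaf <- index$scaffold[k]
    L <- index$length[k]
    cover <- matrix(FALSE, L, n, dimnames = list(NULL, names(sets)))
    for (s in names(sets)) {
      iv <- sets[[s]]
      iv <- iv[iv$scaffold == scaf, , drop = FALSE]
      for (r in seq_len(nrow(iv))) cover[iv$start[r]:iv$end[r], s] <- TRUE
    }
    counts <- rowSums(cover)
    tab <- table(counts)
    bp_at[names(tab)] <- bp_at[names(tab)] + tab
    for (s in names(sets)) {
      private[s] <- private[s] + sum(counts == 1 & cover[, s])
    }
  }
  list(bp_at = bp_at, private = private)
}
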