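test_that("closed-form kinship values hold on classic pedigrees", {
  peds <- fixture_pedigrees()
  K <- kinship_matrix(peds$founders_only)
  expect_equal(diag(K), c(A = 0.5, B = 0.5, C = 0.5))
  expect_equal(K["A", "B"], 0)

  K <- kinship_matrix(peds$trio)
  expect_equal(K["A", "X"], 0.25)   # noninbred parent-offspring
  expect_equal(K["X", "X"], 0.5)    # parents unrelated -> X noninbred

  K <- kinship_matrix(peds$full_sibs_child)
  expect_equal(K["S1", "S2"], 0.25)
  expect_equal(f_ped(peds$full_sibs_child, "X"), 0.25, ignore_attr = TRUE)
  expect_equal(K["X", "X"], 0.625)

  expect_equal(f_ped(peds$half_sibs_child, "X"), 0.125, ignore_attr = TRUE)
  expect_equal(f_ped(peds$trio, "A"), 0, ignore_attr = TRUE)  # founder
  expect_error(f_ped(peds$trio, "nope"), "unknown individual")
})

test_that("tabular kinship equals Wright path counting on all fixtures", {
  for (ped in fixture_pedigrees()) {
    K <- kinship_matrix(ped)
    K_oracle <- kinship_paths(ped)
    expect_equal(K, K_oracle[rownames(K), colnames(K)], tolerance = 1e-12)
  }
})

test_that("2*Theta is positive semi-definite on random pedigrees", {
  set.seed(29)
  for (rep in 1:10) {
    n_founders <- sample(2:4, 1)
    ids <- paste0("I", 1:10)
    sire <- dam <- rep(NA_character_, 10)
    males <- ids[1]; females <- ids[2]
    for (i in (n_founders + 1):10) {
      sire[i] <- sample(males, 1)
      dam[i] <- sample(females, 1)
      if (runif(1) < 0.5) males <- c(males, ids[i]) else females <- c(females, ids[i])
    }
    males <- union(males, ids[seq_len(n_founders)][c(TRUE, FALSE)])
    ped <- pedigree(ids, ifelse(is.na(sire), "0", sire),
                    ifelse(is.na(dam), "0", dam))
    ev <- eigen(2 * kinship_matrix(ped), symmetric = TRUE, only.values = TRUE)
    expect_true(all(ev$values > -1e-10))
  }
})

test_that("adding an unrelated founder changes no existing entry", {
  ped <- fixture_pedigrees()$three_gen
  K1 <- kinship_matrix(ped)
  ped2 <- pedigree(c(ped$id, "NEW"), c(ped$sire, NA), c(ped$dam, NA))
  K2 <- kinship_matrix(ped2)
  expect_equal(K2[rownames(K1), colnames(K1)], K1)
  expect_equal(K2["NEW", "NEW"], 0.5)
  expect_true(all(K2["NEW", rownames(K1)] == 0))
})

test_that("pedigree validation catches cycles, selfing and role conflicts", {
  expect_error(pedigree(c("A", "B"), c("B", "A"), c(0, 0)), "cycle")
  expect_error(pedigree("A", "A", 0), "own-parent")
  expect_error(pedigree(c("A", "B", "X", "Y"), c(0, 0, "A", "B"),
                        c(0, 0, "B", "A")), "both sire and dam")
  expect_error(pedigree(c("A", "X"), c(0, "Z"), c(0, 0)), "not in pedigree")
  # topological order: parents precede offspring even if given reversed
  ped <- pedigree(c("X", "A", "B"), c("A", 0, 0), c("B", 0, 0))
  expect_equal(ped$id, c("A", "B", "X"))
})

test_that("pedigree TSV round trip preserves structure", {
  ped <- fixture_pedigrees()$three_gen
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(id = ped$id, sire = ifelse(is.na(ped$sire), "0", ped$sire),
                         dam = ifelse(is.na(ped$dam), "0", ped$dam)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_pedigree(path)
  expect_equal(back$id, ped$id)
  expect_equal(kinship_matrix(back), kinship_matrix(ped))
})

test_that("unknown parents contribute zero kinship", {
  ped <- fixture_pedigrees()$unknown_parent
  K <- kinship_matrix(ped)
  expect_equal(f_ped(ped, "X"), 0, ignore_attr = TRUE)  # one parent unknown
  expect_equal(K["X", "X"], 0.5)
  # Y = X x B, X carries half of A: Theta(Y,A) = 1/8
  expect_equal(K["Y", "A"], 0.125)
})

test_that("gene-drop realized IBD agrees with pedigree expectation", {
  ped <- fixture_pedigrees()$full_sibs_child
  cfg <- sim_config(scaffold_lengths = setNames(rep(1e8, 10),
                                                paste0("c", 1:10)),
                    mode = "gene_drop", pedigree = ped, seed = 2)
  reps <- gene_drop_replicates(ped, cfg, 300)
  expect_true(all(reps[, c("A", "B")] == 0))        # founders never autozygous
  m <- mean(reps[, "X"])
  se <- sd(reps[, "X"]) / sqrt(nrow(reps))
  expect_lt(abs(m - 0.25), 3 * se)
  evr <- expected_vs_realized(ped, reps)
  expect_gt(evr$var_realized[evr$id == "X"], 0)     # Mendelian sampling
  expect_equal(evr$n_replicates[1], 300)
})

test_that("linkage inflates Mendelian-sampling variance at equal map length", {
  ped <- fixture_pedigrees()$full_sibs_child
  # 10 Morgans as one chromosome versus 10 chromosomes
  cfg1 <- sim_config(scaffold_lengths = c(c1 = 1e9), mode = "gene_drop",
                     pedigree = ped, seed = 4)
  cfg10 <- sim_config(scaffold_lengths = setNames(rep(1e8, 10),
                                                  paste0("c", 1:10)),
                      mode = "gene_drop", pedigree = ped, seed = 4)
  v1 <- var(gene_drop_replicates(ped, cfg1, 250)[, "X"])
  v10 <- var(gene_drop_replicates(ped, cfg10, 250)[, "X"])
  expect_gt(v1, v10)
})
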