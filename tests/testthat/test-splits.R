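test_that("Murcko scaffolds strip side chains and keep linkers", {
  sc <- mp_murcko_scaffold(c("c1ccccc1", "Cc1ccccc1", "CCO",
                             "CC(=O)c1ccccc1"))
  expect_identical(sc[1], sc[2])          # toluene reduces to benzene
  expect_identical(sc[2], sc[4])          # acetyl side chain removed too
  expect_identical(sc[3], "")             # acyclic sentinel
  key <- mp_canonicalize(c(sc[1], "c1ccccc1"))$inchikey
  expect_identical(key[1], key[2])
  # a linker carbonyl between two rings is part of the scaffold
  sc2 <- mp_murcko_scaffold("O=C(Nc1ccccc1)c1ccccc1CC")
  expect_match(sc2, "O=C")
})

test_that("scaffold Tanimoto matrix has unit diagonal and empty-row rule", {
  S <- mp_scaffold_tanimoto(c("c1ccccc1", "c1ccccc1", "", "c1ccncc1"))
  expect_equal(diag(S), rep(1, 4))
  expect_equal(S[1, 2], 1)                # identical scaffolds
  expect_equal(S[3, 1], 0)                # empty scaffold vs others
  expect_true(isSymmetric(S))
  expect_true(all(S >= 0 & S <= 1))
  # Tanimoto on synthetic bit sets: {1,2,3} vs {2,3,4} = 2/4, disjoint = 0
  fp <- rbind(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 0), c(0, 0, 0, 0, 1))
  Tm <- macroperm:::tanimoto_matrix(fp)
  expect_equal(Tm[1, 2], 0.5)
  expect_equal(Tm[1, 3], 0)
})

test_that("fold assignment never splits a unit and balances SMILES folds", {
  smi <- sprintf("C%sO", strrep("C", 1:20))  # 20 distinct alcohols
  df <- tibble::tibble(smiles = c(smi, smi[1]))  # one duplicate structure
  fa <- mp_assign_folds(df, "SMILES", k = 5, seed = 2)
  expect_equal(fa$fold[1], fa$fold[21])   # duplicates share a fold
  sizes <- table(fa$fold[1:20])
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_setequal(unique(fa$fold), 0:4)

  fs <- mp_assign_folds(tibble::tibble(smiles = c("Cc1ccccc1", "CCc1ccccc1",
                                                  "c1ccncc1", "CCO", "CCC")),
                        "SCAFFOLD", k = 2, seed = 1)
  expect_equal(fs$fold[1], fs$fold[2])    # toluene/ethylbenzene same scaffold
  by_unit <- tapply(fs$fold, fs$unit_key, function(x) length(unique(x)))
  expect_true(all(by_unit == 1))

  expect_error(mp_assign_folds(df, "SMILES", k = 25, seed = 1), "exceeds")
  expect_error(mp_assign_folds(df, "SMILES", k = 1), "k must be")
  # determinism
  fa2 <- mp_assign_folds(df, "SMILES", k = 5, seed = 2)
  expect_identical(fa$fold, fa2$fold)
})

test_that("fold union covers all records and folds are disjoint", {
  df <- toy_records()
  df$smiles[c(5, 15)] <- c("c1ccncc1", "Cc1ccncc1")  # a second ring system
  for (mode in c("SMILES", "SCAFFOLD", "RANDOM")) {
    k <- if (mode == "SCAFFOLD") 2L else 3L
    fa <- mp_assign_folds(df, mode, k = k, seed = 4)
    expect_equal(nrow(fa), nrow(df))
    expect_true(all(fa$fold %in% 0:(k - 1)))
    grp <- tapply(fa$fold, fa$unit_key, function(x) length(unique(x)))
    expect_true(all(grp == 1))
  }
})

test_that("high-fidelity clustering recovers separated blobs", {
  set.seed(11)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2),
             matrix(rnorm(60, 8), ncol = 2))
  cl <- mp_cluster_fidelity(X, k_range = 2:5, seed = 3,
                            cluster_space = "fingerprint")
  expect_equal(cl$n_clusters, 2)
  expect_equal(length(unique(cl$assignment[1:30])), 1)
  # silhouette confirmed independently at the chosen k
  sil <- cluster::silhouette(cl$assignment,
                             dmatrix = as.matrix(dist(cl$embedding)))
  expect_gt(mean(sil[, "sil_width"]), 0.7)
  cl2 <- mp_cluster_fidelity(X, k_range = 2:5, seed = 3,
                             cluster_space = "fingerprint")
  expect_identical(cl$assignment, cl2$assignment)
  expect_error(mp_cluster_fidelity(matrix(1, 30, 2), k_range = 2:3, seed = 1,
                                   cluster_space = "fingerprint"),
               "identical")
})

test_that("t-SNE embedding separates blobs and is seeded", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 10), ncol = 2))
  Y1 <- macroperm:::tsne_embed(X, perplexity = 5, n_iter = 150, seed = 9)
  Y2 <- macroperm:::tsne_embed(X, perplexity = 5, n_iter = 150, seed = 9)
  expect_identical(Y1, Y2)
  within <- mean(dist(Y1[1:20, ])) + mean(dist(Y1[21:40, ]))
  between <- mean(as.matrix(dist(Y1))[1:20, 21:40])
  expect_gt(between, within / 2)
})

test_that("injection selects the right count with dedup and overlap math", {
  hf <- tibble::tibble(smiles = sprintf("C%sN", strrep("C", 1:10)),
                       assay = "PAMPA", neg_log_papp = 5)
  lg <- tibble::tibble(smiles = sprintf("C%sO", strrep("C", 1:20)),
                       assay = "CACO2", neg_log_papp = 6)
  r0 <- mp_injection(hf, lg, 0, "RANDOM", seed = 1)
  expect_equal(nrow(r0$selected), 0)
  expect_equal(nrow(r0$augmented_large), 20)
  r1 <- mp_injection(hf, lg, 1, "RANDOM", seed = 1)
  expect_equal(nrow(r1$selected), 10)
  expect_equal(nrow(r1$augmented_large), 30)
  r04a <- mp_injection(hf, lg, 0.4, "RANDOM", seed = 1)
  r04b <- mp_injection(hf, lg, 0.4, "RANDOM", seed = 99)
  expect_equal(nrow(r04a$selected), 4)
  ov <- mp_selection_overlap(r04a$selected, r04b$selected)
  manual <- length(intersect(r04a$selected$inchikey, r04b$selected$inchikey)) / 4
  expect_equal(ov$a_in_b, manual)
  expect_error(mp_injection(hf, lg, 1.2, "RANDOM"), "\\[0, 1\\]")
})

test_that("selection overlap matches set arithmetic in both directions", {
  a <- tibble::tibble(smiles = c("CCO", "CCC", "CCN", "CCCC"))
  b <- tibble::tibble(smiles = c("CCN", "CCCC", "CCI"))
  ov <- mp_selection_overlap(a, b)
  expect_equal(ov$a_in_b, 0.5)
  expect_equal(ov$b_in_a, 2 / 3)
  same <- mp_selection_overlap(a, a)
  expect_equal(same$a_in_b, 1)
  disj <- mp_selection_overlap(a, tibble::tibble(smiles = "CCCl"))
  expect_equal(disj$a_in_b, 0)
  expect_error(mp_selection_overlap(a[0, ], b), "non-empty")
})
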