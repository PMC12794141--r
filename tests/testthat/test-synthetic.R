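spec_small <- mp_synthetic_spec(n_large = 40, n_task = 15, seed = 7)

test_that("glycine tetramer closes to a 12-membered ring", {
  smi <- macroperm:::assemble_peptide(rep("none", 4), rep(FALSE, 4),
                                      cyclic = TRUE)
  expect_equal(mp_largest_ring(smi), 12L)  # 3 backbone atoms x 4 residues
  lin <- macroperm:::assemble_peptide(rep("none", 4), rep(FALSE, 4),
                                      cyclic = FALSE)
  expect_equal(mp_largest_ring(lin), 0L)
})

test_that("library generation is seeded, unique, and annotated correctly", {
  lib1 <- mp_generate_library(spec_small, n = 25)
  lib2 <- mp_generate_library(spec_small, n = 25)
  expect_identical(lib1, lib2)
  expect_false(any(duplicated(lib1$inchikey)))
  expect_true(all(lib1$largest_ring_size[lib1$is_macrocycle] %in%
                    (3 * spec_small$ring_size_range)))
  # perception agrees with the constructed ring sizes
  expect_equal(mp_largest_ring(lib1$smiles[lib1$is_macrocycle][1:3]),
               lib1$largest_ring_size[lib1$is_macrocycle][1:3])
  expect_error(mp_generate_library(spec_small, n = 0), "positive")
})

test_that("the latent permeability function is exactly linear", {
  beta <- mp_synthetic_spec()$beta
  meta <- tibble::tibble(hbd_count = c(3, 4), mw = c(400, 400),
                         hydrophobic_frac = c(0.5, 0.5),
                         is_macrocycle = c(TRUE, TRUE))
  mu <- mp_latent_permeability(meta, beta)
  expect_equal(mu[2] - mu[1], beta[["hbd"]])  # one extra donor
  flat <- c(intercept = 6, hbd = 0, mw = 0, hydrophobic = 0, macrocycle = 0)
  expect_equal(mp_latent_permeability(meta, flat), c(6, 6))
  hand <- beta[["intercept"]] + beta[["hbd"]] * 3 + beta[["mw"]] * 4 +
    beta[["hydrophobic"]] * 0.5 + beta[["macrocycle"]]
  expect_equal(mu[1], hand)
})

test_that("assay simulation applies offsets exactly and noise faithfully", {
  meta <- tibble::tibble(smiles = "CCO", inchikey = "KEY", mu = 6,
                         largest_ring_size = 0)
  sp0 <- mp_synthetic_spec(n_large = 1, n_task = 1, noise_sd = 0, seed = 1)
  rec <- purrr::map(names(sp0$assay_offsets), function(a) {
    mp_simulate_assays(meta, sp0, assays = a)
  }) |> dplyr::bind_rows()
  expect_equal(unname(rec$neg_log_papp - 6), unname(sp0$assay_offsets[rec$assay]))
  # empirical sd of the per-(molecule, assay) streams approaches noise_sd
  sp <- mp_synthetic_spec(n_large = 1, n_task = 1, noise_sd = 0.4, seed = 3)
  meta_many <- tibble::tibble(smiles = "CCO",
                              inchikey = sprintf("K%05d", 1:10000),
                              mu = 6, largest_ring_size = 0)
  recs <- mp_simulate_assays(meta_many, sp, assays = "PAMPA")
  emp <- sd(recs$neg_log_papp - 6 - sp$assay_offsets[["PAMPA"]])
  expect_lt(abs(emp - 0.4) / 0.4, 0.1)
  # draws keyed by identity: adding molecules never perturbs old draws
  recs2 <- mp_simulate_assays(meta_many[1:100, ], sp, assays = "PAMPA")
  expect_identical(recs$neg_log_papp[1:100], recs2$neg_log_papp)
  expect_error(mp_simulate_assays(meta, sp0, assays = "XX"), "offset")
})

test_that("the benchmark separates sets and keeps coherent ground truth", {
  bm <- mp_make_benchmark(spec_small, task_swing = 0.4)
  expect_equal(length(intersect(bm$large$inchikey, bm$task$inchikey)), 0)
  expect_true(all(bm$task$assay == "PAMPA"))
  expect_true(all(bm$truth$true_y %in% 0:1))
  # labels in the large set follow the unified threshold on the noisy value
  expect_true(all((bm$large$neg_log_papp <= 6) == (bm$large$y == 1)))
  # task labels respect the swing exclusion
  inside <- bm$task$neg_log_papp >= 5.6 & bm$task$neg_log_papp < 6.4
  expect_true(all(is.na(bm$task$y[inside])))
  # reproducible end to end
  bm2 <- mp_make_benchmark(spec_small, task_swing = 0.4)
  expect_identical(bm$task$neg_log_papp, bm2$task$neg_log_papp)
})

test_that("wider swings retain cleaner labels on the same draws", {
  sp <- mp_synthetic_spec(n_large = 40, n_task = 120, noise_sd = 0.5,
                          seed = 11)
  lib <- mp_generate_library(sp, n = 120, all_macrocycles = TRUE,
                             seed_tag = "task")
  lib$mu <- mp_latent_permeability(lib, sp$beta)
  recs <- mp_simulate_assays(lib, sp, assays = "PAMPA")
  truth <- mp_swing_label(recs$mu + sp$assay_offsets[["PAMPA"]],
                          center = 6, halfwidth = 0)
  flip_rate <- function(h) {
    lab <- mp_swing_label(recs$neg_log_papp, center = 6, halfwidth = h)
    keep <- lab != "EXCLUDED"
    mean(as.character(lab[keep]) != as.character(truth[keep]))
  }
  rates <- vapply(c(0, 0.4, 0.8), flip_rate, numeric(1))
  expect_gt(rates[1], 0)                  # noise does flip labels
  expect_lte(rates[3], rates[1])          # exclusion removes flip-prone records
})
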