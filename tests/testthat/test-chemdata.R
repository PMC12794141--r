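test_that("canonicalization is idempotent and keys identify molecules", {
  res <- mp_canonicalize(c("C1=CC=CC=C1", "c1ccccc1", "CCO"))
  expect_identical(res$inchikey[1], res$inchikey[2])
  expect_match(res$inchikey[3], "^LFQSCWFLJHTTHZ")
  again <- mp_canonicalize(res$canonical_smiles)
  expect_identical(again$canonical_smiles, res$canonical_smiles)
  expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", res$inchikey)))
})

test_that("unparsable SMILES raise an error naming the string", {
  expect_error(mp_canonicalize("C1CC"), "C1CC")
  expect_error(mp_parse_mols(c("CCO", "C1CC")), "C1CC")
  expect_error(mp_canonicalize(""), "empty")
})

test_that("deduplication keeps one record per (inchikey, assay)", {
  df <- tibble::tibble(
    smiles = c("CCO", "OCC", "CCO", "CCC"),
    assay = c("PAMPA", "PAMPA", "CACO2", "PAMPA"),
    neg_log_papp = c(5, 5.4, 6, 7),
    source_id = c("b", "a", "c", "d"))
  out <- mp_dedup(df)
  expect_equal(nrow(out), 3)              # cross-assay duplicate retained
  expect_equal(mp_report(out)$n_input, 4)
  expect_equal(mp_report(out)$n_deduplicated, 3)
  # first after sorting by source_id: the "a" record wins
  kept <- out[out$assay == "PAMPA" & out$smiles %in% c("CCO", "OCC"), ]
  expect_equal(kept$source_id, "a")
  # aggregate = mean averages replicates in -logP space
  avg <- mp_dedup(df, aggregate = "mean")
  expect_equal(avg$neg_log_papp[avg$assay == "PAMPA" &
                                avg$smiles %in% c("CCO", "OCC")], 5.2)
  empty <- mp_dedup(df[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(mp_report(empty)$n_input, 0)
})

test_that("swing labels follow the half-open exclusion interval", {
  expect_equal(as.character(mp_swing_label(4.8, 6, 0.5)), "PERMEABLE")
  expect_equal(as.character(mp_swing_label(6.0, 6, 0.5)), "EXCLUDED")
  expect_equal(as.character(mp_swing_label(7.0, 6, 0.5)), "IMPERMEABLE")
  # half-open boundary [c - h, c + h)
  expect_equal(as.character(mp_swing_label(5.5, 6, 0.5)), "EXCLUDED")
  expect_equal(as.character(mp_swing_label(6.5, 6, 0.5)), "IMPERMEABLE")
  # halfwidth 0: no exclusions, threshold itself on the permeable side
  labs0 <- mp_swing_label(c(5, 6, 7), 6, 0)
  expect_false(any(labs0 == "EXCLUDED"))
  expect_equal(as.character(labs0), c("PERMEABLE", "PERMEABLE", "IMPERMEABLE"))
  # inverted convention swaps classes
  inv <- mp_swing_label(c(4.8, 7.0), 6, 0.5, label_direction = "inverted")
  expect_equal(as.character(inv), c("IMPERMEABLE", "PERMEABLE"))
  expect_error(mp_swing_label(NA_real_), "finite")
})

test_that("the excluded set is nested and non-decreasing in halfwidth", {
  vals <- seq(4, 8, by = 0.05)
  prev <- rep(FALSE, length(vals))
  for (h in c(0, 0.2, 0.4, 0.5, 0.6, 0.8)) {
    ex <- mp_swing_label(vals, 6, h) == "EXCLUDED"
    expect_true(all(ex[prev]))            # nested
    expect_gte(sum(ex), sum(prev))        # non-decreasing
    prev <- ex
  }
})

test_that("curation report counts are consistent", {
  df <- tibble::tibble(smiles = c("CCO", "CCC", "CCN", "CCCC", "CCCO"),
                       assay = "PAMPA",
                       neg_log_papp = c(5.0, 6.1, 6.6, 7.2, 5.9))
  cur <- mp_curate(df, center = 6, halfwidth = 0.5)
  rep <- mp_report(cur)
  expect_equal(rep$n_positive + rep$n_negative + rep$n_excluded_swing,
               rep$n_deduplicated)
  expect_equal(rep$n_excluded_swing, 2)  # 6.1 and 5.9 inside [5.5, 6.5)
  expect_equal(sum(is.na(cur$y)), 2)
})

test_that("Caco-2 three-bin rule matches the published thresholds", {
  expect_equal(as.character(mp_caco2_bin(5e-7)), "POOR")
  expect_equal(as.character(mp_caco2_bin(5e-6)), "MODERATE")
  expect_equal(as.character(mp_caco2_bin(2e-5)), "WELL")
  expect_equal(as.character(mp_caco2_bin(c(1e-6, 1e-5))),
               c("MODERATE", "MODERATE"))
  expect_error(mp_caco2_bin(0), "positive")
  expect_error(mp_caco2_bin(-1e-6), "positive")
})

test_that("ring-size strata follow the 12/16/19 boundaries", {
  expect_equal(as.character(mp_ring_category(c(6, 0, 14, 12, 15, 18, 16, 19, 30))),
               c("NON_MACROCYCLE", "NON_MACROCYCLE", "SMALL", "SMALL", "SMALL",
                 "MEDIUM", "MEDIUM", "LARGE", "LARGE"))
  expect_error(mp_ring_category(-1))
})

test_that("pair deviation statistics match hand counts and are symmetric", {
  st <- mp_pair_deviation_stats(value_a = c(5.0, 6.4, 7.0),
                                value_b = c(5.3, 5.9, 5.8))
  expect_equal(st$frac_within_delta, 2 / 3)
  expect_equal(st$frac_conflicting, 2 / 3)
  sw <- mp_pair_deviation_stats(value_a = c(5.3, 5.9, 5.8),
                                value_b = c(5.0, 6.4, 7.0))
  expect_equal(sw$frac_within_delta, st$frac_within_delta)
  expect_equal(sw$frac_conflicting, st$frac_conflicting)
  ident <- mp_pair_deviation_stats(value_a = c(5, 7), value_b = c(5, 7))
  expect_equal(ident$frac_within_delta, 1)
  expect_equal(ident$frac_conflicting, 0)
  one <- mp_pair_deviation_stats(value_a = 5.9, value_b = 6.1)
  expect_equal(one$frac_conflicting, 1)
  expect_error(mp_pair_deviation_stats(value_a = numeric(0),
                                       value_b = numeric(0)), "no pairs")
})

test_that("dataset round trip is bit-exact and schema errors are caught", {
  df <- tibble::tibble(smiles = c("CCO", "CCC", "CCN"),
                       assay = c("PAMPA", "CACO2", "MDCK"),
                       neg_log_papp = c(5.123456789012345, 6.5, 1 / 3),
                       ph = c(7.4, NA, 6.5), source_id = c("x", "y", "z"))
  f <- withr::local_tempfile(fileext = ".csv")
  mp_write_dataset(df, f)
  back <- mp_read_dataset(f)
  expect_identical(back$neg_log_papp, df$neg_log_papp)
  expect_identical(back$smiles, df$smiles)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("smiles,neg_log_papp\nCCO,5.0", f2)
  expect_error(mp_read_dataset(f2), "assay")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("smiles,assay,neg_log_papp\nCCO,PAMPA,abc", f3)
  expect_error(mp_read_dataset(f3), "row 1")
  expect_error(mp_read_dataset("nope.csv"), "not found")
})
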