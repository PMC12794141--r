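test_that("SASA of an isolated atom matches the analytic sphere area", {
  cf <- mp_conformer("C", matrix(0, 1, 3))
  s <- mp_sasa(cf)
  analytic <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(s - analytic) / analytic, 0.01)
  expect_equal(analytic, 120.76, tolerance = 1e-2)
})

test_that("two-sphere SASA matches the spherical-cap closed form", {
  d <- 2.0
  R <- 1.7 + 1.4
  cf <- mp_conformer(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)))
  s <- mp_sasa(cf)
  cap_h <- R - d / 2
  analytic <- 4 * pi * R^2 - 2 * pi * R * cap_h
  expect_lt(abs(s[1] - analytic) / analytic, 0.02)
  expect_lt(abs(s[2] - analytic) / analytic, 0.02)
})

test_that("SASA is occluded, bounded, and rigid-motion invariant", {
  # hydrogen fully buried inside a hypothetical giant atom at the origin
  cf <- mp_conformer(c("I", "H"), rbind(c(0, 0, 0), c(0.3, 0, 0)))
  expect_equal(mp_sasa(cf)[2], 0)
  cf2 <- mp_conformer(c("C", "O", "N"),
                      rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1.3, 0)))
  s <- mp_sasa(cf2)
  ub <- 4 * pi * (macroperm:::atom_radii(cf2$elements) + 1.4)^2
  expect_true(all(s <= ub + 1e-9))
  th <- 0.83
  Rm <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  cf3 <- mp_conformer(cf2$elements, cf2$coords %*% Rm + 7)
  # total SASA conservation under rigid motion; the lattice discretization
  # error shrinks with the point count, reaching the 0.5% band by ~2k points
  fine <- mp_geometry_spec(n_test_points = 4096)
  expect_lt(abs(sum(mp_sasa(cf3, fine)) - sum(mp_sasa(cf2, fine))) /
              sum(mp_sasa(cf2, fine)), 0.005)
  expect_error(mp_sasa(mp_conformer("Xq", matrix(0, 1, 3))), "Xq")
})

test_that("hydrogen-bond detection applies both geometric criteria", {
  mk <- function(apos) {
    mp_conformer(c("O", "H", "O"), rbind(c(0, 0, 0), c(1, 0, 0), apos),
                 bonds = rbind(c(1, 2)))
  }
  hit <- mp_detect_imhb(mk(c(3, 0, 0)))     # d = 2.0, angle 180
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 2.0)
  expect_equal(hit$angle, 180)
  expect_equal(nrow(mp_detect_imhb(mk(c(3.6, 0, 0)))), 0)  # d = 2.6 fails
  expect_equal(nrow(mp_detect_imhb(mk(c(1, 2, 0)))), 0)    # 90 degrees fails
  # invariant under rigid transforms
  base <- mk(c(3, 0, 0))
  th <- 1.1
  Rm <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- mp_conformer(base$elements, base$coords %*% Rm - 4,
                        bonds = base$bonds)
  expect_equal(nrow(mp_detect_imhb(moved)), 1)
  # structures without explicit H are rejected
  expect_error(mp_detect_imhb(mp_conformer(c("O", "O"), matrix(0, 2, 3),
                                           bonds = rbind(c(1, 2)))),
               "protonate")
})

test_that("polar exposure averages per-conformer sums over the ensemble", {
  mk <- function(shift) {
    mp_conformer(c("O", "H", "C"),
                 rbind(c(0, 0, 0), c(0.96, 0, 0), c(3 + shift, 0, 0)),
                 bonds = rbind(c(1, 2), c(1, 3)))
  }
  e1 <- mp_polar_exposure(list(mk(0)))
  e2 <- mp_polar_exposure(list(mk(2)))
  both <- mp_polar_exposure(list(mk(0), mk(2)))
  expect_equal(both$total_hbd_sasa,
               (e1$total_hbd_sasa + e2$total_hbd_sasa) / 2)
  expect_equal(both$n_conformers, 2)
  # no donors: NA sentinel per-donor, zero total
  apolar <- mp_conformer(c("C", "H"), rbind(c(0, 0, 0), c(1.1, 0, 0)),
                         bonds = rbind(c(1, 2)))
  ap <- mp_polar_exposure(list(apolar))
  expect_equal(ap$total_hbd_sasa, 0)
  expect_true(is.na(ap$per_donor_sasa))
  # ring-embedded donors are not counted as side-chain
  ring <- mp_polar_exposure(list(mk(0)), ring_atoms = 1L)
  expect_equal(ring$sidechain_hbd_count, 0)
  expect_error(mp_polar_exposure(list()), "empty")
})

test_that("conformer selection is greedy by energy with an RMSD filter", {
  mk <- function(d, en) {
    mp_conformer(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)), energy = en)
  }
  cands <- list(mk(1.5, 3), mk(1.5, 1), mk(1.52, 2), mk(4, 5))
  sel <- mp_select_conformers(cands, k = 4, rmsd_min = 0.5)
  # the 1.5/1.52 family collapses to its lowest-energy member
  expect_equal(vapply(sel, function(x) x$energy, numeric(1)), c(1, 5))
  sel0 <- mp_select_conformers(cands, k = 2, rmsd_min = 0)
  expect_equal(vapply(sel0, function(x) x$energy, numeric(1)), c(1, 2))
  # hand-built case: candidate 2 shadowed by candidate 1, 3 survives
  sel3 <- mp_select_conformers(list(mk(2, 1), mk(2.1, 2), mk(6, 3)),
                               k = 3, rmsd_min = 0.5)
  expect_equal(vapply(sel3, function(x) x$energy, numeric(1)), c(1, 3))
  # Kabsch RMSD itself: pure rotation + translation gives zero
  set.seed(8)
  A <- matrix(rnorm(18), 6, 3)
  th <- 0.5
  Rm <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_lt(macroperm:::kabsch_rmsd(A, A %*% Rm + 2), 1e-8)
})

test_that("top-confident selection ranks within classes with stable ties", {
  out <- mp_top_confident(c(0.9, 0.2, 0.6), c(1, 0, 1), 1)
  expect_equal(out$top_positive, 1)
  expect_equal(out$top_negative, 2)
  tie <- mp_top_confident(rep(0.5, 6), c(1, 1, 1, 0, 0, 0), 2)
  expect_equal(tie$top_positive, c(1, 2))
  expect_equal(tie$top_negative, c(4, 5))
  all6 <- mp_top_confident(runif(6), c(1, 1, 1, 0, 0, 0), 3)
  expect_setequal(all6$top_positive, 1:3)
  expect_error(mp_top_confident(runif(6), c(1, 1, 1, 0, 0, 0), 4), "exceeds")
})

test_that("conformer SDF round trip preserves coordinates and energies", {
  c1 <- mp_conformer(c("O", "H"), rbind(c(0, 0, 0), c(0.96, 0, 0)),
                     bonds = rbind(c(1, 2)), energy = -1.25)
  f <- withr::local_tempfile(fileext = ".sdf")
  mp_write_conformers(list(c1, c1), f)
  back <- mp_read_conformers(f)
  expect_length(back, 2)
  expect_equal(unname(back[[1]]$coords), unname(c1$coords), tolerance = 1e-4)
  expect_equal(back[[1]]$elements, c1$elements)
  expect_equal(back[[1]]$energy, -1.25)
})

test_that("channel importance is zero for an input-blind model and exact at baseline", {
  df <- toy_records()[c(1:6, 11:16), ]
  fit <- mp_fit_classifier(df[c(1:5, 7:11), ], df[c(6, 12), ],
                           tiny_config(epochs = 3), seed = 2)
  imp <- mp_channel_importance(fit, df)
  expect_setequal(imp$channel, names(mp_feature_schema()$node_channels))
  p <- predict(fit, df)$prob
  expect_equal(unname(attr(imp, "baseline_loss")), mp_bce(df$y, p))
  # a model whose first layer ignores node features entirely
  blind <- fit
  blind$params$W_in_n <- blind$params$W_in_n * 0
  imp0 <- mp_channel_importance(blind, df)
  expect_equal(imp0$mean_dloss, rep(0, nrow(imp0)), tolerance = 1e-12)
})
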