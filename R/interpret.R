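#' @title Feature importance and conformer-ensemble geometry
#' @description
#' Node-feature-channel importance by masking (loss difference with and
#' without each channel), and the 3D polar-exposure analysis used for
#' high-confidence macrocycles: intramolecular hydrogen-bond detection by
#' distance/angle criteria, Shrake-Rupley solvent-accessible surface area
#' on a deterministic golden-spiral point lattice, per-donor/acceptor
#' exposure profiles averaged over a conformer ensemble, and greedy
#' energy/RMSD conformer selection.
#' @name interpret
NULL

# Bondi van der Waals radii (Angstrom)
BONDI_RADII <- c(H = 1.20, He = 1.40, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
                 F = 1.47, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
                 Br = 1.85, I = 1.98)

#' Geometry analysis settings
#'
#' @param hb_dmax maximum H...acceptor distance for a hydrogen bond (Angstrom).
#' @param hb_angle_min minimum donor-H-acceptor angle (degrees).
#' @param probe_radius solvent probe radius (1.4 Angstrom for water).
#' @param n_test_points test points per atomic sphere (golden-spiral lattice).
#' @return an `mp_geometry_spec` object.
#' @export
mp_geometry_spec <- function(hb_dmax = 2.5, hb_angle_min = 120,
                             probe_radius = 1.4, n_test_points = 960) {
  stopifnot(hb_dmax > 0, hb_angle_min > 0, hb_angle_min <= 180,
            probe_radius >= 0, n_test_points >= 92)
  structure(list(hb_dmax = hb_dmax, hb_angle_min = hb_angle_min,
                 probe_radius = probe_radius,
                 n_test_points = as.integer(n_test_points)),
            class = "mp_geometry_spec")
}

#' Construct a conformer
#'
#' @param elements character vector of element symbols (hydrogens explicit).
#' @param coords numeric n x 3 matrix of coordinates (Angstrom).
#' @param bonds integer matrix of covalent bonds (columns u, v), optional
#'   but required for hydrogen-bond detection.
#' @param energy optional conformer energy (arbitrary units, lower = better).
#' @return an `mp_conformer` object.
#' @export
mp_conformer <- function(elements, coords, bonds = NULL, energy = NA_real_) {
  coords <- as.matrix(coords)
  stopifnot(length(elements) == nrow(coords), ncol(coords) == 3)
  assert_finite(coords, "coords")
  structure(list(elements = elements, coords = coords, bonds = bonds,
                 energy = energy), class = "mp_conformer")
}

#' @export
print.mp_conformer <- function(x, ...) {
  cat(sprintf("<mp_conformer> %d atoms (%d H), energy %s\n",
              length(x$elements), sum(x$elements == "H"),
              format(x$energy)))
  invisible(x)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elements) {
  r <- BONDI_RADII[elements]
  if (anyNA(r)) {
    abort(sprintf("no van der Waals radius for element(s): %s",
                  paste(unique(elements[is.na(r)]), collapse = ", ")))
  }
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, SASA_i = 4 pi (R_i + R_probe)^2 * N_accessible / N_total,
#' where test points on the probe-expanded sphere count as accessible iff
#' they lie outside every other atom's expanded sphere. The point lattice
#' is a deterministic golden spiral.
#'
#' @param conformer an [mp_conformer()].
#' @param spec an [mp_geometry_spec()].
#' @return numeric vector of per-atom SASA values (Angstrom^2).
#' @export
mp_sasa <- function(conformer, spec = mp_geometry_spec()) {
  el <- conformer$elements
  xyz <- conformer$coords
  n <- length(el)
  R <- atom_radii(el) + spec$probe_radius
  pts <- golden_spiral(spec$n_test_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    P <- pts * R[i]
    P <- sweep(P, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(P))
    for (j in nb) {
      dj <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 + (P[, 3] - xyz[j, 3])^2
      acc <- acc & dj > R[j]^2
      if (!any(acc)) break
    }
    sasa[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  sasa
}

# donor/acceptor assignment from elements + covalent bonds
polar_assignments <- function(conformer) {
  el <- conformer$elements
  if (is.null(conformer$bonds)) abort("conformer has no bond list")
  b <- conformer$bonds
  adj <- lapply(seq_along(el), function(i) {
    c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
  })
  is_h <- el == "H"
  if (!any(is_h)) {
    abort("no explicit hydrogens; protonate the structure before geometry analysis")
  }
  dh_pairs <- list()
  for (h in which(is_h)) {
    for (d in adj[[h]]) {
      if (el[d] %in% c("N", "O")) dh_pairs[[length(dh_pairs) + 1]] <- c(d, h)
    }
  }
  acceptors <- which(el %in% c("N", "O"))
  list(dh_pairs = dh_pairs, acceptors = acceptors, adj = adj,
       donors = unique(vapply(dh_pairs, function(p) as.integer(p[1]), integer(1))))
}

#' Detect intramolecular hydrogen bonds
#'
#' A (donor, hydrogen, acceptor) triple is reported iff the H...A distance
#' is at most `hb_dmax` (2.5 Angstrom) and the D-H-A angle at least
#' `hb_angle_min` (120 degrees), with A distinct from D and not covalently
#' bonded to H.
#'
#' @param conformer an [mp_conformer()] with explicit hydrogens and bonds.
#' @param spec an [mp_geometry_spec()].
#' @return tibble with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices), `distance` and `angle`.
#' @export
mp_detect_imhb <- function(conformer, spec = mp_geometry_spec()) {
  pa <- polar_assignments(conformer)
  xyz <- conformer$coords
  out <- list()
  for (pair in pa$dh_pairs) {
    d <- pair[1]; h <- pair[2]
    for (a in pa$acceptors) {
      if (a == d || a %in% pa$adj[[h]]) next
      dist_ha <- sqrt(sum((xyz[h, ] - xyz[a, ])^2))
      if (dist_ha > spec$hb_dmax) next
      v1 <- xyz[d, ] - xyz[h, ]
      v2 <- xyz[a, ] - xyz[h, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang >= spec$hb_angle_min) {
        out[[length(out) + 1]] <- tibble(donor = d, hydrogen = h, acceptor = a,
                                         distance = dist_ha, angle = ang)
      }
    }
  }
  if (length(out) == 0) {
    tibble(donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
           distance = numeric(0), angle = numeric(0))
  } else bind_rows(out)
}

#' Polar-exposure profile of a conformer ensemble
#'
#' Per conformer: the summed SASA of hydrogen-bond donor groups (donor
#' heavy atom plus its polar hydrogens) and of acceptor atoms, per-donor
#' and per-acceptor averages, the count of side-chain (vs macrocycle-ring)
#' donors, and the intramolecular hydrogen-bond count — each averaged
#' uniformly over the ensemble. Molecules without donors report `NA` for
#' the per-donor average.
#'
#' @param conformers list of [mp_conformer()] objects (same molecule).
#' @param spec an [mp_geometry_spec()].
#' @param ring_atoms optional integer vector of macrocycle-ring atom
#'   indices (donors there count as ring-embedded rather than side-chain).
#' @return one-row tibble of ensemble-averaged exposure statistics.
#' @export
mp_polar_exposure <- function(conformers, spec = mp_geometry_spec(),
                              ring_atoms = integer(0)) {
  if (length(conformers) == 0) abort("empty conformer ensemble")
  per <- lapply(conformers, function(cf) {
    pa <- polar_assignments(cf)
    sasa <- mp_sasa(cf, spec)
    donor_groups <- lapply(pa$donors, function(d) {
      hs <- intersect(pa$adj[[d]], which(cf$elements == "H"))
      c(d, hs)
    })
    hbd_sasa <- sum(unlist(lapply(donor_groups, function(g) sum(sasa[g]))))
    hba_sasa <- sum(sasa[pa$acceptors])
    nd <- length(pa$donors); na_ <- length(pa$acceptors)
    tibble(total_hbd_sasa = hbd_sasa,
           per_donor_sasa = if (nd > 0) hbd_sasa / nd else NA_real_,
           total_hba_sasa = hba_sasa,
           per_acceptor_sasa = if (na_ > 0) hba_sasa / na_ else NA_real_,
           n_donors = nd,
           sidechain_hbd_count = sum(!pa$donors %in% ring_atoms),
           imhb_count = nrow(mp_detect_imhb(cf, spec)))
  })
  bind_rows(per) |>
    summarise(across(everything(), ~ mean(.x))) |>
    mutate(n_conformers = length(conformers))
}

# --- conformer selection ---------------------------------------------------

# optimal-superposition RMSD over heavy atoms (Kabsch)
kabsch_rmsd <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(B, A))
  d <- sign(det(s$v %*% t(s$u)))
  U <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A %*% U - B)^2)))
}

#' Select a diverse low-energy conformer ensemble
#'
#' Greedy selection in ascending energy: a candidate is skipped when its
#' heavy-atom RMSD (after optimal superposition) to any already-selected
#' conformer falls below `rmsd_min`. Selection stops at `k` conformers;
#' fewer survivors are allowed.
#'
#' @param candidates list of [mp_conformer()] objects with energies.
#' @param k target ensemble size.
#' @param rmsd_min minimum pairwise RMSD (Angstrom); 0 keeps the k
#'   lowest-energy candidates.
#' @return list of selected conformers (an ensemble for
#'   [mp_polar_exposure()]).
#' @export
mp_select_conformers <- function(candidates, k = 50, rmsd_min = 0.5) {
  if (length(candidates) == 0) abort("no candidate conformers")
  en <- vapply(candidates, function(cf) cf$energy, numeric(1))
  if (anyNA(en)) en[is.na(en)] <- Inf
  ord <- order(en)
  heavy <- lapply(candidates, function(cf) cf$coords[cf$elements != "H", , drop = FALSE])
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= k) break
    dup <- any(vapply(sel, function(j) {
      kabsch_rmsd(heavy[[i]], heavy[[j]]) < rmsd_min
    }, logical(1)))
    if (!dup) sel <- c(sel, i)
  }
  candidates[sel]
}

#' Most confidently classified molecules per class
#'
#' Positives ranked by probability descending, negatives ascending; ties
#' broken by stable record order.
#'
#' @param prob predicted probabilities.
#' @param label binary labels in \{0, 1\} (predicted or observed class).
#' @param n how many per class (must not exceed either class count).
#' @return list with integer index vectors `top_positive`, `top_negative`.
#' @export
mp_top_confident <- function(prob, label, n) {
  stopifnot(length(prob) == length(label))
  pos <- which(label == 1); neg <- which(label == 0)
  if (n > length(pos) || n > length(neg)) {
    abort(sprintf("n = %d exceeds a class count (%d positive, %d negative)",
                  n, length(pos), length(neg)))
  }
  list(top_positive = pos[order(-prob[pos])][seq_len(n)],
       top_negative = neg[order(prob[neg])][seq_len(n)])
}

# --- channel importance ----------------------------------------------------

#' Node-feature-channel importance by masking
#'
#' For each node channel: rebuild every evaluation graph with the channel
#' zeroed, re-evaluate the model loss, and record the increase over the
#' unmasked baseline (computed once). With a `fold` column present the
#' difference is computed per fold and summarized as mean and sd.
#'
#' @param model a fitted `macro_pp` classifier.
#' @param data evaluation records (`smiles`, `y`, optionally `fold`; no
#'   excluded labels).
#' @param features optional precomputed [mp_featurize()] bundle.
#' @return an `mp_importance` tibble: `channel`, `mean_dloss`, `sd_dloss`,
#'   ranked by decreasing mean.
#' @export
mp_channel_importance <- function(model, data, features = NULL) {
  data <- as_tibble(data)
  if (anyNA(data$y)) abort("EXCLUDED (NA) labels must be removed first")
  schema <- model$schema
  feats <- features %||% mp_featurize(data, schema)
  folds <- if ("fold" %in% names(data)) data$fold else rep(0L, nrow(data))
  eval_loss <- function(fts, rows) {
    p <- predict(model, data[rows, ], features = subset_features(fts, rows))$prob
    mp_bce(data$y[rows], p)
  }
  fold_ids <- sort(unique(folds))
  base <- vapply(fold_ids, function(f) eval_loss(feats, which(folds == f)),
                 numeric(1))
  rows_list <- lapply(fold_ids, function(f) which(folds == f))
  out <- purrr::map(names(schema$node_channels), function(ch) {
    masked <- feats
    masked$graphs <- lapply(feats$graphs, mp_mask_channel, channel = ch,
                            schema = schema)
    dl <- vapply(seq_along(fold_ids), function(i) {
      eval_loss(masked, rows_list[[i]]) - base[i]
    }, numeric(1))
    tibble(channel = ch, mean_dloss = mean(dl), sd_dloss = stats::sd(dl))
  }) |> bind_rows() |> arrange(desc(.data$mean_dloss))
  attr(out, "baseline_loss") <- stats::setNames(base, fold_ids)
  class(out) <- c("mp_importance", class(out))
  out
}

subset_features <- function(feats, rows) {
  out <- list(graphs = feats$graphs[rows],
              desc = feats$desc[rows, , drop = FALSE],
              ecfp = feats$ecfp[rows, , drop = FALSE],
              maccs = feats$maccs[rows, , drop = FALSE],
              smiles = feats$smiles[rows], schema = feats$schema)
  class(out) <- "mp_features"
  out
}

# --- conformer SDF I/O -----------------------------------------------------

#' Read a multi-conformer SDF file
#'
#' Each SDF record becomes one conformer; an `energy` data field is used
#' when present.
#'
#' @param path SDF file path.
#' @return list of [mp_conformer()] objects.
#' @export
mp_read_conformers <- function(path) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  lapply(seq_along(sdfs), function(i) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) NULL
             else cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
    db <- ChemmineR::datablock(sdf)
    en <- suppressWarnings(as.numeric(db[["energy"]]))
    mp_conformer(sub("_.*$", "", rownames(ab)), ab[, 1:3, drop = FALSE],
                 bonds = bonds, energy = if (length(en)) en else NA_real_)
  })
}

#' Write conformers to a multi-record SDF file
#'
#' @param conformers list of [mp_conformer()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
mp_write_conformers <- function(conformers, path) {
  lines <- unlist(lapply(seq_along(conformers), function(i) {
    cf <- conformers[[i]]
    n <- length(cf$elements)
    nb <- if (is.null(cf$bonds)) 0L else nrow(cf$bonds)
    rec <- c(sprintf("conformer_%d", i), " macroperm", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     cf$coords[, 1], cf$coords[, 2], cf$coords[, 3], cf$elements))
    if (nb > 0) {
      rec <- c(rec, sprintf("%3d%3d%3d  0  0  0  0",
                            cf$bonds[, 1], cf$bonds[, 2],
                            rep(1L, nb)))
    }
    c(rec, "M  END",
      if (!is.na(cf$energy)) c("> <energy>", format(cf$energy), ""),
      "$$$$")
  }))
  writeLines(lines, path)
  invisible(path)
}
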