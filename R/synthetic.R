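#' @title Synthetic macrocycle benchmark generator
#' @description
#' Seeded generator of peptide-like macrocycles and acyclic analogs with a
#' known linear latent permeability function, multi-assay offsets, and
#' Gaussian measurement noise. It emulates the structure of the real
#' curation problem — a large, noisy multi-assay set sharing latent
#' structure with a small task-specific PAMPA set — so the full pipeline
#' (curation, splitting, teacher/student training, importance recovery)
#' can be validated against ground truth without external data.
#' @name synthetic
NULL

# side-chain fragments attached at the alpha carbon; polarity drives the
# hydrogen-bond-donor count the latent function rewards
SIDE_CHAINS <- c(none = "", methyl = "C", hydroxyl = "CO",
                 carboxyl = "CC(=O)O", aryl = "Cc2ccccc2")
HYDROPHOBIC_CHAINS <- c("none", "methyl", "aryl")

#' Synthetic benchmark specification
#'
#' Defaults define the package's reference study conditions: 2000 large-set
#' molecules over four assays, 200 task (PAMPA, macrocyclic) molecules,
#' residue counts of 4--7 (ring sizes 12--21), measurement noise of 0.4
#' -logP units, and a latent function dominated by the hydrogen-bond-donor
#' count.
#'
#' @param n_large,n_task molecule counts for the large multi-assay set and
#'   the task-specific set.
#' @param ring_size_range residues per macrocycle (ring size = 3 residues).
#' @param side_chains named SMILES fragments sampled per residue.
#' @param p_n_methyl probability a residue nitrogen is N-methylated.
#' @param p_macrocycle fraction of large-set molecules that are macrocyclic
#'   (the task set is all-macrocycle).
#' @param beta named coefficients of the latent -logP function: intercept,
#'   hbd, mw (per 100 Da), hydrophobic-fraction, macrocycle flag.
#' @param assay_offsets named -logP shifts per assay.
#' @param assays_per_mol range of assays measured per large-set molecule.
#' @param noise_sd measurement noise sd in -logP units.
#' @param seed master seed; all randomness derives from it.
#' @return an `mp_synthetic_spec` object.
#' @export
mp_synthetic_spec <- function(n_large = 2000, n_task = 200,
                              ring_size_range = 4:7,
                              side_chains = SIDE_CHAINS,
                              p_n_methyl = 0.3, p_macrocycle = 0.6,
                              beta = c(intercept = 2.4, hbd = 0.55, mw = 0.15,
                                       hydrophobic = -0.8, macrocycle = -0.3),
                              assay_offsets = c(CACO2 = 0, MDCK = 0.1,
                                                RRCK = 0.1, PAMPA = 0.2),
                              assays_per_mol = 1:4,
                              noise_sd = 0.4, seed = 1) {
  stopifnot(n_large > 0, n_task > 0, noise_sd >= 0, all(ring_size_range >= 2))
  stopifnot(all(c("intercept", "hbd", "mw", "hydrophobic", "macrocycle")
                %in% names(beta)))
  if (!all(names(assay_offsets) %in% ASSAY_LEVELS)) {
    abort("assay_offsets names must be known assays")
  }
  structure(list(n_large = n_large, n_task = n_task,
                 ring_size_range = ring_size_range, side_chains = side_chains,
                 p_n_methyl = p_n_methyl, p_macrocycle = p_macrocycle,
                 beta = beta, assay_offsets = assay_offsets,
                 assays_per_mol = assays_per_mol, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "mp_synthetic_spec")
}

# assemble a (cyclo-)peptide SMILES from residue side chains / methylation
assemble_peptide <- function(chains, n_methyl, cyclic) {
  branch <- function(i) {
    r <- SIDE_CHAINS[[chains[i]]]
    if (nzchar(r)) paste0("(", r, ")") else ""
  }
  nm <- function(i) if (n_methyl[i]) "(C)" else ""
  n <- length(chains)
  if (cyclic) {
    mid <- if (n >= 2) {
      paste0(vapply(2:n, function(i) paste0("N", nm(i), "C", branch(i), "C(=O)"),
                    character(1)), collapse = "")
    } else ""
    paste0("C1", branch(1), "C(=O)", mid, "N1", if (n_methyl[1]) "(C)" else "")
  } else {
    paste0(paste0(vapply(seq_len(n), function(i) {
      paste0("N", nm(i), "C", branch(i), "C(=O)")
    }, character(1)), collapse = ""), "O")
  }
}

#' Generate the synthetic molecule library
#'
#' Cyclic molecules are head-to-tail amide-closed residue sequences (ring
#' size = 3 x residues); acyclic analogs omit the closure. Duplicate
#' structures (including rotational duplicates of the same cycle) are
#' removed by InChIKey and resampled. Deterministic under the spec seed.
#'
#' @param spec an [mp_synthetic_spec()].
#' @param n number of molecules (defaults to `n_large + n_task`).
#' @param all_macrocycles force every molecule cyclic (task-set sampling).
#' @param seed_tag stream tag so different draws from one spec are
#'   independent but reproducible.
#' @return tibble: `smiles`, `inchikey`, `is_macrocycle`, `largest_ring_size`,
#'   `n_residues`, `hbd_count`, `mw`, `hydrophobic_frac`.
#' @export
mp_generate_library <- function(spec, n = spec$n_large + spec$n_task,
                                all_macrocycles = FALSE, seed_tag = "library") {
  if (n <= 0) abort("`n` must be positive")
  draw_batch <- function(m, tag) {
    with_seed(derive_seed(spec$seed, paste0(seed_tag, "_", tag)), {
      purrr::map(seq_len(m), function(i) {
        k <- if (length(spec$ring_size_range) == 1) spec$ring_size_range
             else sample(spec$ring_size_range, 1)
        chains <- sample(names(spec$side_chains), k, replace = TRUE)
        nmeth <- stats::runif(k) < spec$p_n_methyl
        cyclic <- all_macrocycles || stats::runif(1) < spec$p_macrocycle
        tibble(smiles = assemble_peptide(chains, nmeth, cyclic),
               hydrophobic_frac = mean(chains %in% HYDROPHOBIC_CHAINS),
               n_residues = k, is_macrocycle = cyclic)
      }) |> bind_rows()
    })
  }
  lib <- NULL
  round_i <- 0L
  while ((is.null(lib) || nrow(lib) < n) && round_i < 20L) {
    round_i <- round_i + 1L
    short <- n - if (is.null(lib)) 0L else nrow(lib)
    batch <- draw_batch(ceiling(short * 1.4) + 5, round_i)
    batch$inchikey <- mp_canonicalize(batch$smiles)$inchikey
    batch <- batch[!duplicated(batch$inchikey), ]
    if (!is.null(lib)) batch <- batch[!batch$inchikey %in% lib$inchikey, ]
    lib <- bind_rows(lib, batch)
  }
  if (nrow(lib) < n) abort("could not draw enough unique molecules")
  lib <- lib[seq_len(n), ]
  mols <- mp_parse_mols(lib$smiles)
  desc <- t(vapply(mols, descriptors_one, numeric(14)))
  lib$largest_ring_size <- as.integer(desc[, "largest_ring"])
  lib$hbd_count <- as.integer(desc[, "n_hbd"])
  lib$mw <- desc[, "mw"]
  lib[, c("smiles", "inchikey", "is_macrocycle", "largest_ring_size",
          "n_residues", "hbd_count", "mw", "hydrophobic_frac")]
}

#' Latent -log10(Papp) of a molecule
#'
#' mu = b0 + b_hbd * HBD + b_mw * MW/100 + b_hyd * hydrophobic_frac +
#' b_ring * is_macrocycle. Linear and deterministic, so every downstream
#' test has a closed-form ground truth; the donor term dominates by
#' construction.
#'
#' @param metadata tibble from [mp_generate_library()].
#' @param beta named coefficient vector.
#' @return numeric vector of latent -logP values.
#' @export
mp_latent_permeability <- function(metadata, beta = mp_synthetic_spec()$beta) {
  beta[["intercept"]] +
    beta[["hbd"]] * metadata$hbd_count +
    beta[["mw"]] * metadata$mw / 100 +
    beta[["hydrophobic"]] * metadata$hydrophobic_frac +
    beta[["macrocycle"]] * as.numeric(metadata$is_macrocycle)
}

#' Simulate multi-assay measurements
#'
#' Each molecule is measured in 1--4 assays; the recorded value is
#' mu + assay offset + Normal(0, noise_sd). The noise stream for each
#' (molecule, assay) pair derives from a stable hash of the pair, so
#' adding molecules never perturbs existing draws.
#'
#' @param metadata library tibble with a `mu` column.
#' @param spec an [mp_synthetic_spec()].
#' @param assays restrict to these assays (e.g. "PAMPA" for the task set).
#' @return record tibble (`smiles`, `inchikey`, `assay`, `neg_log_papp`,
#'   `mu`, `source_id`, `largest_ring_size`).
#' @export
mp_simulate_assays <- function(metadata, spec, assays = names(spec$assay_offsets)) {
  stopifnot("mu" %in% names(metadata))
  bad <- setdiff(assays, names(spec$assay_offsets))
  if (length(bad)) abort(sprintf("no offset for assay(s): %s", paste(bad, collapse = ", ")))
  rows <- purrr::map(seq_len(nrow(metadata)), function(i) {
    k <- if (length(assays) == 1) 1L else {
      with_seed(derive_seed(spec$seed, paste0("nassay_", metadata$inchikey[i])),
                sample(intersect(spec$assays_per_mol, seq_along(assays)), 1))
    }
    mol_assays <- if (length(assays) == 1) assays else {
      with_seed(derive_seed(spec$seed, paste0("whichassay_", metadata$inchikey[i])),
                sample(assays, k))
    }
    vals <- vapply(mol_assays, function(a) {
      eps <- with_seed(derive_seed(spec$seed, paste0("noise_", metadata$inchikey[i], "_", a)),
                       stats::rnorm(1, 0, spec$noise_sd))
      metadata$mu[i] + spec$assay_offsets[[a]] + eps
    }, numeric(1))
    tibble(smiles = metadata$smiles[i], inchikey = metadata$inchikey[i],
           assay = mol_assays, neg_log_papp = vals, mu = metadata$mu[i],
           largest_ring_size = metadata$largest_ring_size[i],
           source_id = sprintf("synthetic_%05d", i))
  })
  bind_rows(rows)
}

#' Build the teacher/student benchmark
#'
#' A large multi-assay set labeled at the unified threshold (-logP = 6,
#' swing 0) and a task-specific all-macrocycle PAMPA set labeled with a
#' configurable swing, sharing the latent permeability function but no
#' molecules (unless `allow_overlap`). Ground truth (latent mu, true label
#' at the threshold, and the planted driver channel) is returned for
#' recovery tests.
#'
#' @param spec an [mp_synthetic_spec()].
#' @param task_swing swing halfwidth applied to the task set.
#' @param allow_overlap allow molecules shared between the two sets.
#' @return list with `large`, `task` (labeled record tibbles), and `truth`.
#' @export
mp_make_benchmark <- function(spec = mp_synthetic_spec(), task_swing = 0,
                              allow_overlap = FALSE) {
  lib_large <- mp_generate_library(spec, n = spec$n_large, seed_tag = "large")
  lib_task <- mp_generate_library(spec, n = spec$n_task + if (allow_overlap) 0L else 200L,
                                  all_macrocycles = TRUE, seed_tag = "task")
  if (!allow_overlap) {
    lib_task <- lib_task[!lib_task$inchikey %in% lib_large$inchikey, ]
  }
  if (nrow(lib_task) < spec$n_task) abort("could not draw a disjoint task set")
  lib_task <- lib_task[seq_len(spec$n_task), ]
  lib_large$mu <- mp_latent_permeability(lib_large, spec$beta)
  lib_task$mu <- mp_latent_permeability(lib_task, spec$beta)

  large <- mp_simulate_assays(lib_large, spec) |>
    mp_curate(center = 6, halfwidth = 0)
  task <- mp_simulate_assays(lib_task, spec, assays = "PAMPA") |>
    mp_curate(center = 6, halfwidth = task_swing)
  truth <- bind_rows(
    lib_large |> mutate(set = "large"),
    lib_task |> mutate(set = "task")) |>
    mutate(true_label = mp_swing_label(.data$mu, center = 6, halfwidth = 0),
           true_y = as.integer(.data$true_label == "PERMEABLE"),
           driver_channel = "hbd")
  list(large = large, task = task, truth = truth)
}
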