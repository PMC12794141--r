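#' @title Leakage-free fold assignment and the injection protocol
#' @description
#' Cross-validation folds grouped by canonical SMILES, Murcko scaffold, or
#' fingerprint cluster so that no structure (or structural family) straddles
#' a train/validation boundary; scaffold Tanimoto similarity; clustering of
#' the high-fidelity set; and the stratified high-fidelity injection
#' protocol with selection-overlap accounting.
#' @name splits
NULL

#' Murcko scaffolds
#'
#' Reduces each molecule to its ring systems plus connecting linkers: side
#' chains are removed by iteratively pruning terminal atoms, with
#' multiply-bonded terminal atoms (e.g. a linker carbonyl oxygen) retained
#' together with their parent atom. Acyclic molecules yield the empty-string
#' sentinel.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical scaffold SMILES ("" when acyclic).
#' @export
mp_murcko_scaffold <- function(smiles) {
  mols <- mp_parse_mols(smiles)
  vapply(mols, murcko_one, character(1))
}

murcko_one <- function(mol) {
  if (mol$largest_ring == 0) return("")
  n <- mol$n
  keep <- rep(TRUE, n)
  in_ring <- mol$max_ring > 0
  bonds <- mol$bonds
  repeat {
    deg <- integer(n)
    # pendant-multiple terminals (e.g. =O) don't count toward their
    # parent's degree and are removed/retained with the parent
    kept_b <- keep[bonds[, 1]] & keep[bonds[, 2]]
    bu <- bonds[kept_b, 1]; bv <- bonds[kept_b, 2]; bo <- bonds[kept_b, 3]
    raw_deg <- integer(n)
    for (i in seq_along(bu)) {
      raw_deg[bu[i]] <- raw_deg[bu[i]] + 1L
      raw_deg[bv[i]] <- raw_deg[bv[i]] + 1L
    }
    pendant <- raw_deg == 1 & keep
    is_pendant_mult <- rep(FALSE, n)
    for (i in seq_along(bu)) {
      if (bo[i] > 1) {
        if (pendant[bu[i]]) is_pendant_mult[bu[i]] <- TRUE
        if (pendant[bv[i]]) is_pendant_mult[bv[i]] <- TRUE
      }
    }
    eff_deg <- integer(n)
    for (i in seq_along(bu)) {
      if (!is_pendant_mult[bv[i]]) eff_deg[bu[i]] <- eff_deg[bu[i]] + 1L
      if (!is_pendant_mult[bu[i]]) eff_deg[bv[i]] <- eff_deg[bv[i]] + 1L
    }
    removable <- keep & !in_ring & !is_pendant_mult & eff_deg <= 1
    if (!any(removable)) break
    keep[removable] <- FALSE
    # drop pendant-multiple atoms whose parent just left
    for (i in seq_along(bu)) {
      if (is_pendant_mult[bu[i]] && !keep[bv[i]]) keep[bu[i]] <- FALSE
      if (is_pendant_mult[bv[i]] && !keep[bu[i]]) keep[bv[i]] <- FALSE
    }
  }
  sub_sdf <- ChemmineR::atomsubset(mol$sdf, mol$heavy_idx[keep])
  smi <- sdf_to_cansmi(sub_sdf)
  if (is.na(smi)) "" else smi
}

#' Tanimoto similarity matrix over scaffolds
#'
#' ECFP (radius 2, 2048 bits) Tanimoto similarity |A-and-B|/|A-or-B| between
#' scaffold pairs. Empty-scaffold rows are defined as similarity 0 against
#' every other scaffold and 1 with themselves.
#'
#' @param scaffolds character vector of scaffold SMILES ("" allowed).
#' @return symmetric numeric matrix in [0, 1] with unit diagonal.
#' @export
mp_scaffold_tanimoto <- function(scaffolds) {
  n <- length(scaffolds)
  if (n == 0) abort("need at least one scaffold")
  nonempty <- which(nzchar(scaffolds))
  S <- matrix(0, n, n)
  diag(S) <- 1
  if (length(nonempty) > 0) {
    fp <- mp_fingerprints(scaffolds[nonempty])$ecfp
    S[nonempty, nonempty] <- tanimoto_matrix(fp)
  }
  S
}

tanimoto_matrix <- function(fp) {
  inter <- tcrossprod(fp)
  counts <- rowSums(fp)
  uni <- outer(counts, counts, "+") - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  diag(S) <- 1
  S
}

#' Assign leakage-free cross-validation folds
#'
#' Records are grouped into units that must never straddle folds: the
#' canonical structure (`SMILES`), the Murcko scaffold (`SCAFFOLD`), a
#' fingerprint cluster (`CLUSTER`), or each record alone (`RANDOM`).
#' `SMILES`/`RANDOM` units are dealt round-robin after a seeded shuffle
#' (fold sizes differ by at most one unit); `SCAFFOLD`/`CLUSTER` units are
#' greedily bin-packed in descending size to balance record counts.
#'
#' @param data data frame of records with a `smiles` column.
#' @param mode one of `"SMILES"`, `"SCAFFOLD"`, `"CLUSTER"`, `"RANDOM"`.
#' @param k number of folds (>= 2, <= number of distinct units).
#' @param seed integer seed controlling the shuffle.
#' @param k_range candidate cluster counts for CLUSTER mode.
#' @param cluster_space embedding used in CLUSTER mode (see
#'   [mp_cluster_fidelity()]).
#' @return the input tibble with `unit_key` and `fold` (0-based) columns;
#'   attributes `mode`, `k`, `seed`.
#' @export
mp_assign_folds <- function(data, mode = c("SMILES", "SCAFFOLD", "CLUSTER", "RANDOM"),
                            k = 10, seed = 1, k_range = 2:6,
                            cluster_space = c("tsne", "fingerprint")) {
  mode <- match.arg(mode)
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("no records to split")
  if (k < 2) abort("k must be >= 2")
  unit_key <- switch(mode,
    SMILES = mp_canonicalize(data$smiles)$canonical_smiles,
    SCAFFOLD = {
      sc <- mp_murcko_scaffold(data$smiles)
      ifelse(nzchar(sc), sc, "<acyclic>")
    },
    CLUSTER = {
      cl <- mp_cluster_fidelity(data, k_range = k_range, seed = seed,
                                cluster_space = cluster_space)
      paste0("cluster_", cl$assignment)
    },
    RANDOM = sprintf("row_%06d", seq_len(nrow(data)))
  )
  units <- unique(unit_key)
  if (k > length(units)) {
    abort(sprintf("k = %d exceeds the %d distinct %s units", k, length(units), mode))
  }
  fold_of_unit <- with_seed(derive_seed(seed, paste0("folds_", mode)), {
    shuffled <- sample(units)
    if (mode %in% c("SMILES", "RANDOM")) {
      stats::setNames(rep_len(0:(k - 1), length(shuffled)), shuffled)
    } else {
      sizes <- table(unit_key)[shuffled]
      ord <- order(-as.integer(sizes), shuffled)
      load <- numeric(k)
      assign <- integer(length(shuffled))
      for (i in ord) {
        f <- which.min(load)
        assign[i] <- f - 1L
        load[f] <- load[f] + as.integer(sizes[i])
      }
      stats::setNames(assign, shuffled)
    }
  })
  data$unit_key <- unit_key
  data$fold <- as.integer(fold_of_unit[unit_key])
  attr(data, "mode") <- mode
  attr(data, "k") <- as.integer(k)
  attr(data, "seed") <- as.integer(seed)
  data
}

#' Cluster the high-fidelity set in fingerprint space
#'
#' ECFP fingerprints are embedded into 2D (seeded t-SNE by default, or used
#' raw with `cluster_space = "fingerprint"`), k-means is fitted for every k
#' in `k_range`, and the cluster count is chosen by maximum mean silhouette
#' width (ties to the smaller k). The elbow of the within-cluster SSE curve
#' (maximum second difference) is recorded; `chosen_by` is `"BOTH"` when the
#' two criteria agree and `"SILHOUETTE"` otherwise.
#'
#' @param data data frame with a `smiles` column, or a numeric feature matrix.
#' @param k_range integer candidate cluster counts (all >= 2).
#' @param seed integer seed (t-SNE initialization and k-means starts).
#' @param cluster_space `"tsne"` (cluster the 2D embedding) or
#'   `"fingerprint"` (cluster raw fingerprints).
#' @param perplexity t-SNE perplexity.
#' @return an `mp_cluster` object: `n_clusters`, `centroids`, `assignment`,
#'   `embedding`, `chosen_by`, and the per-k `selection` table.
#' @export
mp_cluster_fidelity <- function(data, k_range = 2:6, seed = 1,
                                cluster_space = c("tsne", "fingerprint"),
                                perplexity = 30) {
  cluster_space <- match.arg(cluster_space)
  X <- if (is.matrix(data)) data else mp_fingerprints(as_tibble(data)$smiles)$ecfp
  if (nrow(X) < max(k_range) + 1) abort("too few records for the requested k_range")
  if (nrow(unique(as.data.frame(X))) < 2) {
    abort("all points are identical; a single cluster cannot be split")
  }
  emb <- if (cluster_space == "tsne") {
    tsne_embed(X, perplexity = perplexity, seed = derive_seed(seed, "tsne"))
  } else X
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 2))
  fits <- lapply(k_range, function(k) {
    with_seed(derive_seed(seed, paste0("kmeans_", k)),
              stats::kmeans(emb, centers = k, nstart = 10, iter.max = 50))
  })
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  dE <- as.matrix(stats::dist(emb))
  sil <- vapply(fits, function(f) {
    mean(cluster::silhouette(f$cluster, dmatrix = dE)[, "sil_width"])
  }, numeric(1))
  elbow_k <- if (length(k_range) >= 3) {
    k_range[which.max(diff(diff(wss))) + 1]
  } else k_range[which.min(wss)]
  sil_k <- k_range[which.max(sil)]
  best <- which(k_range == sil_k)
  structure(list(
    n_clusters = sil_k,
    centroids = fits[[best]]$centers,
    assignment = fits[[best]]$cluster,
    embedding = emb,
    chosen_by = if (sil_k == elbow_k) "BOTH" else "SILHOUETTE",
    selection = tibble(k = k_range, wss = wss, silhouette = sil),
    seed = seed
  ), class = "mp_cluster")
}

#' @export
print.mp_cluster <- function(x, ...) {
  cat(sprintf("<mp_cluster> k = %d (chosen by %s) over %d points\n",
              x$n_clusters, x$chosen_by, nrow(x$embedding)))
  invisible(x)
}

#' Inject a fraction of the high-fidelity set into the large set
#'
#' Selects `round(fraction * n)` high-fidelity records — stratified over
#' fingerprint clusters (`FINGERPRINT`), scaffold clusters (`SCAFFOLD`), or
#' uniformly at random (`RANDOM`) — and appends them to the large set with
#' per-(inchikey, assay) deduplication.
#'
#' @param high_fidelity,large record tibbles (keyed; keys are computed from
#'   `smiles` when absent).
#' @param fraction fraction of the high-fidelity set to inject, in [0, 1].
#' @param strategy `"FINGERPRINT"`, `"SCAFFOLD"`, or `"RANDOM"`.
#' @param seed integer seed.
#' @param k_range candidate cluster counts for the stratification.
#' @return list with `augmented_large` and `selected` tibbles.
#' @export
mp_injection <- function(high_fidelity, large, fraction,
                         strategy = c("FINGERPRINT", "SCAFFOLD", "RANDOM"),
                         seed = 1, k_range = 2:6) {
  strategy <- match.arg(strategy)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    abort("`fraction` must lie in [0, 1]")
  }
  high_fidelity <- ensure_keys(as_tibble(high_fidelity))
  large <- ensure_keys(as_tibble(large))
  n_sel <- round(fraction * nrow(high_fidelity))
  if (n_sel == 0) {
    return(list(augmented_large = large, selected = high_fidelity[0, ]))
  }
  stratum <- switch(strategy,
    RANDOM = rep(1L, nrow(high_fidelity)),
    FINGERPRINT = mp_cluster_fidelity(high_fidelity, k_range = k_range,
                                      seed = seed)$assignment,
    SCAFFOLD = {
      sc <- mp_murcko_scaffold(high_fidelity$smiles)
      S <- mp_scaffold_tanimoto(sc)
      hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
      k <- min(max(k_range), max(2L, length(unique(sc))))
      stats::cutree(hc, k = k)
    })
  idx <- with_seed(derive_seed(seed, paste0("inject_", strategy)), {
    strata <- split(seq_len(nrow(high_fidelity)), stratum)
    # largest-remainder proportional allocation across strata
    quota <- n_sel * lengths(strata) / nrow(high_fidelity)
    take <- floor(quota)
    rem <- n_sel - sum(take)
    if (rem > 0) {
      extra <- order(-(quota - take))[seq_len(rem)]
      take[extra] <- take[extra] + 1
    }
    unlist(purrr::map2(strata, take, function(rows, m) {
      if (m == 0) integer(0) else sample(rows, min(m, length(rows)))
    }), use.names = FALSE)
  })
  selected <- high_fidelity[sort(idx), ]
  combined <- bind_rows(large, selected)
  augmented <- combined[!duplicated(combined[c("inchikey", "assay")]), ]
  list(augmented_large = augmented, selected = selected)
}

#' Overlap fraction between two selections
#'
#' |A intersect B| / |A| by InChIKey; asymmetric, so both directions are
#' reported.
#'
#' @param selected_a,selected_b record tibbles with `inchikey` (or `smiles`).
#' @return tibble with `a_in_b` and `b_in_a` fractions.
#' @export
mp_selection_overlap <- function(selected_a, selected_b) {
  selected_a <- ensure_keys(as_tibble(selected_a))
  selected_b <- ensure_keys(as_tibble(selected_b))
  if (nrow(selected_a) == 0 || nrow(selected_b) == 0) {
    abort("selections must be non-empty")
  }
  ka <- unique(selected_a$inchikey)
  kb <- unique(selected_b$inchikey)
  tibble(a_in_b = length(intersect(ka, kb)) / length(ka),
         b_in_a = length(intersect(kb, ka)) / length(kb))
}
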