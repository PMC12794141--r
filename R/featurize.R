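#' @title Molecular graphs, descriptors, and feature masking
#' @description
#' Node/edge feature construction for the message-passing encoder, the
#' physicochemical descriptor block, and channel masking used by the
#' feature-importance analysis. The node schema is versioned and fully
#' configurable; named channels include the hydrogen-bond donor/acceptor
#' flags, lone-pair counts, and large-ring membership that drive the
#' interpretability analyses.
#' @name featurize
NULL

ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453,
                 Br = 79.904, I = 126.904)
VALENCE_ELECTRONS <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4,
                       P = 5, S = 6, Cl = 7, Br = 7, I = 7)

#' Node/edge feature schema
#'
#' Ordered named channels with widths; one-hot blocks carry exactly one
#' active bit per atom. The `in_large_ring` flag marks membership in any
#' smallest-set ring of at least `large_ring_min` atoms (12 by default, the
#' lower bound of the macrocycle strata).
#'
#' @param element_alphabet elements receiving their own one-hot slot;
#'   anything else maps to the trailing "other" slot with a warning.
#' @param large_ring_min ring size (atoms) from which `in_large_ring` is set.
#' @param version schema version string stored with checkpoints.
#' @return an `mp_schema` object.
#' @export
mp_feature_schema <- function(element_alphabet = c("C", "N", "O", "S", "P",
                                                   "F", "Cl", "Br", "I"),
                              large_ring_min = 12, version = "1") {
  node_channels <- list(
    element = length(element_alphabet) + 1L,
    degree = 6L,
    formal_charge = 1L,
    aromatic = 1L,
    hybridization = 4L,
    chirality = 3L,
    hbd = 1L,
    hba = 1L,
    lone_pairs = 1L,
    in_large_ring = 1L,
    total_h = 1L
  )
  edge_channels <- list(bond_type = 4L, conjugated = 1L, in_ring = 1L, stereo = 3L)
  structure(list(element_alphabet = element_alphabet,
                 large_ring_min = large_ring_min,
                 node_channels = node_channels,
                 edge_channels = edge_channels,
                 d_node = sum(unlist(node_channels)),
                 d_edge = sum(unlist(edge_channels)),
                 version = version),
            class = "mp_schema")
}

#' @export
print.mp_schema <- function(x, ...) {
  cat(sprintf("<mp_schema v%s> %d node dims (%s), %d edge dims\n", x$version,
              x$d_node, paste(names(x$node_channels), collapse = ", "), x$d_edge))
  invisible(x)
}

# column index range of a named node channel
schema_channel_cols <- function(schema, channel) {
  widths <- unlist(schema$node_channels)
  if (!channel %in% names(widths)) {
    abort(sprintf("unknown channel \"%s\"; schema channels: %s",
                  channel, paste(names(widths), collapse = ", ")))
  }
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  seq.int(starts[[channel]], ends[[channel]])
}

one_hot <- function(idx, width) {
  v <- numeric(width)
  v[max(1L, min(width, idx))] <- 1
  v
}

#' Lone-pair count of an atom
#'
#' (valence electrons - formal charge - heavy-bond order sum - attached
#' hydrogens) / 2, floored at zero. Oxygen in water has 2 lone pairs,
#' ammonia nitrogen 1, methane carbon 0.
#'
#' @param element element symbol(s).
#' @param charge formal charge(s).
#' @param bond_order_sum summed bond orders to heavy neighbors.
#' @param h_count attached hydrogens.
#' @return integer vector of lone-pair counts (>= 0).
#' @export
mp_lone_pairs <- function(element, charge = 0, bond_order_sum = 0, h_count = 0) {
  v <- VALENCE_ELECTRONS[element]
  unknown <- is.na(v)
  if (any(unknown)) {
    warn(sprintf("no valence-electron count for element(s) %s; lone pairs set to 0",
                 paste(unique(element[unknown]), collapse = ", ")))
    v[unknown] <- charge[unknown] + bond_order_sum + h_count  # forces 0
  }
  pmax(0L, as.integer(floor((v - charge - bond_order_sum - h_count) / 2)))
}

mol_atom_table <- function(mol) {
  n <- mol$n
  ends <- c(mol$bonds[, 1], mol$bonds[, 2])
  ords <- rep(mol$bonds[, 3], 2)
  bos <- numeric(n)
  if (length(ends) > 0) {
    rs <- rowsum(ords, ends)
    bos[as.integer(rownames(rs))] <- rs
  }
  n_double <- tabulate(ends[ords == 2], nbins = n)
  n_triple <- tabulate(ends[ords == 3], nbins = n)
  hyb <- ifelse(n_triple > 0 | n_double >= 2, "sp",
                ifelse(n_double == 1 | mol$aromatic, "sp2", "sp3"))
  lp <- mp_lone_pairs(mol$element, mol$charge, bos, mol$h_count)
  list(element = mol$element, charge = mol$charge, degree = mol$degree,
       h_count = mol$h_count, bond_order_sum = bos,
       aromatic = mol$aromatic, hybridization = hyb, lone_pairs = lp,
       hbd = mol$element %in% c("N", "O") & mol$h_count >= 1,
       hba = mol$element %in% c("N", "O") & lp >= 1,
       max_ring = mol$max_ring)
}

graph_from_mol <- function(mol, schema, at = mol_atom_table(mol)) {
  alpha <- schema$element_alphabet
  n <- mol$n
  outside <- setdiff(unique(at$element), alpha)
  if (length(outside)) {
    warn(sprintf("element(s) %s outside schema alphabet for %s; mapped to \"other\"",
                 paste(outside, collapse = ", "), mol$smiles))
  }
  nel <- length(alpha) + 1L
  el_idx <- match(at$element, alpha)
  el_idx[is.na(el_idx)] <- nel
  hy_idx <- match(at$hybridization, c("sp", "sp2", "sp3"))
  hy_idx[is.na(hy_idx)] <- 4L
  rows <- seq_len(n)
  X <- matrix(0, n, schema$d_node)
  off <- 0L
  X[cbind(rows, el_idx)] <- 1; off <- off + nel
  X[cbind(rows, off + pmin(at$degree, 5L) + 1L)] <- 1; off <- off + 6L
  X[, off + 1L] <- at$charge; off <- off + 1L
  X[, off + 1L] <- as.numeric(at$aromatic); off <- off + 1L
  X[cbind(rows, off + hy_idx)] <- 1; off <- off + 4L
  X[, off + 1L] <- 1                       # chirality: unspecified for 2D input
  off <- off + 3L
  X[, off + 1L] <- as.numeric(at$hbd); off <- off + 1L
  X[, off + 1L] <- as.numeric(at$hba); off <- off + 1L
  X[, off + 1L] <- at$lone_pairs; off <- off + 1L
  X[, off + 1L] <- as.numeric(at$max_ring >= schema$large_ring_min); off <- off + 1L
  X[, off + 1L] <- at$h_count

  nb <- nrow(mol$bonds)
  if (nb > 0) {
    btype <- ifelse(mol$aromatic_bond, 4L, pmax(1L, pmin(3L, mol$bonds[, 3])))
    sp2 <- at$hybridization %in% c("sp", "sp2")
    conj <- sp2[mol$bonds[, 1]] & sp2[mol$bonds[, 2]]
    efeat <- matrix(0, nb, schema$d_edge)
    efeat[cbind(seq_len(nb), btype)] <- 1
    efeat[, 5L] <- as.numeric(conj)
    efeat[, 6L] <- as.numeric(mol$in_ring_bond)
    efeat[, 7L] <- 1                       # stereo: unspecified
    edges <- matrix(0L, 2L * nb, 2)
    edges[seq(1, 2 * nb, by = 2), ] <- mol$bonds[, 1:2, drop = FALSE]
    edges[seq(2, 2 * nb, by = 2), ] <- mol$bonds[, 2:1, drop = FALSE]
    E <- efeat[rep(seq_len(nb), each = 2), , drop = FALSE]
  } else {
    edges <- matrix(integer(0), 0, 2)
    E <- matrix(numeric(0), 0, schema$d_edge)
  }
  structure(list(n_nodes = n, node_features = X, edges = edges,
                 edge_features = E, schema_version = schema$version),
            class = "mp_graph")
}

#' Build a molecular graph
#'
#' Heavy-atom graph with the schema's node features and per-bond edge
#' features stored in both directions (the feature of (u,v) equals that of
#' (v,u)). Construction is deterministic for a fixed schema.
#'
#' @param smiles a single SMILES string.
#' @param schema an [mp_feature_schema()].
#' @return an `mp_graph`: `n_nodes`, `node_features` (|V| x d_node),
#'   `edges` (directed pairs), `edge_features` (|E| x d_edge).
#' @export
mp_mol_graph <- function(smiles, schema = mp_feature_schema()) {
  stopifnot(length(smiles) == 1)
  graph_from_mol(mp_parse_mols(smiles)[[1]], schema)
}

#' @export
print.mp_graph <- function(x, ...) {
  cat(sprintf("<mp_graph> %d nodes, %d directed edges, d_node = %d, d_edge = %d\n",
              x$n_nodes, nrow(x$edges), ncol(x$node_features), ncol(x$edge_features)))
  invisible(x)
}

#' Zero out one node-feature channel
#'
#' Masking is idempotent and touches only the named channel's columns; it
#' is the primitive behind [mp_channel_importance()].
#'
#' @param graph an `mp_graph`.
#' @param channel a node channel name from the schema.
#' @param schema the schema the graph was built with.
#' @return the masked `mp_graph`.
#' @export
mp_mask_channel <- function(graph, channel, schema = mp_feature_schema()) {
  cols <- schema_channel_cols(schema, channel)
  graph$node_features[, cols] <- 0
  graph
}

#' Physicochemical descriptors
#'
#' Family `"physchem"`: a fixed 14-length vector of interpretable 2D
#' descriptors (molecular weight, heavy-atom/ring statistics, hydrogen-bond
#' counts, rotatable bonds, aromatic and sp3 fractions). Values are
#' deterministic; non-finite entries are imputed to 0 with a warning.
#'
#' @param smiles character vector of SMILES.
#' @param family descriptor family (currently `"physchem"`).
#' @return numeric matrix, one row per molecule, named columns.
#' @export
mp_descriptors <- function(smiles, family = "physchem") {
  family <- match.arg(family)
  mols <- mp_parse_mols(smiles)
  desc <- t(vapply(mols, descriptors_one, numeric(14)))
  if (any(!is.finite(desc))) {
    warn("non-finite descriptor values imputed to 0")
    desc[!is.finite(desc)] <- 0
  }
  rownames(desc) <- NULL
  desc
}

descriptors_one <- function(mol, at = mol_atom_table(mol)) {
  mass <- ATOMIC_MASS[at$element]
  mass[is.na(mass)] <- 0
  mw <- sum(mass) + sum(at$h_count) * ATOMIC_MASS[["H"]]
  rot <- 0L
  if (nrow(mol$bonds) > 0) {
    rot <- sum(mol$bonds[, 3] == 1 & !mol$in_ring_bond &
               at$degree[mol$bonds[, 1]] >= 2 & at$degree[mol$bonds[, 2]] >= 2)
  }
  c(mw = mw,
    n_heavy = mol$n,
    n_hbd = sum(at$hbd),
    n_hba = sum(at$hba),
    n_lone_pairs = sum(at$lone_pairs),
    n_rings = mol$n_rings,
    largest_ring = mol$largest_ring,
    is_macrocycle = as.numeric(mol$largest_ring >= 12),
    n_rotatable = rot,
    aromatic_frac = mean(at$aromatic),
    sp3_frac = mean(at$hybridization == "sp3"),
    charge_sum = sum(at$charge),
    hetero_frac = mean(!at$element %in% c("C", "H")),
    total_h = sum(at$h_count))
}

#' Standardize a descriptor matrix with training statistics
#'
#' @param x numeric matrix to transform.
#' @param stats result of a previous call (training statistics), or NULL to
#'   fit mean/sd on `x` (non-finite entries excluded from the fit).
#' @return list with `x` (transformed), `center`, `scale`.
#' @export
mp_standardize <- function(x, stats = NULL) {
  if (is.null(stats)) {
    center <- apply(x, 2, function(v) mean(v[is.finite(v)]))
    scl <- apply(x, 2, function(v) stats::sd(v[is.finite(v)]))
    center[!is.finite(center)] <- 0
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    center <- stats$center
    scl <- stats$scale
  }
  xt <- sweep(sweep(x, 2, center), 2, scl, "/")
  xt[!is.finite(xt)] <- 0
  list(x = xt, center = center, scale = scl)
}

#' Featurize a record set into the multi-representation bundle
#'
#' Parses each distinct molecule once and assembles the four
#' representations the model fuses: molecular graph, physchem descriptors,
#' ECFP (2048 bits), and MACCS keys (167 slots).
#'
#' @param data record tibble with a `smiles` column.
#' @param schema an [mp_feature_schema()].
#' @return an `mp_features` object: `graphs` (list of `mp_graph`), `desc`,
#'   `ecfp`, `maccs` matrices aligned with `data` rows, plus the schema.
#' @export
mp_featurize <- function(data, schema = mp_feature_schema()) {
  data <- as_tibble(data)
  smiles <- data$smiles
  uniq <- unique(smiles)
  idx <- match(smiles, uniq)
  mols <- mp_parse_mols(uniq)
  ats <- lapply(mols, mol_atom_table)
  graphs_u <- purrr::map2(mols, ats, graph_from_mol, schema = schema)
  desc_u <- t(mapply(descriptors_one, mols, ats))
  desc_u[!is.finite(desc_u)] <- 0
  fps <- mp_fingerprints(uniq)
  structure(list(graphs = graphs_u[idx],
                 desc = desc_u[idx, , drop = FALSE],
                 ecfp = fps$ecfp[idx, , drop = FALSE],
                 maccs = fps$maccs[idx, , drop = FALSE],
                 smiles = smiles,
                 schema = schema),
            class = "mp_features")
}

#' @export
print.mp_features <- function(x, ...) {
  cat(sprintf("<mp_features> %d records (%d unique), d_node = %d, %d descriptors\n",
              length(x$graphs), length(unique(x$smiles)),
              x$schema$d_node, ncol(x$desc)))
  invisible(x)
}
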