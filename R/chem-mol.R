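#' @title Molecule parsing and identifiers
#' @description
#' Thin, batched layer over OpenBabel (via the `obabel` CLI shipped with
#' ChemmineOB) and ChemmineR. All SMILES enter the package through here;
#' downstream code works on the parsed `mp_mol` topology (heavy-atom graph
#' with per-atom hydrogen counts, charges, ring and aromaticity perception).
#' @name chem-mol
NULL

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) abort("The `obabel` executable is required but was not found on PATH.")
  p
}

# Run obabel on a batch of SMILES (titles = 1..n for alignment); returns
# stdout lines. OpenBabel chatter on stderr is discarded.
run_obabel <- function(smiles, out_args) {
  inf <- tempfile(fileext = ".smi")
  on.exit(unlink(inf), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), inf)
  out <- suppressWarnings(system2(obabel_path(), c(inf, out_args),
                                  stdout = TRUE, stderr = FALSE))
  attr(out, "status") <- attr(out, "status") %||% 0L
  out
}

# Identify which SMILES OpenBabel can parse at all (cheap batch probe).
smiles_parse_ok <- function(smiles) {
  out <- run_obabel(smiles, c("-osmi"))
  titles <- sub("^\\S*\\s*", "", out)
  seq_along(smiles) %in% suppressWarnings(as.integer(titles))
}

assert_parsable <- function(smiles) {
  if (length(smiles) == 0) abort("no SMILES given")
  if (any(!nzchar(smiles) | is.na(smiles))) abort("empty or missing SMILES string")
  ok <- smiles_parse_ok(smiles)
  if (!all(ok)) {
    abort(sprintf("unparsable SMILES: %s",
                  paste(unique(smiles[!ok]), collapse = ", ")))
  }
  invisible(smiles)
}

#' Canonicalize SMILES and compute InChIKeys
#'
#' Converts each SMILES to its OpenBabel canonical form and 27-character
#' standard InChIKey. Canonicalization is idempotent: canonicalizing the
#' output returns the output. Records of the same molecule written as
#' different SMILES strings collapse to one key, which is the basis for
#' dataset deduplication.
#'
#' @param smiles character vector of SMILES strings.
#' @return A tibble with columns `smiles`, `canonical_smiles`, `inchikey`.
#' @examples
#' \donttest{
#' mp_canonicalize(c("c1ccccc1", "C1=CC=CC=C1"))
#' }
#' @export
mp_canonicalize <- function(smiles) {
  assert_parsable(smiles)
  can_out <- run_obabel(smiles, c("-ocan"))
  cans <- sub("\\s.*$", "", can_out)
  if (length(cans) != length(smiles)) {
    abort("canonicalization dropped molecules unexpectedly")
  }
  ik_out <- run_obabel(smiles, c("-oinchikey"))
  iks <- sub("\\s.*$", "", ik_out)
  iks <- iks[grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", iks)]
  if (length(iks) != length(smiles)) {
    abort("InChIKey generation dropped molecules unexpectedly")
  }
  tibble(smiles = smiles, canonical_smiles = cans, inchikey = iks)
}

#' Parse SMILES into heavy-atom molecular topologies
#'
#' Each molecule is converted once (with explicit hydrogens) and parsed into
#' an `mp_mol`: element symbols, formal charges, per-atom hydrogen counts,
#' the heavy-atom bond list with orders, ring perception (smallest-ring
#' membership and the largest ring size), and per-atom/per-bond aromaticity.
#'
#' @param smiles character vector of SMILES.
#' @return A list of `mp_mol` objects, one per input.
#' @export
mp_parse_mols <- function(smiles) {
  assert_parsable(smiles)
  outf <- tempfile(fileext = ".sdf")
  on.exit(unlink(outf), add = TRUE)
  inf <- tempfile(fileext = ".smi")
  on.exit(unlink(inf), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), inf)
  suppressWarnings(system2(obabel_path(), c(inf, "-osdf", "-h", "-O", outf),
                           stdout = FALSE, stderr = FALSE))
  lines <- readLines(outf)
  rec_end <- which(lines == "$$$$")
  rec_start <- c(1L, utils::head(rec_end, -1) + 1L)
  titles <- suppressWarnings(as.integer(lines[rec_start]))
  if (!identical(titles, seq_along(smiles))) {
    abort("SDF conversion dropped or reordered molecules")
  }
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(outf))
  ChemmineR::cid(sdfset) <- as.character(seq_along(sdfset))
  lapply(seq_along(smiles), function(i) {
    chg_lines <- grep("^M  CHG", lines[rec_start[i]:rec_end[i]], value = TRUE)
    build_mp_mol(smiles[i], sdfset[[i]], chg_lines)
  })
}

parse_chg_lines <- function(chg_lines, n_atoms) {
  charge <- integer(n_atoms)
  for (l in chg_lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) charge[f[2 * j]] <- f[2 * j + 1]
  }
  charge
}

# Smallest-set-like ring perception: BFS spanning forest identifies one
# ring-closure edge per independent cycle; for each closure edge the
# shortest path between its endpoints (excluding the edge) completes the
# smallest ring through it.
perceive_rings <- function(n, bonds) {
  if (nrow(bonds) == 0) return(list())
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds[i, 1]]] <- c(adj[[bonds[i, 1]]], i)
    adj[[bonds[i, 2]]] <- c(adj[[bonds[i, 2]]], i)
  }
  visited <- rep(FALSE, n)
  tree_edge <- rep(FALSE, nrow(bonds))
  for (root in seq_len(n)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (ei in adj[[u]]) {
        v <- bonds[ei, 1] + bonds[ei, 2] - u
        if (!visited[v]) {
          visited[v] <- TRUE
          tree_edge[ei] <- TRUE
          queue <- c(queue, v)
        }
      }
    }
  }
  rings <- list()
  seen <- character(0)
  for (ei in which(!tree_edge)) {
    u <- bonds[ei, 1]; v <- bonds[ei, 2]
    prev <- rep(0L, n); prev[u] <- -1L
    queue <- u
    while (length(queue) && prev[v] == 0L) {
      w <- queue[[1]]; queue <- queue[-1]
      for (ej in adj[[w]]) {
        if (ej == ei) next
        x <- bonds[ej, 1] + bonds[ej, 2] - w
        if (prev[x] == 0L) {
          prev[x] <- w
          if (x == v) break
          queue <- c(queue, x)
        }
      }
    }
    if (prev[v] == 0L) next
    path <- v; w <- v
    while (w != u) { w <- prev[w]; path <- c(path, w) }
    key <- paste(sort(path), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1]] <- path
    }
  }
  rings
}

# Hueckel-style call on a kekulized ring: 5--7-membered, every atom either
# carries a double bond (1 pi electron) or is a N/O/S lone-pair donor
# (2 pi electrons), total 4n + 2.
ring_aromatic <- function(ring, element, in_double) {
  k <- length(ring)
  if (k < 5 || k > 7) return(FALSE)
  pi_e <- 0
  for (a in ring) {
    if (in_double[a]) {
      pi_e <- pi_e + 1
    } else if (element[a] %in% c("N", "O", "S")) {
      pi_e <- pi_e + 2
    } else {
      return(FALSE)
    }
  }
  pi_e %% 4 == 2
}

build_mp_mol <- function(smiles, sdf, chg_lines) {
  ab <- ChemmineR::atomblock(sdf)
  sym_all <- sub("_.*$", "", rownames(ab))
  n_all <- length(sym_all)
  bb <- ChemmineR::bondblock(sdf)
  bonds_all <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(integer(0), ncol = 3)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  charge_all <- parse_chg_lines(chg_lines, n_all)

  heavy_idx <- which(sym_all != "H")
  n <- length(heavy_idx)
  all2heavy <- integer(n_all)
  all2heavy[heavy_idx] <- seq_len(n)

  is_h <- sym_all == "H"
  bu <- bonds_all[, 1]; bv <- bonds_all[, 2]; bo <- bonds_all[, 3]
  h_parents <- c(bv[is_h[bu] & !is_h[bv]], bu[is_h[bv] & !is_h[bu]])
  h_count <- tabulate(all2heavy[h_parents], nbins = n)
  keep <- !is_h[bu] & !is_h[bv]
  bonds <- cbind(u = all2heavy[bu[keep]], v = all2heavy[bv[keep]], order = bo[keep])
  degree <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)

  # ring perception on the heavy-atom graph (H atoms never sit in rings)
  ring_atoms <- perceive_rings(n, bonds)
  in_double <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    dbl <- bonds[bonds[, 3] == 2, 1:2, drop = FALSE]
    in_double[unique(as.vector(dbl))] <- TRUE
  }
  ring_arom <- vapply(ring_atoms, ring_aromatic, logical(1),
                      element = sym_all[heavy_idx], in_double = in_double)
  max_ring <- integer(n)
  aromatic <- logical(n)
  for (k in seq_along(ring_atoms)) {
    idx <- ring_atoms[[k]]
    max_ring[idx] <- pmax(max_ring[idx], length(idx))
    if (isTRUE(ring_arom[k])) aromatic[idx] <- TRUE
  }
  in_ring_bond <- logical(nrow(bonds))
  arom_bond <- logical(nrow(bonds))
  if (nrow(bonds) > 0 && length(ring_atoms) > 0) {
    for (k in seq_along(ring_atoms)) {
      idx <- ring_atoms[[k]]
      hit <- bonds[, 1] %in% idx & bonds[, 2] %in% idx
      in_ring_bond <- in_ring_bond | hit
      if (isTRUE(ring_arom[k])) arom_bond <- arom_bond | hit
    }
  }

  structure(list(
    smiles = smiles,
    sdf = sdf,
    n = n,
    element = sym_all[heavy_idx],
    charge = charge_all[heavy_idx],
    h_count = h_count,
    degree = degree,
    bonds = bonds,
    aromatic = aromatic,
    aromatic_bond = arom_bond,
    in_ring_bond = in_ring_bond,
    max_ring = max_ring,
    largest_ring = if (length(ring_atoms)) max(lengths(ring_atoms)) else 0L,
    n_rings = length(ring_atoms),
    heavy_idx = heavy_idx
  ), class = "mp_mol")
}

#' @export
print.mp_mol <- function(x, ...) {
  cat(sprintf("<mp_mol> %s: %d heavy atoms, %d bonds, largest ring %d\n",
              x$smiles, x$n, nrow(x$bonds), x$largest_ring))
  invisible(x)
}

#' Largest ring size of each molecule
#'
#' @param smiles character vector of SMILES.
#' @return integer vector; 0 for acyclic molecules.
#' @export
mp_largest_ring <- function(smiles) {
  vapply(mp_parse_mols(smiles), function(m) as.integer(m$largest_ring), integer(1))
}

# --- fingerprints ----------------------------------------------------------

# nibble -> 4-bit expansion table (hex digit, most significant bit first)
NIBBLE_BITS <- t(vapply(0:15, function(x) {
  as.integer(c(bitwAnd(x, 8L) > 0, bitwAnd(x, 4L) > 0,
               bitwAnd(x, 2L) > 0, bitwAnd(x, 1L) > 0))
}, integer(4)))

run_fps <- function(smiles, fptype, n_bits) {
  out <- run_obabel(smiles, c("-ofps", paste0("-xf", fptype)))
  out <- out[!startsWith(out, "#")]
  parts <- strsplit(out, "\t")
  titles <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  if (!identical(titles, seq_along(smiles))) {
    abort(sprintf("fingerprint generation failed for some molecules (%s)", fptype))
  }
  hexes <- vapply(parts, `[`, "", 1)
  nhex <- nchar(hexes[1])
  nib <- matrix(strtoi(do.call(rbind, strsplit(hexes, "")), base = 16L),
                nrow = length(hexes))
  bits <- matrix(0L, length(hexes), 4L * nhex)
  for (b in 1:4) {
    bits[, seq(b, 4L * nhex, by = 4L)] <- NIBBLE_BITS[nib + 1L, b]
  }
  bits[, seq_len(n_bits), drop = FALSE]
}

#' Compute ECFP and MACCS fingerprints
#'
#' Extended-connectivity fingerprints (radius 2) folded to 2048 bits, and
#' 167-slot MACCS structural keys (classic key numbering: slot 1 unused,
#' keys 1--166 in slots 2--167).
#'
#' @param smiles character vector of SMILES.
#' @return list with `ecfp` (n x 2048 0/1 matrix) and `maccs` (n x 167).
#' @export
mp_fingerprints <- function(smiles) {
  assert_parsable(smiles)
  ecfp4096 <- run_fps(smiles, "ECFP4", 4096L)
  ecfp <- pmin(ecfp4096[, 1:2048, drop = FALSE] + ecfp4096[, 2049:4096, drop = FALSE], 1L)
  maccs166 <- run_fps(smiles, "MACCS", 166L)
  maccs <- cbind(0L, maccs166)
  rownames(ecfp) <- rownames(maccs) <- NULL
  colnames(maccs) <- NULL
  list(ecfp = ecfp, maccs = maccs)
}

# SDF object -> canonical SMILES (used for scaffolds)
sdf_to_cansmi <- function(sdf) {
  f <- tempfile(fileext = ".sdf")
  on.exit(unlink(f), add = TRUE)
  sdfl <- as(as(sdf, "SDFstr"), "list")[[1]]
  writeLines(c(sdfl, "$$$$"), f)
  out <- suppressWarnings(system2(obabel_path(), c(f, "-ocan"),
                                  stdout = TRUE, stderr = FALSE))
  if (length(out) == 0) return(NA_character_)
  sub("\\s.*$", "", out[[1]])
}
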