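#' Chain-growth fragments
#'
#' A fragment is a rigid set of atoms (coordinates in Angstrom) with
#' designated overlap-atom subsets at its head and tail (e.g. the heavy
#' atoms of the terminal sugar and nucleobase). Chains are assembled by
#' superposing the head overlap of one fragment onto the tail overlap of
#' another.
#'
#' @param xyz numeric matrix (n x 3), Angstrom.
#' @param head_idx,tail_idx row indices of the head/tail overlap atoms
#'   (non-empty, matched in order between fragments to be joined).
#' @param labels optional atom labels.
#' @param is_dye logical; dye fragments carry a reference atom marking
#'   the fluorophore position.
#' @param ref_idx reference atom index (dye position) for dye fragments.
#' @return object of class `cg_fragment`.
#' @export
cg_fragment <- function(xyz, head_idx, tail_idx, labels = NULL,
                        is_dye = FALSE, ref_idx = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, all(is.finite(xyz)),
            length(head_idx) >= 1L, length(tail_idx) >= 1L)
  if (is.null(labels)) labels <- paste0("X", seq_len(nrow(xyz)))
  structure(list(xyz = xyz, head_idx = as.integer(head_idx),
                 tail_idx = as.integer(tail_idx), labels = labels,
                 is_dye = is_dye, ref_idx = ref_idx),
            class = "cg_fragment")
}

#' Assembly gates for hierarchical chain growth
#' @param rmsd_max superposition RMSD acceptance threshold (Angstrom,
#'   strict: pass iff rmsd < rmsd_max; default 0.8).
#' @param clash_dist heavy-atom clash distance (Angstrom; a pair closer
#'   than this fails; default 2.0).
#' @export
assembly_gates <- function(rmsd_max = 0.8, clash_dist = 2.0) {
  stopifnot(rmsd_max > 0, clash_dist > 0)
  list(rmsd_max = rmsd_max, clash_dist = clash_dist)
}

#' Least-squares rigid superposition (Kabsch) with an RMSD gate
#'
#' Finds the proper rotation + translation minimizing the RMSD between
#' matched overlap atom sets (reflections excluded: the rotation
#' determinant is +1, preserving chirality), and gates acceptance on
#' rmsd < rmsd_max.
#'
#' @param ref_xyz target overlap coordinates (n x 3; e.g. the tail of the
#'   growing chain).
#' @param mov_xyz moving overlap coordinates (n x 3, matched row order;
#'   e.g. the head of the incoming fragment).
#' @param gates an [assembly_gates] list.
#' @return list with `rotation` (3 x 3, det +1), `translation` (applied
#'   as x %*% rotation + translation), `rmsd` (Angstrom), `pass`.
#' @export
superpose_and_gate <- function(ref_xyz, mov_xyz, gates = assembly_gates()) {
  ref_xyz <- as.matrix(ref_xyz); mov_xyz <- as.matrix(mov_xyz)
  if (nrow(ref_xyz) != nrow(mov_xyz))
    stop("overlap sets must have matched atoms", call. = FALSE)
  if (nrow(ref_xyz) < 3L)
    stop("superposition underdetermined with < 3 atom correspondences",
         call. = FALSE)
  ca <- colMeans(ref_xyz); cb <- colMeans(mov_xyz)
  A <- sweep(ref_xyz, 2, ca); B <- sweep(mov_xyz, 2, cb)
  M <- t(B) %*% A
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  Q <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  moved <- B %*% Q
  rmsd <- sqrt(mean(rowSums((moved - A)^2)))
  list(rotation = Q, translation = ca - (cb %*% Q)[1, ], rmsd = rmsd,
       pass = rmsd < gates$rmsd_max)
}

apply_transform <- function(xyz, tr) {
  sweep(xyz %*% tr$rotation, 2, tr$translation, "+")
}

#' Clash detection between two atom sets
#'
#' TRUE (pass) iff no non-excluded atom pair across the two sets is
#' closer than `clash_dist`. Uses a spatial-hash (cell list) neighbor
#' search with cells of the clash distance, comparing only atoms in
#' adjacent cells.
#'
#' @param xyz1,xyz2 coordinate matrices (Angstrom) in a common frame.
#' @param clash_dist clash distance (Angstrom).
#' @param excl1,excl2 row indices (into xyz1/xyz2) excluded from the
#'   check (e.g. the shared overlap atoms and bonded neighbors).
#' @return logical: TRUE when clash-free.
#' @export
clash_test <- function(xyz1, xyz2, clash_dist = 2.0,
                       excl1 = integer(), excl2 = integer()) {
  xyz1 <- as.matrix(xyz1); xyz2 <- as.matrix(xyz2)
  if (length(excl1)) xyz1 <- xyz1[-excl1, , drop = FALSE]
  if (length(excl2)) xyz2 <- xyz2[-excl2, , drop = FALSE]
  if (!nrow(xyz1) || !nrow(xyz2)) return(TRUE)
  # small problems: vectorized all-pairs distances beat the hash overhead
  if (as.numeric(nrow(xyz1)) * nrow(xyz2) <= 4e4) {
    d2 <- outer(rowSums(xyz1^2), rowSums(xyz2^2), "+") -
      2 * xyz1 %*% t(xyz2)
    return(!any(d2 < clash_dist^2))
  }
  cell <- function(m) {
    ic <- floor(m / clash_dist)
    paste(ic[, 1], ic[, 2], ic[, 3], sep = ",")
  }
  # hash set-2 atoms by cell
  key2 <- cell(xyz2)
  buckets <- split(seq_len(nrow(xyz2)), key2)
  ic1 <- floor(xyz1 / clash_dist)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  c2 <- clash_dist^2
  for (i in seq_len(nrow(xyz1))) {
    for (k in seq_len(27)) {
      key <- paste(ic1[i, 1] + off[k, 1], ic1[i, 2] + off[k, 2],
                   ic1[i, 3] + off[k, 3], sep = ",")
      js <- buckets[[key]]
      if (is.null(js)) next
      dd <- (xyz2[js, 1] - xyz1[i, 1])^2 + (xyz2[js, 2] - xyz1[i, 2])^2 +
            (xyz2[js, 3] - xyz1[i, 3])^2
      if (any(dd < c2)) return(FALSE)
    }
  }
  TRUE
}

# join fragment b onto the tail of fragment a; b's head overlap atoms are
# dropped after superposition (they coincide with a's tail overlap)
join_fragments <- function(a, b, gates) {
  tr <- superpose_and_gate(a$xyz[a$tail_idx, , drop = FALSE],
                           b$xyz[b$head_idx, , drop = FALSE], gates)
  if (!tr$pass) return(NULL)
  bxyz <- apply_transform(b$xyz, tr)
  keep_b <- setdiff(seq_len(nrow(b$xyz)), b$head_idx)
  # clashes between the existing chain and the new atoms, excluding the
  # chain's own tail overlap (bonded junction region)
  if (!clash_test(a$xyz, bxyz[keep_b, , drop = FALSE], gates$clash_dist,
                  excl1 = a$tail_idx))
    return(NULL)
  new_tail <- nrow(a$xyz) + match(b$tail_idx, keep_b)
  ref <- if (!is.null(b$ref_idx)) nrow(a$xyz) + match(b$ref_idx, keep_b)
         else a$ref_idx
  cg_fragment(rbind(a$xyz, bxyz[keep_b, , drop = FALSE]),
              head_idx = a$head_idx, tail_idx = new_tail,
              labels = c(a$labels, b$labels[keep_b]),
              ref_idx = ref)
}

draw_pair_joined <- function(lib_a, lib_b, gates, retry_cap) {
  for (i in seq_len(retry_cap)) {
    a <- lib_a[[sample.int(length(lib_a), 1)]]
    b <- lib_b[[sample.int(length(lib_b), 1)]]
    j <- join_fragments(a, b, gates)
    if (!is.null(j)) return(list(joined = j, tries = i))
  }
  NULL
}

#' Attach a dye fragment to one end of a chain
#'
#' Superposes the dye's attachment overlap (its head set) onto the
#' chain's head or tail overlap under the RMSD gate, clash-tests the
#' placed dye atoms against the chain, and returns the transformed dye
#' coordinates with the fluorophore reference position.
#'
#' @param chain,dye [cg_fragment]s; the dye must carry `ref_idx`.
#' @param end "head" or "tail".
#' @param gates an [assembly_gates] list.
#' @return list with `xyz` (placed dye atoms) and `ref` (fluorophore
#'   position, Angstrom), or NULL if either gate fails.
#' @export
attach_dye <- function(chain, dye, end = c("tail", "head"),
                       gates = assembly_gates()) {
  end <- match.arg(end)
  ov <- if (end == "head") chain$head_idx else chain$tail_idx
  tr <- superpose_and_gate(chain$xyz[ov, , drop = FALSE],
                           dye$xyz[dye$head_idx, , drop = FALSE], gates)
  if (!tr$pass) return(NULL)
  dxyz <- apply_transform(dye$xyz, tr)
  keep <- setdiff(seq_len(nrow(dye$xyz)), dye$head_idx)
  if (length(keep) &&
      !clash_test(chain$xyz, dxyz[keep, , drop = FALSE], gates$clash_dist,
                  excl1 = ov))
    return(NULL)
  list(xyz = dxyz, ref = dxyz[dye$ref_idx, ])
}

draw_dye_attached <- function(chain, dyes, end, gates, retry_cap) {
  for (i in seq_len(retry_cap)) {
    d <- dyes[[sample.int(length(dyes), 1)]]
    at <- attach_dye(chain, d, end, gates)
    if (!is.null(at)) return(at)
  }
  NULL
}

#' Hierarchical chain growth from a fragment library
#'
#' Assembles full-length chains by repeatedly pairing randomly drawn
#' fragments: rigid superposition of the tail overlap of one piece onto
#' the head overlap of the next, gated by the superposition RMSD, then a
#' clash filter on the merged coordinates. In `"doubling"` mode pieces
#' are combined hierarchically (fragments to half-chains to chains,
#' requiring a power-of-two fragment count); `"sequential"` mode extends
#' one fragment at a time. Optional dye fragments are attached at both
#' ends under the same gates, and the returned end-to-end distances are
#' then dye-to-dye.
#'
#' @param library list of [cg_fragment]s.
#' @param n_fragments fragments per chain (power of 2 for doubling).
#' @param n_chains ensemble size.
#' @param gates an [assembly_gates] list.
#' @param seed RNG seed.
#' @param mode assembly order, "doubling" or "sequential".
#' @param dye_head,dye_tail optional lists of dye [cg_fragment]s for the
#'   two ends.
#' @param retry_cap random-pairing retries per junction before giving up.
#' @return list with `assemblies` (list of `cg_fragment` chains),
#'   `distances_nm` (end-to-end or dye-to-dye distances, nm),
#'   `acceptance_rate` (junctions accepted / pairs tried).
#' @export
grow_chain <- function(library, n_fragments, n_chains = 100,
                       gates = assembly_gates(), seed = NULL,
                       mode = c("doubling", "sequential"),
                       dye_head = NULL, dye_tail = NULL,
                       retry_cap = 1e4) {
  mode <- match.arg(mode)
  if (!length(library)) stop("empty fragment library", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "doubling" &&
      abs(log2(n_fragments) - round(log2(n_fragments))) > 1e-9)
    stop("doubling mode needs a power-of-two fragment count",
         call. = FALSE)
  tries_total <- 0; joins_total <- 0
  # hierarchical doubling: fragments -> 2-mers -> half-chains -> chains;
  # every conformer is assembled from an independent recursion tree so
  # ensemble members are statistically independent draws
  build_tree <- function(level) {
    if (level == 0L) return(library[[sample.int(length(library), 1)]])
    a <- build_tree(level - 1L)
    for (i in seq_len(retry_cap)) {
      b <- build_tree(level - 1L)
      tries_total <<- tries_total + 1
      j <- join_fragments(a, b, gates)
      if (!is.null(j)) { joins_total <<- joins_total + 1; return(j) }
      if (i %% 25L == 0L) a <- build_tree(level - 1L)  # escape bad left piece
    }
    stop("fragment library incompatible with gates: junction acceptance ",
         "below floor after ", retry_cap, " retries", call. = FALSE)
  }
  build_one <- function(c_i) {
    if (mode == "doubling") {
      build_tree(round(log2(n_fragments)))
    } else {
      chain <- library[[sample.int(length(library), 1)]]
      for (step in seq_len(n_fragments - 1L)) {
        res <- draw_pair_joined(list(chain), library, gates, retry_cap)
        if (is.null(res))
          stop("fragment library incompatible with gates", call. = FALSE)
        tries_total <<- tries_total + res$tries
        joins_total <<- joins_total + 1
        chain <- res$joined
      }
      chain
    }
  }
  assemblies <- vector("list", n_chains)
  dists <- numeric(n_chains)
  for (c_i in seq_len(n_chains)) {
    ch <- build_one(c_i)
    # end-to-end reference points: first atom of each overlap set, or
    # the dye fluorophore positions when dyes are attached
    p1 <- ch$xyz[ch$head_idx[1], ]
    p2 <- ch$xyz[ch$tail_idx[1], ]
    if (!is.null(dye_head)) {
      at <- draw_dye_attached(ch, dye_head, "head", gates, retry_cap)
      if (is.null(at)) stop("dye attachment failed", call. = FALSE)
      ch$xyz <- rbind(ch$xyz, at$xyz)
      ch$labels <- c(ch$labels, paste0("DYH", seq_len(nrow(at$xyz))))
      p1 <- at$ref
    }
    if (!is.null(dye_tail)) {
      at <- draw_dye_attached(ch, dye_tail, "tail", gates, retry_cap)
      if (is.null(at)) stop("dye attachment failed", call. = FALSE)
      ch$xyz <- rbind(ch$xyz, at$xyz)
      ch$labels <- c(ch$labels, paste0("DYT", seq_len(nrow(at$xyz))))
      p2 <- at$ref
    }
    assemblies[[c_i]] <- ch
    dists[c_i] <- sqrt(sum((p1 - p2)^2)) / 10  # Angstrom -> nm
  }
  list(assemblies = assemblies, distances_nm = dists,
       acceptance_rate = joins_total / max(tries_total, 1))
}

#' Synthetic freely-jointed fragment library
#'
#' Builds a toy library whose members share identical head/tail overlap
#' triads (so every superposition is exact) but carry independent random
#' step orientations: chains grown from it are freely jointed random
#' walks whose end-to-end distance distribution approaches the Gaussian
#' chain at large length, providing the polymer-limit oracle for the
#' assembly operators.
#'
#' @param n_members library size.
#' @param step_A segment length (Angstrom).
#' @param seed RNG seed.
#' @return list of [cg_fragment]s (3-atom head and tail overlap triads).
#' @export
synthetic_fragment_library <- function(n_members = 64, step_A = 6.3,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  triad <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0))
  lapply(seq_len(n_members), function(i) {
    R <- random_rotation()
    v <- random_unit() * step_A
    tail <- sweep(triad %*% R, 2, v, "+")
    cg_fragment(rbind(triad, tail), head_idx = 1:3, tail_idx = 4:6)
  })
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

random_rotation <- function() {
  # QR of a Gaussian matrix with positive-diagonal correction
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Fragment PDB and correspondence-list I/O
#'
#' Fragments written/read as PDB via bio3d; the overlap correspondence
#' (head/tail index lists) travels as JSON.
#' @param frag a [cg_fragment]; `path`,`json_path` file paths.
#' @name chain_growth_io
#' @export
write_fragment_pdb <- function(frag, path, json_path = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("bio3d is required for PDB output", call. = FALSE)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(frag$xyz)),
                   resno = rep(1L, nrow(frag$xyz)),
                   resid = rep("FRG", nrow(frag$xyz)),
                   elety = frag$labels)
  if (!is.null(json_path))
    jsonlite::write_json(list(head_idx = frag$head_idx,
                              tail_idx = frag$tail_idx,
                              is_dye = frag$is_dye,
                              ref_idx = frag$ref_idx),
                         json_path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname chain_growth_io
#' @export
read_fragment_pdb <- function(path, json_path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("bio3d is required for PDB input", call. = FALSE)
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  cg_fragment(xyz, head_idx = meta$head_idx, tail_idx = meta$tail_idx,
              labels = pdb$atom$elety,
              is_dye = isTRUE(meta$is_dye),
              ref_idx = meta$ref_idx)
}

#' Export a grown ensemble's distances and coordinates
#'
#' Distances as CSV (one row per conformer, nm); coordinates as
#' multi-model XYZ.
#' @param ensemble output of [grow_chain()]; `csv_path`,`xyz_path` file
#'   paths.
#' @export
write_ensemble_distances <- function(ensemble, csv_path,
                                     xyz_path = NULL) {
  utils::write.csv(data.frame(conformer = seq_along(ensemble$distances_nm),
                              r_nm = ensemble$distances_nm),
                   csv_path, row.names = FALSE)
  if (!is.null(xyz_path)) {
    con <- file(xyz_path, "w")
    on.exit(close(con))
    for (ch in ensemble$assemblies) {
      writeLines(as.character(nrow(ch$xyz)), con)
      writeLines("chain-growth assembly (Angstrom)", con)
      writeLines(sprintf("C %.3f %.3f %.3f", ch$xyz[, 1], ch$xyz[, 2],
                         ch$xyz[, 3]), con)
    }
  }
  invisible(csv_path)
}
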