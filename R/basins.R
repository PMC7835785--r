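# Basin partitioning of an ELF grid: discrete steepest ascent, attractor
# merging, synapticity classification, and aromatic-ring bond labelling.

#' Partition an ELF grid into basins
#'
#' Discrete steepest ascent over the 26-neighbour stencil assigns every
#' non-vacuum voxel to a local maximum (attractor); ties are broken by lowest
#' linear voxel index. Attractors closer than `merge_dist` with ELF values
#' differing by less than `merge_eta` are coalesced (grid noise splits
#' degenerate maxima, e.g. ring-shaped ones).
#'
#' @param grid an ELF `field_grid` from [elf_on_grid()], or any scalar
#'   `field_grid` (e.g. a synthetic test field)
#' @param merge_dist attractor merge distance, bohr
#' @param merge_eta maximum ELF difference for merging
#' @return object of class `basin_partition`: integer label array (0 =
#'   vacuum), attractor table, and grid metadata
#' @export
find_basins <- function(grid, merge_dist = 0.2, merge_eta = 1e-3) {
  stopifnot(inherits(grid, "field_grid"))
  rho <- attr(grid, "rho")
  floorv <- attr(grid, "floor")
  dims <- grid$shape
  if (is.null(rho)) {
    # synthetic field without an attached density: no vacuum
    vac <- rep(FALSE, prod(dims))
  } else {
    vac <- as.vector(rho) < floorv
  }
  lab_root <- cpp_basin_ascent(as.vector(grid$values), dims, vac, 0.0)
  roots <- sort(unique(lab_root[lab_root > 0L]))
  if (!length(roots)) stop("degenerate field: no attractors found")
  # attractor voxel coordinates and ELF values
  idx0 <- roots - 1L
  iz <- idx0 %/% (dims[1] * dims[2])
  iy <- (idx0 %% (dims[1] * dims[2])) %/% dims[1]
  ix <- idx0 %% dims[1]
  pos <- cbind(grid$origin[1] + ix * grid$spacing[1],
               grid$origin[2] + iy * grid$spacing[2],
               grid$origin[3] + iz * grid$spacing[3])
  eta <- as.vector(grid$values)[roots]
  # union-find merge of near-degenerate attractors: (a) attractors that are
  # close in space and in value (grid noise on one maximum), (b) adjacent
  # basins whose separating saddle is within merge_eta of the lower
  # attractor (ring-shaped or plateau maxima split by the grid)
  k <- length(roots)
  parent <- seq_len(k)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (k > 1) {
    if (k > 20000)
      stop("implausibly many attractors (", k, "); the field is likely noise")
    # provisional labels for the saddle scan
    map0 <- integer(max(roots)); map0[roots] <- seq_len(k)
    lab0 <- integer(length(lab_root))
    nz0 <- lab_root > 0L
    lab0[nz0] <- map0[lab_root[nz0]]
    sad <- cpp_boundary_saddle(lab0, dims, as.vector(grid$values), k)
    d2 <- as.matrix(stats::dist(pos))
    deta <- abs(outer(eta, eta, "-"))
    emin <- outer(eta, eta, pmin)
    close_pair <- d2 < merge_dist & deta < merge_eta
    shallow <- sad >= 0 & deta < merge_eta & (emin - sad) < merge_eta
    idx <- which((close_pair | shallow) & upper.tri(d2), arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      pi_ <- findp(idx[r, 1]); pj <- findp(idx[r, 2])
      if (pi_ != pj) parent[max(pi_, pj)] <- min(pi_, pj)
    }
  }
  group <- vapply(seq_len(k), findp, 1L)
  ugroups <- sort(unique(group))
  final_of_root <- match(group, ugroups)
  # merged attractor = member with highest eta
  att <- data.frame(id = seq_along(ugroups), x = 0, y = 0, z = 0, eta = 0,
                    n_merged = 0L)
  for (g in seq_along(ugroups)) {
    memb <- which(group == ugroups[g])
    best <- memb[which.max(eta[memb])]
    att$x[g] <- pos[best, 1]; att$y[g] <- pos[best, 2]; att$z[g] <- pos[best, 3]
    att$eta[g] <- eta[best]
    att$n_merged[g] <- length(memb)
  }
  map <- integer(max(roots))
  map[roots] <- final_of_root
  labels <- integer(length(lab_root))
  nz <- lab_root > 0L
  labels[nz] <- map[lab_root[nz]]
  structure(list(labels = array(labels, dims), attractors = att,
                 origin = grid$origin, spacing = grid$spacing, shape = dims,
                 nuclei = grid$nuclei, field = grid$values,
                 n_vacuum = sum(vac), records = NULL),
            class = "basin_partition")
}

#' @export
print.basin_partition <- function(x, ...) {
  cat("<basin_partition>", nrow(x$attractors), "basins on",
      paste(x$shape, collapse = " x "), "grid\n")
  if (!is.null(x$records)) {
    tb <- table(x$records$type)
    cat("  ", paste(names(tb), tb, sep = ":", collapse = "  "), "\n")
  }
  invisible(x)
}

.atom_names <- function(nuclei) {
  sym <- nuclei$symbol
  idx <- stats::ave(seq_along(sym), sym, FUN = seq_along)
  paste0(sym, idx)
}

#' Classify basin synapticity
#'
#' Basins whose attractor lies within `core_radius` of a Z > 2 nucleus are
#' cores; hydrogen never owns a core. The synaptic order of a valence basin
#' is the number of distinct atoms whose core basins share a boundary with
#' it, plus any hydrogen nucleus within `h_dist` of its attractor.
#'
#' @param partition a `basin_partition`
#' @param wf the [wavefunction] the grid was computed from (same geometry)
#' @param core_radius core assignment radius, bohr
#' @param h_dist attractor-to-H distance that counts H as a connected atom
#' @param spurious_pop populations below this (electrons) are flagged; needs
#'   `obs` or is deferred until [integrate_basins()]
#' @return the partition with a filled `records` data.frame (id, name, type,
#'   atoms, eta)
#' @export
classify_synapticity <- function(partition, wf, core_radius = 0.6,
                                 h_dist = 1.5, spurious_pop = 0.05) {
  stopifnot(inherits(partition, "basin_partition"), inherits(wf, "wavefunction"))
  .check_geometry(partition, wf)
  nuc <- wf$nuclei
  aname <- .atom_names(nuc)
  att <- partition$attractors
  K <- nrow(att)
  adj <- cpp_basin_adjacency(as.vector(partition$labels), partition$shape, K)
  # distance attractor -> nucleus
  dmat <- outer(seq_len(K), seq_len(nrow(nuc)), Vectorize(function(b, a) {
    sqrt((att$x[b] - nuc$x[a])^2 + (att$y[b] - nuc$y[a])^2 + (att$z[b] - nuc$z[a])^2)
  }))
  core_atom <- integer(K)
  for (b in seq_len(K)) {
    heavy <- which(nuc$Z > 2)
    if (length(heavy)) {
      d <- dmat[b, heavy]
      if (min(d) < core_radius) core_atom[b] <- heavy[which.min(d)]
    }
  }
  type <- character(K); name <- character(K); atoms <- vector("list", K)
  for (b in seq_len(K)) {
    if (core_atom[b] > 0) {
      type[b] <- "core"
      atoms[[b]] <- core_atom[b]
      name[b] <- paste0("C(", aname[core_atom[b]], ")")
      next
    }
    touching <- which(core_atom > 0 & adj[b, ] > 0)
    conn <- unique(core_atom[touching])
    hyd <- which(nuc$Z <= 2)
    hnear <- hyd[dmat[b, hyd] < h_dist]
    # a hydrogen nucleus lying inside the basin region is connected to it
    # (protonated basins), regardless of where the attractor sits
    hin <- hyd[vapply(hyd, function(a) {
      ixa <- pmin(pmax(round((c(nuc$x[a], nuc$y[a], nuc$z[a]) - partition$origin) /
                               partition$spacing), 0), partition$shape - 1L)
      partition$labels[ixa[1] + 1, ixa[2] + 1, ixa[3] + 1] == b
    }, TRUE)]
    conn <- sort(unique(c(conn, hnear, hin)))
    atoms[[b]] <- conn
    if (length(conn) == 0) {
      type[b] <- "unknown"
      name[b] <- sprintf("V?(%d)", b)
    } else {
      type[b] <- c("monosynaptic", "disynaptic", "polysynaptic")[min(length(conn), 3)]
      name[b] <- paste0("V(", paste(aname[conn], collapse = ","), ")")
    }
  }
  partition$records <- data.frame(id = seq_len(K), name = name, type = type,
                                  eta = att$eta)
  partition$records$atoms <- atoms
  partition$adjacency <- adj
  partition$atom_names <- aname
  partition
}

.check_geometry <- function(partition, wf, tol = 1e-6) {
  a <- as.matrix(partition$nuclei[, c("x", "y", "z")])
  b <- as.matrix(wf$nuclei[, c("x", "y", "z")])
  if (nrow(a) != nrow(b) || max(abs(a - b)) > tol)
    stop("geometry mismatch between partition and wavefunction (nuclei differ)")
  invisible(TRUE)
}

#' Label aromatic-ring bond basins b12 ... b61
#'
#' Detects the six-membered carbon ring from the connectivity of disynaptic
#' V(C,C) basins, picks the ipso carbon C1 (the ring carbon attached to the
#' substituent), and assigns the bond basins walking around the ring. For
#' benzene (no substituent) any consistent circular labelling is accepted.
#'
#' @param partition a classified `basin_partition` (see
#'   [classify_synapticity()])
#' @param substituent_attachment optional nucleus index of the substituent
#'   atom bonded to the ring; if `NULL` it is auto-detected as the unique
#'   non-ring, non-hydrogen neighbour of a ring carbon (falling back to an
#'   arbitrary C1 for benzene)
#' @return object of class `ring_labeling`: `ring_atoms` (C1..C6 nucleus
#'   indices) and `bond_basins` (named b12, b23, b34, b45, b56, b61)
#' @export
label_ring_basins <- function(partition, substituent_attachment = NULL) {
  rec <- partition$records
  if (is.null(rec)) stop("run classify_synapticity() first")
  nuc <- partition$nuclei
  carbons <- which(nuc$symbol == "C")
  # edges: disynaptic basins connecting two carbons
  edges <- list()
  for (b in seq_len(nrow(rec))) {
    at <- rec$atoms[[b]]
    if (rec$type[b] == "disynaptic" && length(at) == 2 && all(at %in% carbons))
      edges[[length(edges) + 1]] <- c(at, b)
  }
  if (!length(edges)) stop("no C-C bond basins found; cannot label a ring")
  emat <- do.call(rbind, edges)
  nbr <- function(a) {
    r <- emat[emat[, 1] == a | emat[, 2] == a, , drop = FALSE]
    setdiff(unique(c(r[, 1], r[, 2])), a)
  }
  # find a 6-cycle by DFS
  ring <- NULL
  for (start in unique(c(emat[, 1], emat[, 2]))) {
    path <- start
    found <- NULL
    dfs <- function(path) {
      if (!is.null(found)) return()
      cur <- path[length(path)]
      for (nx in nbr(cur)) {
        if (nx == start && length(path) == 6) { found <<- path; return() }
        if (!(nx %in% path) && length(path) < 6) dfs(c(path, nx))
      }
    }
    dfs(path)
    if (!is.null(found)) { ring <- found; break }
  }
  if (is.null(ring)) stop("no six-membered carbon ring detected")
  # ipso carbon
  heavy_sub <- function(a) {
    # heavy neighbour outside the ring, via any disynaptic basin
    out <- integer(0)
    for (b in seq_len(nrow(rec))) {
      at <- rec$atoms[[b]]
      if (length(at) == 2 && a %in% at) {
        o <- setdiff(at, a)
        if (length(o) && !(o %in% ring) && nuc$Z[o] > 2) out <- c(out, o)
      }
    }
    out
  }
  if (!is.null(substituent_attachment)) {
    cand <- ring[vapply(ring, function(a) {
      any(vapply(seq_len(nrow(rec)), function(b) {
        at <- rec$atoms[[b]]
        length(at) == 2 && a %in% at && substituent_attachment %in% at
      }, TRUE))
    }, TRUE)]
    if (length(cand) != 1)
      stop("substituent attachment atom does not identify a unique ipso carbon")
    c1 <- cand
  } else {
    withsub <- ring[vapply(ring, function(a) length(heavy_sub(a)) > 0, TRUE)]
    if (length(withsub) > 1)
      stop("two candidate ipso carbons; pass substituent_attachment")
    c1 <- if (length(withsub) == 1) withsub else ring[1]
  }
  # rotate ring so C1 first
  i1 <- which(ring == c1)
  ring <- c(ring[i1:length(ring)], ring[seq_len(i1 - 1)])
  basin_of <- function(a, b) {
    r <- emat[(emat[, 1] == a & emat[, 2] == b) | (emat[, 1] == b & emat[, 2] == a), ,
              drop = FALSE]
    if (nrow(r) != 1) stop("missing or duplicated ring bond basin between atoms ",
                           a, " and ", b)
    r[1, 3]
  }
  bonds <- integer(6)
  for (k in 1:6) bonds[k] <- basin_of(ring[k], ring[k %% 6 + 1])
  names(bonds) <- c("b12", "b23", "b34", "b45", "b56", "b61")
  structure(list(ring_atoms = ring, bond_basins = bonds,
                 atom_names = partition$atom_names[ring]),
            class = "ring_labeling")
}

#' @export
print.ring_labeling <- function(x, ...) {
  cat("<ring_labeling> C1..C6 =", paste(x$atom_names, collapse = " "), "\n")
  cat("  ", paste(names(x$bond_basins), x$bond_basins, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}
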