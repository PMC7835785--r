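# Per-basin populations, positive-definite kinetic energies and domain
# overlap matrices, by plain Riemann voxel sums over the partition.

#' Integrate basin observables
#'
#' For every basin: population `n = int_basin rho`, positive-definite
#' kinetic energy `T = int_basin tau`, and the domain overlap matrix
#' `S^Omega_ij = int_basin phi_i phi_j` over the occupied orbitals.
#' Closed-shell identity `n = 2 trace(S)` holds by construction.
#'
#' @param partition a `basin_partition` (classified records are carried over
#'   if present)
#' @param wf the [wavefunction] on the same geometry
#' @param spurious_pop basins below this population (electrons) are flagged
#'   in the table (column `spurious`), never merged silently
#' @param refine subdivision factor for boundary and near-core voxels
#'   (`1` = plain centre-point Riemann sums). Sub-points of inter-basin
#'   boundary voxels are assigned by trilinear-gradient ascent of the ELF;
#'   sub-points near heavy nuclei capture the steep core densities.
#' @param refine_radius radius (bohr) around Z > 2 nuclei within which
#'   voxels are subdivided even away from basin boundaries
#' @param refine_rho_min boundary voxels below this density (e/bohr^3) are
#'   not subdivided (their content is negligible)
#' @return object of class `basin_observables`: `table` (data.frame with n,
#'   T, t_per_e), `S` (nocc x nocc x K array), `total_electrons`
#' @export
integrate_basins <- function(partition, wf, spurious_pop = 0.05, refine = 3,
                             refine_radius = 1.2, refine_rho_min = 1e-5) {
  stopifnot(inherits(partition, "basin_partition"), inherits(wf, "wavefunction"))
  .check_geometry(partition, wf)
  K <- nrow(partition$attractors)
  if (refine > 1 && !is.null(partition$field)) {
    heavy <- as.matrix(partition$nuclei[partition$nuclei$Z > 2,
                                        c("x", "y", "z"), drop = FALSE])
    out <- cpp_integrate_basins_refined(
      wf$shells, wf$mo_coefficients, wf$mo_occupations,
      partition$origin, partition$spacing, partition$shape,
      as.vector(partition$labels), as.vector(partition$field), K,
      as.integer(refine), heavy, refine_radius, refine_rho_min)
  } else {
    out <- cpp_integrate_basins(wf$shells, wf$mo_coefficients,
                                wf$mo_occupations,
                                partition$origin, partition$spacing,
                                partition$shape, as.vector(partition$labels), K)
  }
  n <- as.numeric(out$n)
  TT <- as.numeric(out$T)
  tab <- data.frame(id = seq_len(K), n = n, T = TT,
                    t_per_e = ifelse(n > 0, TT / n, NA_real_),
                    spurious = n < spurious_pop)
  if (!is.null(partition$records)) {
    tab$name <- partition$records$name
    tab$type <- partition$records$type
  }
  structure(list(table = tab, S = out$S,
                 total_electrons = wf$total_electrons,
                 occ = wf$mo_occupations,
                 voxel_volume = prod(partition$spacing)),
            class = "basin_observables")
}

#' @export
print.basin_observables <- function(x, ...) {
  cat("<basin_observables>", nrow(x$table), "basins, sum n =",
      round(sum(x$table$n), 4), "of", x$total_electrons, "electrons\n")
  tb <- x$table
  cols <- intersect(c("id", "name", "type", "n", "T", "t_per_e"), names(tb))
  print(tb[cols], digits = 4)
  invisible(x)
}

#' Domain kinetic energy per electron
#'
#' @param obs a `basin_observables`
#' @param basin basin id (or name if records present)
#' @return T_Omega / n_Omega in hartree per electron
#' @export
kinetic_per_electron <- function(obs, basin) {
  stopifnot(inherits(obs, "basin_observables"))
  tab <- obs$table
  if (is.character(basin)) {
    if (is.null(tab$name)) stop("basin names unavailable; classify first")
    i <- match(basin, tab$name)
  } else i <- match(basin, tab$id)
  if (is.na(i)) stop("no such basin: ", basin)
  if (!tab$n[i] > 0) stop("basin ", basin, " has zero population; t/n undefined")
  tab$T[i] / tab$n[i]
}
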