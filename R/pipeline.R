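# End-to-end orchestration: wavefunction -> ELF grid -> basins -> ring
# descriptors, with a benzene reference for the Delta quantities.

.settings_hash <- function(settings) {
  s <- paste(names(settings), vapply(settings, function(v)
    paste(format(v, digits = 12), collapse = ","), ""), sep = "=", collapse = ";")
  # small stable hash without extra dependencies
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Analyze one molecule end to end
#'
#' Runs the full chain: ELF on a grid, basin partition, synapticity
#' classification, ring labelling, basin observables and delocalization
#' indices, and (optionally) the vicinal ring descriptors.
#'
#' @param wf a [wavefunction] or a path to a wavefunction file
#' @param n_points grid points per axis (default 150, the analysis protocol)
#' @param margin box margin in bohr
#' @param substituent_attachment optional nucleus index of the substituent
#'   atom bonded to the ring (auto-detected when `NULL`)
#' @param ring detect and label the aromatic ring
#' @return object of class `elf_analysis` with components `wf`, `grid`
#'   settings, `partition`, `obs`, `di`, `ring`, `ring_values`
#' @export
analyze_molecule <- function(wf, n_points = 150, margin = 5,
                             substituent_attachment = NULL, ring = TRUE) {
  if (is.character(wf)) wf <- read_wavefunction(wf)
  stopifnot(inherits(wf, "wavefunction"))
  grid <- elf_on_grid(wf, n_points = n_points, margin = margin)
  part <- find_basins(grid)
  part <- classify_synapticity(part, wf)
  obs <- integrate_basins(part, wf)
  di <- di_matrix(obs)
  rl <- NULL
  rv <- NULL
  if (ring) {
    rl <- label_ring_basins(part, substituent_attachment)
    b <- rl$bond_basins
    nv <- obs$table$n[match(b, obs$table$id)]
    tv <- obs$table$T[match(b, obs$table$id)]
    names(nv) <- names(tv) <- names(b)
    vd <- vicinal_di(di, rl)
    rv <- list(n = nv, t = tv, vicinal = vd)
  }
  settings <- list(n_points = n_points, margin = margin, floor = RHO_FLOOR,
                   merge_dist = 0.2, merge_eta = 1e-3)
  structure(list(wf = wf, partition = part, obs = obs, di = di,
                 ring = rl, ring_values = rv, settings = settings,
                 settings_hash = .settings_hash(settings)),
            class = "elf_analysis")
}

#' @export
print.elf_analysis <- function(x, ...) {
  cat("<elf_analysis>", nrow(x$wf$nuclei), "atoms,",
      nrow(x$partition$attractors), "basins\n")
  if (!is.null(x$ring_values)) {
    cat("  ring n_ij:", paste(names(x$ring_values$n),
                              round(x$ring_values$n, 3), collapse = " "), "\n")
    cat("  DI(a):", paste(names(x$ring_values$vicinal$DI),
                          round(x$ring_values$vicinal$DI, 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' Assemble the ring descriptor report for one substituted benzene
#'
#' Combines a molecule analysis with the benzene reference computed at the
#' same settings: symmetry-averaged populations and kinetic energies, their
#' changes versus benzene, kinetic energy per electron, vicinal DI(a) and
#' dDI(a), the inductive/mesomeric pattern label, and the predicted
#' orientation.
#'
#' @param analysis an `elf_analysis` of the substituted molecule
#' @param reference an `elf_analysis` of benzene at identical settings (pass
#'   the analysis itself for benzene-vs-self)
#' @param eps_pop pattern tolerance for populations (electrons)
#' @param eps_di sign tolerance for dDI
#' @return object of class `ring_descriptors` (a list; `as.data.frame()`
#'   gives the flat table)
#' @export
build_report <- function(analysis, reference, eps_pop = 0.01, eps_di = 0.005) {
  stopifnot(inherits(analysis, "elf_analysis"))
  if (is.null(analysis$ring_values)) stop("analysis lacks ring descriptors")
  if (!inherits(reference, "elf_analysis") || is.null(reference$ring_values))
    stop("reference must be an elf_analysis of benzene with ring descriptors")
  if (analysis$settings_hash != reference$settings_hash)
    stop("reference settings differ from analysis settings; ",
         "recompute the reference with identical grid parameters")
  n_avg <- symmetry_average(analysis$ring_values$n)
  t_avg <- symmetry_average(analysis$ring_values$t, warn_spread = 0.2)
  rn_avg <- symmetry_average(reference$ring_values$n)
  rt_avg <- symmetry_average(reference$ring_values$t, warn_spread = 0.2)
  tn <- c(q12 = t_avg$q12 / n_avg$q12, q23 = t_avg$q23 / n_avg$q23,
          q34 = t_avg$q34 / n_avg$q34)
  rtn <- c(q12 = rt_avg$q12 / rn_avg$q12, q23 = rt_avg$q23 / rn_avg$q23,
           q34 = rt_avg$q34 / rn_avg$q34)
  DI <- analysis$ring_values$vicinal$DI
  rDI <- reference$ring_values$vicinal$DI
  dDI <- DI - rDI
  pattern <- classify_pattern(n_avg$q12, n_avg$q23, n_avg$q34, eps = eps_pop)
  orientation <- predict_orientation(dDI[["o"]], dDI[["m"]], dDI[["p"]],
                                     eps = eps_di)
  structure(list(
    n = c(q12 = n_avg$q12, q23 = n_avg$q23, q34 = n_avg$q34),
    t = c(q12 = t_avg$q12, q23 = t_avg$q23, q34 = t_avg$q34),
    t_per_e = tn,
    mean_ring_population = mean(unlist(analysis$ring_values$n)),
    delta_n = c(q12 = n_avg$q12 - rn_avg$q12, q23 = n_avg$q23 - rn_avg$q23,
                q34 = n_avg$q34 - rn_avg$q34),
    delta_t_per_e = tn - rtn,
    DI = DI, delta_DI = dDI,
    pattern = pattern, orientation = orientation,
    spread_flagged = n_avg$flagged,
    settings = analysis$settings,
    settings_hash = analysis$settings_hash), class = "ring_descriptors")
}

#' @export
print.ring_descriptors <- function(x, ...) {
  cat("<ring_descriptors>\n")
  cat(sprintf("  n:      q12 %.3f  q23 %.3f  q34 %.3f  (mean ring %.3f)\n",
              x$n[1], x$n[2], x$n[3], x$mean_ring_population))
  cat(sprintf("  t/n:    q12 %.4f  q23 %.4f  q34 %.4f au\n",
              x$t_per_e[1], x$t_per_e[2], x$t_per_e[3]))
  cat(sprintf("  dn:     %+.3f %+.3f %+.3f   d(t/n): %+.4f %+.4f %+.4f\n",
              x$delta_n[1], x$delta_n[2], x$delta_n[3],
              x$delta_t_per_e[1], x$delta_t_per_e[2], x$delta_t_per_e[3]))
  cat(sprintf("  DI(i/o/m/p): %.3f %.3f %.3f %.3f   dDI: %+.3f %+.3f %+.3f %+.3f\n",
              x$DI[1], x$DI[2], x$DI[3], x$DI[4],
              x$delta_DI[1], x$delta_DI[2], x$delta_DI[3], x$delta_DI[4]))
  cat("  pattern:", x$pattern, "  orientation:", x$orientation, "\n")
  invisible(x)
}

#' @export
as.data.frame.ring_descriptors <- function(x, ...) {
  data.frame(n12 = x$n[["q12"]], n23 = x$n[["q23"]], n34 = x$n[["q34"]],
             mean_ring_population = x$mean_ring_population,
             t12_per_n12 = x$t_per_e[["q12"]],
             dn12 = x$delta_n[["q12"]],
             d_t12_n12 = x$delta_t_per_e[["q12"]],
             DI_i = x$DI[["i"]], DI_o = x$DI[["o"]],
             DI_m = x$DI[["m"]], DI_p = x$DI[["p"]],
             dDI_o = x$delta_DI[["o"]], dDI_m = x$delta_DI[["m"]],
             dDI_p = x$delta_DI[["p"]],
             pattern = x$pattern, orientation = x$orientation)
}

#' Serialize a descriptor report to JSON
#'
#' Embeds the grid settings and settings hash for reproducibility.
#' @param report a `ring_descriptors`
#' @param path output file
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "ring_descriptors"))
  obj <- unclass(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Locate a shipped example wavefunction
#'
#' Optimized closed-shell wavefunctions for benzene and monosubstituted
#' benzenes (B3LYP with VWN3 correlation, 6-31G(d), Cartesian d) ship with
#' the package as Molden files with occupied orbitals only.
#'
#' @param name molecule name, e.g. `"benzene"`; `NULL` lists available names
#' @return file path (or character vector of names)
#' @export
elfiqa_example <- function(name = NULL) {
  dir <- system.file("extdata", package = "elfiqa")
  files <- list.files(dir, pattern = "\\.molden$")
  if (is.null(name)) return(sub("\\.molden$", "", files))
  p <- file.path(dir, paste0(name, ".molden"))
  if (!file.exists(p)) stop("no shipped wavefunction named '", name, "'")
  p
}
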