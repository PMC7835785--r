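# Electron localization function: kernel, Lorentzian mapping, grids.

#' Fermi constant of the homogeneous electron gas
#' @keywords internal
CF_FERMI <- 0.3 * (3 * pi^2)^(2 / 3)

#' Default density floor (e/bohr^3) below which a point is treated as vacuum
#' @export
RHO_FLOOR <- 1e-10

#' ELF kernel chi
#'
#' Ratio of the Pauli kinetic energy density `D = tau - |grad rho|^2/(8 rho)`
#' to the homogeneous-gas value `D0 = c_F rho^(5/3)` (closed-shell,
#' total-density convention). Points with `rho` below `floor` receive
#' `chi = Inf`, which maps to ELF 0.
#'
#' @param rho density (e/bohr^3)
#' @param grad_rho gradient matrix (n x 3) or `NULL` if `gradsq` given
#' @param tau positive-definite kinetic energy density (hartree/bohr^3)
#' @param gradsq optional |grad rho|^2, used instead of `grad_rho`
#' @param floor density floor
#' @return chi values (dimensionless, >= 0)
#' @export
chi_kernel <- function(rho, grad_rho = NULL, tau, gradsq = NULL,
                       floor = RHO_FLOOR) {
  if (is.null(gradsq)) {
    grad_rho <- as.matrix(grad_rho)
    gradsq <- rowSums(grad_rho^2)
  }
  if (any(rho < -1e-12) || any(tau < -1e-12))
    stop("rho and tau must be non-negative")
  dead <- rho < floor
  rs <- pmax(rho, floor)
  D <- pmax(tau - gradsq / (8 * rs), 0)
  chi <- D / (CF_FERMI * rs^(5 / 3))
  chi[dead] <- Inf
  chi
}

#' ELF from its kernel (Lorentzian mapping)
#'
#' `eta = 1 / (1 + chi^2)`, monotone decreasing in chi, in `[0, 1]`.
#' @param chi kernel values (>= 0, possibly `Inf`)
#' @return eta in `[0, 1]`
#' @export
elf <- function(chi) {
  if (any(chi < 0, na.rm = TRUE)) stop("chi must be non-negative")
  1 / (1 + chi^2)
}

#' Regular field grid container
#'
#' @param origin 3-vector, bohr
#' @param spacing 3-vector, bohr (> 0)
#' @param values 3D array
#' @param field_name identifier (rho, tau, chi, elf, ...)
#' @param nuclei data.frame of nuclei carried for cube output / consistency
#' @return object of class `field_grid`
#' @export
field_grid <- function(origin, spacing, values, field_name, nuclei = NULL) {
  stopifnot(length(origin) == 3, length(spacing) == 3, all(spacing > 0))
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (field_name == "elf" &&
      (min(values, na.rm = TRUE) < -1e-12 || max(values, na.rm = TRUE) > 1 + 1e-12))
    stop("elf field values must lie in [0, 1]")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 shape = dim(values), values = values,
                 field_name = field_name, nuclei = nuclei),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat("<field_grid>", x$field_name, paste(x$shape, collapse = " x "),
      "\n  origin:", paste(signif(x$origin, 5), collapse = ", "),
      "\n  spacing:", paste(signif(x$spacing, 5), collapse = ", "), "bohr\n")
  invisible(x)
}

.default_box <- function(wf, margin) {
  xyz <- as.matrix(wf$nuclei[, c("x", "y", "z")])
  list(lo = apply(xyz, 2, min) - margin, hi = apply(xyz, 2, max) + margin)
}

#' Compute the ELF on a regular grid
#'
#' Evaluates rho, |grad rho|^2 and tau over a box enclosing the molecule and
#' maps them through the ELF kernel. The defaults (150 points per axis,
#' 5 bohr margin) match the analysis protocol used throughout the package.
#'
#' @param wf a [wavefunction]
#' @param n_points points per axis (scalar or length-3)
#' @param margin box margin beyond the outermost nucleus, bohr
#' @param box optional `list(lo=, hi=)` overriding the automatic box
#' @param floor density floor for the vacuum sentinel
#' @return a `field_grid` of ELF values; attributes `rho`, `tau`, `chi`
#'   carry the underlying 3D arrays for downstream basin integration
#' @export
elf_on_grid <- function(wf, n_points = 150, margin = 5, box = NULL,
                        floor = RHO_FLOOR) {
  stopifnot(inherits(wf, "wavefunction"))
  n_points <- rep(as.integer(n_points), length.out = 3)
  if (any(n_points < 2)) stop("n_points must be at least 2 per axis")
  if (is.null(box)) box <- .default_box(wf, margin)
  ext <- box$hi - box$lo
  if (any(ext <= 0)) stop("degenerate bounding box (zero extent)")
  spacing <- ext / (n_points - 1)
  fx <- cpp_grid_fields(wf$shells, wf$mo_coefficients, wf$mo_occupations,
                        box$lo, spacing, n_points)
  rho <- fx$rho
  tau <- pmax(fx$tau, 0)
  chi <- chi_kernel(rho, tau = tau, gradsq = fx$gradsq, floor = floor)
  eta <- elf(chi)
  g <- field_grid(box$lo, spacing, array(eta, n_points), "elf",
                  nuclei = wf$nuclei)
  attr(g, "rho") <- array(rho, n_points)
  attr(g, "tau") <- array(tau, n_points)
  attr(g, "chi") <- array(chi, n_points)
  attr(g, "floor") <- floor
  g
}

#' Write a field grid as a Gaussian cube file
#'
#' Standard cube layout: bohr units, voxel vectors on the diagonal, nuclei
#' block, then values with z fastest.
#'
#' @param grid a `field_grid`
#' @param path output file
#' @param comment first header line
#' @export
write_cube <- function(grid, path, comment = grid$field_name) {
  stopifnot(inherits(grid, "field_grid"))
  nuc <- grid$nuclei
  if (is.null(nuc)) nuc <- data.frame(symbol = character(0), Z = numeric(0),
                                      x = numeric(0), y = numeric(0), z = numeric(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("cube:", comment), "generated by elfiqa"), con)
  fmt <- function(i, x, y, z) sprintf("%5d%12.6f%12.6f%12.6f", i, x, y, z)
  writeLines(fmt(nrow(nuc), grid$origin[1], grid$origin[2], grid$origin[3]), con)
  writeLines(fmt(grid$shape[1], grid$spacing[1], 0, 0), con)
  writeLines(fmt(grid$shape[2], 0, grid$spacing[2], 0), con)
  writeLines(fmt(grid$shape[3], 0, 0, grid$spacing[3]), con)
  for (i in seq_len(nrow(nuc)))
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", round(nuc$Z[i]),
                       nuc$Z[i], nuc$x[i], nuc$y[i], nuc$z[i]), con)
  v <- grid$values
  for (ix in seq_len(grid$shape[1]))
    for (iy in seq_len(grid$shape[2])) {
      row <- v[ix, iy, ]
      lines <- split(row, ceiling(seq_along(row) / 6))
      writeLines(vapply(lines, function(r) paste(sprintf("%13.5E", r),
                                                 collapse = ""), ""), con)
    }
  invisible(path)
}
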