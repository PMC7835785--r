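#' @useDynLib elfiqa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

BOHR_PER_ANGSTROM <- 1 / 0.529177210903

ELEMENT_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15,
               S = 16, Cl = 17, Ar = 18, K = 19, Ca = 20, Br = 35)

.dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

# (l,0,0) primitive normalisation; folded into contraction coefficients so
# the C++ kernels evaluate plain x^i y^j z^k exp(-a r^2) times a component
# factor.
.prim_norm <- function(a, l) {
  (2 * a / pi)^0.75 * (4 * a)^(l / 2) / sqrt(.dfact(2 * l - 1))
}

.ncomp <- function(l) c(1L, 3L, 6L)[l + 1L]

#' Construct a wavefunction object
#'
#' Assembles the internal single-determinant wavefunction representation:
#' nuclei, contracted Cartesian Gaussian shells, occupied MO coefficients and
#' occupations. All positions are in bohr, energies in hartree.
#'
#' @param nuclei data.frame with columns `symbol`, `Z`, `x`, `y`, `z` (bohr).
#' @param shells list of shells, each `list(l=, center_index=, exp=, coef=)`
#'   with raw (unnormalised-primitive) contraction coefficients.
#' @param mo_coefficients numeric matrix, basis functions x occupied MOs.
#' @param mo_occupations numeric vector of occupations (2 for closed shell).
#' @param net_charge integer molecular charge.
#' @param orthonormalize if `TRUE` (default) occupied MOs whose overlap
#'   residual is small but above 1e-8 are symmetrically (Loewdin)
#'   re-orthonormalised; this cleans up coefficient files stored at reduced
#'   precision without biasing the density.
#' @return object of class `wavefunction`.
#' @export
wavefunction <- function(nuclei, shells, mo_coefficients, mo_occupations,
                         net_charge = 0L, orthonormalize = TRUE) {
  stopifnot(is.data.frame(nuclei), nrow(nuclei) >= 1)
  nsh <- length(shells)
  l <- integer(nsh); nprim <- integer(nsh); pstart <- integer(nsh)
  center <- matrix(0, nsh, 3)
  pexp <- numeric(0); pcoef <- numeric(0)
  for (s in seq_len(nsh)) {
    sh <- shells[[s]]
    if (!sh$l %in% 0:2) stop("only s, p, d shells are supported (got l=", sh$l, ")")
    if (any(sh$exp <= 0)) stop("non-positive Gaussian exponent in shell ", s)
    l[s] <- sh$l
    nprim[s] <- length(sh$exp)
    pstart[s] <- length(pexp)
    center[s, ] <- as.numeric(nuclei[sh$center_index, c("x", "y", "z")])
    pexp <- c(pexp, sh$exp)
    pcoef <- c(pcoef, sh$coef * vapply(sh$exp, .prim_norm, 0, l = sh$l))
  }
  nbf <- sum(.ncomp(l))
  C <- as.matrix(mo_coefficients)
  if (nrow(C) != nbf)
    stop("mo_coefficients has ", nrow(C), " rows; basis has ", nbf, " functions")
  if (length(mo_occupations) != ncol(C))
    stop("length(mo_occupations) must equal the number of MO columns")
  wf <- structure(list(
    nuclei = nuclei,
    shells = list(l = l, center = center, pstart = pstart, nprim = nprim,
                  pexp = pexp, pcoef = pcoef),
    shell_center_index = vapply(shells, function(s) as.integer(s$center_index), 1L),
    raw_shells = shells,
    mo_coefficients = C,
    mo_occupations = as.numeric(mo_occupations),
    total_electrons = sum(mo_occupations),
    net_charge = as.integer(net_charge),
    nbf = nbf
  ), class = "wavefunction")
  S <- cpp_overlap(wf$shells)
  M <- crossprod(C, S %*% C)
  resid <- max(abs(M - diag(ncol(C))))
  if (resid > 1e-3)
    stop("occupied MOs are far from orthonormal (residual ", signif(resid, 3),
         "); corrupt or mis-parsed coefficients?")
  if (orthonormalize && resid > 1e-8) {
    e <- eigen(M, symmetric = TRUE)
    Mi <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
    wf$mo_coefficients <- C %*% Mi
  }
  wf
}

#' @export
print.wavefunction <- function(x, ...) {
  cat("<wavefunction>", nrow(x$nuclei), "nuclei,",
      length(x$shells$l), "shells,", x$nbf, "basis functions\n")
  cat("  electrons:", x$total_electrons, " occupied MOs:",
      ncol(x$mo_coefficients), " charge:", x$net_charge, "\n")
  invisible(x)
}

#' MO orthonormality residual
#'
#' Maximum absolute deviation of the occupied-MO overlap from the identity,
#' measured with the analytic basis overlap matrix.
#' @param wf a [wavefunction] object
#' @return scalar residual
#' @export
orthonormality_residual <- function(wf) {
  S <- cpp_overlap(wf$shells)
  C <- wf$mo_coefficients
  max(abs(crossprod(C, S %*% C) - diag(ncol(C))))
}

# ---------------------------------------------------------------- parsers --

.detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("molden", "mold", "input")) return("molden")
  if (ext == "wfn") return("wfn")
  if (ext == "wfx") return("wfx")
  head <- readLines(path, n = 5, warn = FALSE)
  if (any(grepl("\\[Molden Format\\]", head, ignore.case = TRUE))) return("molden")
  if (any(grepl("<Number of Nuclei>", head))) return("wfx")
  if (any(grepl("GAUSSIAN", head)) && any(grepl("MOL ORBITALS", head))) return("wfn")
  stop("cannot determine wavefunction format of '", path, "'")
}

#' Read a wavefunction file
#'
#' Parses Molden, AIM `.wfn` or `.wfx` files into the internal representation.
#' Only closed-shell single determinants are accepted; open-shell input is
#' rejected. For Molden, Cartesian d shells are assumed (the `[5D]` tag, i.e.
#' spherical d, is rejected unless `cartesian_d = FALSE` data are absent);
#' coefficients are taken to multiply unit-normalised Cartesian components.
#'
#' @param path file path
#' @param format one of `"auto"`, `"molden"`, `"wfn"`, `"wfx"`
#' @param net_charge molecular charge (Molden files do not record it;
#'   inferred as `sum(Z) - electrons` when `NULL`)
#' @return a [wavefunction] object
#' @export
read_wavefunction <- function(path, format = c("auto", "molden", "wfn", "wfx"),
                              net_charge = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .detect_format(path)
  switch(format,
         molden = .read_molden(path, net_charge),
         wfn = .read_wfn(path, net_charge),
         wfx = .read_wfx(path, net_charge))
}

.read_molden <- function(path, net_charge) {
  ln <- readLines(path, warn = FALSE)
  secline <- grep("^\\s*\\[", ln)
  if (!length(secline)) stop("not a Molden file (no [section] headers): ", path)
  sec_of <- function(name) {
    i <- grep(paste0("^\\s*\\[", name, "\\]"), ln, ignore.case = TRUE)
    if (!length(i)) return(NULL)
    j <- secline[secline > i[1]]
    ln[(i[1] + 1):(if (length(j)) j[1] - 1 else length(ln))]
  }
  if (any(grepl("^\\s*\\[5D", ln, ignore.case = TRUE)))
    stop("spherical-harmonic d shells ([5D]) are not supported; ",
         "re-export with Cartesian (6d) functions")
  hdr <- grep("^\\s*\\[Atoms\\]", ln, ignore.case = TRUE, value = TRUE)
  if (!length(hdr)) stop("Molden file lacks an [Atoms] section: ", path)
  to_bohr <- if (grepl("Angs", hdr[1], ignore.case = TRUE)) BOHR_PER_ANGSTROM else 1
  at <- sec_of("Atoms")
  at <- at[nzchar(trimws(at))]
  parts <- strsplit(trimws(at), "\\s+")
  bad <- which(vapply(parts, length, 1L) < 6)
  if (length(bad)) stop("malformed [Atoms] record ", bad[1], " in ", path)
  nuclei <- data.frame(
    symbol = vapply(parts, `[[`, "", 1),
    Z = as.numeric(vapply(parts, `[[`, "", 3)),
    x = as.numeric(vapply(parts, `[[`, "", 4)) * to_bohr,
    y = as.numeric(vapply(parts, `[[`, "", 5)) * to_bohr,
    z = as.numeric(vapply(parts, `[[`, "", 6)) * to_bohr)
  if (anyNA(nuclei$Z) || anyNA(nuclei$x))
    stop("non-numeric entry in [Atoms] section of ", path)
  gto <- sec_of("GTO")
  if (is.null(gto)) stop("Molden file lacks a [GTO] section: ", path)
  shells <- list()
  i <- 1
  lmap <- c(s = 0L, p = 1L, d = 2L, f = 3L)
  while (i <= length(gto)) {
    line <- trimws(gto[i])
    if (!nzchar(line)) { i <- i + 1; next }
    hd <- strsplit(line, "\\s+")[[1]]
    atom_idx <- suppressWarnings(as.integer(hd[1]))
    if (is.na(atom_idx)) stop("malformed [GTO] atom header near: '", line, "'")
    i <- i + 1
    while (i <= length(gto) && nzchar(trimws(gto[i]))) {
      sh <- strsplit(trimws(gto[i]), "\\s+")[[1]]
      ltag <- tolower(sh[1])
      if (!ltag %in% names(lmap)) stop("unknown shell type '", sh[1], "' in [GTO]")
      lval <- lmap[[ltag]]
      if (lval > 2L) stop("f and higher shells are not supported")
      np <- as.integer(sh[2])
      ex <- numeric(np); co <- numeric(np)
      for (k in seq_len(np)) {
        i <- i + 1
        pr <- strsplit(trimws(gsub("[dD]([+-])", "e\\1", gto[i])), "\\s+")[[1]]
        ex[k] <- as.numeric(pr[1]); co[k] <- as.numeric(pr[2])
      }
      if (anyNA(ex) || anyNA(co)) stop("malformed primitive in [GTO] of ", path)
      shells[[length(shells) + 1]] <-
        list(l = lval, center_index = atom_idx, exp = ex, coef = co)
      i <- i + 1
    }
    i <- i + 1
  }
  mo <- sec_of("MO")
  if (is.null(mo)) stop("Molden file lacks an [MO] section: ", path)
  nbf <- sum(vapply(shells, function(s) .ncomp(s$l), 1L))
  occs <- numeric(0); cols <- list(); cur <- NULL; spins <- character(0)
  flush_cur <- function() {
    if (!is.null(cur)) {
      if (length(cur$c) != nbf)
        stop("MO ", length(cols) + 1, " has ", length(cur$c),
             " coefficients; basis has ", nbf)
      cols[[length(cols) + 1]] <<- cur$c
      occs <<- c(occs, cur$occ)
      spins <<- c(spins, cur$spin)
    }
  }
  for (line in mo) {
    t <- trimws(line)
    if (!nzchar(t)) next
    if (grepl("^Sym\\s*=", t, ignore.case = TRUE)) {
      flush_cur(); cur <- list(c = numeric(0), occ = NA_real_, spin = "Alpha")
    } else if (grepl("^Ene\\s*=", t, ignore.case = TRUE)) {
      if (is.null(cur)) cur <- list(c = numeric(0), occ = NA_real_, spin = "Alpha")
    } else if (grepl("^Spin\\s*=", t, ignore.case = TRUE)) {
      cur$spin <- trimws(sub(".*=", "", t))
    } else if (grepl("^Occup\\s*=", t, ignore.case = TRUE)) {
      cur$occ <- as.numeric(sub(".*=", "", t))
    } else {
      pr <- strsplit(t, "\\s+")[[1]]
      if (length(pr) >= 2 && !is.na(suppressWarnings(as.integer(pr[1]))))
        cur$c[as.integer(pr[1])] <- as.numeric(pr[2])
    }
  }
  flush_cur()
  if (any(tolower(spins) == "beta" & occs > 0))
    stop("open-shell (beta-spin) orbitals present; only closed-shell ",
         "determinants are supported")
  keep <- which(occs > 1e-8)
  if (!length(keep)) stop("no occupied orbitals found in [MO] section")
  if (any(abs(occs[keep] - 2) > 1e-6))
    stop("fractional occupations found; only closed-shell integer ",
         "occupations are supported")
  C <- do.call(cbind, cols[keep])
  nel <- sum(occs[keep])
  if (is.null(net_charge))
    net_charge <- as.integer(round(sum(nuclei$Z) - nel))
  wavefunction(nuclei, shells, C, occs[keep], net_charge = net_charge)
}

# AIM .wfn: primitive-based MO expansion; primitives are treated as
# unit-normalised Cartesian components (AIMPAC convention).
.read_wfn <- function(path, net_charge) {
  ln <- readLines(path, warn = FALSE)
  hd <- grep("MOL ORBITALS", ln, value = TRUE)
  if (!length(hd)) stop("not a .wfn file (missing header): ", path)
  nums <- as.integer(regmatches(hd[1], gregexpr("[0-9]+", hd[1]))[[1]])
  if (length(nums) < 3) stop("malformed .wfn header: ", hd[1])
  nmo <- nums[1]; nprim <- nums[2]; nat <- nums[3]
  atl <- grep("CHARGE =", ln, value = TRUE)[seq_len(nat)]
  sym <- sub("^\\s*([A-Za-z]+).*", "\\1", atl)
  xyz <- t(vapply(atl, function(s) {
    v <- as.numeric(regmatches(s, gregexpr("-?[0-9]+\\.[0-9]+", s))[[1]])
    v[1:4]  # x y z charge
  }, numeric(4)))
  grab <- function(tag) {
    sel <- grep(tag, ln, value = TRUE)
    as.numeric(unlist(regmatches(sel, gregexpr("-?[0-9]+\\.?[0-9]*([ED][+-][0-9]+)?", sel))))
  }
  cent <- as.integer(unlist(regmatches(grep("CENTRE ASSIGNMENTS", ln, value = TRUE),
                                       gregexpr("[0-9]+", grep("CENTRE ASSIGNMENTS", ln, value = TRUE)))))
  typ <- as.integer(unlist(regmatches(grep("TYPE ASSIGNMENTS", ln, value = TRUE),
                                      gregexpr("[0-9]+", grep("TYPE ASSIGNMENTS", ln, value = TRUE)))))
  expo_lines <- grep("EXPONENTS", ln)
  # exponents run until first MO line
  mo_lines <- grep("^MO", ln)
  expo_txt <- ln[expo_lines[1]:(mo_lines[1] - 1)]
  expo <- as.numeric(gsub("[dD]", "e", unlist(regmatches(expo_txt,
            gregexpr("-?[0-9]+\\.[0-9]+[dDeE][+-][0-9]+", expo_txt)))))
  if (length(cent) != nprim || length(typ) != nprim || length(expo) != nprim)
    stop("truncated .wfn: primitive tables incomplete in ", path)
  occs <- numeric(nmo)
  Cp <- matrix(0, nprim, nmo)
  end_line <- grep("END DATA", ln)
  if (!length(end_line)) stop("truncated .wfn: no END DATA in ", path)
  for (k in seq_len(nmo)) {
    st <- mo_lines[k]
    en <- if (k < nmo) mo_lines[k + 1] - 1 else end_line[1] - 1
    occs[k] <- as.numeric(sub(".*OCC NO =\\s*([-0-9.]+).*", "\\1", ln[st]))
    vals <- as.numeric(gsub("[dD]", "e",
             unlist(regmatches(ln[(st + 1):en],
               gregexpr("-?[0-9]+\\.[0-9]+[dDeE][+-][0-9]+", ln[(st + 1):en])))))
    if (length(vals) != nprim)
      stop("truncated .wfn: MO ", k, " has ", length(vals), "/", nprim,
           " coefficients")
    Cp[, k] <- vals
  }
  # map type codes to (l, component): 1 s; 2-4 px,py,pz; 5-10 xx,yy,zz,xy,xz,yz
  comp_of <- c(1L, 1L, 2L, 3L, 1L, 2L, 3L, 4L, 5L, 6L)
  l_of <- c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L)
  if (any(typ > 10)) stop("f or higher primitives in .wfn are not supported")
  nuclei <- data.frame(symbol = sym, Z = xyz[, 4],
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  # each primitive becomes a 1-primitive shell; group p/d components of the
  # same (centre, exponent, l) into one shell
  key <- paste(cent, l_of[typ], expo)
  shells <- list(); Crows <- list()
  nbf_type <- integer(0)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    l <- l_of[typ[idx[1]]]
    shells[[length(shells) + 1]] <- list(l = l, center_index = cent[idx[1]],
                                         exp = expo[idx[1]],
                                         coef = 1 / .prim_norm(expo[idx[1]], l))
    rows <- matrix(0, .ncomp(l), nmo)
    for (j in idx) rows[comp_of[typ[j]], ] <- Cp[j, ]
    Crows[[length(Crows) + 1]] <- rows
  }
  C <- do.call(rbind, Crows)
  keep <- which(occs > 1e-8)
  if (any(abs(occs[keep] - 2) > 1e-6))
    stop("only closed-shell (occupation 2) .wfn files are supported")
  if (is.null(net_charge))
    net_charge <- as.integer(round(sum(nuclei$Z) - sum(occs[keep])))
  wavefunction(nuclei, lapply(shells, identity), C[, keep, drop = FALSE],
               occs[keep], net_charge = net_charge)
}

.read_wfx <- function(path, net_charge) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  tag <- function(name) {
    m <- regmatches(txt, regexpr(paste0("<", name, ">[\\s\\S]*?</", name, ">"),
                                 txt, perl = TRUE))
    if (!length(m)) stop("missing <", name, "> section in ", path)
    inner <- sub(paste0("^<", name, ">"), "", sub(paste0("</", name, ">$"), "", m))
    trimws(inner)
  }
  num <- function(name) as.numeric(strsplit(tag(name), "\\s+")[[1]])
  nat <- as.integer(tag("Number of Nuclei"))
  nprim <- as.integer(tag("Number of Primitives"))
  nmo <- as.integer(tag("Number of Occupied Molecular Orbitals"))
  sym <- strsplit(tag("Nuclear Names"), "\\s+")[[1]]
  sym <- gsub("[0-9]+$", "", sym)
  Zs <- num("Atomic Numbers")
  xyz <- matrix(num("Nuclear Cartesian Coordinates"), ncol = 3, byrow = TRUE)
  cent <- as.integer(strsplit(tag("Primitive Centers"), "\\s+")[[1]])
  typ <- as.integer(strsplit(tag("Primitive Types"), "\\s+")[[1]])
  expo <- num("Primitive Exponents")
  occs <- num("Molecular Orbital Occupation Numbers")
  mo_txt <- tag("Molecular Orbital Primitive Coefficients")
  mo_txt <- gsub("<MO Number>\\s*[0-9]+\\s*</MO Number>", "", mo_txt)
  vals <- as.numeric(strsplit(trimws(mo_txt), "\\s+")[[1]])
  if (length(vals) != nprim * nmo)
    stop("truncated .wfx: expected ", nprim * nmo, " MO coefficients, got ",
         length(vals))
  Cp <- matrix(vals, nprim, nmo)
  ln_fake <- NULL
  comp_of <- c(1L, 1L, 2L, 3L, 1L, 2L, 3L, 4L, 5L, 6L)
  l_of <- c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L)
  if (any(typ > 10)) stop("f or higher primitives in .wfx are not supported")
  nuclei <- data.frame(symbol = sym, Z = Zs, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  key <- paste(cent, l_of[typ], expo)
  shells <- list(); Crows <- list()
  for (kk in unique(key)) {
    idx <- which(key == kk)
    l <- l_of[typ[idx[1]]]
    shells[[length(shells) + 1]] <- list(l = l, center_index = cent[idx[1]],
                                         exp = expo[idx[1]],
                                         coef = 1 / .prim_norm(expo[idx[1]], l))
    rows <- matrix(0, .ncomp(l), nmo)
    for (j in idx) rows[comp_of[typ[j]], ] <- Cp[j, ]
    Crows[[length(Crows) + 1]] <- rows
  }
  C <- do.call(rbind, Crows)
  keep <- which(occs > 1e-8)
  if (any(abs(occs[keep] - 2) > 1e-6))
    stop("only closed-shell (occupation 2) .wfx files are supported")
  if (is.null(net_charge)) {
    nc <- tryCatch(as.integer(round(as.numeric(tag("Net Charge")))),
                   error = function(e) NA_integer_)
    net_charge <- if (is.na(nc)) as.integer(round(sum(Zs) - sum(occs[keep]))) else nc
  }
  wavefunction(nuclei, shells, C[, keep, drop = FALSE], occs[keep],
               net_charge = net_charge)
}

# ------------------------------------------------------------------- toys --

#' Analytic toy wavefunctions
#'
#' Small closed-shell model systems with closed-form properties, used for
#' oracle tests. `one_orbital_bond` is a single doubly-occupied sigma-type MO
#' built from two s Gaussians: its ELF is identically 1 wherever the density
#' is above the floor. `two_orbital_model` occupies the symmetric and
#' antisymmetric combinations (4 electrons). `atomlike` superimposes a tight
#' core and a diffuse valence s MO on one centre, giving a core + shell ELF
#' topology.
#'
#' @param kind one of `"one_orbital_bond"`, `"two_orbital_model"`, `"atomlike"`
#' @param distance centre separation in bohr (bond-type toys)
#' @param alpha s-Gaussian exponent (bohr^-2), must be positive
#' @param alpha_core,alpha_valence exponents for `atomlike`
#' @return a [wavefunction] object
#' @export
make_toy_wavefunction <- function(kind = c("one_orbital_bond", "two_orbital_model",
                                           "atomlike"),
                                  distance = 1.4, alpha = 1.0,
                                  alpha_core = 8.0, alpha_valence = 0.35) {
  kind <- match.arg(kind)
  if (alpha <= 0 || alpha_core <= 0 || alpha_valence <= 0)
    stop("Gaussian exponents must be positive")
  if (kind %in% c("one_orbital_bond", "two_orbital_model")) {
    nuclei <- data.frame(symbol = c("H", "H"), Z = c(1, 1),
                         x = 0, y = 0, z = c(-distance / 2, distance / 2))
    shells <- list(list(l = 0L, center_index = 1L, exp = alpha, coef = 1),
                   list(l = 0L, center_index = 2L, exp = alpha, coef = 1))
    # overlap of two unit s Gaussians
    s12 <- exp(-alpha * distance^2 / 2)
    if (kind == "one_orbital_bond") {
      C <- matrix(1 / sqrt(2 * (1 + s12)), 2, 1)
      return(wavefunction(nuclei, shells, C, 2, net_charge = 0L))
    }
    Cp <- c(1, 1) / sqrt(2 * (1 + s12))
    Cm <- c(1, -1) / sqrt(2 * (1 - s12))
    return(wavefunction(nuclei, shells, cbind(Cp, Cm), c(2, 2),
                        net_charge = -2L))
  }
  # atomlike: He-like core + diffuse valence shell on one centre
  nuclei <- data.frame(symbol = "Be", Z = 4, x = 0, y = 0, z = 0)
  shells <- list(list(l = 0L, center_index = 1L, exp = alpha_core, coef = 1),
                 list(l = 0L, center_index = 1L, exp = alpha_valence, coef = 1))
  s12 <- (2 * sqrt(alpha_core * alpha_valence) / (alpha_core + alpha_valence))^1.5
  # symmetric orthonormalisation of the two s functions
  Sm <- matrix(c(1, s12, s12, 1), 2)
  e <- eigen(Sm, symmetric = TRUE)
  X <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  wavefunction(nuclei, shells, X, c(2, 2), net_charge = 0L)
}

#' Evaluate density, gradient, kinetic-energy density and MOs at points
#'
#' Computes the electron density rho, its gradient, the positive-definite
#' kinetic energy density tau = 1/2 sum_i n_i |grad phi_i|^2 and (optionally)
#' per-orbital amplitudes at arbitrary points.
#'
#' @param wf a [wavefunction]
#' @param points numeric matrix (n x 3), bohr
#' @param want_mo also return per-orbital amplitudes
#' @return list with `rho`, `grad_rho` (n x 3), `tau`, and optionally
#'   `mo_values` (n x nocc)
#' @export
evaluate_fields <- function(wf, points, want_mo = FALSE) {
  stopifnot(inherits(wf, "wavefunction"))
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an n x 3 matrix")
  if (!all(is.finite(points))) stop("points must be finite")
  out <- cpp_eval_fields(wf$shells, wf$mo_coefficients, wf$mo_occupations,
                         points, want_mo)
  out$rho <- as.numeric(out$rho)
  out$tau <- pmax(as.numeric(out$tau), 0)
  out
}
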