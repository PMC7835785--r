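# Delocalization indices from domain overlap matrices, vicinal DI(a)
# descriptors, and a brute-force pair-density covariance oracle.

#' Delocalization index matrix
#'
#' For a closed-shell single determinant, the delocalization index between
#' domains A and B is `delta(A,B) = 4 sum_ij S^A_ij S^B_ij` and the
#' localization index `lambda(A) = 2 sum_ij (S^A_ij)^2`; these satisfy
#' `lambda(A) + 1/2 sum_B delta(A,B) = n_A`. delta equals `-2 cov(n_A, n_B)`,
#' the (negative, doubled) covariance of the domain electron counts.
#'
#' @param obs a `basin_observables`
#' @return object of class `di_matrix`: `delta` (K x K symmetric, zero
#'   diagonal), `lambda` (length K), basin `table`
#' @export
di_matrix <- function(obs) {
  stopifnot(inherits(obs, "basin_observables"))
  S <- obs$S
  K <- dim(S)[3]
  Sm <- matrix(S, ncol = K)          # (nocc*nocc) x K
  cross <- crossprod(Sm)             # sum_ij S^A_ij S^B_ij
  delta <- 4 * cross
  lambda <- 2 * diag(cross)
  diag(delta) <- 0
  rn <- if (!is.null(obs$table$name)) obs$table$name else as.character(obs$table$id)
  dimnames(delta) <- list(rn, rn)
  names(lambda) <- rn
  structure(list(delta = delta, lambda = lambda, table = obs$table),
            class = "di_matrix")
}

#' @export
print.di_matrix <- function(x, ...) {
  cat("<di_matrix>", nrow(x$delta), "basins; sum-rule residual max |lambda ",
      "+ sum delta/2 - n| =",
      signif(max(abs(x$lambda + rowSums(x$delta) / 2 - x$table$n)), 3), "\n")
  invisible(x)
}

#' Vicinal delocalization indices DI(i), DI(o), DI(m), DI(p)
#'
#' Delocalization indices between adjacent ring bond basins, labelled by the
#' shared carbon: ipso (C1), ortho, meta, para. The two symmetry-equivalent
#' branches are averaged; both raw values are returned.
#'
#' @param di a `di_matrix`
#' @param ring a `ring_labeling`
#' @return list with `DI` (named i/o/m/p), `raw` branch values, and `spread`
#' @export
vicinal_di <- function(di, ring) {
  stopifnot(inherits(di, "di_matrix"), inherits(ring, "ring_labeling"))
  b <- ring$bond_basins
  if (anyNA(match(b, di$table$id))) stop("ring basin missing from DI matrix")
  d <- function(p, q) di$delta[b[[p]], b[[q]]]
  raw <- list(i = d("b61", "b12"),
              o = c(d("b12", "b23"), d("b56", "b61")),
              m = c(d("b23", "b34"), d("b45", "b56")),
              p = d("b34", "b45"))
  DI <- vapply(raw, mean, 0)
  spread <- vapply(raw, function(v) diff(range(v)), 0)
  list(DI = DI, raw = raw, spread = spread)
}

#' Brute-force covariance oracle for delocalization indices
#'
#' Computes `-2 cov(n_A, n_B)` directly from the single-determinant pair
#' density on the grid: `cov = int_A int_B [rho2(1,2) - rho(1) rho(2)]` for
#' A != B (plus `n_A` when A = B), with
#' `rho2(1,2) = rho(1) rho(2) - |rho1(1,2)|^2 / 2` and the one-matrix
#' `rho1(1,2) = 2 sum_i phi_i(1) phi_i(2)` evaluated explicitly on voxel
#' pairs. Quadratic in grid size: refuses systems with more than
#' `max_mo` occupied orbitals.
#'
#' @param partition a `basin_partition`
#' @param wf the [wavefunction]
#' @param basinA,basinB basin ids
#' @param max_mo refuse larger systems (oracle is a test fixture)
#' @return `-2 cov(n_A, n_B)`
#' @export
covariance_oracle <- function(partition, wf, basinA, basinB, max_mo = 2) {
  stopifnot(inherits(partition, "basin_partition"), inherits(wf, "wavefunction"))
  if (ncol(wf$mo_coefficients) > max_mo)
    stop("covariance oracle is restricted to toy systems (<= ", max_mo,
         " occupied MOs)")
  dims <- partition$shape
  lab <- as.vector(partition$labels)
  voxels_of <- function(b) which(lab == b)
  vA <- voxels_of(basinA); vB <- voxels_of(basinB)
  if (!length(vA) || !length(vB)) stop("empty basin")
  coords <- function(v) {
    i0 <- v - 1L
    iz <- i0 %/% (dims[1] * dims[2])
    iy <- (i0 %% (dims[1] * dims[2])) %/% dims[1]
    ix <- i0 %% dims[1]
    cbind(partition$origin[1] + ix * partition$spacing[1],
          partition$origin[2] + iy * partition$spacing[2],
          partition$origin[3] + iz * partition$spacing[3])
  }
  dV <- prod(partition$spacing)
  fA <- evaluate_fields(wf, coords(vA), want_mo = TRUE)
  fB <- if (basinA == basinB) fA else evaluate_fields(wf, coords(vB), want_mo = TRUE)
  nA <- sum(fA$rho) * dV
  nB <- sum(fB$rho) * dV
  # int_A int_B |rho1|^2/2 via explicit one-matrix blocks (chunked)
  MA <- fA$mo_values * sqrt(2)   # (MA MB^T) = 2 sum_i phi_i(1) phi_i(2) = rho1
  MB <- fB$mo_values * sqrt(2)
  acc <- 0
  chunk <- 4000L
  for (s in seq(1, nrow(MA), by = chunk)) {
    e <- min(nrow(MA), s + chunk - 1L)
    block <- MA[s:e, , drop = FALSE] %*% t(MB)
    acc <- acc + sum(block^2)
  }
  exch <- 0.5 * acc * dV * dV      # int int |rho1|^2 / 2
  pair_int <- nA * nB - exch
  covAB <- pair_int - nA * nB + (if (basinA == basinB) nA else 0)
  -2 * covAB
}
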