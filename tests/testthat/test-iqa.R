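# Inter-basin IQA terms at coarse quadrature: limits, identities, oracles.

test_that("well-separated charge distributions obey the 1/R limit", {
  R <- 14
  nuclei <- data.frame(symbol = c("H", "H"), Z = c(1, 1), x = 0, y = 0,
                       z = c(-R / 2, R / 2))
  shells <- list(list(l = 0L, center_index = 1L, exp = 1, coef = 1),
                 list(l = 0L, center_index = 2L, exp = 1, coef = 1))
  wf <- wavefunction(nuclei, shells, diag(2), c(2, 2), net_charge = -2L)
  g <- elf_on_grid(wf, n_points = 80, margin = 6)
  part <- find_basins(g)
  ids <- part$attractors$id[order(part$attractors$z)]
  cc <- coulomb_pair(part, wf, ids[1], ids[2], resolution = 20)
  # spherical non-overlapping 2e clouds: Velec = 4/R exactly (shell theorem)
  expect_equal(cc$Velec, 4 / R, tolerance = 0.01)
  # with the embedded protons, the fragments are net -1 each
  expect_equal(cc$Vcoul, 1 / R, tolerance = 0.02)
  # zero MO overlap: exchange vanishes
  ex <- exchange_pair(part, wf, ids[1], ids[2], resolution = 20)
  expect_equal(ex$Vx, 0, tolerance = 1e-10)
})

test_that("intra-basin repulsion approaches the Gaussian self-energy", {
  a <- 1.0
  nuc <- data.frame(symbol = "H", Z = 1, x = 0, y = 0, z = 0)
  sh <- list(list(l = 0L, center_index = 1L, exp = a, coef = 1))
  wf <- wavefunction(nuc, sh, matrix(1, 1, 1), 2, net_charge = -1L)
  g <- elf_on_grid(wf, n_points = 80, margin = 6)
  part <- find_basins(g)
  cc <- coulomb_pair(part, wf, 1, 1, resolution = 24)
  exact <- 4 * sqrt(a / pi)   # (1/2) int int rho rho / r12 for 2e Gaussian
  # coarse cells with self-term exclusion: a few percent low
  expect_equal(cc$Velec, exact, tolerance = 0.05)
})

test_that("exchange matches the brute-force 6D voxel sum at equal resolution", {
  wf <- make_toy_wavefunction("one_orbital_bond", distance = 1.4, alpha = 1.0)
  g <- elf_on_grid(wf, n_points = 40, margin = 4.5)
  part <- midplane_partition(find_basins(g))
  ex <- exchange_pair(part, wf, 1, 2, resolution = 40)  # voxel-level cells
  # independent O(N^2) voxel-pair sum
  dims <- part$shape
  vox <- function(b) which(as.vector(part$labels) == b)
  coords <- function(v) {
    i0 <- v - 1L
    iz <- i0 %/% (dims[1] * dims[2])
    iy <- (i0 %% (dims[1] * dims[2])) %/% dims[1]
    ix <- i0 %% dims[1]
    cbind(part$origin[1] + ix * part$spacing[1],
          part$origin[2] + iy * part$spacing[2],
          part$origin[3] + iz * part$spacing[3])
  }
  vA <- vox(1); vB <- vox(2)
  dV <- prod(part$spacing)
  fA <- evaluate_fields(wf, coords(vA), want_mo = TRUE)
  fB <- evaluate_fields(wf, coords(vB), want_mo = TRUE)
  pA <- fA$mo_values[, 1]^2 * dV
  pB <- fB$mo_values[, 1]^2 * dV
  xyzA <- coords(vA); xyzB <- coords(vB)
  acc <- 0
  for (s in seq(1, length(vA), by = 2000)) {
    e <- min(length(vA), s + 1999)
    d <- sqrt(outer(xyzA[s:e, 1], xyzB[, 1], "-")^2 +
              outer(xyzA[s:e, 2], xyzB[, 2], "-")^2 +
              outer(xyzA[s:e, 3], xyzB[, 3], "-")^2)
    acc <- acc + sum(outer(pA[s:e], pB) / d)
  }
  expect_equal(ex$Vx, -2 * acc, tolerance = 1e-10)
  expect_lt(ex$Vx, 0)
})

test_that("exchange is negative and decays with separation", {
  vals <- vapply(c(1.4, 2.4, 3.6), function(d) {
    wf <- make_toy_wavefunction("one_orbital_bond", distance = d, alpha = 1.0)
    g <- elf_on_grid(wf, n_points = 36, margin = 4)
    part <- midplane_partition(find_basins(g))
    exchange_pair(part, wf, 1, 2, resolution = 18)$Vx
  }, 0)
  expect_true(all(vals < 0))
  expect_true(all(diff(abs(vals)) < 0))
})

test_that("assemble_iqa honours the structural identities", {
  wf <- make_toy_wavefunction("two_orbital_model", distance = 1.6)
  g <- elf_on_grid(wf, n_points = 40, margin = 4.5)
  part <- midplane_partition(find_basins(g))
  obs <- integrate_basins(part, wf)
  iq <- assemble_iqa(part, wf, rbind(c(1, 2)), obs = obs, resolution = 20)
  pt <- iq$pair_table
  # inter: E = Vcoul + Vx by construction; Vcoul = Ven+Vne+Vnn+Velec
  expect_equal(pt$E_inter, pt$Vcoul + pt$Vx, tolerance = 1e-12)
  expect_equal(pt$Vcoul, pt$Velec + pt$Ven + pt$Vne + pt$Vnn, tolerance = 1e-12)
  # intra: E = T + Vcoul + Vx
  it <- iq$intra_table
  expect_equal(it$E_intra, it$T + it$Vcoul + it$Vx, tolerance = 1e-12)
  # these basins contain the protons: nuclear terms present
  expect_true(all(pt$Ven != 0) && all(pt$Vne != 0) && all(pt$Vnn != 0))
  expect_error(assemble_iqa(part, wf, rbind(c(1, 1))), "distinct")
})

test_that("bond-bond pairs carry electron-electron terms only", {
  # nucleus-free basins: fragments of a 2-orbital toy with protons relocated
  # to dedicated core-like basins is overkill; instead verify directly that
  # a basin owning no nucleus contributes no Ven/Vnn
  wf <- make_toy_wavefunction("one_orbital_bond", distance = 1.4)
  g <- elf_on_grid(wf, n_points = 40, margin = 4.5)
  part <- find_basins(g)   # single basin containing both protons
  # split into 3 slabs: the central slab holds no nucleus
  dims <- part$shape
  zc <- part$origin[3] + (slice.index(part$labels, 3) - 1) * part$spacing[3]
  labs <- ifelse(part$labels == 0L, 0L,
                 ifelse(zc < -0.5, 1L, ifelse(zc > 0.5, 3L, 2L)))
  part$labels <- array(labs, dims)
  part$attractors <- data.frame(id = 1:3, x = 0, y = 0, z = c(-2, 0, 2),
                                eta = 1, n_merged = 1L)
  cc <- coulomb_pair(part, wf, 2, 2, resolution = 20)
  expect_identical(cc$Ven, 0)   # central slab owns no nucleus
  cc13 <- coulomb_pair(part, wf, 1, 3, resolution = 20)
  expect_true(cc13$Vnn != 0)    # outer slabs own one proton each
})

test_that("sum of all IQA terms reproduces the total interaction energy", {
  # 2 electrons in one orbital: V_ee = J_11 exactly. The IQA term set
  # (intra Velec + Vx of both halves, plus the inter pair) must assemble to
  # it within the coarse-quadrature tolerance.
  wf <- make_toy_wavefunction("one_orbital_bond", distance = 1.4, alpha = 1.0)
  g <- elf_on_grid(wf, n_points = 44, margin = 5)
  part <- midplane_partition(find_basins(g))
  iq <- assemble_iqa(part, wf, rbind(c(1, 2)), resolution = 24)
  ee_iqa <- sum(iq$intra_table$Vcoul - ifelse(is.na(iq$intra_table$Vcoul), 0, 0)) -
    sum(iq$intra_table$T) * 0 + sum(iq$intra_table$Vx) +
    iq$pair_table$Velec[1] + iq$pair_table$Vx[1]
  # subtract the intra nuclear-attraction parts folded into intra Vcoul
  ven1 <- coulomb_pair(part, wf, 1, 1, resolution = 24)$Ven
  ven2 <- coulomb_pair(part, wf, 2, 2, resolution = 24)$Ven
  ee_iqa <- ee_iqa - ven1 - ven2
  # independent voxel-pair reference for J_11
  dims <- part$shape
  v <- which(as.vector(part$labels) > 0)
  i0 <- v - 1L
  iz <- i0 %/% (dims[1] * dims[2])
  iy <- (i0 %% (dims[1] * dims[2])) %/% dims[1]
  ix <- i0 %% dims[1]
  xyz <- cbind(part$origin[1] + ix * part$spacing[1],
               part$origin[2] + iy * part$spacing[2],
               part$origin[3] + iz * part$spacing[3])
  dV <- prod(part$spacing)
  f <- evaluate_fields(wf, xyz, want_mo = TRUE)
  phi2 <- f$mo_values[, 1]^2 * dV   # one-electron density elements
  Jacc <- 0
  for (s in seq(1, length(v), by = 2000)) {
    e <- min(length(v), s + 1999)
    d <- sqrt(outer(xyz[s:e, 1], xyz[, 1], "-")^2 +
              outer(xyz[s:e, 2], xyz[, 2], "-")^2 +
              outer(xyz[s:e, 3], xyz[, 3], "-")^2)
    d[d < 1e-12] <- Inf
    Jacc <- Jacc + sum(outer(phi2[s:e], phi2) / d)
  }
  J11 <- Jacc   # ordered-pair sum approximates int int phi^2 phi^2 / r12
  expect_equal(ee_iqa, J11, tolerance = 0.05)
})
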