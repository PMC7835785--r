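# Basin integrals: populations, kinetic energies, overlap matrices,
# conservation sums.

test_that("whole-space basin recovers normalization and kinetic energy", {
  a <- 1.0
  nuc <- data.frame(symbol = "H", Z = 1, x = 0, y = 0, z = 0)
  sh <- list(list(l = 0L, center_index = 1L, exp = a, coef = 1))
  wf <- wavefunction(nuc, sh, matrix(1, 1, 1), 2, net_charge = -1L)
  g <- elf_on_grid(wf, n_points = 70, margin = 6)
  part <- find_basins(g)
  expect_equal(nrow(part$attractors), 1)
  obs <- integrate_basins(part, wf)
  expect_equal(obs$table$n, 2, tolerance = 5e-3)
  expect_equal(obs$table$T, 3 * a, tolerance = 1e-2)
  # n = 2 trace(S) for closed shells
  expect_equal(obs$table$n, 2 * obs$S[1, 1, 1], tolerance = 1e-10)
})

test_that("midplane split of the symmetric bond gives 1.000 e per half", {
  wf <- make_toy_wavefunction("one_orbital_bond", distance = 1.4, alpha = 1.0)
  g <- elf_on_grid(wf, n_points = 60, margin = 5)  # even grid: no tie plane
  part <- midplane_partition(find_basins(g))
  obs <- integrate_basins(part, wf, refine = 1)
  expect_equal(obs$table$n, c(1, 1), tolerance = 1e-3)
  expect_equal(obs$table$T[1], obs$table$T[2], tolerance = 1e-10)
})

test_that("conservation suite holds on the toys", {
  for (kind in c("two_orbital_model", "atomlike")) {
    wf <- make_toy_wavefunction(kind)
    g <- elf_on_grid(wf, n_points = 70, margin = 6)
    part <- find_basins(g)
    obs <- integrate_basins(part, wf, refine = 1)
    # sum n = N
    expect_equal(sum(obs$table$n), wf$total_electrons, tolerance = 0.05)
    # sum T = total positive-definite kinetic energy (same quadrature)
    Ttot <- sum(attr(g, "tau")) * prod(g$spacing)
    expect_equal(sum(obs$table$T), Ttot, tolerance = 1e-6)
    expect_true(all(obs$table$T >= 0))
    # sum of overlap matrices = identity
    Ssum <- apply(obs$S, c(1, 2), sum)
    expect_lt(max(abs(Ssum - diag(nrow(Ssum)))), 5e-3)
  }
})

test_that("kinetic per electron accessor and error contracts", {
  wf <- make_toy_wavefunction("one_orbital_bond")
  g <- elf_on_grid(wf, n_points = 40, margin = 4)
  part <- midplane_partition(find_basins(g))
  obs <- integrate_basins(part, wf)
  expect_equal(kinetic_per_electron(obs, 1), obs$table$T[1] / obs$table$n[1])
  expect_error(kinetic_per_electron(obs, 99), "no such basin")
  # zero-population basin triggers the undefined-ratio error
  obs2 <- obs
  obs2$table$n[1] <- 0
  expect_error(kinetic_per_electron(obs2, 1), "zero population")
})

test_that("geometry mismatch between partition and wavefunction errors", {
  wf <- make_toy_wavefunction("one_orbital_bond")
  g <- elf_on_grid(wf, n_points = 30, margin = 4)
  part <- find_basins(g)
  wf2 <- wf
  wf2$nuclei$z <- wf2$nuclei$z + 0.01
  expect_error(integrate_basins(part, wf2), "geometry mismatch")
})

test_that("grid refinement moves benzene bond populations by < 0.02 e", {
  skip_if_not(has_fixture("benzene"), "benzene fixture not shipped")
  an150 <- fixture_analysis("benzene")
  an100 <- fixture_analysis("benzene", n_points = 100)
  n150 <- sort(an150$ring_values$n)
  n100 <- sort(an100$ring_values$n)
  expect_lt(max(abs(n150 - n100)), 0.02)
})
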