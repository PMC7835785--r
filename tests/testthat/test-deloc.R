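# Delocalization indices: closed forms, covariance oracle, sum rules,
# invariances.

test_that("one-orbital split: delta = 4 s (1 - s) and oracle equivalence", {
  wf <- make_toy_wavefunction("one_orbital_bond", distance = 1.4, alpha = 1.0)
  g <- elf_on_grid(wf, n_points = 60, margin = 5)
  part <- midplane_partition(find_basins(g))
  obs <- integrate_basins(part, wf, refine = 1)
  di <- di_matrix(obs)
  s <- obs$S[1, 1, 1]
  expect_equal(di$delta[1, 2], 4 * s * (1 - s), tolerance = 1e-7)
  # symmetric split: s = 1/2, delta = 1 exactly
  expect_equal(s, 0.5, tolerance = 1e-3)
  expect_equal(di$delta[1, 2], 1.0, tolerance = 1e-3)
  # brute-force pair-density covariance agrees to 1e-6
  expect_equal(di$delta[1, 2],
               covariance_oracle(part, wf, 1, 2), tolerance = 1e-6)
  # A = B route: -2cov(nA,nA) = -2(lambda-ish) consistency through sum rule
  lamA <- obs$table$n[1] + 0.5 * covariance_oracle(part, wf, 1, 1)
  expect_equal(lamA, unname(di$lambda[1]), tolerance = 1e-6)
})

test_that("whole space as one basin: lambda = n, delta row zero", {
  wf <- make_toy_wavefunction("two_orbital_model")
  g <- elf_on_grid(wf, n_points = 60, margin = 6)
  part <- find_basins(g)
  # force a single basin
  part$labels <- array(ifelse(part$labels == 0L, 0L, 1L), dim(part$labels))
  part$attractors <- part$attractors[1, ]
  obs <- integrate_basins(part, wf, refine = 1)
  di <- di_matrix(obs)
  expect_equal(di$lambda[[1]], wf$total_electrons, tolerance = 0.02)
  expect_equal(sum(abs(di$delta)), 0)
})

test_that("disjoint fragments share no electrons: delta -> 0", {
  R <- 14
  nuclei <- data.frame(symbol = c("H", "H"), Z = c(1, 1), x = 0, y = 0,
                       z = c(-R / 2, R / 2))
  shells <- list(list(l = 0L, center_index = 1L, exp = 1, coef = 1),
                 list(l = 0L, center_index = 2L, exp = 1, coef = 1))
  wf <- wavefunction(nuclei, shells, diag(2), c(2, 2), net_charge = -2L)
  g <- elf_on_grid(wf, n_points = 60, margin = 5)
  part <- find_basins(g)
  expect_equal(nrow(part$attractors), 2)
  di <- di_matrix(integrate_basins(part, wf))
  expect_lt(max(abs(di$delta)), 1e-8)
})

test_that("sum rule lambda + delta/2 = n holds on every basin of the toys", {
  for (kind in c("two_orbital_model", "atomlike")) {
    wf <- make_toy_wavefunction(kind)
    g <- elf_on_grid(wf, n_points = 70, margin = 6)
    part <- find_basins(g)
    obs <- integrate_basins(part, wf)
    di <- di_matrix(obs)
    resid <- di$lambda + rowSums(di$delta) / 2 - obs$table$n
    expect_lt(max(abs(resid)), 0.05)
  }
})

test_that("delta is invariant under occupied-MO rotation", {
  wf <- make_toy_wavefunction("two_orbital_model", distance = 1.6)
  g <- elf_on_grid(wf, n_points = 50, margin = 5)
  part <- midplane_partition(find_basins(g))
  di1 <- di_matrix(integrate_basins(part, wf))
  set.seed(5)
  th <- runif(1, 0, 2 * pi)
  U <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  wf2 <- wf
  wf2$mo_coefficients <- wf$mo_coefficients %*% U
  di2 <- di_matrix(integrate_basins(part, wf2))
  expect_equal(di1$delta, di2$delta, tolerance = 1e-8)
  expect_equal(di1$lambda, di2$lambda, tolerance = 1e-8)
})

test_that("covariance oracle refuses large systems", {
  skip_if_not(has_fixture("benzene"), "benzene fixture not shipped")
  an <- fixture_analysis("benzene", n_points = 100)
  expect_error(covariance_oracle(an$partition, an$wf, 1, 2), "toy systems")
})

test_that("benzene D6h degeneracy of DI(a) and the dDI(i)-n12 link", {
  skip_if_not(has_fixture("benzene"), "benzene fixture not shipped")
  an <- fixture_analysis("benzene")
  v <- an$ring_values$vicinal
  expect_lt(diff(range(v$DI)), 0.01)
  # vicinal pairs average cleanly: branch spread small
  expect_lt(max(v$spread), 0.01)
})
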