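# ELF kernel, Lorentzian mapping, grids, and invariances.

test_that("kernel and Lorentzian mapping honour their fixed points", {
  # homogeneous-gas condition: tau = c_F rho^{5/3}, grad = 0 -> chi = 1
  rho <- c(0.3, 1.2)
  tau <- 0.3 * (3 * pi^2)^(2 / 3) * rho^(5 / 3)
  chi <- chi_kernel(rho, tau = tau, gradsq = c(0, 0))
  expect_equal(chi, c(1, 1), tolerance = 1e-12)
  expect_equal(elf(0), 1)
  expect_equal(elf(1), 0.5)
  expect_equal(elf(Inf), 0)
  expect_true(all(diff(elf(seq(0, 10, 0.1))) < 0))  # strictly decreasing
  # vacuum sentinel: no division fault, eta -> 0
  chi0 <- chi_kernel(0, tau = 0, gradsq = 0)
  expect_identical(chi0, Inf)
  expect_equal(elf(chi0), 0)
  expect_error(chi_kernel(-1, tau = 1, gradsq = 0), "non-negative")
})

test_that("one doubly-occupied orbital gives D = 0, ELF = 1 everywhere", {
  wf <- make_toy_wavefunction("one_orbital_bond", distance = 1.4, alpha = 1.0)
  g <- elf_on_grid(wf, n_points = 50, margin = 5)
  sel <- attr(g, "rho") > 1e-8
  expect_lt(max(abs(g$values[sel] - 1)), 1e-8)
  # pointwise identity tau = |grad rho|^2/(8 rho) for a single occupied MO
  set.seed(7)
  pts <- matrix(runif(150, -2, 2), ncol = 3)
  ev <- evaluate_fields(wf, pts)
  expect_equal(ev$tau, rowSums(ev$grad_rho^2) / (8 * ev$rho), tolerance = 1e-10)
})

test_that("grid density integrates to the electron count within 0.5%", {
  for (kind in c("one_orbital_bond", "two_orbital_model", "atomlike")) {
    wf <- make_toy_wavefunction(kind)
    g <- elf_on_grid(wf, n_points = 80, margin = 6)
    N <- sum(attr(g, "rho")) * prod(g$spacing)
    expect_equal(N, wf$total_electrons, tolerance = 5e-3)
  }
})

test_that("ELF lies in [0,1] and is invariant under occupied-MO rotation", {
  wf <- make_toy_wavefunction("two_orbital_model", distance = 1.6)
  g <- elf_on_grid(wf, n_points = 40, margin = 5)
  expect_true(all(g$values >= 0 & g$values <= 1))
  # random unitary rotation among the two occupied MOs
  set.seed(21)
  th <- runif(1, 0, 2 * pi)
  U <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  wf2 <- wf
  wf2$mo_coefficients <- wf$mo_coefficients %*% U
  g2 <- elf_on_grid(wf2, n_points = 40, margin = 5)
  expect_lt(max(abs(g$values - g2$values)), 1e-8)
})

test_that("rigid translation moves the ELF field identically", {
  wf <- make_toy_wavefunction("two_orbital_model", distance = 1.6)
  shift <- c(0.8, -0.5, 1.1)
  wf2 <- wf
  wf2$nuclei$x <- wf$nuclei$x + shift[1]
  wf2$nuclei$y <- wf$nuclei$y + shift[2]
  wf2$nuclei$z <- wf$nuclei$z + shift[3]
  wf2$shells$center <- sweep(wf$shells$center, 2, shift, "+")
  box1 <- list(lo = c(-5, -5, -6), hi = c(5, 5, 6))
  box2 <- list(lo = box1$lo + shift, hi = box1$hi + shift)
  g1 <- elf_on_grid(wf, n_points = 40, box = box1)
  g2 <- elf_on_grid(wf2, n_points = 40, box = box2)
  expect_lt(max(abs(g1$values - g2$values)), 1e-8)
})

test_that("degenerate boxes and bad grids are rejected", {
  wf <- make_toy_wavefunction("one_orbital_bond")
  expect_error(elf_on_grid(wf, box = list(lo = c(0, 0, 0), hi = c(0, 1, 1))),
               "degenerate")
  expect_error(elf_on_grid(wf, n_points = 1), "at least 2")
})

test_that("cube files round-trip their header and values", {
  wf <- make_toy_wavefunction("one_orbital_bond")
  g <- elf_on_grid(wf, n_points = 12, margin = 3)
  tmp <- tempfile(fileext = ".cube")
  write_cube(g, tmp)
  ln <- readLines(tmp)
  expect_equal(as.integer(strsplit(trimws(ln[3]), "\\s+")[[1]][1]), 2) # 2 atoms
  nx <- as.integer(strsplit(trimws(ln[4]), "\\s+")[[1]][1])
  expect_equal(nx, 12)
  # first data value matches the grid corner
  first <- as.numeric(strsplit(trimws(ln[9]), "\\s+")[[1]][1])
  expect_equal(first, g$values[1, 1, 1], tolerance = 1e-4)
})
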