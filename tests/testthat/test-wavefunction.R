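# Wavefunction construction, file parsing, and point evaluation.

test_that("toy wavefunctions are valid closed-shell determinants", {
  wf <- make_toy_wavefunction("one_orbital_bond", distance = 1.4, alpha = 1.0)
  expect_equal(wf$total_electrons, 2)
  expect_equal(ncol(wf$mo_coefficients), 1)
  expect_lt(orthonormality_residual(wf), 1e-6)

  wf2 <- make_toy_wavefunction("two_orbital_model")
  expect_equal(wf2$total_electrons, 4)
  expect_equal(ncol(wf2$mo_coefficients), 2)
  expect_lt(orthonormality_residual(wf2), 1e-6)

  expect_error(make_toy_wavefunction("one_orbital_bond", alpha = -1),
               "positive")
})

test_that("single s-Gaussian density matches the closed form at the origin", {
  # doubly occupied normalized s orbital, exponent a: rho(0) = 2 (2a/pi)^{3/2}
  for (a in c(0.5, 1.0, 2.3)) {
    nuc <- data.frame(symbol = "H", Z = 1, x = 0, y = 0, z = 0)
    sh <- list(list(l = 0L, center_index = 1L, exp = a, coef = 1))
    wf <- wavefunction(nuc, sh, matrix(1, 1, 1), 2, net_charge = -1L)
    ev <- evaluate_fields(wf, matrix(0, 1, 3))
    expect_equal(ev$rho, 2 * (2 * a / pi)^1.5, tolerance = 1e-12)
  }
})

test_that("analytic density gradients match central finite differences", {
  wf <- make_toy_wavefunction("two_orbital_model", distance = 1.7, alpha = 0.8)
  set.seed(11)
  pts <- matrix(runif(300, -2, 2), ncol = 3)
  ev <- evaluate_fields(wf, pts)
  h <- 1e-5
  for (k in 1:3) {
    pp <- pts; pp[, k] <- pp[, k] + h
    pm <- pts; pm[, k] <- pm[, k] - h
    fd <- (evaluate_fields(wf, pp)$rho - evaluate_fields(wf, pm)$rho) / (2 * h)
    expect_equal(ev$grad_rho[, k], fd, tolerance = 1e-6)
  }
})

test_that("tau integrates to the analytic Gaussian kinetic energy", {
  # one normalized s Gaussian, occupation 2: T = 2 * (3/2) a / ... analytic:
  # <phi|-(1/2)nabla^2|phi> = 3a/2 per electron
  a <- 0.9
  nuc <- data.frame(symbol = "H", Z = 1, x = 0, y = 0, z = 0)
  sh <- list(list(l = 0L, center_index = 1L, exp = a, coef = 1))
  wf <- wavefunction(nuc, sh, matrix(1, 1, 1), 2, net_charge = -1L)
  g <- elf_on_grid(wf, n_points = 80, margin = 6)
  Tnum <- sum(attr(g, "tau")) * prod(g$spacing)
  expect_equal(Tnum, 2 * 1.5 * a, tolerance = 2e-3)
})

test_that("rho and tau are non-negative on random points", {
  wf <- make_toy_wavefunction("atomlike")
  set.seed(4)
  pts <- matrix(rnorm(600, sd = 3), ncol = 3)
  ev <- evaluate_fields(wf, pts)
  expect_true(all(ev$rho >= 0))
  expect_true(all(ev$tau >= 0))
})

test_that("Molden round trip: electron counts and parse errors", {
  skip_if_not(has_fixture("benzene"), "benzene fixture not shipped")
  wf <- read_wavefunction(elfiqa_example("benzene"))
  expect_equal(wf$total_electrons, 42)
  expect_equal(ncol(wf$mo_coefficients), 21)
  expect_equal(wf$net_charge, 0L)
  expect_lt(orthonormality_residual(wf), 1e-6)

  # truncated file must fail loudly, not load partially
  full <- readLines(elfiqa_example("benzene"))
  tmp <- tempfile(fileext = ".molden")
  writeLines(full[1:(length(full) %/% 2)], tmp)
  expect_error(read_wavefunction(tmp), "coefficients|malformed|lacks")
})

test_that("open-shell and fractional occupations are rejected", {
  lines <- c("[Molden Format]", "[Atoms] AU",
             "H 1 1 0.0 0.0 -0.7", "H 2 1 0.0 0.0 0.7",
             "[GTO]", " 1 0", " s 1 1.00", "  1.0 1.0", "",
             " 2 0", " s 1 1.00", "  1.0 1.0", "",
             "[MO]", " Sym= A", " Ene= -0.5", " Spin= Alpha", " Occup= 1.0",
             "  1 0.548", "  2 0.548")
  tmp <- tempfile(fileext = ".molden")
  writeLines(lines, tmp)
  expect_error(read_wavefunction(tmp), "occupation")
})

test_that("wfn and wfx dialects parse a hydrogenic toy consistently", {
  # H2+-like single MO over two s primitives (alpha = 1), occ 2
  s12 <- exp(-1 * 1.4^2 / 2)
  c1 <- (2 / pi)^0.75 / sqrt(2 * (1 + s12))   # primitive-normalised coeff
  wfn <- c(
    " TOY",
    "GAUSSIAN              1 MOL ORBITALS      2 PRIMITIVES        2 NUCLEI",
    "  H    1    (CENTRE  1)   0.00000000  0.00000000 -0.70000000  CHARGE =  1.0",
    "  H    2    (CENTRE  2)   0.00000000  0.00000000  0.70000000  CHARGE =  1.0",
    "CENTRE ASSIGNMENTS    1  2",
    "TYPE ASSIGNMENTS      1  1",
    sprintf("EXPONENTS  %.8e %.8e", 1.0, 1.0),
    "MO    1     MO 0.0        OCC NO =    2.0000000  ORB. ENERGY =   -0.5",
    sprintf(" %.8e %.8e", c1, c1),
    "END DATA")
  tmp <- tempfile(fileext = ".wfn")
  writeLines(gsub("e([+-])", "D\\1", wfn), tmp)
  wf <- read_wavefunction(tmp)
  expect_equal(wf$total_electrons, 2)
  ref <- make_toy_wavefunction("one_orbital_bond", distance = 1.4, alpha = 1.0)
  pts <- matrix(c(0, 0, 0, 0.3, -0.2, 0.5), 2, 3, byrow = TRUE)
  expect_equal(evaluate_fields(wf, pts)$rho, evaluate_fields(ref, pts)$rho,
               tolerance = 1e-6)

  wfx <- c("<Number of Nuclei>", " 2", "</Number of Nuclei>",
           "<Number of Primitives>", " 2", "</Number of Primitives>",
           "<Number of Occupied Molecular Orbitals>", " 1",
           "</Number of Occupied Molecular Orbitals>",
           "<Nuclear Names>", " H1 H2", "</Nuclear Names>",
           "<Atomic Numbers>", " 1 1", "</Atomic Numbers>",
           "<Nuclear Cartesian Coordinates>",
           " 0.0 0.0 -0.7", " 0.0 0.0 0.7",
           "</Nuclear Cartesian Coordinates>",
           "<Primitive Centers>", " 1 2", "</Primitive Centers>",
           "<Primitive Types>", " 1 1", "</Primitive Types>",
           "<Primitive Exponents>", " 1.0 1.0", "</Primitive Exponents>",
           "<Molecular Orbital Occupation Numbers>", " 2.0",
           "</Molecular Orbital Occupation Numbers>",
           "<Molecular Orbital Primitive Coefficients>",
           "<MO Number> 1 </MO Number>",
           sprintf(" %.10e %.10e", c1, c1),
           "</Molecular Orbital Primitive Coefficients>")
  tmpx <- tempfile(fileext = ".wfx")
  writeLines(wfx, tmpx)
  wf2 <- read_wavefunction(tmpx)
  expect_equal(evaluate_fields(wf2, pts)$rho, evaluate_fields(ref, pts)$rho,
               tolerance = 1e-6)
})
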