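# Basin construction: ascent, merging, exhaustiveness, synapticity,
# ring labelling.

test_that("single and double Gaussian bumps give one and two basins", {
  g1 <- bump_field(list(c(0, 0, 0)), n = 40)
  p1 <- find_basins(g1)
  expect_equal(nrow(p1$attractors), 1)
  expect_equal(sum(p1$labels == 1), prod(p1$shape))  # no vacuum: exhaustive

  g2 <- bump_field(list(c(-1.5, 0, 0), c(1.5, 0, 0)), n = 40)
  p2 <- find_basins(g2)
  expect_equal(nrow(p2$attractors), 2)
  # equal halves by mirror symmetry (even n: no voxel on the plane)
  cnt <- table(as.vector(p2$labels))
  expect_equal(unname(cnt[1]), unname(cnt[2]))
  # every voxel labelled
  expect_equal(sum(cnt), prod(p2$shape))
})

test_that("grid ascent agrees with a trilinear-interpolation ascent oracle", {
  g <- bump_field(list(c(-1.5, 0, 0), c(1.5, 0, 0)), n = 31)
  p <- find_basins(g)
  # continuous gradient ascent with trilinear interpolation, on a sample
  interp <- function(pos) {
    u <- (pos - g$origin) / g$spacing
    i <- pmin(pmax(floor(u), 0), g$shape - 2)
    f <- u - i
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      v <- v + w * g$values[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1]
    }
    v
  }
  ascend <- function(pos) {
    h <- min(g$spacing) * 0.5
    for (it in 1:300) {
      gr <- vapply(1:3, function(k) {
        e <- rep(0, 3); e[k] <- 1e-4
        (interp(pos + e) - interp(pos - e)) / 2e-4
      }, 0)
      nrm <- sqrt(sum(gr^2))
      if (nrm < 1e-10) break
      pos <- pmin(pmax(pos + h * gr / nrm, g$origin),
                  g$origin + (g$shape - 1) * g$spacing)
    }
    if (pos[1] < 0) 1L else 2L   # basin by final x sign (bumps at -/+1.5)
  }
  set.seed(3)
  idx <- sample(prod(p$shape), 400)
  agree <- 0
  total <- 0
  for (v in idx) {
    i0 <- v - 1L
    iz <- i0 %/% (p$shape[1] * p$shape[2])
    iy <- (i0 %% (p$shape[1] * p$shape[2])) %/% p$shape[1]
    ix <- i0 %% p$shape[1]
    pos <- p$origin + c(ix, iy, iz) * p$spacing
    if (abs(pos[1]) < 2 * p$spacing[1]) next  # skip the separatrix band
    lab_o <- ascend(pos)
    lab_g <- if (p$attractors$x[p$labels[ix + 1, iy + 1, iz + 1]] < 0) 1L else 2L
    total <- total + 1
    agree <- agree + (lab_o == lab_g)
  }
  expect_gte(agree / total, 0.999)
})

test_that("flat-ELF plateau merges into a single disynaptic bond basin", {
  wf <- make_toy_wavefunction("one_orbital_bond", distance = 1.4, alpha = 1.0)
  g <- elf_on_grid(wf, n_points = 50, margin = 5)
  part <- find_basins(g)
  expect_equal(nrow(part$attractors), 1)
  part <- classify_synapticity(part, wf)
  expect_equal(part$records$type, "disynaptic")
})

test_that("atom-like shell pair produces a core plus a shell attractor", {
  wf <- make_toy_wavefunction("atomlike")
  g <- elf_on_grid(wf, n_points = 64, margin = 6)
  part <- find_basins(g)
  expect_equal(nrow(part$attractors), 2)
  part <- classify_synapticity(part, wf)
  expect_true("core" %in% part$records$type)
})

test_that("degenerate flat field raises an error", {
  f <- array(1, c(8, 8, 8))
  g <- field_grid(c(0, 0, 0), c(1, 1, 1), f, "test")
  attr(g, "rho") <- array(0, c(8, 8, 8))  # all vacuum
  attr(g, "floor") <- 1e-10
  expect_error(find_basins(g), "no attractors")
})

test_that("benzene partitions into the 18-basin aromatic census", {
  skip_if_not(has_fixture("benzene"), "benzene fixture not shipped")
  an <- fixture_analysis("benzene")
  tab <- an$obs$table
  # far-field artifacts are flagged spurious, never silently merged; the
  # chemically meaningful census is the non-spurious set
  real <- tab[!tab$spurious, ]
  expect_equal(nrow(real), 18)
  expect_equal(sum(real$type == "core"), 6)
  cc <- grepl("^V\\(C[0-9]+,C[0-9]+\\)$", real$name)
  ch <- grepl("^V\\(C[0-9]+,H[0-9]+\\)$", real$name)
  expect_equal(sum(cc), 6)
  expect_equal(sum(ch), 6)
  expect_true(all(real$type[cc | ch] == "disynaptic"))
  # partition exhaustiveness: labels cover all non-vacuum voxels
  labs <- as.vector(an$partition$labels)
  expect_equal(sum(labs > 0) + an$partition$n_vacuum, prod(an$partition$shape))
  # D6h: six V(C,C) populations equal within 1%
  ncc <- real$n[cc]
  expect_lt(diff(range(ncc)) / mean(ncc), 0.01)
})

test_that("ring labelling is circular and anchored at the ipso carbon", {
  skip_if_not(has_fixture("toluene"), "toluene fixture not shipped")
  an <- fixture_analysis("toluene")
  rl <- an$ring
  expect_equal(length(rl$bond_basins), 6)
  expect_named(rl$bond_basins, c("b12", "b23", "b34", "b45", "b56", "b61"))
  # C1 carries the methyl substituent: some disynaptic basin joins C1 to a
  # non-ring heavy atom
  rec <- an$partition$records
  c1 <- rl$ring_atoms[1]
  has_sub <- any(vapply(seq_len(nrow(rec)), function(b) {
    at <- rec$atoms[[b]]
    length(at) == 2 && c1 %in% at &&
      any(!(at %in% rl$ring_atoms) & an$wf$nuclei$Z[at] > 2)
  }, TRUE))
  expect_true(has_sub)
})
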