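# Shared toy builders and a per-session cache for expensive analyses.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# Gaussian-bump scalar field on a cube
bump_field <- function(centers, n = 40, half = 4, width = 1) {
  ax <- seq(-half, half, length.out = n)
  f <- array(0, c(n, n, n))
  for (cc in centers) {
    gx <- exp(-((ax - cc[1]) / width)^2)
    gy <- exp(-((ax - cc[2]) / width)^2)
    gz <- exp(-((ax - cc[3]) / width)^2)
    f <- f + outer(outer(gx, gy), gz)
  }
  field_grid(rep(-half, 3), rep(ax[2] - ax[1], 3), f, "test")
}

# Replace a partition's labels by a z-midplane split (used for the
# closed-form DI and observable oracles); even grids avoid tie voxels.
midplane_partition <- function(part) {
  labs <- part$labels
  dims <- dim(labs)
  zc <- part$origin[3] + (slice.index(labs, 3) - 1) * part$spacing[3]
  part$labels <- array(ifelse(labs == 0L, 0L, ifelse(zc < 0, 1L, 2L)), dims)
  part$attractors <- data.frame(id = 1:2, x = 0, y = 0, z = c(-0.7, 0.7),
                                eta = 1, n_merged = 1L)
  part$records <- NULL
  part
}

# analysis of a shipped wavefunction, computed once per session
fixture_analysis <- function(name, n_points = 150) {
  cached(paste0(name, "_", n_points), {
    analyze_molecule(elfiqa_example(name), n_points = n_points)
  })
}

has_fixture <- function(name) {
  name %in% elfiqa_example()
}
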