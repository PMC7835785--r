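# Descriptor assembly: symmetry averaging, pattern rules, orientation,
# Hammett regression.

test_that("symmetry averaging pairs the mirror-equivalent bonds", {
  v <- c(b12 = 2.80, b23 = 2.80, b34 = 2.80, b45 = 2.80, b56 = 2.80, b61 = 2.80)
  a <- symmetry_average(v)
  expect_equal(c(a$q12, a$q23, a$q34), rep(2.80, 3))
  expect_equal(a$max_spread, 0)

  v2 <- c(b12 = 2.90, b23 = 2.80, b34 = 2.70, b45 = 2.72, b56 = 2.82, b61 = 2.88)
  a2 <- symmetry_average(v2)
  expect_equal(a2$q12, 2.89)
  expect_equal(a2$q23, 2.81)
  expect_equal(a2$q34, 2.71)
  expect_false(a2$flagged)

  v3 <- v2; v3["b56"] <- v3["b23"] + 0.15
  expect_warning(a3 <- symmetry_average(v3), "spread")
  expect_true(a3$flagged)
  expect_error(symmetry_average(c(b12 = 1)), "named")
})

test_that("decay and oscillation patterns classify as specified", {
  expect_equal(classify_pattern(2.90, 2.80, 2.70), "inductive_decay")
  expect_equal(classify_pattern(2.70, 3.10, 2.75), "mesomeric_oscillatory")
  expect_equal(classify_pattern(2.80, 2.80, 2.80), "mixed")
  # inside the tolerance band -> mixed
  expect_equal(classify_pattern(2.805, 2.80, 2.796), "mixed")
})

test_that("orientation prediction follows the sign rules", {
  expect_equal(predict_orientation(+0.05, -0.03, +0.04), "ortho_para")
  expect_equal(predict_orientation(-0.04, +0.02, -0.05), "meta")
  expect_equal(predict_orientation(-0.04, -0.02, -0.05), "meta")  # all-negative
  expect_equal(predict_orientation(+0.01, +0.01, -0.04), "indeterminate")
  expect_equal(predict_orientation(0.001, -0.001, 0.002), "indeterminate")
})

test_that("Hammett regression: exact fit, degeneracies, permutation null", {
  rec <- data.frame(substituent = letters[1:5],
                    DI_m = c(0.1, 0.2, 0.3, 0.4, 0.5),
                    DI_p = 0)
  rec$sigma_m <- 2 * (rec$DI_m - rec$DI_p) + 0.3
  rec$sigma_p <- 0
  fit <- hammett_regression(rec)
  expect_equal(fit$r, 1.0, tolerance = 1e-12)
  expect_equal(fit$slope, 2.0, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(td$estimate, c(0.3, 2.0), tolerance = 1e-10)
  expect_equal(glance(fit)$r.squared, 1.0, tolerance = 1e-12)

  expect_error(hammett_regression(rec[1:2, ]), "at least 3")
  rec2 <- rec; rec2$DI_m <- 0.2
  expect_error(hammett_regression(rec2), "zero variance")

  # shuffled pairing destroys the correlation on average
  set.seed(42)
  rec3 <- data.frame(substituent = as.character(1:12),
                     DI_m = rnorm(12), DI_p = 0, sigma_p = 0, sigma_m = 0)
  rec3$sigma_m <- 1.5 * rec3$DI_m + rnorm(12, sd = 0.05)
  rs <- replicate(200, {
    sh <- rec3
    sh$sigma_m <- sample(sh$sigma_m)
    abs(hammett_regression(sh)$r)
  })
  r0 <- abs(hammett_regression(rec3)$r)
  expect_gt(r0, 0.95)
  expect_lt(mean(rs), 0.4)
})

test_that("shipped Hammett table loads and validates", {
  tb <- read_hammett_table(system.file("extdata", "hammett_sigma.csv",
                                       package = "elfiqa"))
  expect_true(all(c("substituent", "sigma_m", "sigma_p") %in% names(tb)))
  expect_true(all(is.finite(tb$sigma_m)))
  bad <- tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_hammett_table(bad), "columns")
})
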