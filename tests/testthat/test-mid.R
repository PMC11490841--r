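test_that("correcting the natural spectrum of an unlabelled fragment gives m+0 = 1", {
  iso <- isotope_table()
  reg <- fragment_registry()
  for (met in c("glycine", "succinate", "glutamate")) {
    cm <- build_correction_matrix(reg[[met]], iso)
    m <- cm$matrix[, 1]  # theoretical unlabelled spectrum
    mid <- correct_mid(m, cm)
    expect_equal(unname(mid[1]), 1, tolerance = 1e-6)
    expect_equal(total_enrichment(mid), 0, tolerance = 1e-6)
  }
})

test_that("round-trip: forward model then correction recovers the truth MID", {
  iso <- isotope_table()
  cm <- build_correction_matrix(fragment_spec("c1", c(C = 1), 1),
                                isotope_table(purity = 1))
  m <- as.vector(cm$matrix %*% c(0.5, 0.5))
  expect_equal(as.numeric(correct_mid(m, cm)), c(0.5, 0.5), tolerance = 1e-9)

  reg <- fragment_registry()
  set.seed(101)
  for (rep in 1:20) {
    frag <- reg[[sample(names(reg), 1)]]
    cm <- build_correction_matrix(frag, iso)
    x <- stats::runif(frag$n_tracer_carbons + 1)
    x <- x / sum(x)
    m <- as.vector(cm$matrix %*% x) * stats::runif(1, 1e3, 1e7)
    got <- correct_mid(m, cm)
    expect_equal(as.numeric(got), x, tolerance = 1e-6)
    # pinv solver agrees on clean data
    got2 <- correct_mid(m, cm, solver = "pinv")
    expect_equal(as.numeric(got2), x, tolerance = 1e-6)
  }
})

test_that("noisy measurements still yield a valid non-negative MID", {
  set.seed(7)
  cm <- build_correction_matrix(fragment_spec("x", c(C = 3, H = 4), 3),
                                isotope_table())
  x <- c(0.94, 0.04, 0.015, 0.005)
  m <- as.vector(cm$matrix %*% x)
  m <- pmax(m + rnorm(length(m), 0, 2e-4), 0)
  mid <- correct_mid(m, cm)
  expect_true(all(mid >= 0))
  expect_equal(sum(mid), 1, tolerance = 1e-12)
})

test_that("empty and oversized measurements are errors", {
  cm <- build_correction_matrix(fragment_spec("x", c(C = 2), 2),
                                isotope_table())
  expect_error(correct_mid(numeric(nrow(cm$matrix)), cm), "total intensity")
  expect_error(correct_mid(rep(1, nrow(cm$matrix) + 1), cm), "longer")
})

test_that("enrichment is one minus the unlabelled fraction", {
  expect_equal(total_enrichment(as_mid(c(0.4, 0.1, 0.5))), 0.6)
  expect_equal(total_enrichment(as_mid(c(1, 0, 0))), 0)
  expect_equal(total_enrichment(as_mid(c(0.37, 0.23, 0.4))), 0.63)
  expect_error(as_mid(c(0.4, 0.4)), "sum")
  expect_error(as_mid(c(-0.1, 1.1)), "non-negative")
})

test_that("isotopologue ratios divide the right fractions and flag zero denominators", {
  glu <- as_mid(c(0.7, 0, 0, 0, 0, 0.3))
  gln <- as_mid(c(0.4, 0, 0, 0, 0, 0.6))
  r <- isotopologue_ratio(glu, 5, gln, 5)
  expect_equal(r$ratio, 0.5)
  expect_equal(isotopologue_ratio(glu, 5, glu, 5)$ratio, 1)
  zero <- as_mid(c(1, 0, 0, 0, 0, 0))
  r0 <- isotopologue_ratio(glu, 5, zero, 5)
  expect_false(r0$computable)
  expect_true(is.na(r0$ratio))
  expect_error(isotopologue_ratio(glu, 9, gln, 5), "out of range")
})

test_that("relative abundance normalises to internal standard and cell count", {
  r <- relative_abundance(c(6e5, 3e5, 1e5), 1e5, 1e6)
  expect_equal(r$abundance, 1e-5)
  expect_true(r$cell_normalised)
  # scale invariance to a shared detector gain
  r2 <- relative_abundance(2 * c(6e5, 3e5, 1e5), 2e5, 1e6)
  expect_equal(r2$abundance, r$abundance)
  r3 <- relative_abundance(c(6e5, 4e5), 1e5)
  expect_false(r3$cell_normalised)
  expect_equal(r3$abundance, 10)
  expect_error(relative_abundance(c(1, 2), 0, 1), "internal-standard")
})

test_that("log2 ratio-to-mean matches hand computation and its invariants", {
  out <- ratio_to_mean(rbind(a = c(2, 4, 8)))
  expect_equal(as.numeric(out), c(-1.222392, -0.222392, 0.777608),
               tolerance = 1e-6)
  expect_equal(as.numeric(ratio_to_mean(rbind(c(5, 5, 5)))), c(0, 0, 0))
  # row-mean-of-ratios property and row-scaling invariance
  set.seed(3)
  m <- matrix(stats::rlnorm(24), 4)
  out <- ratio_to_mean(m)
  expect_equal(rowMeans(2^out), rep(1, 4), tolerance = 1e-12)
  expect_equal(ratio_to_mean(m * 100)[2, ], out[2, ], tolerance = 1e-12)
  m[2, 3] <- 0
  expect_error(ratio_to_mean(m), "non-positive")
})
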