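test_that("simulators are deterministic under a fixed seed", {
  a <- simulate_flux_plate(seed = 42)
  b <- simulate_flux_plate(seed = 42)
  expect_identical(a, b)
  expect_false(identical(simulate_flux_plate(seed = 43)$plate$ocr,
                         a$plate$ocr))
  expect_identical(simulate_labelling(seed = 9), simulate_labelling(seed = 9))
  expect_identical(simulate_omics(n_proteins = 50, seed = 9),
                   simulate_omics(n_proteins = 50, seed = 9))
})

test_that("noise-free plates reproduce the design plateaus exactly", {
  sim <- simulate_flux_plate(wells_per_group = 2, noise_sd = 0,
                             cell_factor_sd = 0, od_noise_sd = 0, seed = 1)
  ps <- summarize_phases(normalize_plate(sim$plate, sim$od), sim$protocol)
  design <- default_flux_design()
  for (g in names(design)) {
    rows <- ps[ps$group == g, ]
    expect_equal(rows$basal_ocr, rep(design[[g]]$ocr[["basal"]], 2),
                 tolerance = 1e-12)
    expect_equal(rows$fccp_ocr, rep(design[[g]]$ocr[["fccp"]], 2),
                 tolerance = 1e-12)
    expect_equal(rows$monensin_ecar, rep(design[[g]]$ecar[["monensin"]], 2),
                 tolerance = 1e-12)
  }
})

test_that("negative plateaus are rejected", {
  design <- default_flux_design()
  design$C1$ocr[["fccp"]] <- -1
  expect_error(simulate_flux_plate(design = design, seed = 1),
               "negative plateau")
})

test_that("noise-free labelling round-trips truth MIDs through correction", {
  sim <- simulate_labelling(noise_sdlog = 0, is_noise_sdlog = 0,
                            replicates = 1, seed = 1)
  reg <- fragment_registry()
  iso <- isotope_table()
  truth <- sim$truth$params$truth_mids
  for (met in names(truth)) {
    cm <- build_correction_matrix(reg[[met]], iso)
    v <- sim$intensities[sim$intensities$metabolite == met, ]
    m <- numeric(max(v$mass_shift) + 1L)
    m[v$mass_shift + 1L] <- v$intensity
    got <- correct_mid(m, cm)
    expect_equal(as.numeric(got), as.numeric(as_mid(truth[[met]])),
                 tolerance = 1e-6)
  }
})

test_that("unlabelled truth produces the natural-abundance spectrum", {
  reg <- fragment_registry()
  iso <- isotope_table()
  sim <- simulate_labelling(
    truth_mids = list(glycine = c(1, 0, 0)),
    abundances = c(glycine = 1e6), noise_sdlog = 0, replicates = 1, seed = 2
  )
  cm <- build_correction_matrix(reg$glycine, iso)
  v <- sim$intensities$intensity
  expect_equal(v / 1e6, cm$matrix[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("labelling simulation validates its inputs", {
  expect_error(simulate_labelling(truth_mids = list(unobtainium = c(1, 0)),
                                  seed = 1),
               "not in the fragment registry")
  expect_error(simulate_labelling(truth_mids = list(glycine = c(1, 0, 0, 0)),
                                  seed = 1),
               "length")
})

test_that("spiked proteome effects land on the requested proteins", {
  eff <- data.frame(protein = c(5, 10), log2fc = c(2, -2))
  sim <- simulate_omics(n_proteins = 20, effects = eff, noise_sd = 0.01,
                        seed = 3)
  lg <- log2(sim$proteome$mat)
  d <- rowMeans(lg[, 4:6]) - rowMeans(lg[, 1:3])
  expect_equal(d[5], 2, tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(d[10], -2, tolerance = 0.05, ignore_attr = TRUE)
  expect_lt(max(abs(d[-c(5, 10)])), 0.1)
  expect_error(simulate_omics(n_proteins = 10,
                              effects = data.frame(protein = 11, log2fc = 1),
                              seed = 1),
               "out of range")
})

test_that("growth curves rise from the seeding confluence toward capacity", {
  sim <- simulate_omics(n_proteins = 10, seed = 4)
  g <- sim$growth[sim$growth$well == "control_w1", ]
  expect_equal(g$confluence[1], 5, tolerance = 0.5)
  expect_gt(tail(g$confluence, 1), 50)
  rel <- relative_growth(g$time_h, g$confluence)
  expect_equal(rel$relative[1], 1)
})

test_that("truth records round-trip through serialisation losslessly", {
  dir <- withr::local_tempdir()
  for (truth in list(simulate_flux_plate(seed = 6)$truth,
                     simulate_labelling(seed = 6)$truth,
                     simulate_omics(n_proteins = 10, seed = 6)$truth)) {
    path <- file.path(dir, "truth.json")
    write_truth(truth, path)
    back <- read_truth(path)
    expect_identical(back$kind, truth$kind)
    expect_identical(back$seed, truth$seed)
    expect_equal(back$params, truth$params, tolerance = 0)
  }
})
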