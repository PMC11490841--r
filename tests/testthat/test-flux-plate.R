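make_plate <- function(ocr, ecar = ocr, normalised = FALSE) {
  n_w <- nrow(ocr)
  flux_plate(
    wells = data.frame(well_id = paste0("W", seq_len(n_w)),
                       group = "G", condition = "assay"),
    cycles = seq_len(ncol(ocr)), ocr = ocr, ecar = ecar,
    normalised = normalised
  )
}

test_that("normalisation divides each well by its OD595 and flips the flag", {
  plate <- make_plate(matrix(c(120, 120, 60, 60), 2, byrow = TRUE))
  od <- data.frame(well_id = c("W1", "W2"), od595 = c(0.6, 1.0))
  norm <- normalize_plate(plate, od)
  expect_true(norm$normalised)
  expect_equal(norm$ocr["W1", ], c(200, 200))
  expect_equal(norm$ocr["W2", ], c(60, 60))
  # OD 1.0 leaves the well untouched
  expect_equal(norm$ecar["W2", ], plate$ecar["W2", ])
  expect_error(normalize_plate(norm, od), "already normalised")
})

test_that("normalisation errors name the offending wells", {
  plate <- make_plate(matrix(1, 2, 3))
  expect_error(normalize_plate(plate, data.frame(well_id = "W1", od595 = 1)),
               "W2")
  expect_error(
    normalize_plate(plate, data.frame(well_id = c("W1", "W2"),
                                      od595 = c(0, 1))),
    "OD595 <= 0.*W1"
  )
})

test_that("scale equivariance: scaling raw rates and OD together is a no-op", {
  sim <- simulate_flux_plate(wells_per_group = 4, seed = 7)
  norm1 <- normalize_plate(sim$plate, sim$od)
  k <- 3.7
  plate2 <- sim$plate
  plate2$ocr <- plate2$ocr * k
  plate2$ecar <- plate2$ecar * k
  od2 <- sim$od
  od2$od595 <- od2$od595 * k
  norm2 <- normalize_plate(plate2, od2)
  expect_equal(norm2$ocr, norm1$ocr)
  expect_equal(norm2$ecar, norm1$ecar)
})

test_that("phase summarisation applies the default aggregators", {
  # basal mean, oligomycin min, FCCP max, antimycin/rotenone min
  ocr <- matrix(c(100, 98, 102, 40, 38, 36, 150, 160, 155, 20, 18, 19), 1)
  plate <- make_plate(ocr, normalised = TRUE)
  protocol <- injection_protocol(
    data.frame(name = c("oligomycin", "fccp", "antimycin_rotenone"),
               first_cycle_index = c(3, 6, 9)),
    n_cycles = 12
  )
  ps <- summarize_phases(plate, protocol)
  expect_equal(ps$basal_ocr, 100)
  expect_equal(ps$oligo_ocr, 36)
  expect_equal(ps$fccp_ocr, 160)
  expect_equal(ps$aarot_ocr, 18)
  expect_true(is.na(ps$monensin_ecar))  # protocol had no monensin
  expect_equal(attr(ps, "aggregators")$fccp, "max")
})

test_that("singleton phases return the single cycle and aggregates stay in range", {
  ocr <- matrix(c(100, 40, 160, 20, 25), 1)
  plate <- make_plate(ocr, normalised = TRUE)
  protocol <- injection_protocol(
    data.frame(name = c("oligomycin", "fccp", "antimycin_rotenone",
                        "monensin"),
               first_cycle_index = 1:4),
    n_cycles = 5
  )
  ps <- summarize_phases(plate, protocol)
  expect_equal(unlist(ps[c("basal_ocr", "oligo_ocr", "fccp_ocr",
                           "aarot_ocr")], use.names = FALSE),
               c(100, 40, 160, 20))
  # aggregates never leave the min/max of their phase's cycles
  sim <- simulate_flux_plate(wells_per_group = 3, seed = 11)
  p <- normalize_plate(sim$plate, sim$od)
  ps2 <- summarize_phases(p, sim$protocol)
  cyc <- rep(c("basal", "oligomycin", "fccp", "antimycin_rotenone",
               "monensin"), each = 3)
  for (w in seq_len(nrow(ps2))) {
    rng <- range(p$ocr[w, cyc == "basal"])
    expect_gte(ps2$basal_ocr[w], rng[1])
    expect_lte(ps2$basal_ocr[w], rng[2])
  }
})

test_that("degenerate protocols are rejected", {
  expect_error(
    injection_protocol(data.frame(name = c("oligomycin", "fccp"),
                                  first_cycle_index = c(3, 3)),
                       n_cycles = 12),
    "strictly increasing"
  )
  # FCCP injected at the same cycle as the following inhibitor -> empty phase
  expect_error(
    injection_protocol(data.frame(name = c("oligomycin", "fccp",
                                           "antimycin_rotenone"),
                                  first_cycle_index = c(3, 6, 6)),
                       n_cycles = 12),
    "strictly increasing|zero cycles"
  )
  expect_error(
    injection_protocol(data.frame(name = "uncoupler_x", first_cycle_index = 3),
                       n_cycles = 12),
    "unknown injection"
  )
  expect_error(
    injection_protocol(data.frame(name = "oligomycin", first_cycle_index = 0),
                       n_cycles = 12),
    ">= 1"
  )
})

test_that("ingestion rejects ragged or missing traces", {
  expect_error(make_plate(matrix(c(1, NA, 3, 4), 2)), "missing")
  trace <- data.frame(well_id = "W1", group = "G", condition = "a",
                      cycle_index = c(0, 2), time_min = c(1, 3),
                      ocr = c(1, 2), ecar = c(1, 2))
  expect_error(flux_plate_from_table(trace), "gaps")
})
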