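coef0 <- bioenergetic_coefficients(buffering_power = 0.1)

test_that("the worked ATP example is reproduced through the full path", {
  we <- worked_example_plate()
  ps <- summarize_phases(we$plate, we$protocol)
  rp <- respiratory_params(ps)
  af <- atp_fluxes(ps, rp, coef0)
  # frozen from the spreadsheet-style oracle: ECAR 20, mito 82, coupled 64
  orc <- oracle_atp(20, 82, 64, coef0)
  expect_equal(af$j_atp_glyc_basal, orc$j_glyc, tolerance = 1e-12)
  expect_equal(af$j_atp_ox_basal, orc$j_ox, tolerance = 1e-12)
  expect_equal(af$glycolytic_index, orc$index, tolerance = 1e-12)
  expect_equal(af$j_atp_glyc_basal, 149.242, tolerance = 1e-4)
  expect_equal(af$j_atp_ox_basal, 338.052, tolerance = 1e-4)
  expect_equal(af$glycolytic_index, 30.627, tolerance = 1e-4)
})

test_that("pure-glycolysis limit: zero OCR gives index 100", {
  we <- worked_example_plate(basal = 0, oligo = 0, fccp = 0, aarot = 0,
                             ecar_basal = 20)
  ps <- summarize_phases(we$plate, we$protocol)
  af <- atp_fluxes(ps, respiratory_params(ps), coef0)
  expect_equal(af$j_atp_ox_basal, 0)
  expect_equal(af$glycolytic_index, 100)
})

test_that("zero ECAR clamps the lactate term, leaving the bicarbonate-coupled term", {
  we <- worked_example_plate(ecar_basal = 0, ecar_monensin = 0)
  ps <- summarize_phases(we$plate, we$protocol)
  rp <- respiratory_params(ps)
  af <- atp_fluxes(ps, rp, coef0)
  expect_equal(af$j_atp_glyc_basal, 82 * 2 * coef0$po_glyc)
  expect_true(af$glyc_clamped)
})

test_that("dead well: zero total ATP flags the index as undefined", {
  we <- worked_example_plate(basal = 0, oligo = 0, fccp = 0, aarot = 0,
                             ecar_basal = 0, ecar_monensin = 0)
  ps <- summarize_phases(we$plate, we$protocol)
  af <- atp_fluxes(ps, respiratory_params(ps), coef0)
  expect_true(is.na(af$glycolytic_index))
  expect_true(af$index_undefined)
})

test_that("missing monensin phase drops maximal glycolysis but keeps basal", {
  ocr <- matrix(rep(c(100, 36, 160, 18), each = 3), 1)
  ecar <- matrix(rep(20, 12), 1)
  plate <- flux_plate(data.frame(well_id = "W1", group = "G",
                                 condition = "assay"),
                      cycles = 1:12, ocr = ocr, ecar = ecar,
                      normalised = TRUE)
  protocol <- injection_protocol(
    data.frame(name = c("oligomycin", "fccp", "antimycin_rotenone"),
               first_cycle_index = c(3, 6, 9)),
    n_cycles = 12
  )
  ps <- summarize_phases(plate, protocol)
  af <- atp_fluxes(ps, respiratory_params(ps), coef0)
  expect_true(is.na(af$j_atp_glyc_max))
  expect_true(is.na(af$j_atp_total_max))
  expect_false(is.na(af$j_atp_glyc_basal))
  expect_false(is.na(af$j_atp_ox_max))
})

test_that("total ATP is conserved as glycolytic + oxidative at both states", {
  sim <- simulate_flux_plate(seed = 3)
  ps <- summarize_phases(normalize_plate(sim$plate, sim$od), sim$protocol)
  af <- atp_fluxes(ps, respiratory_params(ps), coef0)
  expect_equal(af$j_atp_total_basal, af$j_atp_glyc_basal + af$j_atp_ox_basal,
               tolerance = 1e-12)
  expect_equal(af$j_atp_total_max, af$j_atp_glyc_max + af$j_atp_ox_max,
               tolerance = 1e-12)
  ok <- !is.na(af$glycolytic_index)
  expect_true(all(af$glycolytic_index[ok] >= 0 &
                    af$glycolytic_index[ok] <= 100))
})

test_that("glycolytic index is monotone in ECAR and anti-monotone in coupled OCR", {
  base <- oracle_atp(20, 82, 64, coef0)$index
  idx_ecar <- vapply(seq(20, 60, by = 5), function(e) {
    we <- worked_example_plate(ecar_basal = e)
    ps <- summarize_phases(we$plate, we$protocol)
    atp_fluxes(ps, respiratory_params(ps), coef0)$glycolytic_index
  }, numeric(1))
  expect_true(all(diff(idx_ecar) >= 0))
  # raising coupled OCR (lower oligomycin plateau) must not raise the index
  idx_coupled <- vapply(c(36, 30, 24, 18), function(ol) {
    we <- worked_example_plate(oligo = ol)
    ps <- summarize_phases(we$plate, we$protocol)
    atp_fluxes(ps, respiratory_params(ps), coef0)$glycolytic_index
  }, numeric(1))
  expect_true(all(diff(idx_coupled) <= 0))
  expect_equal(idx_ecar[1], base, tolerance = 1e-12)
})

test_that("group scope averages per group and can exclude flagged wells", {
  sim <- simulate_flux_plate(wells_per_group = 6, seed = 5)
  ps <- summarize_phases(normalize_plate(sim$plate, sim$od), sim$protocol)
  af <- atp_fluxes(ps, respiratory_params(ps), coef0)
  sc <- group_scope(af, exclude_flagged = FALSE)
  expect_setequal(sc$group, names(default_flux_design()))
  expect_equal(sc$j_atp_total_basal,
               sc$j_atp_glyc_basal + sc$j_atp_ox_basal, tolerance = 1e-9)
})
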