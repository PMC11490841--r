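# Independent oracles, deliberately written as brute-force enumerations /
# spreadsheet-style arithmetic, sharing no code with the implementation.

# Exhaustive isotope-assignment enumeration for small fragments: every atom
# is assigned each of its isotopes in turn; probabilities multiply, shifts
# add. Column j of the correction matrix treats j carbons as tracer
# positions (13C with prob = purity, else 12C).
oracle_correction_column <- function(counts, n_lab, j, iso_abund, purity,
                                     n_rows) {
  atoms <- list()
  for (k in seq_len(j)) {
    atoms[[length(atoms) + 1L]] <- data.frame(shift = c(1, 0),
                                              p = c(purity, 1 - purity))
  }
  for (el in names(counts)) {
    n_nat <- counts[[el]] - if (el == "C") j else 0L
    for (k in seq_len(n_nat)) {
      atoms[[length(atoms) + 1L]] <-
        data.frame(shift = iso_abund[[el]]$shift, p = iso_abund[[el]]$abundance)
    }
  }
  col <- numeric(n_rows)
  if (!length(atoms)) {
    col[1] <- 1
    return(col)
  }
  idx <- expand.grid(lapply(atoms, function(a) seq_len(nrow(a))))
  for (r in seq_len(nrow(idx))) {
    sh <- 0; pr <- 1
    for (a in seq_along(atoms)) {
      row <- idx[r, a]
      sh <- sh + atoms[[a]]$shift[row]
      pr <- pr * atoms[[a]]$p[row]
    }
    if (sh < n_rows) col[sh + 1L] <- col[sh + 1L] + pr
  }
  col
}

oracle_correction_matrix <- function(frag, iso, tail = 4L) {
  n_rows <- frag$n_tracer_carbons + tail + 1L
  sapply(0:frag$n_tracer_carbons, function(j) {
    oracle_correction_column(frag$counts, frag$n_tracer_carbons, j,
                             iso$elements, iso$purity, n_rows)
  })
}

# Benjamini-Hochberg step-up by direct definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  q[ord] <- vapply(seq_len(m), function(i) {
    min(p[ord][i:m] * m / (i:m))
  }, numeric(1))
  pmin(q, 1)
}

# Spreadsheet-style recomputation of the ATP decomposition for one well.
oracle_atp <- function(ecar_basal, ocr_mito, ocr_coupled, coef) {
  f_resp <- 10^(coef$medium_ph - coef$pk1)
  f_resp <- f_resp / (1 + f_resp)
  ppr_total <- ecar_basal / coef$buffering_power
  ppr_from_resp <- f_resp * coef$max_h_per_o2 * ocr_mito
  ppr_from_glyc <- max(ppr_total - ppr_from_resp, 0)
  j_glyc <- ppr_from_glyc * coef$atp_per_lactate +
    ocr_mito * 2 * coef$po_glyc
  j_ox <- ocr_coupled * 2 * coef$po_oxphos + ocr_mito * 2 * coef$po_tca
  list(j_glyc = j_glyc, j_ox = j_ox,
       index = 100 * j_glyc / (j_glyc + j_ox))
}

# Single-well plate whose phase aggregates are exactly the given values,
# for worked-example tests: constant OCR per phase, constant ECAR.
worked_example_plate <- function(basal = 100, oligo = 36, fccp = 160,
                                 aarot = 18, ecar_basal = 20,
                                 ecar_monensin = 45, cycles_per_phase = 3) {
  phases_ocr <- c(basal, oligo, fccp, aarot, aarot)
  phases_ecar <- c(ecar_basal, ecar_basal, ecar_basal, ecar_basal,
                   ecar_monensin)
  ocr <- rep(phases_ocr, each = cycles_per_phase)
  ecar <- rep(phases_ecar, each = cycles_per_phase)
  n <- length(ocr)
  plate <- flux_plate(
    wells = data.frame(well_id = "W1", group = "G", condition = "assay"),
    cycles = seq_len(n), ocr = matrix(ocr, 1), ecar = matrix(ecar, 1),
    normalised = TRUE
  )
  protocol <- injection_protocol(
    data.frame(name = c("oligomycin", "fccp", "antimycin_rotenone",
                        "monensin"),
               first_cycle_index = cycles_per_phase * 1:4),
    n_cycles = n
  )
  list(plate = plate, protocol = protocol)
}

random_small_fragment <- function() {
  # <= 6 atoms total, >= 1 carbon
  repeat {
    counts <- c(C = sample(1:3, 1), H = sample(0:2, 1), N = sample(0:1, 1),
                O = sample(0:1, 1), Si = sample(0:1, 1), S = sample(0:1, 1))
    counts <- counts[counts > 0]
    if (sum(counts) <= 6) break
  }
  fragment_spec("random", counts, n_tracer_carbons = sample(seq_len(counts[["C"]]), 1))
}
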