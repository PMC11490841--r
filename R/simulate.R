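# Simulators for every pipeline stage. Each returns the exact objects the
# analysis functions ingest plus a `synthetic_truth` record (parameters +
# seed) so recovery tests can compare against known ground truth. All draws
# go through set.seed(seed), making outputs reproducible bit-for-bit.

new_truth <- function(kind, params, seed) {
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Serialise / restore simulation ground truth
#'
#' Truth records are written as JSON with 17 significant digits, so doubles
#' round-trip exactly.
#'
#' @param truth a `synthetic_truth` object.
#' @param path file path.
#' @return `read_truth()` returns the restored `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  json <- jsonlite::serializeJSON(unclass(truth), digits = 17)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  structure(obj, class = "synthetic_truth")
}

#' Default stress-test plateau design
#'
#' Phase plateaus (OCR then ECAR, per phase) for a four-line
#' adenoma-to-carcinoma panel: an early-adenoma-like group with low ECAR and
#' a large spare respiratory capacity, and three progressed groups with
#' elevated glycolytic acidification. Values are in instrument units for a
#' well at OD595 = 1.
#'
#' @return named list group -> list(ocr = named vector, ecar = named vector)
#'   over phases `basal`, `oligomycin`, `fccp`, `antimycin_rotenone`,
#'   `monensin`.
#' @export
default_flux_design <- function() {
  ph <- c("basal", "oligomycin", "fccp", "antimycin_rotenone", "monensin")
  mk <- function(ocr, ecar) list(ocr = stats::setNames(ocr, ph),
                                 ecar = stats::setNames(ecar, ph))
  list(
    C1 = mk(c(100, 36, 220, 18, 18), c(12, 20, 20, 8, 28)),
    SB = mk(c(100, 38, 150, 20, 20), c(30, 40, 40, 12, 55)),
    `10C` = mk(c(105, 40, 150, 20, 20), c(32, 42, 42, 12, 58)),
    M = mk(c(130, 45, 175, 22, 22), c(33, 44, 44, 13, 60))
  )
}

#' Simulate a stress-test flux plate
#'
#' Per well: raw OCR/ECAR at each cycle is the group's phase plateau scaled by
#' a well-specific cell-number factor plus additive Gaussian measurement
#' noise; the crystal-violet OD595 shares the same cell-number factor (with
#' small multiplicative reading noise), so OD595 normalisation is meaningful.
#'
#' @param design group -> phase plateaus, as [default_flux_design()].
#' @param wells_per_group technical replicates per group (default 12, within
#'   the 6-15 range typical of 96-well stress tests).
#' @param cycles_per_phase measurement cycles per phase.
#' @param cycle_minutes minutes between cycles.
#' @param noise_sd additive rate noise SD (instrument units).
#' @param cell_factor_sd SD of the log-normal well cell-number factor.
#' @param od_base OD595 of a reference well (cell factor 1).
#' @param od_noise_sd SD of multiplicative OD-reading noise.
#' @param seed RNG seed; same seed, same parameters -> identical output.
#' @return list with `plate` (raw [flux_plate()]), `od` (well_id/od595
#'   data.frame), `protocol` ([injection_protocol()]), `truth`
#'   (`synthetic_truth`).
#' @export
simulate_flux_plate <- function(design = default_flux_design(),
                                wells_per_group = 12L,
                                cycles_per_phase = 3L,
                                cycle_minutes = 6.5,
                                noise_sd = 5,
                                cell_factor_sd = 0.2,
                                od_base = 1,
                                od_noise_sd = 0.01,
                                seed = 1L) {
  stopifnot(length(design) >= 1, cycles_per_phase >= 1, noise_sd >= 0)
  phases <- c("basal", "oligomycin", "fccp", "antimycin_rotenone", "monensin")
  for (g in names(design)) {
    for (ch in c("ocr", "ecar")) {
      v <- design[[g]][[ch]]
      if (!all(phases %in% names(v))) {
        stop("design for group ", g, " lacks ", ch, " plateaus for: ",
             paste(setdiff(phases, names(v)), collapse = ", "), call. = FALSE)
      }
      if (any(v < 0)) {
        stop("validation error: negative plateau in group ", g, call. = FALSE)
      }
    }
  }
  set.seed(seed)
  n_phase <- length(phases)
  n_cyc <- n_phase * cycles_per_phase
  cyc_phase <- rep(phases, each = cycles_per_phase)
  groups <- names(design)
  n_wells <- length(groups) * wells_per_group

  wells <- data.frame(
    well_id = sprintf("W%03d", seq_len(n_wells)),
    group = rep(groups, each = wells_per_group),
    condition = "assay", stringsAsFactors = FALSE
  )
  cell_factor <- exp(stats::rnorm(n_wells, 0, cell_factor_sd))
  ocr <- matrix(0, n_wells, n_cyc)
  ecar <- matrix(0, n_wells, n_cyc)
  for (w in seq_len(n_wells)) {
    d <- design[[wells$group[w]]]
    mu_ocr <- d$ocr[cyc_phase] * cell_factor[w]
    mu_ecar <- d$ecar[cyc_phase] * cell_factor[w]
    ocr[w, ] <- mu_ocr + stats::rnorm(n_cyc, 0, noise_sd)
    ecar[w, ] <- mu_ecar + stats::rnorm(n_cyc, 0, noise_sd)
  }
  od <- data.frame(
    well_id = wells$well_id,
    od595 = od_base * cell_factor * exp(stats::rnorm(n_wells, 0, od_noise_sd))
  )
  protocol <- injection_protocol(
    data.frame(name = phases[-1],
               first_cycle_index = cycles_per_phase * seq_len(n_phase - 1L)),
    n_cycles = n_cyc
  )
  plate <- flux_plate(wells, cycles = cycle_minutes * seq_len(n_cyc),
                      ocr = ocr, ecar = ecar, normalised = FALSE)
  truth <- new_truth(
    "flux_plate",
    list(design = design, wells_per_group = wells_per_group,
         cycles_per_phase = cycles_per_phase, noise_sd = noise_sd,
         cell_factor_sd = cell_factor_sd, od_base = od_base,
         od_noise_sd = od_noise_sd, cell_factor = cell_factor),
    seed
  )
  list(plate = plate, od = od, protocol = protocol, truth = truth)
}

#' Default ground-truth labelling patterns
#'
#' Plausible MIDs for a uniformly-13C-glutamine trace: glutamine mostly m+5,
#' glutamate m+5 from glutaminolysis, TCA intermediates dominated by m+4
#' (oxidative anaplerosis) with small m+5/m+3 contributions.
#'
#' @return named list metabolite -> MID fraction vector (length
#'   n_tracer_carbons + 1 of the packaged registry entry).
#' @export
default_truth_mids <- function() {
  list(
    glutamine = c(0.08, 0.01, 0.01, 0.01, 0.04, 0.85),
    glutamate = c(0.25, 0.02, 0.03, 0.05, 0.10, 0.55),
    alpha_ketoglutarate = c(0.30, 0.02, 0.03, 0.05, 0.10, 0.50),
    succinate = c(0.40, 0.03, 0.07, 0.10, 0.40),
    fumarate = c(0.42, 0.03, 0.07, 0.10, 0.38),
    malate = c(0.45, 0.03, 0.07, 0.10, 0.35),
    aspartate = c(0.50, 0.03, 0.07, 0.10, 0.30),
    citrate = c(0.50, 0.02, 0.08, 0.05, 0.25, 0.07, 0.03)
  )
}

#' Simulate GC/MS labelling measurements
#'
#' Forward model shared with the correction stage: measured intensities are
#' `abundance * (correction_matrix %*% truth_mid)` perturbed by multiplicative
#' log-normal noise, plus an internal-standard channel.
#'
#' @param truth_mids named list metabolite -> ground-truth MID (length must
#'   match the registry fragment's `n_tracer_carbons + 1`).
#' @param registry [fragment_registry()] list covering the metabolites.
#' @param abundances named vector of total-ion abundances (arbitrary units);
#'   scalar recycled.
#' @param replicates biological replicates to draw.
#' @param noise_sdlog SD of the log-normal intensity noise (0.05 = ~5%).
#' @param is_intensity internal-standard channel intensity.
#' @param is_noise_sdlog log-normal noise on the internal standard.
#' @param cell_count cells per plate for abundance normalisation.
#' @param iso [isotope_table()] used in the forward model.
#' @param seed RNG seed.
#' @return list with `intensities` (long data.frame: metabolite, sample,
#'   mass_shift, intensity), `internal_standard` (sample, intensity),
#'   `cell_count`, `truth`.
#' @export
simulate_labelling <- function(truth_mids = default_truth_mids(),
                               registry = fragment_registry(),
                               abundances = 1e6,
                               replicates = 3L,
                               noise_sdlog = 0.05,
                               is_intensity = 1e5,
                               is_noise_sdlog = 0.02,
                               cell_count = 1e6,
                               iso = isotope_table(),
                               seed = 1L) {
  mets <- names(truth_mids)
  missing_frag <- setdiff(mets, names(registry))
  if (length(missing_frag)) {
    stop("metabolite(s) not in the fragment registry: ",
         paste(missing_frag, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(abundances))) {
    abundances <- stats::setNames(rep(abundances, length.out = length(mets)),
                                  mets)
  }
  set.seed(seed)
  rows <- list()
  for (met in mets) {
    frag <- registry[[met]]
    x <- truth_mids[[met]]
    if (length(x) != frag$n_tracer_carbons + 1L) {
      stop("truth MID for ", met, " has length ", length(x), ", expected ",
           frag$n_tracer_carbons + 1L, call. = FALSE)
    }
    x <- as_mid(x)
    cm <- build_correction_matrix(frag, iso)
    clean <- abundances[[met]] * as.vector(cm$matrix %*% x)
    for (r in seq_len(replicates)) {
      noisy <- clean * exp(stats::rnorm(length(clean), 0, noise_sdlog))
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = met, sample = sprintf("rep%d", r),
        mass_shift = seq_along(clean) - 1L, intensity = noisy,
        stringsAsFactors = FALSE
      )
    }
  }
  is_tab <- data.frame(
    sample = sprintf("rep%d", seq_len(replicates)),
    intensity = is_intensity * exp(stats::rnorm(replicates, 0, is_noise_sdlog))
  )
  truth <- new_truth(
    "labelling",
    list(truth_mids = truth_mids, abundances = as.list(abundances),
         replicates = replicates, noise_sdlog = noise_sdlog,
         is_intensity = is_intensity, is_noise_sdlog = is_noise_sdlog,
         cell_count = cell_count, purity = iso$purity),
    seed
  )
  list(intensities = do.call(rbind, rows), internal_standard = is_tab,
       cell_count = cell_count, truth = truth)
}

#' Simulate a proteomics table and growth curves
#'
#' Proteins get log-normal abundances (per-protein log2 baseline drawn once,
#' shared across samples) with group effects added on the log2 scale for the
#' spiked proteins; confluence follows a logistic curve per condition with
#' multiplicative observation noise, and an optional apoptosis-reporter
#' green-object count.
#'
#' @param n_proteins number of proteins.
#' @param groups group labels (two-group design).
#' @param n_per_group samples per group.
#' @param effects data.frame(`protein` index, `log2fc`) of true effects
#'   applied to the second group; empty for a pure-null table.
#' @param base_log2_mean,base_log2_sd distribution of per-protein baselines.
#' @param noise_sd per-measurement log2 noise SD.
#' @param growth_hours,growth_rates,confluence0,capacity,growth_noise_sdlog
#'   logistic confluence-curve settings (rates per hour, named per condition).
#' @param seed RNG seed.
#' @return list with `proteome` (`mat`, `groups`), `growth` (long data.frame:
#'   condition, well, time_h, confluence, green_count), `truth`.
#' @export
simulate_omics <- function(n_proteins = 2000L,
                           groups = c("C1", "M"),
                           n_per_group = 3L,
                           effects = data.frame(protein = integer(),
                                                log2fc = numeric()),
                           base_log2_mean = 10, base_log2_sd = 1.5,
                           noise_sd = 0.1,
                           growth_hours = seq(0, 96, by = 4),
                           growth_rates = c(control = 0.05, treated = 0.02),
                           confluence0 = 5, capacity = 95,
                           growth_noise_sdlog = 0.03,
                           seed = 1L) {
  stopifnot(n_proteins >= 1, length(groups) == 2, n_per_group >= 2)
  if (nrow(effects) &&
      (any(effects$protein < 1) || any(effects$protein > n_proteins))) {
    stop("validation error: effect protein index out of range", call. = FALSE)
  }
  set.seed(seed)
  n_samp <- 2L * n_per_group
  grp <- rep(groups, each = n_per_group)
  base <- stats::rnorm(n_proteins, base_log2_mean, base_log2_sd)
  eff <- numeric(n_proteins)
  if (nrow(effects)) eff[effects$protein] <- effects$log2fc
  lg <- matrix(base, n_proteins, n_samp) +
    outer(eff, as.numeric(grp == groups[2])) +
    matrix(stats::rnorm(n_proteins * n_samp, 0, noise_sd), n_proteins)
  mat <- 2^lg
  rownames(mat) <- sprintf("P%05d", seq_len(n_proteins))
  colnames(mat) <- paste0(grp, "_", rep(seq_len(n_per_group), 2L))

  growth <- do.call(rbind, lapply(names(growth_rates), function(cond) {
    r <- growth_rates[[cond]]
    mu <- capacity / (1 + ((capacity - confluence0) / confluence0) *
                        exp(-r * growth_hours))
    do.call(rbind, lapply(1:3, function(w) {
      data.frame(
        condition = cond, well = sprintf("%s_w%d", cond, w),
        time_h = growth_hours,
        confluence = mu * exp(stats::rnorm(length(mu), 0, growth_noise_sdlog)),
        green_count = stats::rpois(length(mu), lambda = 2 + 0.01 * mu),
        stringsAsFactors = FALSE
      )
    }))
  }))

  truth <- new_truth(
    "omics",
    list(n_proteins = n_proteins, groups = groups, n_per_group = n_per_group,
         effects = effects, base_log2_mean = base_log2_mean,
         base_log2_sd = base_log2_sd, noise_sd = noise_sd,
         growth_rates = as.list(growth_rates), confluence0 = confluence0,
         capacity = capacity, growth_noise_sdlog = growth_noise_sdlog),
    seed
  )
  list(proteome = list(mat = mat, groups = grp), growth = growth,
       truth = truth)
}
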