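#' Plate-format extracellular-flux traces
#'
#' Container for a mitochondrial stress-test run: per-well oxygen consumption
#' (OCR, pmol O2/min) and extracellular acidification (ECAR, mpH/min) on a
#' shared measurement-cycle grid. Rates are raw instrument output until
#' [normalize_plate()] divides them by the per-well crystal-violet OD595.
#'
#' @param wells data.frame with columns `well_id`, `group`, `condition`.
#' @param cycles numeric vector of measurement times (min), strictly increasing.
#' @param ocr,ecar numeric matrices, wells x cycles, rownames = `well_id`.
#' @param normalised logical; whether rates are already per OD595 unit.
#'
#' @return An object of class `flux_plate`.
#' @export
flux_plate <- function(wells, cycles, ocr, ecar, normalised = FALSE) {
  wells <- as.data.frame(wells)
  need <- c("well_id", "group", "condition")
  miss <- setdiff(need, names(wells))
  if (length(miss)) {
    stop("`wells` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(wells$well_id)) stop("duplicate well_id", call. = FALSE)
  cycles <- as.numeric(cycles)
  if (is.unsorted(cycles, strictly = TRUE)) {
    stop("cycle times must be strictly increasing", call. = FALSE)
  }
  ocr <- as.matrix(ocr); ecar <- as.matrix(ecar)
  n_w <- nrow(wells); n_c <- length(cycles)
  for (nm in c("ocr", "ecar")) {
    m <- get(nm)
    if (!all(dim(m) == c(n_w, n_c))) {
      stop(sprintf("`%s` must be %d wells x %d cycles", nm, n_w, n_c),
           call. = FALSE)
    }
    if (anyNA(m) || !all(is.finite(m))) {
      stop(sprintf("`%s` contains missing/non-finite values; missing cycles ",
                   nm), "are an ingestion error", call. = FALSE)
    }
  }
  rownames(ocr) <- rownames(ecar) <- wells$well_id
  structure(
    list(wells = wells, cycles = cycles, ocr = ocr, ecar = ecar,
         normalised = isTRUE(normalised)),
    class = "flux_plate"
  )
}

#' @export
print.flux_plate <- function(x, ...) {
  cat(sprintf("flux_plate: %d wells x %d cycles (%s), groups: %s\n",
              nrow(x$wells), length(x$cycles),
              if (x$normalised) "normalised per OD595" else "raw",
              paste(unique(x$wells$group), collapse = ", ")))
  invisible(x)
}

#' Stress-test injection protocol
#'
#' Ordered injections partition the cycle grid into half-open phases
#' `[first_cycle_i, first_cycle_{i+1})`; cycles before the first injection are
#' the basal phase. Cycle indices are 0-based, matching the trace files.
#'
#' @param events data.frame with columns `name` (one of `oligomycin`, `fccp`,
#'   `antimycin_rotenone`, `monensin`) and `first_cycle_index` (0-based,
#'   strictly increasing, all >= 1 so a basal phase exists). An optional
#'   `concentration` column is carried as metadata.
#' @param n_cycles total number of measurement cycles on the plate.
#'
#' @return Object of class `injection_protocol`: a data.frame of phases with
#'   `phase`, `first_cycle`, `last_cycle` (0-based, inclusive).
#' @export
injection_protocol <- function(events, n_cycles) {
  events <- as.data.frame(events)
  known <- c("oligomycin", "fccp", "antimycin_rotenone", "monensin")
  if (!all(c("name", "first_cycle_index") %in% names(events))) {
    stop("`events` needs columns `name` and `first_cycle_index`", call. = FALSE)
  }
  bad <- setdiff(events$name, known)
  if (length(bad)) {
    stop("unknown injection name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx <- as.integer(events$first_cycle_index)
  if (any(idx < 1L) || is.unsorted(idx, strictly = TRUE)) {
    stop("first_cycle_index must be strictly increasing and >= 1 ",
         "(basal cycles precede the first injection)", call. = FALSE)
  }
  if (max(idx) > n_cycles - 1L) {
    stop("injection beyond the last cycle", call. = FALSE)
  }
  first <- c(0L, idx)
  last <- c(idx - 1L, n_cycles - 1L)
  phases <- data.frame(phase = c("basal", events$name),
                       first_cycle = first, last_cycle = last,
                       stringsAsFactors = FALSE)
  if (any(phases$last_cycle < phases$first_cycle)) {
    empty <- phases$phase[phases$last_cycle < phases$first_cycle]
    stop("protocol error: phase(s) with zero cycles: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  structure(phases, class = c("injection_protocol", "data.frame"),
            n_cycles = as.integer(n_cycles))
}

#' Normalise a flux plate to cell number
#'
#' Divides every raw OCR/ECAR measurement by the well's crystal-violet OD595,
#' the plate-reader proxy for adherent cell number.
#'
#' @param plate A raw [flux_plate()].
#' @param od data.frame with columns `well_id`, `od595`; must cover every well
#'   on the plate, all OD595 strictly positive.
#' @return The plate with rates in pmol O2/min (or mpH/min) per OD595 unit and
#'   `normalised = TRUE`.
#' @export
#' @examples
#' sim <- simulate_flux_plate(seed = 1)
#' norm <- normalize_plate(sim$plate, sim$od)
normalize_plate <- function(plate, od) {
  stopifnot(inherits(plate, "flux_plate"))
  if (plate$normalised) stop("plate is already normalised", call. = FALSE)
  od <- as.data.frame(od)
  if (!all(c("well_id", "od595") %in% names(od))) {
    stop("`od` needs columns `well_id` and `od595`", call. = FALSE)
  }
  miss <- setdiff(plate$wells$well_id, od$well_id)
  if (length(miss)) {
    stop("ingestion error: OD595 missing for well(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  v <- od$od595[match(plate$wells$well_id, od$well_id)]
  bad <- plate$wells$well_id[!(is.finite(v) & v > 0)]
  if (length(bad)) {
    stop("validation error: OD595 <= 0 (empty/failed well?) for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  plate$ocr <- plate$ocr / v
  plate$ecar <- plate$ecar / v
  plate$normalised <- TRUE
  plate
}

default_aggregators <- function() {
  list(basal = "mean", oligomycin = "min", fccp = "max",
       antimycin_rotenone = "min", monensin = "max")
}

apply_agg <- function(x, how) {
  switch(how,
         mean = mean(x), min = min(x), max = max(x), median = stats::median(x),
         last = x[length(x)],
         stop("unknown aggregator: ", how, call. = FALSE))
}

#' Summarise stress-test phases per well
#'
#' Collapses each protocol phase to one rate per well. Defaults follow common
#' stress-test practice: basal = mean of basal cycles; oligomycin and
#' antimycin/rotenone = phase minimum (full inhibition); FCCP and monensin =
#' phase extremum (peak uncoupled respiration / peak glycolytic acidification).
#' The choice is recorded in the output's `aggregators` attribute.
#'
#' @param plate A normalised [flux_plate()].
#' @param protocol An [injection_protocol()] covering the plate's cycle grid.
#' @param aggregators Named list phase -> one of `"mean"`, `"min"`, `"max"`,
#'   `"median"`, `"last"`; unnamed phases fall back to the defaults.
#'
#' @return data.frame (class `phase_summary`) with one row per well:
#'   `basal_ocr`, `oligo_ocr`, `fccp_ocr`, `aarot_ocr`, `basal_ecar`,
#'   `monensin_ecar` (NA when the protocol lacks monensin).
#' @export
summarize_phases <- function(plate, protocol, aggregators = list()) {
  stopifnot(inherits(plate, "flux_plate"), inherits(protocol, "injection_protocol"))
  if (!plate$normalised) {
    stop("plate must be normalised before phase summarisation", call. = FALSE)
  }
  if (attr(protocol, "n_cycles") != length(plate$cycles)) {
    stop("protocol error: protocol cycle count does not match the plate",
         call. = FALSE)
  }
  agg <- utils::modifyList(default_aggregators(), aggregators)
  phase_cols <- function(ph) {
    r <- protocol[protocol$phase == ph, ]
    if (!nrow(r)) return(NULL)
    seq.int(r$first_cycle + 1L, r$last_cycle + 1L)
  }
  agg_phase <- function(mat, ph) {
    cols <- phase_cols(ph)
    if (is.null(cols)) return(rep(NA_real_, nrow(mat)))
    apply(mat[, cols, drop = FALSE], 1L, apply_agg, how = agg[[ph]])
  }
  need <- c("basal", "oligomycin", "fccp", "antimycin_rotenone")
  miss <- setdiff(need, protocol$phase)
  if (length(miss)) {
    stop("protocol error: stress-test phase(s) missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    well_id = plate$wells$well_id,
    group = plate$wells$group,
    condition = plate$wells$condition,
    basal_ocr = agg_phase(plate$ocr, "basal"),
    oligo_ocr = agg_phase(plate$ocr, "oligomycin"),
    fccp_ocr = agg_phase(plate$ocr, "fccp"),
    aarot_ocr = agg_phase(plate$ocr, "antimycin_rotenone"),
    basal_ecar = agg_phase(plate$ecar, "basal"),
    monensin_ecar = agg_phase(plate$ecar, "monensin"),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("phase_summary", "data.frame"), aggregators = agg)
}
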