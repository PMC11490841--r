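# Validated ingestion of the pipeline's CSV dialects. Comma-separated, UTF-8,
# header row required, `.` decimal. Cycle and mass-shift indices are 0-based
# throughout.

table_schemas <- function() {
  list(
    flux_trace = list(
      cols = c(well_id = "character", group = "character",
               condition = "character", cycle_index = "integer",
               time_min = "numeric", ocr = "numeric", ecar = "numeric"),
      key = c("well_id", "cycle_index")
    ),
    od = list(
      cols = c(well_id = "character", od595 = "numeric"),
      key = "well_id"
    ),
    intensities = list(
      cols = c(metabolite = "character", sample = "character",
               mass_shift = "integer", intensity = "numeric"),
      key = c("metabolite", "sample", "mass_shift")
    ),
    proteome = list(cols = c(protein = "character"), key = "protein"),
    sample_sheet = list(
      cols = c(sample = "character", group = "character"),
      key = "sample"
    ),
    growth = list(
      cols = c(well = "character", time = "numeric", confluence = "numeric"),
      key = c("well", "time")
    )
  )
}

#' Read and validate a pipeline input table
#'
#' @param path CSV path (comma-separated, header row, `.` decimal).
#' @param schema one of `"flux_trace"`, `"od"`, `"intensities"`,
#'   `"proteome"`, `"sample_sheet"`, `"growth"`. The `proteome` schema
#'   requires a `protein` column; all remaining columns are treated as
#'   numeric sample abundances.
#' @return validated data.frame.
#' @export
read_table <- function(path, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) {
    stop("unknown schema: ", schema, call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- schemas[[schema]]
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(names(sc$cols), names(d))
  if (length(miss)) {
    stop("schema error in ", basename(path), ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  num_cols <- names(sc$cols)[sc$cols %in% c("numeric", "integer")]
  if (schema == "proteome") {
    num_cols <- setdiff(names(d), "protein")
  }
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) & d[[col]] != "")
    if (length(bad) || anyNA(v)) {
      loc <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stop("parse error in ", basename(path), ": non-numeric value in `",
           col, "` at data row ", loc, call. = FALSE)
    }
    d[[col]] <- v
  }
  if (!is.null(sc$key)) {
    if (anyDuplicated(d[sc$key])) {
      stop("integrity error in ", basename(path), ": duplicated key (",
           paste(sc$key, collapse = ", "), ")", call. = FALSE)
    }
  }
  d
}

#' Assemble a flux plate from tidy trace and OD tables
#'
#' @param trace data.frame in the `flux_trace` schema (0-based `cycle_index`).
#' @return [flux_plate()] (raw).
#' @export
flux_plate_from_table <- function(trace) {
  wells <- unique(trace[c("well_id", "group", "condition")])
  cyc <- sort(unique(trace$cycle_index))
  if (!identical(as.integer(cyc), seq_along(cyc) - 1L)) {
    stop("cycle_index must cover 0..n-1 without gaps", call. = FALSE)
  }
  times <- vapply(cyc, function(ci) {
    unique(trace$time_min[trace$cycle_index == ci])[1]
  }, numeric(1))
  n_w <- nrow(wells); n_c <- length(cyc)
  ocr <- matrix(NA_real_, n_w, n_c)
  ecar <- matrix(NA_real_, n_w, n_c)
  wi <- match(trace$well_id, wells$well_id)
  ci <- trace$cycle_index + 1L
  ocr[cbind(wi, ci)] <- trace$ocr
  ecar[cbind(wi, ci)] <- trace$ecar
  if (anyNA(ocr) || anyNA(ecar)) {
    stop("ingestion error: missing (well, cycle) measurements", call. = FALSE)
  }
  flux_plate(wells, times, ocr, ecar, normalised = FALSE)
}

#' Write a flux plate to the tidy trace CSV dialect
#' @param plate a [flux_plate()].
#' @param path output CSV path.
#' @export
write_flux_table <- function(plate, path) {
  stopifnot(inherits(plate, "flux_plate"))
  n_c <- length(plate$cycles)
  d <- data.frame(
    well_id = rep(plate$wells$well_id, each = n_c),
    group = rep(plate$wells$group, each = n_c),
    condition = rep(plate$wells$condition, each = n_c),
    cycle_index = rep(seq_len(n_c) - 1L, times = nrow(plate$wells)),
    time_min = rep(plate$cycles, times = nrow(plate$wells)),
    ocr = as.vector(t(plate$ocr)),
    ecar = as.vector(t(plate$ecar))
  )
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an injection protocol from YAML
#'
#' Expects a top-level `injections:` list of `name` / `first_cycle_index`
#' (0-based) entries and an `n_cycles` field.
#' @param path YAML file.
#' @return [injection_protocol()].
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$injections) || is.null(y$n_cycles)) {
    stop("protocol file needs `injections` and `n_cycles`", call. = FALSE)
  }
  ev <- do.call(rbind, lapply(y$injections, function(e) {
    data.frame(name = e$name, first_cycle_index = e$first_cycle_index,
               stringsAsFactors = FALSE)
  }))
  injection_protocol(ev, n_cycles = y$n_cycles)
}
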