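#' Natural-abundance isotope table
#'
#' Per-element mass-shift distributions (integer Da above the monoisotopic
#' mass, natural abundance fraction) plus the tracer element and tracer
#' isotopic purity. Defaults are the standard IUPAC natural abundances for
#' the elements occurring in TBDMS-derivatized metabolite fragments
#' (C, H, N, O, Si, S), with carbon as the tracer and 0.99 purity, typical of
#' commercial uniformly-13C tracers.
#'
#' @param elements named list: element -> data.frame(`shift`, `abundance`).
#' @param tracer_element element symbol carrying the label (default `"C"`).
#' @param purity tracer isotopic purity in (0, 1].
#' @return Object of class `isotope_table`.
#' @export
#' @examples
#' iso <- isotope_table()
#' iso$elements$C
isotope_table <- function(elements = default_isotope_abundances(),
                          tracer_element = "C", purity = 0.99) {
  for (el in names(elements)) {
    d <- elements[[el]]
    if (!all(c("shift", "abundance") %in% names(d))) {
      stop("element ", el, ": need columns `shift`, `abundance`", call. = FALSE)
    }
    if (any(d$shift < 0) || any(d$shift != floor(d$shift))) {
      stop("element ", el, ": mass shifts must be non-negative integers",
           call. = FALSE)
    }
    if (abs(sum(d$abundance) - 1) > 1e-9 || any(d$abundance < 0)) {
      stop("element ", el, ": abundances must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  if (!tracer_element %in% names(elements)) {
    stop("tracer element ", tracer_element, " not in the table", call. = FALSE)
  }
  if (!(purity > 0 && purity <= 1)) {
    stop("tracer purity must lie in (0, 1]", call. = FALSE)
  }
  structure(list(elements = elements, tracer_element = tracer_element,
                 purity = purity),
            class = "isotope_table")
}

#' @rdname isotope_table
#' @export
default_isotope_abundances <- function() {
  list(
    C  = data.frame(shift = c(0, 1), abundance = c(0.9893, 0.0107)),
    H  = data.frame(shift = c(0, 1), abundance = c(0.999885, 0.000115)),
    N  = data.frame(shift = c(0, 1), abundance = c(0.99636, 0.00364)),
    O  = data.frame(shift = c(0, 1, 2), abundance = c(0.99757, 0.00038, 0.00205)),
    Si = data.frame(shift = c(0, 1, 2), abundance = c(0.92223, 0.04685, 0.03092)),
    S  = data.frame(shift = c(0, 1, 2, 4),
                    abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
  )
}

#' Parse an elemental formula
#'
#' `"C11H26NO2Si2"` -> `c(C = 11, H = 26, N = 1, O = 2, Si = 2)`. Repeated
#' element symbols are summed.
#'
#' @param formula character scalar, Hill-style element counts.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts) || paste(parts, collapse = "") != formula) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- sub("^[A-Za-z]+", "", parts)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  tapply(n, el, sum)[unique(el)]
}

#' Derivatized-fragment specification
#'
#' A GC/MS fragment of a metabolite: its full elemental formula (including
#' derivatization atoms, e.g. the C/H/Si a TBDMS group adds) and how many of
#' its carbons come from the metabolite backbone and can therefore carry
#' tracer label.
#'
#' @param metabolite metabolite name.
#' @param formula element counts: either a named numeric vector or a formula
#'   string for [parse_formula()].
#' @param n_tracer_carbons number of label-accessible carbons
#'   (>= 1, <= total C).
#' @param note free-text provenance/derivatization note.
#' @return Object of class `fragment_spec`.
#' @export
#' @examples
#' fragment_spec("glutamate", "C18H38NO4Si3", 5, "TBDMS [M-57]+")
fragment_spec <- function(metabolite, formula, n_tracer_carbons, note = "") {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  counts <- counts[counts > 0]
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  n_c <- if ("C" %in% names(counts)) unname(counts[["C"]]) else 0L
  if (n_tracer_carbons < 1) {
    stop("validation error: n_tracer_carbons must be >= 1 (fragment ",
         metabolite, " cannot carry tracer)", call. = FALSE)
  }
  if (n_tracer_carbons > n_c) {
    stop("validation error: n_tracer_carbons (", n_tracer_carbons,
         ") exceeds the fragment's carbon count (", n_c, ")", call. = FALSE)
  }
  structure(list(metabolite = metabolite, counts = counts,
                 n_tracer_carbons = as.integer(n_tracer_carbons),
                 note = note),
            class = "fragment_spec")
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat(sprintf("fragment_spec: %s [%s], %d tracer carbons%s\n", x$metabolite,
              paste0(names(x$counts), x$counts, collapse = ""),
              x$n_tracer_carbons,
              if (nzchar(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

#' Fragment registry
#'
#' Loads a registry of fragment specifications from CSV (columns `metabolite`,
#' `formula`, `n_tracer_carbons`, `note`). The packaged default
#' (`inst/extdata/fragment_registry.csv`) holds curated TBDMS [M-57]+ fragment
#' formulas for the TCA-cycle intermediates and amino acids typically
#' quantified in 13C-tracing of tumour cells; entries are editable defaults
#' and should be checked against the local GC/MS method.
#'
#' @param path CSV path; default is the packaged registry.
#' @return named list of [fragment_spec()] objects.
#' @export
fragment_registry <- function(path = system.file("extdata",
                                                 "fragment_registry.csv",
                                                 package = "oncoflux")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "formula", "n_tracer_carbons")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("registry missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(d$note)) d$note <- ""
  specs <- lapply(seq_len(nrow(d)), function(i) {
    fragment_spec(d$metabolite[i], d$formula[i], d$n_tracer_carbons[i],
                  d$note[i])
  })
  names(specs) <- d$metabolite
  specs
}
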