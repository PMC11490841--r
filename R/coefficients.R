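#' Bioenergetic conversion coefficients
#'
#' Constants that convert cell-number-normalised extracellular-flux rates
#' (OCR, ECAR) into ATP production rates attributed to glycolysis and
#' oxidative phosphorylation. Defaults correspond to glucose oxidation in
#' bicarbonate-buffered assay medium at 37 degrees C.
#'
#' The decomposition needs: the medium buffering power to turn ECAR (mpH/min)
#' into a total proton production rate; the CO2/bicarbonate equilibrium
#' (`medium_ph`, `pk1`, `max_h_per_o2`) to subtract respiratory acidification;
#' the ATP yield per lactate exported (`atp_per_lactate`); and P/O ratios for
#' the glycolytic substrate-level term coupled to pyruvate oxidation
#' (`po_glyc`), oxidative phosphorylation proper (`po_oxphos`) and TCA-cycle
#' substrate-level phosphorylation (`po_tca`).
#'
#' @param buffering_power Medium buffering power, mpH per pmol H+ per well.
#'   In strict mode this must be supplied explicitly (it is medium-specific).
#' @param medium_ph Assay medium pH.
#' @param pk1 First pKa of carbonic acid at assay temperature.
#' @param max_h_per_o2 Maximal H+ released per O2 consumed during complete
#'   substrate oxidation (1.0 for glucose).
#' @param atp_per_lactate ATP per lactate from pyruvate reduction (1.0).
#' @param po_glyc P/O ratio of glycolytic ATP coupled to pyruvate oxidation
#'   (2 ATP per glucose / 12 O = 0.167).
#' @param po_oxphos P/O ratio of oxidative phosphorylation (2.486 for glucose).
#' @param po_tca P/O ratio of TCA-cycle substrate-level phosphorylation (0.121).
#' @param strict If `TRUE`, require `buffering_power` to be given explicitly.
#'
#' @return An object of class `bioenergetic_coefficients` (a validated named
#'   list), serialisable with [coefficients_to_list()] /
#'   [bioenergetic_coefficients_from_list()].
#' @export
#' @examples
#' coef <- bioenergetic_coefficients(buffering_power = 0.1)
#' coef$po_oxphos
bioenergetic_coefficients <- function(buffering_power = 0.1,
                                      medium_ph = 7.4,
                                      pk1 = 6.093,
                                      max_h_per_o2 = 1.0,
                                      atp_per_lactate = 1.0,
                                      po_glyc = 0.167,
                                      po_oxphos = 2.486,
                                      po_tca = 0.121,
                                      strict = FALSE) {
  if (strict && missing(buffering_power)) {
    stop("strict mode: `buffering_power` must be supplied explicitly ",
         "(it depends on the assay medium)", call. = FALSE)
  }
  coef <- list(
    buffering_power = buffering_power, medium_ph = medium_ph, pk1 = pk1,
    max_h_per_o2 = max_h_per_o2, atp_per_lactate = atp_per_lactate,
    po_glyc = po_glyc, po_oxphos = po_oxphos, po_tca = po_tca
  )
  bad <- vapply(coef, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v <= 0, logical(1))
  if (any(bad)) {
    stop("bioenergetic coefficients must be strictly positive scalars; bad: ",
         paste(names(coef)[bad], collapse = ", "), call. = FALSE)
  }
  structure(coef, class = "bioenergetic_coefficients")
}

#' @export
print.bioenergetic_coefficients <- function(x, ...) {
  cat("Bioenergetic coefficients:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @rdname bioenergetic_coefficients
#' @param coef A `bioenergetic_coefficients` object.
#' @export
coefficients_to_list <- function(coef) {
  stopifnot(inherits(coef, "bioenergetic_coefficients"))
  unclass(coef)
}

#' @rdname bioenergetic_coefficients
#' @param x A named list, e.g. parsed from YAML/JSON config.
#' @export
bioenergetic_coefficients_from_list <- function(x) {
  do.call(bioenergetic_coefficients, x)
}
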