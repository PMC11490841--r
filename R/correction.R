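# Forward model: the measured mass-shift spectrum of a fragment is the
# convolution of (i) a tracer-purity binomial over the labelled positions,
# (ii) the natural-abundance distribution of the remaining tracer-element
# atoms and (iii) the natural-abundance distributions of all other elements.

conv_trunc <- function(a, b, maxlen) {
  # linear convolution of probability vectors, truncated to maxlen entries
  n <- min(length(a) + length(b) - 1L, maxlen)
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1L)
    if (jmax >= 1L) {
      idx <- i:(i + jmax - 1L)
      out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
    }
  }
  out
}

element_shift_dist <- function(iso_df, n_atoms, maxlen) {
  # mass-shift distribution of n_atoms iid atoms of one element
  if (n_atoms == 0L) return(1)
  single <- numeric(max(iso_df$shift) + 1L)
  single[iso_df$shift + 1L] <- iso_df$abundance
  out <- 1
  for (i in seq_len(n_atoms)) out <- conv_trunc(out, single, maxlen)
  out
}

#' Build a natural-abundance correction matrix
#'
#' Column `j` (0-based, `j = 0..n_tracer_carbons`) is the theoretical
#' mass-shift distribution of the fragment when exactly `j` backbone carbons
#' are tracer-labelled: a binomial over the `j` labelled positions at the
#' tracer purity (an impure position contributes no shift), convolved with the
#' natural-abundance distribution of the remaining carbons and of every
#' non-carbon element in the fragment. Rows run over observed mass shifts
#' `0..n_tracer_carbons + tail`; probability mass pushed beyond the last row
#' by heavy Si/S/O isotopes is truncated and recorded.
#'
#' @param frag A [fragment_spec()].
#' @param iso An [isotope_table()].
#' @param tail extra rows beyond `n_tracer_carbons` (default 4) to capture
#'   heavy-isotope envelopes of the derivatization atoms.
#' @return Object of class `correction_matrix`: list with `matrix`
#'   ((tail+N+1) x (N+1), dimnames `m+i` / `lab_j`), `truncated_mass` per
#'   column, `condition_number`, and the generating `fragment`/`purity`.
#' @export
#' @examples
#' cm <- build_correction_matrix(
#'   fragment_spec("glycine", "C10H24NO2Si2", 2, "TBDMS [M-57]+"),
#'   isotope_table())
#' round(cm$matrix, 4)
build_correction_matrix <- function(frag, iso = isotope_table(), tail = 4L) {
  stopifnot(inherits(frag, "fragment_spec"), inherits(iso, "isotope_table"))
  miss <- setdiff(names(frag$counts), names(iso$elements))
  if (length(miss)) {
    stop("configuration error: isotope table lacks element(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n_lab <- frag$n_tracer_carbons
  tracer <- iso$tracer_element
  n_rows <- n_lab + as.integer(tail) + 1L
  counts <- frag$counts

  # natural-abundance envelope of everything except the labelled positions
  nat_other <- 1
  for (el in names(counts)) {
    if (el == tracer) next
    nat_other <- conv_trunc(nat_other,
                            element_shift_dist(iso$elements[[el]], counts[[el]],
                                               n_rows), n_rows)
  }

  n_tracer_total <- if (tracer %in% names(counts)) counts[[tracer]] else 0L
  mat <- matrix(0, nrow = n_rows, ncol = n_lab + 1L)
  trunc_mass <- numeric(n_lab + 1L)
  for (j in 0:n_lab) {
    lab_part <- stats::dbinom(0:j, j, iso$purity)     # shift from labelled C
    nat_c <- element_shift_dist(iso$elements[[tracer]],
                                n_tracer_total - j, n_rows)
    col <- conv_trunc(conv_trunc(lab_part, nat_c, n_rows), nat_other, n_rows)
    mat[seq_along(col), j + 1L] <- col
    trunc_mass[j + 1L] <- 1 - sum(col)
  }
  dimnames(mat) <- list(paste0("m+", 0:(n_rows - 1L)),
                        paste0("lab_", 0:n_lab))
  structure(list(matrix = mat, truncated_mass = trunc_mass,
                 condition_number = kappa(mat, exact = TRUE),
                 fragment = frag, purity = iso$purity),
            class = "correction_matrix")
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat(sprintf("correction_matrix for %s: %d x %d, condition number %.3g\n",
              x$fragment$metabolite, nrow(x$matrix), ncol(x$matrix),
              x$condition_number))
  invisible(x)
}

#' Correct raw isotopologue intensities to a mass-isotopomer distribution
#'
#' Solves the forward model `cm %*% x = m` for the tracer-labelling
#' distribution `x` under a non-negativity constraint, then renormalises to a
#' proper MID (fractions summing to 1). The default solver is non-negative
#' least squares; `solver = "pinv"` uses an unconstrained least-squares solve
#' with negative entries clamped to zero (reported in diagnostics).
#'
#' @param intensities numeric vector of raw intensities per observed mass
#'   shift `m+0, m+1, ...`; shorter vectors are zero-padded to the matrix row
#'   count.
#' @param cm A [build_correction_matrix()] result.
#' @param solver `"nnls"` (default) or `"pinv"`.
#' @param condition_warn warn when the matrix condition number exceeds this.
#' @return Object of class `mid`: numeric fraction vector `m+0..m+N` with
#'   attributes `residual` (relative residual norm of the fit) and
#'   `clamped_mass` (fraction removed by the non-negativity clamp, `pinv`
#'   solver only).
#' @export
#' @examples
#' cm <- build_correction_matrix(fragment_spec("x", "C3", 3), isotope_table())
#' m <- as.vector(cm$matrix %*% c(0.2, 0.3, 0.1, 0.4))
#' correct_mid(m, cm)
correct_mid <- function(intensities, cm, solver = c("nnls", "pinv"),
                        condition_warn = 1e6) {
  solver <- match.arg(solver)
  stopifnot(inherits(cm, "correction_matrix"))
  m <- as.numeric(intensities)
  if (any(m < 0)) stop("intensities must be non-negative", call. = FALSE)
  total <- sum(m)
  if (total <= 0) {
    stop("empty-measurement error: total intensity is zero", call. = FALSE)
  }
  n_rows <- nrow(cm$matrix)
  if (length(m) > n_rows) {
    stop("intensity vector longer than the correction-matrix row range (",
         n_rows, " mass shifts); rebuild with a larger tail", call. = FALSE)
  }
  m <- c(m, numeric(n_rows - length(m))) / total
  if (cm$condition_number > condition_warn) {
    warning("correction matrix is ill-conditioned (condition number ",
            format(cm$condition_number, digits = 3), ")", call. = FALSE)
  }
  clamped_mass <- 0
  if (solver == "nnls") {
    x <- pracma::lsqnonneg(cm$matrix, m)$x
  } else {
    x <- qr.solve(cm$matrix, m)
    clamped_mass <- sum(-x[x < 0])
    x <- pmax(x, 0)
  }
  if (sum(x) <= 0) {
    stop("correction produced an all-zero labelling distribution", call. = FALSE)
  }
  resid <- sqrt(sum((cm$matrix %*% x - m)^2))
  mid <- x / sum(x)
  names(mid) <- paste0("m+", seq_along(mid) - 1L)
  structure(mid, class = "mid", residual = resid, clamped_mass = clamped_mass)
}

#' Construct a MID directly
#'
#' Validates and normalises a vector of isotopologue fractions.
#' @param x non-negative fractions `m+0..m+N`; renormalised to sum 1 (must be
#'   within 1e-6 of 1 already unless `renormalise = TRUE`).
#' @param renormalise allow rescaling an unnormalised non-negative vector.
#' @return `mid` object.
#' @export
as_mid <- function(x, renormalise = FALSE) {
  x <- as.numeric(x)
  if (any(x < 0) || any(!is.finite(x))) {
    stop("MID fractions must be finite and non-negative", call. = FALSE)
  }
  s <- sum(x)
  if (s <= 0) stop("MID must have positive mass", call. = FALSE)
  if (!renormalise && abs(s - 1) > 1e-6) {
    stop("validation error: MID fractions sum to ", format(s),
         ", not 1", call. = FALSE)
  }
  out <- x / s
  names(out) <- paste0("m+", seq_along(out) - 1L)
  structure(out, class = "mid")
}

#' Fractional enrichment of a MID
#'
#' Total tracer incorporation: 1 minus the unlabelled (m+0) fraction.
#' @param mid A `mid` object (or vector accepted by [as_mid()]).
#' @return scalar in \[0, 1\].
#' @export
total_enrichment <- function(mid) {
  if (!inherits(mid, "mid")) mid <- as_mid(mid)
  unname(1 - mid[1])
}

#' Ratio of two isotopologue fractions
#'
#' E.g. m+5 glutamate / m+5 glutamine from uniformly-13C-glutamine labelling,
#' an index of glutaminolysis.
#'
#' @param mid_a,mid_b `mid` objects.
#' @param i,j isotopologue indices (mass shifts, 0-based).
#' @return list with `ratio` (NA when the denominator is zero) and
#'   `computable`.
#' @export
isotopologue_ratio <- function(mid_a, i, mid_b, j) {
  if (!inherits(mid_a, "mid")) mid_a <- as_mid(mid_a)
  if (!inherits(mid_b, "mid")) mid_b <- as_mid(mid_b)
  if (i < 0 || i >= length(mid_a) || j < 0 || j >= length(mid_b)) {
    stop("isotopologue index out of range", call. = FALSE)
  }
  den <- unname(mid_b[j + 1L])
  if (den == 0) {
    return(list(ratio = NA_real_, computable = FALSE,
                reason = "denominator isotopologue fraction is zero"))
  }
  list(ratio = unname(mid_a[i + 1L]) / den, computable = TRUE)
}

#' Cell-number-normalised relative metabolite abundance
#'
#' Total ion intensity over the internal-standard intensity, divided by the
#' cell count from the duplicate plate.
#'
#' @param intensities raw isotopologue intensities.
#' @param internal_standard internal-standard channel intensity (> 0).
#' @param cell_count cells on the duplicate plate; `NA` returns the
#'   un-normalised ratio with `cell_normalised = FALSE`.
#' @return list with `abundance`, `cell_normalised`.
#' @export
relative_abundance <- function(intensities, internal_standard,
                               cell_count = NA_real_) {
  if (!is.finite(internal_standard) || internal_standard <= 0) {
    stop("internal-standard intensity must be > 0 (failed derivatization?)",
         call. = FALSE)
  }
  ratio <- sum(intensities) / internal_standard
  if (is.na(cell_count)) {
    return(list(abundance = ratio, cell_normalised = FALSE))
  }
  if (cell_count <= 0) stop("cell count must be > 0", call. = FALSE)
  list(abundance = ratio / cell_count, cell_normalised = TRUE)
}

#' Log2 ratio-to-mean matrix
#'
#' Heatmap transform: per metabolite (row), each abundance becomes
#' `log2(value / arithmetic row mean)`, so `sum(2^row)/n = 1` for every row.
#'
#' @param mat numeric matrix, metabolites x samples, all entries > 0.
#' @return matrix of the same shape.
#' @export
#' @examples
#' ratio_to_mean(rbind(a = c(2, 4, 8)))
ratio_to_mean <- function(mat) {
  mat <- as.matrix(mat)
  bad <- which(!(is.finite(mat) & mat > 0), arr.ind = TRUE)
  if (nrow(bad)) {
    lab <- apply(bad, 1L, function(ij) {
      paste0("[", if (!is.null(rownames(mat))) rownames(mat)[ij[1]] else ij[1],
             ", ", if (!is.null(colnames(mat))) colnames(mat)[ij[2]] else ij[2],
             "]")
    })
    stop("validation error: non-positive abundance at ",
         paste(utils::head(lab, 5L), collapse = ", "),
         if (nrow(bad) > 5L) " ..." else "", call. = FALSE)
  }
  log2(mat / rowMeans(mat))
}
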