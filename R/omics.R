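#' Normalise a proteomics table to total peptide amount
#'
#' Scales every sample column so that all samples have the same summed
#' abundance (the mean of the original column totals), the standard
#' within-sample total normalisation for TMT-style quantification.
#'
#' @param mat numeric matrix, proteins x samples, abundances > 0.
#' @return matrix of the same shape with equal column sums.
#' @export
normalize_total <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat)) || any(mat <= 0)) {
    stop("abundances must be finite and > 0 before normalisation",
         call. = FALSE)
  }
  totals <- colSums(mat)
  sweep(mat, 2L, totals / mean(totals), "/")
}

#' Differential protein abundance between two groups
#'
#' The downstream proteomics significance stage: total-peptide normalisation,
#' log2 transform, per-protein Welch t-test (Satterthwaite degrees of
#' freedom), Benjamini-Hochberg adjustment across all tested proteins, and
#' the conjunctive significance rule: BH q < 0.05, -log10 p > 1.3 and
#' |log2 fold change| > 0.48. Fold changes are differences of group means on
#' the log2 scale, reported as `g2` over `g1`.
#'
#' @param mat numeric matrix, proteins x samples (raw abundances > 0 unless
#'   `normalise = FALSE` and `log2_input = TRUE`).
#' @param groups factor/character per sample.
#' @param g1,g2 group labels to compare (fold change direction `g2/g1`).
#' @param normalise apply [normalize_total()] first (default `TRUE`).
#' @param log2_input set `TRUE` if `mat` is already log2-transformed.
#' @param q_cut,p_cut_log10,lfc_cut thresholds of the significance rule.
#' @return data.frame (class `differential_result`): `protein`, `log2_fc`,
#'   `p_value`, `neg_log10_p`, `q_value`, `significant`, `direction`
#'   (`"up"`/`"down"`/`"ns"`), `flat` (constant across all samples, p forced
#'   to 1).
#' @export
#' @examples
#' sim <- simulate_omics(n_proteins = 100, seed = 1)
#' res <- differential_proteome(sim$proteome$mat, sim$proteome$groups,
#'                              "C1", "M")
#' head(res)
differential_proteome <- function(mat, groups, g1, g2, normalise = TRUE,
                                  log2_input = FALSE,
                                  q_cut = 0.05, p_cut_log10 = 1.3,
                                  lfc_cut = 0.48) {
  mat <- as.matrix(mat)
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) {
    stop("`groups` must have one entry per sample column", call. = FALSE)
  }
  i1 <- which(groups == g1); i2 <- which(groups == g2)
  if (length(i1) < 2 || length(i2) < 2) {
    stop("each group needs >= 2 samples for a Welch test", call. = FALSE)
  }
  if (normalise) mat <- normalize_total(mat)
  lg <- if (log2_input) mat else {
    if (any(mat <= 0)) stop("abundances must be > 0 for log2", call. = FALSE)
    log2(mat)
  }
  x1 <- lg[, i1, drop = FALSE]; x2 <- lg[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)
  n1 <- length(i1); n2 <- length(i2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  flat <- se2 == 0
  p[flat] <- 1
  q <- stats::p.adjust(p, method = "BH")
  lfc <- m2 - m1
  sig <- (q < q_cut) & (-log10(p) > p_cut_log10) & (abs(lfc) > lfc_cut)
  res <- data.frame(
    protein = if (!is.null(rownames(mat))) rownames(mat) else
      paste0("P", seq_len(nrow(mat))),
    log2_fc = lfc, p_value = p, neg_log10_p = -log10(p), q_value = q,
    significant = sig,
    direction = ifelse(!sig, "ns", ifelse(lfc > 0, "up", "down")),
    flat = flat, row.names = NULL, stringsAsFactors = FALSE
  )
  structure(res, class = c("differential_result", "data.frame"),
            comparison = c(g1 = g1, g2 = g2),
            thresholds = c(q = q_cut, neg_log10_p = p_cut_log10,
                           log2_fc = lfc_cut))
}

#' Growth series relative to the first timepoint
#'
#' Confluence or crystal-violet OD595 divided by the anchor measurement
#' (0 h / day 0), so the anchor maps to 1.
#'
#' @param time numeric, strictly increasing; first entry is the anchor.
#' @param value confluence (%) or OD595 per timepoint; anchor must be > 0.
#' @return data.frame `time`, `relative`.
#' @export
relative_growth <- function(time, value) {
  if (length(time) != length(value)) stop("length mismatch", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(value[1]) || value[1] <= 0) {
    stop("validation error: anchor (first timepoint) measurement must be > 0",
         call. = FALSE)
  }
  data.frame(time = time, relative = value / value[1])
}

#' Relative apoptosis series
#'
#' Caspase-reporter green-object count (1/mm^2) normalised to relative
#' confluence at each timepoint.
#'
#' @param green_count green-object counts per timepoint.
#' @param relative_confluence matched relative-confluence values (from
#'   [relative_growth()]).
#' @return data.frame `relative_apoptosis`, `computable`; timepoints with
#'   missing or zero confluence are flagged, not dropped.
#' @export
relative_apoptosis <- function(green_count, relative_confluence) {
  if (length(green_count) != length(relative_confluence)) {
    stop("length mismatch", call. = FALSE)
  }
  ok <- is.finite(relative_confluence) & relative_confluence > 0
  out <- ifelse(ok, green_count / relative_confluence, NA_real_)
  data.frame(relative_apoptosis = out, computable = ok)
}
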