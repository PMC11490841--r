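#' Mitochondrial stress-test parameters
#'
#' Decomposes per-well phase aggregates into the canonical respiratory
#' parameters: non-mitochondrial OCR (post antimycin/rotenone), mitochondrial
#' OCR (basal minus non-mito), ATP-synthesis-coupled OCR (basal minus
#' oligomycin), proton leak (oligomycin minus non-mito), maximal respiratory
#' capacity (MRC; OCR following FCCP addition) and spare respiratory capacity
#' (SRC = MRC minus basal OCR).
#'
#' Derived rates that come out negative (noise exceeding signal) are clamped
#' to zero and the well flagged; the unclamped values are kept in the `*_raw`
#' diagnostic columns. To preserve the exact identity
#' `ocr_mito = ocr_coupled + ocr_leak` under clamping, the reported
#' mitochondrial OCR is the sum of the clamped components (in clean data all
#' three equal the naive differences).
#'
#' @param ps A [summarize_phases()] result.
#' @param subtract_nonmito_from_mrc If `TRUE`, report MRC as post-FCCP OCR
#'   minus non-mitochondrial OCR. Default `FALSE`: MRC is the raw post-FCCP
#'   rate.
#' @return data.frame (class `respiratory_params`) with one row per well:
#'   `ocr_nonmito`, `ocr_mito`, `ocr_coupled`, `ocr_leak`, `mrc`, `src`,
#'   raw (unclamped) diagnostics and a logical `clamped` flag.
#' @export
respiratory_params <- function(ps, subtract_nonmito_from_mrc = FALSE) {
  stopifnot(inherits(ps, "phase_summary"))
  nonmito <- ps$aarot_ocr
  coupled_raw <- ps$basal_ocr - ps$oligo_ocr
  leak_raw <- ps$oligo_ocr - ps$aarot_ocr
  mito_raw <- ps$basal_ocr - ps$aarot_ocr
  coupled <- pmax(coupled_raw, 0)
  leak <- pmax(leak_raw, 0)
  mito <- coupled + leak
  mrc <- if (subtract_nonmito_from_mrc) ps$fccp_ocr - nonmito else ps$fccp_ocr
  src_raw <- mrc - ps$basal_ocr
  src <- pmax(src_raw, 0)
  clamped <- (coupled_raw < 0) | (leak_raw < 0) | (src_raw < 0)
  structure(
    data.frame(
      well_id = ps$well_id, group = ps$group, condition = ps$condition,
      ocr_nonmito = nonmito, ocr_mito = mito, ocr_coupled = coupled,
      ocr_leak = leak, mrc = mrc, src = src,
      ocr_mito_raw = mito_raw, ocr_coupled_raw = coupled_raw,
      ocr_leak_raw = leak_raw, src_raw = src_raw,
      clamped = clamped, stringsAsFactors = FALSE
    ),
    class = c("respiratory_params", "data.frame"),
    mrc_nonmito_subtracted = subtract_nonmito_from_mrc
  )
}

#' ATP production rates from extracellular flux
#'
#' Splits total ATP production into a glycolytic and an oxidative component at
#' two metabolic states: basal (before any injection) and maximal (ECAR from
#' the monensin phase, OCR contributions from the FCCP phase).
#'
#' Per well and state `s`:
#' \deqn{PPR_{tot} = ECAR_s / BP}
#' \deqn{PPR_{resp} = \frac{10^{pH-pK_1}}{1+10^{pH-pK_1}} \cdot
#'   \mathrm{maxH/O_2} \cdot OCR_{mito,s}}
#' \deqn{J_{ATP,glyc} = \max(PPR_{tot}-PPR_{resp},0) \cdot ATP/lactate +
#'   OCR_{mito,s} \cdot 2 \cdot P/O_{glyc}}
#' \deqn{J_{ATP,ox} = OCR_{coupled,s} \cdot 2 \cdot P/O_{oxphos} +
#'   OCR_{mito,s} \cdot 2 \cdot P/O_{TCA}}
#' The glycolytic index is glycolytic ATP as a percentage of total ATP at
#' baseline. Maximal-state mitochondrial/coupled OCR are derived from the
#' post-FCCP rate (`mito_max = fccp - nonmito`, `coupled_max = mito_max -
#' leak`, clamped at zero).
#'
#' @param ps A [summarize_phases()] result.
#' @param rp The matching [respiratory_params()] result.
#' @param coef A [bioenergetic_coefficients()] object.
#' @return data.frame (class `atp_flux`) with per-well columns
#'   `j_atp_glyc_basal`, `j_atp_ox_basal`, `j_atp_total_basal`,
#'   `j_atp_glyc_max`, `j_atp_ox_max`, `j_atp_total_max`,
#'   `glycolytic_index` (percent, NA with `index_undefined` flag when total
#'   basal ATP is zero) and a `glyc_clamped` flag. Maximal-glycolysis columns
#'   are NA when the protocol lacked a monensin phase. The coefficient set is
#'   attached as attribute `coefficients`.
#' @export
#' @examples
#' sim <- simulate_flux_plate(seed = 1)
#' ps <- summarize_phases(normalize_plate(sim$plate, sim$od), sim$protocol)
#' rp <- respiratory_params(ps)
#' head(atp_fluxes(ps, rp, bioenergetic_coefficients()))
atp_fluxes <- function(ps, rp, coef) {
  stopifnot(inherits(ps, "phase_summary"), inherits(rp, "respiratory_params"),
            inherits(coef, "bioenergetic_coefficients"))
  if (!identical(ps$well_id, rp$well_id)) {
    stop("`ps` and `rp` must come from the same plate (well order differs)",
         call. = FALSE)
  }
  gamma <- 10^(coef$medium_ph - coef$pk1) / (1 + 10^(coef$medium_ph - coef$pk1))

  state_flux <- function(ecar, mito, coupled) {
    ppr_tot <- ecar / coef$buffering_power
    ppr_resp <- gamma * coef$max_h_per_o2 * mito
    ppr_glyc <- pmax(ppr_tot - ppr_resp, 0)
    j_glyc <- ppr_glyc * coef$atp_per_lactate + mito * 2 * coef$po_glyc
    j_ox <- coupled * 2 * coef$po_oxphos + mito * 2 * coef$po_tca
    list(glyc = j_glyc, ox = j_ox, clamped = ppr_tot - ppr_resp < 0)
  }

  basal <- state_flux(ps$basal_ecar, rp$ocr_mito, rp$ocr_coupled)
  mito_max <- pmax(ps$fccp_ocr - rp$ocr_nonmito, 0)
  coupled_max <- pmax(mito_max - rp$ocr_leak, 0)
  mx <- state_flux(ps$monensin_ecar, mito_max, coupled_max)

  total_basal <- basal$glyc + basal$ox
  index <- ifelse(total_basal > 0, 100 * basal$glyc / total_basal, NA_real_)

  out <- data.frame(
    well_id = ps$well_id, group = ps$group, condition = ps$condition,
    j_atp_glyc_basal = basal$glyc, j_atp_ox_basal = basal$ox,
    j_atp_total_basal = total_basal,
    j_atp_glyc_max = mx$glyc,
    j_atp_ox_max = coupled_max * 2 * coef$po_oxphos + mito_max * 2 * coef$po_tca,
    j_atp_total_max = NA_real_,
    glycolytic_index = index,
    index_undefined = !(total_basal > 0),
    glyc_clamped = basal$clamped | (mx$clamped %in% TRUE),
    stringsAsFactors = FALSE
  )
  out$j_atp_total_max <- out$j_atp_glyc_max + out$j_atp_ox_max
  structure(out, class = c("atp_flux", "data.frame"),
            coefficients = coefficients_to_list(coef))
}

#' Group-level bioenergetic scope
#'
#' Averages per-well ATP fluxes within groups to give the basal and maximal
#' (glycolytic, oxidative) point pairs used for bioenergetic-scope plots.
#' Wells flagged as heavily clamped can be excluded before averaging.
#'
#' @param af An [atp_fluxes()] result.
#' @param exclude_flagged Drop wells with `glyc_clamped` or undefined index.
#' @return data.frame with one row per group: mean flux at each state, mean
#'   glycolytic index, and `n_wells` used.
#' @export
group_scope <- function(af, exclude_flagged = TRUE) {
  stopifnot(inherits(af, "atp_flux"))
  keep <- if (exclude_flagged) !(af$glyc_clamped | af$index_undefined) else
    rep(TRUE, nrow(af))
  d <- af[keep, , drop = FALSE]
  num <- c("j_atp_glyc_basal", "j_atp_ox_basal", "j_atp_total_basal",
           "j_atp_glyc_max", "j_atp_ox_max", "j_atp_total_max",
           "glycolytic_index")
  agg <- stats::aggregate(d[num], by = list(group = d$group), FUN = mean,
                          na.rm = TRUE)
  agg$n_wells <- as.vector(table(d$group)[agg$group])
  agg
}

#' Paired nutrient-restriction ratios with a one-sample t-test
#'
#' For per-replicate summary values measured under nutrient restriction and
#' the paired control (e.g. -Glc vs +Glc, -Q vs +Q), computes the per-replicate
#' ratio treated/control, its mean and SEM, and a two-sided one-sample t-test
#' of the ratios against 1.
#'
#' @param treated,control numeric vectors paired by biological replicate.
#' @return list with `ratios`, `mean`, `sem`, `t`, `df`, `p_value`,
#'   `computable` (FALSE with a `reason` when n < 2 or the ratios have zero
#'   variance).
#' @export
#' @examples
#' nutrient_stress_ratio(c(50, 40, 60), c(100, 100, 100))
nutrient_stress_ratio <- function(treated, control) {
  if (length(treated) != length(control)) {
    stop("treated and control must be paired by replicate (equal length)",
         call. = FALSE)
  }
  zero <- which(control == 0)
  if (length(zero)) {
    stop("control value 0 for replicate(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  ratios <- treated / control
  out <- list(ratios = ratios, mean = mean(ratios),
              sem = stats::sd(ratios) / sqrt(length(ratios)),
              t = NA_real_, df = NA_real_, p_value = NA_real_,
              computable = FALSE, reason = NULL)
  if (length(ratios) < 2) {
    out$reason <- "fewer than 2 replicates"
    out$sem <- NA_real_
    return(out)
  }
  if (stats::sd(ratios) == 0) {
    out$reason <- "zero variance among ratios"
    return(out)
  }
  tt <- stats::t.test(ratios, mu = 1)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p_value <- tt$p.value
  out$computable <- TRUE
  out
}

#' Significance stars
#'
#' Star coding at 0.05 / 0.01 / 0.001 / 0.0001.
#' @param p numeric vector of p-values.
#' @return character vector of `""`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", ""), right = FALSE) |>
    as.character()
}

#' Compare a summary statistic across groups
#'
#' One-way ANOVA with all-pairs Tukey HSD (3+ groups), or Student's t-test for
#' exactly two groups, with the star coding used throughout the package.
#'
#' @param values numeric vector of per-well (or per-replicate) statistics.
#' @param groups factor/character of the same length.
#' @param method `"anova_tukey"` or `"t_test"`.
#' @param var_equal For `t_test`, assume equal variances (classical Student's
#'   t). Default `TRUE`.
#' @return list with `method`, `anova_f`, `anova_p` (ANOVA route) and a
#'   `pairs` data.frame (`group1`, `group2`, `diff`, `p_adj`, `stars`,
#'   `computable`).
#' @export
group_compare <- function(values, groups,
                          method = c("anova_tukey", "t_test"),
                          var_equal = TRUE) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  counts <- table(groups)
  small <- names(counts)[counts < 2]
  if (method == "anova_tukey") {
    if (length(small)) {
      return(list(method = method, anova_f = NA_real_, anova_p = NA_real_,
                  pairs = data.frame(), computable = FALSE,
                  reason = paste("group(s) with <2 observations:",
                                 paste(small, collapse = ", "))))
    }
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairs <- data.frame(
      group1 = vapply(nm, `[`, "", 2L), group2 = vapply(nm, `[`, "", 1L),
      diff = tk[, "diff"], p_adj = tk[, "p adj"],
      stars = significance_stars(tk[, "p adj"]),
      computable = TRUE, row.names = NULL, stringsAsFactors = FALSE
    )
    list(method = method, anova_f = an[["F value"]][1],
         anova_p = an[["Pr(>F)"]][1], pairs = pairs, computable = TRUE)
  } else {
    if (nlevels(groups) != 2) {
      stop("t_test method needs exactly 2 groups", call. = FALSE)
    }
    lv <- levels(groups)
    if (length(small)) {
      return(list(method = method, anova_f = NA_real_, anova_p = NA_real_,
                  pairs = data.frame(group1 = lv[1], group2 = lv[2],
                                     diff = NA_real_, p_adj = NA_real_,
                                     stars = "", computable = FALSE),
                  computable = FALSE,
                  reason = "group with <2 observations"))
    }
    tt <- stats::t.test(values[groups == lv[2]], values[groups == lv[1]],
                        var.equal = var_equal)
    pairs <- data.frame(group1 = lv[1], group2 = lv[2],
                        diff = diff(rev(tt$estimate))[[1]] * -1,
                        p_adj = tt$p.value,
                        stars = significance_stars(tt$p.value),
                        computable = TRUE, stringsAsFactors = FALSE)
    pairs$diff <- mean(values[groups == lv[2]]) - mean(values[groups == lv[1]])
    list(method = method, anova_f = NA_real_, anova_p = NA_real_,
         pairs = pairs, computable = TRUE)
  }
}
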