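# End-to-end orchestration: validated config in, stage outputs + provenance
# manifest out. Stages run in dependency order; a failed stage is recorded
# and its dependants are skipped. Outputs carry no timestamps, so re-running
# an identical configuration reproduces byte-identical files.

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Validate a pipeline run configuration
#'
#' @param config named list (or YAML path) with a `stages` character vector
#'   (subset of `flux`, `mid`, `omics`) and one block per enabled stage:
#'   \describe{
#'     \item{flux}{`trace`, `od` (CSV paths), `protocol` (YAML path),
#'       optional `coefficients` (named list), `aggregators`.}
#'     \item{mid}{`intensities` (CSV path), optional `registry` (CSV path),
#'       `purity`, `cell_count`, `internal_standard` (named per-sample list
#'       or scalar).}
#'     \item{omics}{`abundance` (proteome CSV), `samples` (sample sheet CSV),
#'       `groups` (two labels); optional `growth` (growth CSV).}
#'   }
#'   A `strict` flag rejects unknown top-level keys.
#' @return validated config list (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  known <- c("stages", "flux", "mid", "omics", "strict", "seed")
  if (isTRUE(config$strict)) {
    extra <- setdiff(names(config), known)
    if (length(extra)) {
      stop("strict mode: unknown config key(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  stages <- config$stages
  if (is.null(stages) || !length(stages)) {
    stop("config must enable at least one stage", call. = FALSE)
  }
  bad <- setdiff(stages, c("flux", "mid", "omics"))
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  req <- list(flux = c("trace", "od", "protocol"),
              mid = "intensities",
              omics = c("abundance", "samples", "groups"))
  for (st in stages) {
    miss <- setdiff(req[[st]], names(config[[st]]))
    if (length(miss)) {
      stop("stage `", st, "` config missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(config, class = c("run_config", "list"))
}

run_stage <- function(name, manifest, expr) {
  res <- tryCatch(
    list(status = "ok", value = expr(), error = NULL),
    error = function(e) list(status = "error", value = NULL,
                             error = conditionMessage(e))
  )
  manifest$stages[[name]] <- list(status = res$status, error = res$error)
  list(value = res$value, manifest = manifest, ok = res$status == "ok")
}

stage_flux <- function(cfg, out_dir) {
  trace <- read_table(cfg$trace, "flux_trace")
  od <- read_table(cfg$od, "od")
  protocol <- read_protocol(cfg$protocol)
  plate <- normalize_plate(flux_plate_from_table(trace), od)
  ps <- summarize_phases(plate, protocol,
                         aggregators = cfg$aggregators %||% list())
  rp <- respiratory_params(ps)
  coef <- if (!is.null(cfg$coefficients)) {
    bioenergetic_coefficients_from_list(cfg$coefficients)
  } else bioenergetic_coefficients()
  af <- atp_fluxes(ps, rp, coef)
  write_tsv(as.data.frame(ps), file.path(out_dir, "flux_phase_summary.tsv"))
  write_tsv(as.data.frame(rp), file.path(out_dir, "flux_respiratory_params.tsv"))
  write_tsv(as.data.frame(af), file.path(out_dir, "flux_atp.tsv"))
  write_tsv(group_scope(af), file.path(out_dir, "flux_group_scope.tsv"))
  list(coefficients = coefficients_to_list(coef),
       aggregators = attr(ps, "aggregators"),
       n_wells = nrow(ps))
}

stage_mid <- function(cfg, out_dir) {
  intens <- read_table(cfg$intensities, "intensities")
  registry <- if (!is.null(cfg$registry)) fragment_registry(cfg$registry) else
    fragment_registry()
  iso <- isotope_table(purity = cfg$purity %||% 0.99)
  mids <- list(); enr <- list(); diag <- list()
  for (met in unique(intens$metabolite)) {
    if (!met %in% names(registry)) {
      stop("metabolite not in fragment registry: ", met, call. = FALSE)
    }
    cm <- build_correction_matrix(registry[[met]], iso)
    sub <- intens[intens$metabolite == met, ]
    for (s in unique(sub$sample)) {
      v <- sub[sub$sample == s, ]
      m <- numeric(max(v$mass_shift) + 1L)
      m[v$mass_shift + 1L] <- v$intensity
      mid <- correct_mid(m, cm)
      mids[[length(mids) + 1L]] <- data.frame(
        metabolite = met, sample = s,
        isotopologue = names(mid), fraction = as.numeric(mid)
      )
      enr[[length(enr) + 1L]] <- data.frame(
        metabolite = met, sample = s, enrichment = total_enrichment(mid)
      )
      diag[[length(diag) + 1L]] <- data.frame(
        metabolite = met, sample = s,
        residual = attr(mid, "residual"),
        condition_number = cm$condition_number
      )
    }
  }
  mid_tab <- do.call(rbind, mids)
  enr_tab <- do.call(rbind, enr)
  write_tsv(mid_tab, file.path(out_dir, "mid_corrected.tsv"))
  write_tsv(enr_tab, file.path(out_dir, "mid_enrichment.tsv"))
  write_tsv(do.call(rbind, diag), file.path(out_dir, "mid_diagnostics.tsv"))
  # per-metabolite log2 ratio-to-mean of enrichment across samples
  em <- stats::xtabs(enrichment ~ metabolite + sample, data = enr_tab)
  if (all(em > 0)) {
    rtm <- ratio_to_mean(as.matrix(unclass(em)))
    d <- data.frame(metabolite = rownames(rtm), as.data.frame(rtm),
                    check.names = FALSE)
    write_tsv(d, file.path(out_dir, "mid_log2_ratio_to_mean.tsv"))
  }
  list(n_metabolites = length(unique(intens$metabolite)),
       purity = iso$purity)
}

stage_omics <- function(cfg, out_dir) {
  ab <- read_table(cfg$abundance, "proteome")
  sheet <- read_table(cfg$samples, "sample_sheet")
  mat <- as.matrix(ab[setdiff(names(ab), "protein")])
  rownames(mat) <- ab$protein
  groups <- sheet$group[match(colnames(mat), sheet$sample)]
  if (anyNA(groups)) {
    stop("sample sheet does not cover all abundance columns", call. = FALSE)
  }
  res <- differential_proteome(mat, groups, cfg$groups[[1]], cfg$groups[[2]])
  write_tsv(as.data.frame(res), file.path(out_dir, "omics_differential.tsv"))
  out <- list(n_proteins = nrow(res), n_significant = sum(res$significant))
  if (!is.null(cfg$growth)) {
    g <- read_table(cfg$growth, "growth")
    rel <- do.call(rbind, lapply(split(g, g$well), function(w) {
      w <- w[order(w$time), ]
      r <- relative_growth(w$time, w$confluence)
      out <- data.frame(well = w$well, time = r$time,
                        relative_confluence = r$relative)
      if (!is.null(w$green_count)) {
        ap <- relative_apoptosis(w$green_count, r$relative)
        out$relative_apoptosis <- ap$relative_apoptosis
      }
      out
    }))
    rownames(rel) <- NULL
    write_tsv(rel, file.path(out_dir, "omics_growth_relative.tsv"))
    out$n_growth_wells <- length(unique(g$well))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pipeline
#'
#' Executes the enabled stages in dependency order and writes every stage
#' output plus `manifest.json` (config echo, package version, md5 digests of
#' inputs and outputs, per-stage status) into `out_dir`.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list; `manifest$exit_status` is 0 iff all
#'   enabled stages succeeded.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("oncoflux")),
    config = unclass(cfg), stages = list(), inputs = list(), outputs = list()
  )
  input_paths <- unlist(lapply(c("flux", "mid", "omics"), function(st) {
    blk <- cfg[[st]]
    blk[vapply(blk, function(v) is.character(v) && length(v) == 1L &&
                 file.exists(v), logical(1))]
  }))
  manifest$inputs <- as.list(tools::md5sum(unlist(input_paths)))

  runners <- list(flux = stage_flux, mid = stage_mid, omics = stage_omics)
  for (st in c("flux", "mid", "omics")) {
    if (!st %in% cfg$stages) next
    r <- run_stage(st, manifest, function() runners[[st]](cfg[[st]], out_dir))
    manifest <- r$manifest
    if (r$ok) manifest$stages[[st]]$info <- r$value
  }
  statuses <- vapply(manifest$stages, `[[`, "", "status")
  manifest$exit_status <- if (all(statuses == "ok")) 0L else 1L
  outs <- setdiff(list.files(out_dir, full.names = TRUE),
                  file.path(out_dir, "manifest.json"))
  manifest$outputs <- as.list(tools::md5sum(outs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
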