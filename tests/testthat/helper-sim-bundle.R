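# Writes a full simulated input bundle (flux + labelling + omics CSVs and
# protocol YAML) and returns the matching pipeline config.
write_sim_bundle <- function(dir, seed = 1) {
  flux <- simulate_flux_plate(wells_per_group = 4, seed = seed)
  write_flux_table(flux$plate, file.path(dir, "flux_trace.csv"))
  utils::write.csv(flux$od, file.path(dir, "od.csv"), row.names = FALSE,
                   quote = FALSE)
  yaml::write_yaml(list(
    n_cycles = attr(flux$protocol, "n_cycles"),
    injections = lapply(which(flux$protocol$phase != "basal"), function(i) {
      list(name = flux$protocol$phase[i],
           first_cycle_index = flux$protocol$first_cycle[i])
    })
  ), file.path(dir, "protocol.yaml"))

  lab <- simulate_labelling(seed = seed)
  utils::write.csv(lab$intensities, file.path(dir, "intensities.csv"),
                   row.names = FALSE, quote = FALSE)

  om <- simulate_omics(n_proteins = 120, n_per_group = 3,
                       effects = data.frame(protein = 1:5, log2fc = 2),
                       seed = seed)
  ab <- data.frame(protein = rownames(om$proteome$mat), om$proteome$mat,
                   check.names = FALSE)
  utils::write.csv(ab, file.path(dir, "abundance.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(sample = colnames(om$proteome$mat),
                              group = om$proteome$groups),
                   file.path(dir, "samples.csv"), row.names = FALSE,
                   quote = FALSE)
  growth <- om$growth
  names(growth)[names(growth) == "time_h"] <- "time"
  utils::write.csv(growth, file.path(dir, "growth.csv"), row.names = FALSE,
                   quote = FALSE)
  list(
    stages = c("flux", "mid", "omics"),
    flux = list(trace = file.path(dir, "flux_trace.csv"),
                od = file.path(dir, "od.csv"),
                protocol = file.path(dir, "protocol.yaml")),
    mid = list(intensities = file.path(dir, "intensities.csv")),
    omics = list(abundance = file.path(dir, "abundance.csv"),
                 samples = file.path(dir, "samples.csv"),
                 groups = c("C1", "M"),
                 growth = file.path(dir, "growth.csv"))
  )
}
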