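# Shared synthetic scenario builder: full study + raw libraries + degradome,
# sized for quick per-module tests.
build_scenario <- function(seed = 7, n_unigenes = 30, n_mirnas = 10,
                           n_de = 4, n_multi_locus = 1, n_targets = 3,
                           noise_reads = 30, reads_per_site = 10,
                           background_reads = 40) {
  st <- simulate_study(n_unigenes = n_unigenes, n_mirnas = n_mirnas,
                       n_de = n_de, n_multi_locus = n_multi_locus,
                       n_targets = n_targets, seed = seed)
  libs <- simulate_srna_libraries(st$truth, st$adapter, st$ncrna,
                                  st$transcriptome,
                                  contaminant_fraction = 0.05,
                                  noise_reads = noise_reads, seed = seed)
  dg <- simulate_degradome(st$truth, st$transcriptome,
                           reads_per_site = reads_per_site,
                           background_reads = background_reads, seed = seed)
  c(st, list(libraries = libs, degradome = dg))
}
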