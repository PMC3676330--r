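# Shared configuration for the demo analysis.
#
# One breed-like population with a single embedded recessive lethal at 10%
# carrier-chromosome frequency and full penetrance. The genome is
# density-compressed relative to a real 50k array (100 markers per
# chromosome instead of ~1,500), so a 20-marker window spans a fifth of a
# chromosome; recombination is kept on so that the deficit signal decays
# away from the lethal window and the merged region localizes, at the cost
# of some erosion of the intact haplotype string across meioses.

library(lethalscan)

demo_config <- function(seed = 2024) {
  simulation_config(
    n_sires = 150, n_mgs = 150, n_dams = 3000,
    n_founder_haplotypes = 25,
    n_chromosomes = 2, markers_per_chromosome = 100,
    chromosome_length_bp = 1e8,
    recombination_rate_per_bp = 1e-8,
    insems_per_dam = 8,
    mu_heifer = 0.55, mu_cow = 0.45,
    lethal_specs = list(
      lethal_spec(chromosome = 1, window_start_marker = 40,
                  window_n_markers = 20, target_frequency = 0.1,
                  penetrance = 1)),
    seed = seed)
}

data_dir <- "results/data"
report_dir <- "results"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
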