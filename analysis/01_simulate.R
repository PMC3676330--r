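#!/usr/bin/env Rscript
# Simulate the demo population: marker map, pedigree, phased genotypes,
# insemination records, and the carrier truth used later for validation.

source("analysis/00_config.R")

cfg <- demo_config()
map <- simulate_marker_map(cfg)
pop <- simulate_population(map, cfg)
ins <- simulate_inseminations(pop$pedigree, pop$carrier_truth, cfg)

write.table(map, file.path(data_dir, "marker_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_phased(pop$genotypes, file.path(data_dir, "phased.tsv"))
write_pedigree(pop$pedigree, file.path(data_dir, "pedigree.tsv"))
write_inseminations(ins, file.path(data_dir, "inseminations.tsv"))
write.table(pop$carrier_truth, file.path(data_dir, "carrier_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pop$lethal_windows, file.path(data_dir, "lethal_windows.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ct <- pop$carrier_truth
cat(sprintf("Simulated %d genotyped animals over %d markers.\n",
            length(pop$genotypes$animal_id), nrow(map)))
cat(sprintf(
  "Embedded lethal %s on chr%d (markers %d-%d), carrier sires: %d/%d.\n",
  pop$lethal_windows$lethal_id, pop$lethal_windows$chromosome,
  pop$lethal_windows$start_marker, pop$lethal_windows$end_marker,
  sum(ct$copies == 1 & ct$role == "sire"), cfg$n_sires))
cat(sprintf(
  "Homozygous conceptuses removed before genotyping: %d; %d inseminations recorded (mean conception %.3f).\n",
  sum(ct$died), nrow(ins), mean(ins$outcome)))
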