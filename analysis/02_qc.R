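#!/usr/bin/env Rscript
# Marker quality control: minor allele frequency >= 3% pooled over the
# population, then Hardy-Weinberg equilibrium at p >= 1e-4.

source("analysis/00_config.R")

map <- read.table(file.path(data_dir, "marker_map.tsv"), sep = "\t",
                  header = TRUE, stringsAsFactors = FALSE)
geno <- read_phased(file.path(data_dir, "phased.tsv"), map)

after_maf <- filter_maf(geno, threshold = 0.03)
after_hwe <- filter_hwe(geno, after_maf, p_threshold = 1e-4)

write.table(after_hwe, file.path(data_dir, "marker_map_qc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("MAF filter removed %d of %d markers; HWE removed another %d.\n",
            nrow(map) - nrow(after_maf), nrow(map),
            nrow(after_maf) - nrow(after_hwe)))
cat(sprintf("%d markers kept for the scan.\n", nrow(after_hwe)))
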