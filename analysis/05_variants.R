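#!/usr/bin/env Rscript
# Candidate-mutation stage: simulate sequence variants for a panel of
# carrier and control bulls over the detected region extended by a 6 Mb
# flank, apply the heterozygous-in-carriers / absent-in-controls filter and
# the protein-consequence filter, and validate the surviving candidate's
# haplotype association.

source("analysis/00_config.R")

cfg <- demo_config()
regions <- read.table(file.path(report_dir, "regions.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
ped <- read_pedigree(file.path(data_dir, "pedigree.tsv"))
ct <- read.table(file.path(data_dir, "carrier_truth.tsv"), sep = "\t",
                 header = TRUE, stringsAsFactors = FALSE)
stopifnot(nrow(regions) >= 1)

status <- setNames(ct$copies > 0, ct$animal_id)
bulls <- ped$animal_id[ped$role == "sire"]
carriers <- head(bulls[status[bulls]], 2)
controls <- head(bulls[!status[bulls]], 10)

region <- define_search_region(regions[1, ], flank_mb = 6)
cat(sprintf("Search region: chr%d %.1f-%.1f Mb (haplotype %.1f-%.1f + 6 Mb flank)\n",
            region$chromosome, region$start_mb, region$end_mb,
            regions$start_mb[1], regions$end_mb[1]))

vcf <- simulate_vcf(region, carriers, controls,
                    causative = list(gene = "CAND1"),
                    n_background = 60, seed = cfg$seed + 3L)
write_variant_vcf(vcf, file.path(data_dir, "panel.vcf"))

cand <- filter_genotype_pattern(vcf, carriers, controls, region = region)
cand <- filter_consequence(cand)
write.table(cand$sites, file.path(report_dir, "candidates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d variants survive the genotype and consequence filters:\n",
            nrow(cand$sites), nrow(vcf$sites)))
print(cand$sites[, c("chrom", "pos", "ref", "alt", "gene", "consequence")],
      row.names = FALSE)

# haplotype association on the sequenced panel
dip <- data.frame(animal_id = c(carriers, controls),
                  hap1 = ifelse(status[c(carriers, controls)], "HAP_LETHAL",
                                "OTHER_A"),
                  hap2 = "OTHER_B", stringsAsFactors = FALSE)
chk <- haplotype_association_check(
  setNames(cand$geno[1, ], colnames(cand$geno)), dip, "HAP_LETHAL")
cat(sprintf("Association check for the top candidate: %s (haplotypes: %s)\n",
            chk$status, paste(chk$associated, collapse = ", ")))
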