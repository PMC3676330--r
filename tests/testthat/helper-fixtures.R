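# Published deficit-of-homozygotes regions in three French dairy breeds
# (Holstein HOL, Montbeliarde MON, Normande NOR): expected and observed
# homozygote counts with the p-values as printed, in 2-significant-figure
# scientific notation. HH2 is the sub-threshold reference region reported
# alongside the significant ones.
table1_reference <- function() {
  txt <- "breed name E O freq p_printed
HOL BY 49 0 3.6 2.6E-12
HOL HH1 18 0 2.6 2.2E-05
HOL HH2 14 3 1.7 3.3E-03
HOL HH3 21 0 2.5 4.6E-06
HOL HH4 49 0 3.6 2.6E-12
HOL HH5 68 24 3.9 9.5E-08
HOL HH6 91 38 4.6 2.8E-08
HOL HH7 202 100 6.9 7.1E-13
HOL HH8 15 0 2.1 1.1E-04
HOL HH9 40 13 2.9 2.0E-05
HOL HH10 24 1 2.2 2.7E-06
HOL HH11 75 35 3.2 3.9E-06
HOL HH12 127 54 5.5 9.3E-11
HOL HH13 32 5 3.7 1.8E-06
HOL HH14 40 8 2.4 4.2E-07
HOL HH15 68 25 2.7 1.8E-07
HOL HH16 26 2 2.0 2.5E-06
HOL HH17 33 5 1.8 1.1E-06
MON MH1 131 0 9.0 2.5E-30
MON MH2 80 1 7.0 1.0E-18
MON MH3 39 9 5.1 1.6E-06
MON MH4 21 1 3.5 1.3E-05
MON MH5 122 14 7.1 1.4E-22
MON MH6 21 3 2.6 8.6E-05
MON MH7 126 21 7.1 8.4E-21
MON MH8 26 3 3.5 6.5E-06
MON MH9 33 6 2.6 2.6E-06
MON MH10 26 0 2.5 3.4E-07
MON MH11 159 29 7.2 6.4E-25
NOR NH1 12 0 1.8 5.3E-04
NOR NH2 49 14 3.8 5.7E-07
NOR NH3 41 10 5.9 1.3E-06
NOR NH4 38 12 5.2 2.5E-05
NOR NH5 58 20 1.9 6.0E-07
NOR NH6 45 17 1.9 3.0E-05"
  read.table(text = txt, header = TRUE, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "numeric", "integer",
                            "numeric", "character"))
}

# Small phased genotype set built directly from allele matrices.
make_phased <- function(pat, mat, chromosome = 1L) {
  m <- ncol(pat)
  map <- data.frame(marker_id = sprintf("chr%d_m%04d", chromosome, 1:m),
                    chromosome = chromosome,
                    position_bp = seq(1e6, by = 1e6, length.out = m),
                    allele1 = "1", allele2 = "2", stringsAsFactors = FALSE)
  phased_genotypes(sprintf("A%03d", seq_len(nrow(pat))), pat, mat, map)
}

# A small simulated population with one embedded lethal; defaults sized for
# fast unit tests.
quick_population <- function(seed = 7, penetrance = 1, target_frequency = 0.08,
                             n_dams = 500, n_sires = 60, n_mgs = 60,
                             markers_per_chromosome = 80, n_chromosomes = 2,
                             recombination_rate_per_bp = 1e-8, ...) {
  win_start <- if (markers_per_chromosome >= 49) 30
               else markers_per_chromosome - 19
  cfg <- simulation_config(
    n_sires = n_sires, n_mgs = n_mgs, n_dams = n_dams,
    n_founder_haplotypes = 20, n_chromosomes = n_chromosomes,
    markers_per_chromosome = markers_per_chromosome,
    recombination_rate_per_bp = recombination_rate_per_bp,
    lethal_specs = list(lethal_spec(1, win_start, 20,
                                    target_frequency = target_frequency,
                                    penetrance = penetrance)),
    seed = seed, ...)
  map <- simulate_marker_map(cfg)
  pop <- simulate_population(map, cfg)
  pop$config <- cfg
  pop
}
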