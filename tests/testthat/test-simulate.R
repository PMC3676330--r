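test_that("marker map has strictly increasing unique positions and is reproducible", {
  cfg <- simulation_config(n_chromosomes = 2, markers_per_chromosome = 100,
                           chromosome_length_bp = 1e7, seed = 42)
  map <- simulate_marker_map(cfg)
  expect_equal(nrow(map), 200)
  for (chr in 1:2) {
    pos <- map$position_bp[map$chromosome == chr]
    expect_length(pos, 100)
    expect_true(all(diff(pos) > 0))
    expect_true(all(pos >= 1 & pos <= 1e7))
  }
  expect_false(anyDuplicated(map$marker_id) > 0)
  expect_identical(map, simulate_marker_map(cfg))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(markers_per_chromosome = 0), "integer >= 1")
  expect_error(simulation_config(n_chromosomes = 0), "integer >= 1")
  expect_error(simulation_config(mu_heifer = 1.2), "probability")
  expect_error(lethal_spec(1, 1, 20, target_frequency = 0.6), "0, 0.5")
  # fewer than one carrier reachable in a parental stratum
  expect_error(
    simulation_config(n_sires = 4, n_mgs = 4, lethal_specs = list(
      lethal_spec(1, 1, 20, target_frequency = 0.01))),
    "unreachable")
})

test_that("complete penetrance leaves no genotyped lethal homozygote", {
  pop <- quick_population(seed = 7, penetrance = 1)
  ct <- pop$carrier_truth
  hom_genotyped <- ct[ct$copies == 2L & ct$genotyped & ct$role == "progeny", ]
  expect_equal(nrow(hom_genotyped), 0L)
  # and the genotyped cohort itself contains no window homozygote
  lw <- pop$lethal_windows
  idx <- which(pop$genotypes$map$chromosome == lw$chromosome)
  idx <- idx[lw$start_marker:lw$end_marker]
  keys <- enumerate_window_haplotypes(pop$genotypes, idx)
  prog <- pop$pedigree$animal_id[pop$pedigree$role == "progeny"]
  prog <- intersect(prog, pop$genotypes$animal_id)
  expect_equal(sum(keys$pat[prog] == lw$haplotype &
                     keys$mat[prog] == lw$haplotype), 0L)
})

test_that("zero penetrance leaves homozygotes at the Mendelian rate", {
  pop <- quick_population(seed = 11, penetrance = 0, n_dams = 3000,
                          recombination_rate_per_bp = 0)
  ct <- pop$carrier_truth
  ped <- pop$pedigree
  prog <- ped[ped$role == "progeny", ]
  copies <- setNames(ct$copies, ct$animal_id)
  # expectation from the parents' true diplotypes, conceptus by conceptus
  p_hom <- (copies[prog$sire_id] / 2) * (copies[prog$dam_id] / 2)
  expected <- sum(p_hom)
  sdev <- sqrt(sum(p_hom * (1 - p_hom)))
  observed <- sum(ct$copies == 2L & ct$role == "progeny")
  expect_gt(expected, 5)  # the check must have power
  expect_lt(abs(observed - expected), 3 * sdev + 1e-9)
  expect_true(all(ct$genotyped[ct$role == "progeny"]))
})

test_that("without recombination every progeny haplotype copies one parental chromosome", {
  pop <- quick_population(seed = 3, n_dams = 50, penetrance = 0,
                          recombination_rate_per_bp = 0,
                          markers_per_chromosome = 60)
  g <- pop$genotypes
  ped <- pop$pedigree
  prog <- ped[ped$role == "progeny" & ped$animal_id %in% g$animal_id, ]
  for (chr in 1:2) {
    idx <- which(g$map$chromosome == chr)
    for (i in seq_len(min(nrow(prog), 20))) {
      child <- g$pat[prog$animal_id[i], idx]
      sire <- prog$sire_id[i]
      expect_true(identical(child, g$pat[sire, idx]) ||
                    identical(child, g$mat[sire, idx]))
    }
  }
})

test_that("realized maternal-chromosome frequency matches the target", {
  # rate 0: the frequency bookkeeping matches real marker density, where a
  # 20-marker window is ~1 Mb and within-window recombination is negligible;
  # on the compressed test genome a window spans a third of the chromosome
  # and crossovers would erode the intact haplotype string
  f <- 0.08
  pop <- quick_population(seed = 5, penetrance = 0, target_frequency = f,
                          n_dams = 6000, n_sires = 50, n_mgs = 50,
                          markers_per_chromosome = 60, n_chromosomes = 1,
                          recombination_rate_per_bp = 0)
  lw <- pop$lethal_windows
  g <- pop$genotypes
  idx <- lw$start_marker:lw$end_marker
  prog <- intersect(pop$pedigree$animal_id[pop$pedigree$role == "progeny"],
                    g$animal_id)
  km <- enumerate_window_haplotypes(g, idx)$mat[prog]
  n <- length(km)
  expect_gte(n, 5000)
  f_hat <- mean(km == lw$haplotype)
  se <- sqrt(f * (1 - f) / n)
  expect_lt(abs(f_hat - f), 3 * se)
})

test_that("population simulation is reproducible under a fixed seed", {
  a <- quick_population(seed = 9, n_dams = 100)
  b <- quick_population(seed = 9, n_dams = 100)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$carrier_truth, b$carrier_truth)
})

test_that("insemination outcomes follow the parity means and lethal risk", {
  pop <- quick_population(seed = 13, n_dams = 4000, target_frequency = 0.1)
  cfg <- pop$config
  ins <- simulate_inseminations(pop$pedigree, pop$carrier_truth, cfg)
  expect_setequal(names(ins), c("bull_id", "cow_id", "cow_sire_id",
                                "parity_class", "outcome"))
  ct <- pop$carrier_truth
  copies <- setNames(ct$copies, ct$animal_id)
  nc <- ins[copies[ins$bull_id] == 0L, ]  # noncarrier bull: no lethal risk
  for (par in c("heifer", "cow")) {
    mu <- if (par == "heifer") cfg$mu_heifer else cfg$mu_cow
    x <- nc$outcome[nc$parity_class == par]
    expect_lt(abs(mean(x) - mu), 3 * sqrt(mu * (1 - mu) / length(x)))
  }
  expect_identical(ins, simulate_inseminations(pop$pedigree,
                                               pop$carrier_truth, cfg))
})

test_that("zero conception rate yields all-failure inseminations", {
  pop <- quick_population(seed = 17, n_dams = 200, mu_heifer = 0, mu_cow = 0)
  ins <- simulate_inseminations(pop$pedigree, pop$carrier_truth, pop$config)
  expect_true(all(ins$outcome == 0L))
})
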