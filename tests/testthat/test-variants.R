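test_that("search regions add the flank and clamp at the chromosome start", {
  r <- define_search_region(list(chromosome = 21, start_bp = 20.2e6,
                                 end_bp = 22.3e6), flank_mb = 6)
  expect_equal(c(r$start_mb, r$end_mb), c(14.2, 28.3))
  r2 <- define_search_region(list(chromosome = 1, start_bp = 1.9e6,
                                  end_bp = 3.3e6), flank_mb = 6)
  expect_equal(r2$start_bp, 1)
  expect_equal(c(r2$start_mb, r2$end_mb), c(0, 9.3))
  r3 <- define_search_region(list(chromosome = 2, start_bp = 5e6,
                                  end_bp = 6e6), flank_mb = 0)
  expect_equal(c(r3$start_bp, r3$end_bp), c(5e6, 6e6))
  expect_error(define_search_region(list(chromosome = 1, start_bp = 1,
                                         end_bp = 2), flank_mb = -1),
               "nonnegative")
  # the output interval always contains the input
  expect_lte(r$start_bp, 20.2e6)
  expect_gte(r$end_bp, 22.3e6)
})

test_that("genotype-pattern filter equals brute-force enumeration and keeps the causative", {
  region <- list(chromosome = 5, start_bp = 10e6, end_bp = 22e6)
  carriers <- c("CAR1", "CAR2")
  controls <- sprintf("CTL%02d", 1:10)
  vcf <- simulate_vcf(region, carriers, controls,
                      causative = list(gene = "CAND1"), n_background = 50,
                      seed = 61)
  expect_equal(nrow(vcf$sites), 51L)
  keep <- brute_force_pattern(vcf, carriers, controls)
  got <- filter_genotype_pattern(vcf, carriers, controls)
  expect_identical(got$sites, vcf$sites[keep, , drop = FALSE])
  # the embedded causative always survives; here it is the only survivor
  expect_equal(nrow(got$sites), 1L)
  expect_equal(got$sites$gene, "CAND1")
  # without a causative the filter returns (almost surely) nothing
  vcf0 <- simulate_vcf(region, carriers, controls, causative = NULL,
                       n_background = 50, seed = 61)
  got0 <- filter_genotype_pattern(vcf0, carriers, controls)
  expect_identical(brute_force_pattern(vcf0, carriers, controls),
                   rep(FALSE, 50))
  expect_equal(nrow(got0$sites), 0L)
})

test_that("the pattern filter is monotone in carriers and controls", {
  region <- list(chromosome = 1, start_bp = 1e6, end_bp = 5e6)
  carriers <- c("CAR1", "CAR2", "CAR3")
  controls <- sprintf("CTL%02d", 1:8)
  vcf <- simulate_vcf(region, carriers, controls,
                      causative = list(), n_background = 80, seed = 71)
  base <- nrow(filter_genotype_pattern(vcf, carriers[1], controls[1:4])$sites)
  more_car <- nrow(filter_genotype_pattern(vcf, carriers[1:2],
                                           controls[1:4])$sites)
  more_ctl <- nrow(filter_genotype_pattern(vcf, carriers[1],
                                           controls[1:8])$sites)
  expect_lte(more_car, base)
  expect_lte(more_ctl, base)
})

test_that("hom-alt carriers, missing genotypes and empty controls are handled", {
  sites <- data.frame(chrom = 1, pos = c(100, 200, 300),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  geno <- matrix(c(2L, 0L,   # hom-alt carrier: rejected
                   1L, 0L,   # clean het/absent: kept
                   NA, 0L),  # missing carrier genotype
                 nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, c("CAR1", "CTL1")))
  vs <- variant_set(sites, geno)
  strict <- filter_genotype_pattern(vs, "CAR1", "CTL1")
  expect_equal(strict$sites$pos, 200)
  lenient <- filter_genotype_pattern(vs, "CAR1", "CTL1", lenient = TRUE)
  expect_equal(lenient$sites$pos, c(200, 300))
  expect_warning(filter_genotype_pattern(vs, "CAR1", character(0)),
                 "empty control set")
  expect_error(filter_genotype_pattern(vs, "NOPE", "CTL1"), "NOPE")
  expect_error(filter_genotype_pattern(vs, "CAR1", "CAR1"), "disjoint")
  expect_error(filter_genotype_pattern(vs, character(0), "CTL1"), "empty")
})

test_that("consequence filter keeps protein-truncating and doubly damaging missense", {
  sites <- data.frame(chrom = 1, pos = 1:5, ref = "A", alt = "T",
                      gene = paste0("G", 1:5),
                      consequence = c("stop_gain", "missense", "missense",
                                      "synonymous", "frameshift"),
                      sift_damaging = c(FALSE, TRUE, TRUE, TRUE, FALSE),
                      polyphen_damaging = c(FALSE, TRUE, FALSE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  geno <- matrix(1L, 5, 1, dimnames = list(NULL, "CAR1"))
  out <- filter_consequence(variant_set(sites, geno))
  expect_equal(out$sites$consequence, c("stop_gain", "missense", "frameshift"))
  expect_equal(out$sites$pos, c(1L, 2L, 5L))
})

test_that("consequence filter joins an external annotation and flags unannotated sites", {
  sites <- data.frame(chrom = 1, pos = c(10, 20), ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  geno <- matrix(1L, 2, 1, dimnames = list(NULL, "CAR1"))
  ann <- data.frame(chrom = 1, pos = 10, alt = "T", gene = "SHBG",
                    consequence = "stop_gain", sift_damaging = TRUE,
                    polyphen_damaging = TRUE, stringsAsFactors = FALSE)
  expect_warning(out <- filter_consequence(variant_set(sites, geno), ann),
                 "unknown")
  expect_equal(out$sites$consequence, c("stop_gain", "unknown"))
  expect_equal(out$sites$gene[1], "SHBG")
})

test_that("haplotype association distinguishes exclusive, multiple and eliminated", {
  dip <- data.frame(animal_id = paste0("K", 1:6),
                    hap1 = c("H4", "H4", "Hx", "Hy", "Hz", "Hy"),
                    hap2 = c("Ha", "Hb", "Ha", "Hb", "Ha", "Hz"),
                    stringsAsFactors = FALSE)
  # variant only in H4 carriers
  g1 <- setNames(c(1L, 1L, 0L, 0L, 0L, 0L), dip$animal_id)
  chk1 <- haplotype_association_check(g1, dip, "H4")
  expect_equal(chk1$associated, "H4")
  expect_equal(chk1$status, "exclusive association")
  expect_false(chk1$ancestral_segregating)
  # variant on three haplotypes plus a viable homozygote: eliminated
  g2 <- setNames(c(1L, 1L, 1L, 2L, 1L, 1L), dip$animal_id)
  chk2 <- haplotype_association_check(g2, dip, "H4")
  expect_equal(chk2$status, "eliminated")
  expect_equal(chk2$hom_alt_animals, "K4")
  # haplotype homozygote that is only heterozygous for the variant
  dip3 <- data.frame(animal_id = c("K1", "K2"), hap1 = c("H2", "Ha"),
                     hap2 = c("H2", "Hb"), stringsAsFactors = FALSE)
  g3 <- setNames(c(1L, 0L), dip3$animal_id)
  chk3 <- haplotype_association_check(g3, dip3, "H2")
  expect_true(chk3$ancestral_segregating)
  expect_equal(chk3$ancestral_animals, "K1")
  expect_error(haplotype_association_check(setNames(1L, "ZZ"), dip, "H4"),
               "no animal shared")
})

test_that("variant sets round-trip through VCF with annotation intact", {
  region <- list(chromosome = 3, start_bp = 1e6, end_bp = 2e6)
  vcf <- simulate_vcf(region, c("CAR1", "CAR2"), c("CTL1", "CTL2"),
                      causative = list(gene = "CAND1"), n_background = 10,
                      seed = 81)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(vcf, path)
  back <- read_vcf_variants(path)
  expect_equal(back$sites$pos, vcf$sites$pos)
  expect_equal(back$sites$consequence, vcf$sites$consequence)
  expect_equal(back$sites$sift_damaging, vcf$sites$sift_damaging)
  expect_identical(unname(back$geno), unname(vcf$geno))
  # identical seed gives a byte-identical VCF body
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(simulate_vcf(region, c("CAR1", "CAR2"),
                                 c("CTL1", "CTL2"),
                                 causative = list(gene = "CAND1"),
                                 n_background = 10, seed = 81), path2)
  expect_identical(readLines(path), readLines(path2))
})
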