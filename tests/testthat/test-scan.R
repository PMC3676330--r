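test_that("window keys are exact allele strings", {
  pat <- rbind(c(1L, 2L, 1L), c(1L, 2L, 1L))
  mat <- rbind(c(2L, 2L, 2L), c(1L, 2L, 1L))
  g <- make_phased(pat, mat)
  keys <- enumerate_window_haplotypes(g, 1:3)
  expect_equal(unname(keys$pat), c("121", "121"))
  expect_equal(unname(keys$mat), c("222", "121"))
  # identical strings share a key across animals and copies
  expect_equal(keys$pat[["A001"]], keys$mat[["A002"]])
})

test_that("distinct key count is bounded by chromosome copies and 2^n", {
  pop <- quick_population(seed = 31, n_dams = 80, markers_per_chromosome = 40)
  g <- pop$genotypes
  idx <- which(g$map$chromosome == 1)[1:20]
  keys <- enumerate_window_haplotypes(g, idx)
  n_keys <- length(unique(c(keys$pat, keys$mat)))
  expect_lte(n_keys, min(2 * length(g$animal_id), 2^20))
})

test_that("boundary-crossing windows are skipped with a message", {
  pop <- quick_population(seed = 31, n_dams = 20, markers_per_chromosome = 30)
  expect_message(out <- enumerate_window_haplotypes(pop$genotypes, 25:35),
                 "boundary")
  expect_null(out)
})

test_that("haplotype frequencies count maternal chromosomes of animals with progeny", {
  ped <- data.frame(animal_id = c(sprintf("A%03d", 1:10), "C1"),
                    sire_id = c(rep(NA, 10), "A001"),
                    mgs_id = c(rep(NA, 10), "A002"),
                    dam_id = c(rep(NA, 10), "A003"),
                    stringsAsFactors = FALSE)
  keys <- setNames(c("11", "11", "22", rep("22", 7)), sprintf("A%03d", 1:10))
  f <- estimate_frequencies(keys, ped)
  expect_equal(sum(f$freq), 1)
  # only A001..A003 have progeny; A001/A002 carry "11", A003 carries "22"
  expect_equal(f$freq[f$haplotype == "11"], 2 / 3)
  expect_equal(f$freq[f$haplotype == "22"], 1 / 3)
  # strict 'higher than' drop rule
  keys100 <- setNames(c("11", rep("22", 99)), sprintf("A%03d", 1:100))
  allped <- data.frame(animal_id = paste0("C", 1:100),
                       sire_id = sprintf("A%03d", 1:100),
                       mgs_id = NA, dam_id = NA, stringsAsFactors = FALSE)
  f100 <- estimate_frequencies(keys100, allped, min_freq = 0.01)
  expect_false("11" %in% f100$haplotype)  # f = 0.01 exactly is dropped
  expect_warning(estimate_frequencies(keys, ped[0, ]), "no genotyped animal")
})

test_that("expected homozygote count follows the transmission formula", {
  g <- data.frame(n_ij = 100, p_ik = 0.5, q_jk = 0.5)
  expect_equal(expected_homozygotes(g, f_k = 0.1), 15)
  gd <- data.frame(n_ij = 7, p_ik = 1, q_jk = 1, r_jk = 1)
  expect_equal(expected_homozygotes(gd, f_k = 0.3, use_dam = TRUE), 7)
  g0 <- data.frame(n_ij = 50, p_ik = 0.5, q_jk = 0)
  expect_equal(expected_homozygotes(g0, f_k = 0), 0)
  expect_error(expected_homozygotes(data.frame(n_ij = 5, p_ik = 0, q_jk = 0.5),
                                    f_k = 0.1), "carrier-sire")
  expect_error(expected_homozygotes(data.frame(n_ij = 5, p_ik = 0.3, q_jk = 0.5),
                                    f_k = 0.1), "0, 0.5 or 1")
})

test_that("genotyped-dam expectation is invariant to haplotype frequency", {
  set.seed(99)
  g <- random_groups(6, use_dam = TRUE)
  vals <- sapply(c(0, 0.05, 0.2, 0.49), function(f)
    expected_homozygotes(g, f_k = f, use_dam = TRUE))
  expect_true(all(vals == vals[1]))
  # while the MGS form does move with f
  vals2 <- sapply(c(0, 0.2), function(f) expected_homozygotes(g, f_k = f))
  expect_false(vals2[1] == vals2[2])
})

test_that("deficit test is a one-cell 1-df chi-square with one-sided flagging", {
  t0 <- deficit_test(10, 10)
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p, 1)
  expect_false(t0$deficit)
  t1 <- deficit_test(0, 20)
  expect_equal(t1$chi2, 20)
  expect_equal(t1$p, pchisq(20, 1, lower.tail = FALSE))
  expect_true(t1$deficit)
  # excess is tested but not flagged as deficit
  t2 <- deficit_test(40, 20)
  expect_false(t2$deficit)
  expect_error(deficit_test(0, 0), "E <= 0")
})

test_that("observed homozygotes are counted by exact double match", {
  kp <- c("11", "12", "11", "22")
  km <- c("11", "11", "11", "22")
  expect_equal(observed_homozygotes(kp, km, "11"), 2)
  expect_equal(observed_homozygotes(kp, km, "12"), 0)
})

test_that("the scan finds an embedded lethal window with zero homozygotes", {
  pop <- quick_population(seed = 41, n_dams = 2000, n_sires = 100,
                          n_mgs = 100, target_frequency = 0.1)
  res <- scan_genome(pop$genotypes, pop$pedigree)
  lw <- pop$lethal_windows
  hit <- res[res$chromosome == lw$chromosome & res$window == lw$start_marker &
               res$haplotype == lw$haplotype, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$O, 0)
  expect_gt(hit$E, 5)
  expect_true(hit$deficit)
  # results are sorted and frequencies respect the floor
  expect_true(all(res$freq > 0.01))
  expect_true(!is.unsorted(res$chromosome))
  # determinism
  res2 <- scan_genome(pop$genotypes, pop$pedigree)
  expect_identical(res, res2)
})

test_that("an empty genotype set yields an empty scan result", {
  pop <- quick_population(seed = 41, n_dams = 20, markers_per_chromosome = 30)
  g0 <- subset_phased(pop$genotypes,
                      animals = pop$genotypes$animal_id[
                        !grepl("^P", pop$genotypes$animal_id)])
  # no eligible progeny -> empty result with the standard columns
  ped0 <- pop$pedigree[pop$pedigree$role != "progeny", ]
  res <- scan_genome(g0, ped0)
  expect_equal(nrow(res), 0L)
  expect_true(all(c("chromosome", "haplotype", "E", "O", "p") %in% names(res)))
})

test_that("null simulations produce no excess of significant deficits", {
  cfg <- simulation_config(n_sires = 120, n_mgs = 120, n_dams = 2500,
                           n_founder_haplotypes = 25, n_chromosomes = 4,
                           markers_per_chromosome = 130, seed = 271)
  map <- simulate_marker_map(cfg)
  pop <- simulate_population(map, cfg)
  res <- scan_genome(pop$genotypes, pop$pedigree)
  expect_gte(nrow(res), 1e4)
  false_pos <- mean(res$p < 1e-4 & res$deficit)
  expect_lte(false_pos, 10 * 1e-4)
})

test_that("consecutive significant windows sharing the minimum O merge into regions", {
  base <- data.frame(chromosome = 1L, start_bp = 0L, end_bp = 0L,
                     haplotype = "11", freq = 0.05, E = 30, O = 0L,
                     chi2 = 30, p = 1e-7, deficit = TRUE)
  mk <- function(win, O, p = 1e-7, chr = 1L) {
    r <- base; r$window <- win; r$O <- O; r$p <- p; r$chromosome <- chr
    r$start_bp <- win * 1e6; r$end_bp <- (win + 19) * 1e6
    r
  }
  # run 10..14 with O = 0, plus a separated window 40 also with O = 0, plus
  # a significant window with O = 2 (not the minimum) and a non-significant one
  res <- rbind(mk(10, 0), mk(11, 0), mk(12, 0), mk(13, 0), mk(14, 0),
               mk(40, 0), mk(20, 2), mk(60, 0, p = 0.5))
  res$deficit <- res$p < 0.4
  regions <- merge_windows(res, scan_config())
  expect_equal(nrow(regions), 2L)
  expect_equal(regions$start_bp[1], 10e6)
  expect_equal(regions$end_bp[1], (14 + 19) * 1e6)
  expect_equal(regions$n_windows, c(5L, 1L))
  expect_equal(regions$O, c(0L, 0L))
  # a single significant window is its own region
  single <- merge_windows(mk(7, 0), scan_config())
  expect_equal(nrow(single), 1L)
  expect_equal(single$start_bp, 7e6)
  # two chromosomes are merged independently
  two <- merge_windows(rbind(mk(5, 0), mk(5, 0, chr = 2L)), scan_config())
  expect_equal(two$chromosome, c(1L, 2L))
})

test_that("carrier concordance reports the overlap percentage", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(carrier_concordance(a, a)$pct_overlap, 100)
  expect_equal(carrier_concordance(a, !a)$pct_overlap, 0)
  expect_equal(carrier_concordance(a, !a)$n_b_only, 2)
  expect_error(carrier_concordance(rep(FALSE, 4), a), "no carrier")
  expect_error(carrier_concordance(a, a[1:2]), "same animal set")
})
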