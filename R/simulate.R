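#' Specification of an embedded lethal haplotype
#'
#' Describes one recessive lethal to embed in a simulated population: the
#' marker window it occupies, its carrier-chromosome frequency in the
#' parental generation, and its penetrance (the probability that a homozygous
#' conceptus dies before entering the genotyped cohort). Incomplete
#' penetrance leaves residual homozygotes, as observed for several real
#' deficit regions; `fertility_effect = FALSE` models defects where death (or
#' culling) happens after calving, so homozygotes are missing from the
#' genotyped cohort but conception records are untouched (the syndactyly
#' pattern).
#'
#' @param chromosome chromosome index the lethal sits on.
#' @param window_start_marker 1-based index of the first marker of the lethal
#'   window within that chromosome.
#' @param window_n_markers number of markers in the window (default 20, the
#'   scan window size).
#' @param target_frequency carrier-chromosome frequency in (0, 0.5).
#' @param penetrance probability in `[0, 1]` that a homozygote dies before
#'   genotyping.
#' @param fertility_effect logical; if `TRUE` the death occurs before calving
#'   and zeroes the conception outcome of the mating.
#' @return a list of class `lethal_spec`.
#' @export
lethal_spec <- function(chromosome, window_start_marker, window_n_markers = 20,
                        target_frequency, penetrance = 1,
                        fertility_effect = TRUE) {
  assert_count(chromosome, "chromosome")
  assert_count(window_start_marker, "window_start_marker")
  assert_count(window_n_markers, "window_n_markers", min = 2L)
  if (!is.numeric(target_frequency) || target_frequency <= 0 ||
      target_frequency >= 0.5)
    stop_config("'target_frequency' must lie in (0, 0.5)")
  assert_prob(penetrance, "penetrance")
  structure(list(chromosome = as.integer(chromosome),
                 window_start_marker = as.integer(window_start_marker),
                 window_n_markers = as.integer(window_n_markers),
                 target_frequency = target_frequency,
                 penetrance = penetrance,
                 fertility_effect = isTRUE(fertility_effect)),
            class = "lethal_spec")
}

#' Simulation configuration
#'
#' Parameters of the synthetic AI population: a parental generation of
#' `n_sires` mating bulls and `n_mgs` maternal grandsires whose chromosomes
#' are drawn from a founder haplotype pool, `n_dams` ungenotyped dams (each a
#' daughter of a random MGS), and a progeny generation produced by gene drop.
#' Defaults emulate a mid-sized dairy breed section: conception rates of 55%
#' in heifers and 45% in lactating cows (field values range roughly 40-55%
#' by breed and parity), and a recombination rate of 1e-8 per bp per meiosis
#' (about 1 Morgan per 100 Mb).
#'
#' @param n_sires,n_mgs number of mating bulls / maternal grandsires.
#' @param n_dams number of dams (daughters of the MGS stratum).
#' @param progeny_per_mating_mean Poisson mean number of genotyping-candidate
#'   conceptuses per mating.
#' @param insems_per_dam number of recorded inseminations per dam in
#'   [simulate_inseminations()].
#' @param n_founder_haplotypes size of the founder haplotype pool per
#'   chromosome.
#' @param n_chromosomes,markers_per_chromosome,chromosome_length_bp genome
#'   dimensions of the marker map.
#' @param lethal_specs list of [lethal_spec()] objects (possibly empty).
#' @param mu_heifer,mu_cow mean conception rates by parity class.
#' @param recombination_rate_per_bp crossover rate per bp per meiosis.
#' @param emit_dam_genotypes logical; dams are simulated but their genotypes
#'   are withheld by default, mirroring populations where dams are rarely
#'   genotyped. Set `TRUE` to include them (enables the genotyped-dam
#'   expectation formula).
#' @param heifer_fraction fraction of dams in the heifer parity class.
#' @param seed integer seed; all generator outputs are reproducible
#'   bit-for-bit given the same configuration.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_sires = 150, n_mgs = 150, n_dams = 2000,
                              progeny_per_mating_mean = 1,
                              insems_per_dam = 1,
                              n_founder_haplotypes = 30,
                              n_chromosomes = 2,
                              markers_per_chromosome = 150,
                              chromosome_length_bp = 1e8,
                              lethal_specs = list(),
                              mu_heifer = 0.55, mu_cow = 0.45,
                              recombination_rate_per_bp = 1e-8,
                              emit_dam_genotypes = FALSE,
                              heifer_fraction = 0.3,
                              seed = 1L) {
  assert_count(n_sires, "n_sires"); assert_count(n_mgs, "n_mgs")
  assert_count(n_dams, "n_dams")
  assert_count(n_founder_haplotypes, "n_founder_haplotypes", min = 2L)
  assert_count(n_chromosomes, "n_chromosomes")
  assert_count(markers_per_chromosome, "markers_per_chromosome")
  assert_count(chromosome_length_bp, "chromosome_length_bp")
  assert_count(insems_per_dam, "insems_per_dam")
  if (!is.numeric(progeny_per_mating_mean) || progeny_per_mating_mean <= 0)
    stop_config("'progeny_per_mating_mean' must be positive")
  assert_prob(mu_heifer, "mu_heifer"); assert_prob(mu_cow, "mu_cow")
  assert_prob(heifer_fraction, "heifer_fraction")
  if (!is.numeric(recombination_rate_per_bp) || recombination_rate_per_bp < 0)
    stop_config("'recombination_rate_per_bp' must be nonnegative")
  if (markers_per_chromosome > chromosome_length_bp)
    stop_config("more markers than base pairs on a chromosome")
  if (!is.list(lethal_specs) ||
      !all(vapply(lethal_specs, inherits, TRUE, "lethal_spec")))
    stop_config("'lethal_specs' must be a list of lethal_spec objects")
  for (ls in lethal_specs) {
    if (ls$chromosome > n_chromosomes)
      stop_config("lethal chromosome %d exceeds n_chromosomes", ls$chromosome)
    if (ls$window_start_marker + ls$window_n_markers - 1L >
        markers_per_chromosome)
      stop_config("lethal window exceeds markers_per_chromosome")
    if (round(2 * ls$target_frequency * n_sires) < 1 ||
        round(2 * ls$target_frequency * n_mgs) < 1)
      stop_config(
        "target_frequency %.3f unreachable: fewer than one carrier in a parental stratum",
        ls$target_frequency)
    if (round(ls$target_frequency * n_founder_haplotypes) < 1)
      stop_config("target_frequency %.3f unreachable with founder pool of %d",
                  ls$target_frequency, n_founder_haplotypes)
  }
  structure(list(n_sires = as.integer(n_sires), n_mgs = as.integer(n_mgs),
                 n_dams = as.integer(n_dams),
                 progeny_per_mating_mean = progeny_per_mating_mean,
                 insems_per_dam = as.integer(insems_per_dam),
                 n_founder_haplotypes = as.integer(n_founder_haplotypes),
                 n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 chromosome_length_bp = as.numeric(chromosome_length_bp),
                 lethal_specs = lethal_specs,
                 mu_heifer = mu_heifer, mu_cow = mu_cow,
                 recombination_rate_per_bp = recombination_rate_per_bp,
                 emit_dam_genotypes = isTRUE(emit_dam_genotypes),
                 heifer_fraction = heifer_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a SNP-array marker map
#'
#' Draws `markers_per_chromosome` marker positions per autosome, uniformly at
#' random without replacement, so positions are strictly increasing 1-based
#' integers. Marker ids are unique across chromosomes.
#'
#' @param config a [simulation_config()].
#' @return a `data.frame` with columns `marker_id`, `chromosome`,
#'   `position_bp`, `allele1`, `allele2`, sorted by (chromosome, position).
#' @export
simulate_marker_map <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  maps <- lapply(seq_len(config$n_chromosomes), function(chr) {
    pos <- sort(sample.int(config$chromosome_length_bp,
                           config$markers_per_chromosome))
    data.frame(marker_id = sprintf("chr%d_m%04d", chr,
                                   seq_len(config$markers_per_chromosome)),
               chromosome = chr, position_bp = pos,
               allele1 = "1", allele2 = "2",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

# One meiotic gamete per row. P and M are (gametes x markers) matrices giving
# each gamete's parental pat/mat haplotypes; crossovers are Poisson along the
# chromosome at `rate` per bp.
make_gametes <- function(P, M, pos, rate) {
  n <- nrow(P)
  start <- sample(c(0L, 1L), n, replace = TRUE)
  out <- matrix(1L, n, ncol(P))
  k <- if (rate > 0) stats::rpois(n, rate * pos[length(pos)]) else integer(n)
  plain <- k == 0L
  pickP <- plain & start == 0L
  pickM <- plain & start == 1L
  out[pickP, ] <- P[pickP, , drop = FALSE]
  out[pickM, ] <- M[pickM, , drop = FALSE]
  for (i in which(!plain)) {
    cx <- sort(stats::runif(k[i], min = 1, max = pos[length(pos)]))
    strand <- (start[i] + findInterval(pos, cx)) %% 2L
    out[i, ] <- ifelse(strand == 0L, P[i, ], M[i, ])
  }
  out
}

window_string <- function(hap_matrix, idx) {
  do.call(paste0, as.data.frame(hap_matrix[, idx, drop = FALSE]))
}

#' Simulate an AI-structured population by founder-pool gene drop
#'
#' Builds a three-layer population with the family structure the
#' deficit-of-homozygotes scan assumes: genotyped sires and maternal
#' grandsires (MGS) whose chromosomes come from a founder haplotype pool,
#' ungenotyped dams (each the daughter of one MGS and an anonymous pool
#' chromosome), and genotyped progeny gene-dropped from sire x dam matings
#' with recombination.
#'
#' Each [lethal_spec()] is realized as one designated founder haplotype
#' string over its marker window. Carriers in the sire and MGS strata are
#' placed exactly: `round(2 * f * n)` distinct heterozygous carriers per
#' stratum (a live parent cannot be a lethal homozygote), with the carrier
#' copy assigned to the paternal or maternal slot at random; dam maternal
#' chromosomes carry the lethal founder with probability `f`. Homozygous
#' progeny are removed before genotype emission with probability
#' `penetrance`.
#'
#' @param map marker map from [simulate_marker_map()].
#' @param config a [simulation_config()]; must be the one used for `map`.
#' @return a list of class `sim_population` with elements:
#'   \describe{
#'     \item{pedigree}{`data.frame` with columns `animal_id`, `sire_id`,
#'       `mgs_id`, `dam_id`, `sex`, `parity_class`, `role`.}
#'     \item{genotypes}{[phased_genotypes()] of sires, MGS and surviving
#'       progeny (plus dams when `emit_dam_genotypes`).}
#'     \item{carrier_truth}{`data.frame` (`animal_id`, `role`, `lethal_id`,
#'       `copies`, `died`, `genotyped`): every animal's true diplotype at
#'       each lethal window.}
#'     \item{lethal_windows}{`data.frame` describing each embedded lethal:
#'       id, chromosome, marker span, bp span, allele string.}
#'   }
#' @export
simulate_population <- function(map, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  nchr <- config$n_chromosomes
  m <- config$markers_per_chromosome
  nf <- config$n_founder_haplotypes
  chr_idx <- lapply(seq_len(nchr), function(chr) which(map$chromosome == chr))

  lethals <- config$lethal_specs
  lethal_ids <- if (length(lethals))
    sprintf("LH%d", seq_along(lethals)) else character(0)
  # one designated founder index per lethal, distinct within a chromosome
  lethal_founder <- integer(length(lethals))
  for (chr in unique(vapply(lethals, `[[`, 1L, "chromosome")))
    lethal_founder[vapply(lethals, `[[`, 1L, "chromosome") == chr] <-
      seq_len(sum(vapply(lethals, `[[`, 1L, "chromosome") == chr))

  # founder pool per chromosome: iid allele draws at marker-specific
  # frequencies; lethal window strings made unique to their founder
  pool <- vector("list", nchr)
  win_idx_local <- vector("list", length(lethals))
  for (chr in seq_len(nchr)) {
    freq1 <- stats::runif(m, 0.1, 0.9)
    H <- matrix(ifelse(stats::runif(nf * m) < rep(freq1, each = nf), 1L, 2L),
                nrow = nf, ncol = m)
    for (li in seq_along(lethals)) {
      ls <- lethals[[li]]
      if (ls$chromosome != chr) next
      idx <- ls$window_start_marker:(ls$window_start_marker +
                                       ls$window_n_markers - 1L)
      win_idx_local[[li]] <- idx
      lf <- lethal_founder[li]
      for (rep in seq_len(200L)) {
        key <- paste0(H[lf, idx], collapse = "")
        clash <- which(window_string(H, idx) == key)
        clash <- setdiff(clash, lf)
        if (!length(clash)) break
        H[clash, idx] <- ifelse(stats::runif(length(clash) * length(idx)) <
                                  rep(freq1[idx], each = length(clash)),
                                1L, 2L)
      }
    }
    pool[[chr]] <- H
  }

  lethal_chr <- vapply(lethals, `[[`, 1L, "chromosome")
  lethal_key <- vapply(seq_along(lethals), function(li) {
    paste0(pool[[lethal_chr[li]]][lethal_founder[li], win_idx_local[[li]]],
           collapse = "")
  }, character(1))

  nonlethal_idx <- lapply(seq_len(nchr), function(chr)
    setdiff(seq_len(nf), lethal_founder[lethal_chr == chr]))

  draw_parent_stratum <- function(n, prefix) {
    # two pool haplotypes per animal and chromosome from non-lethal founders
    ids <- sprintf("%s%04d", prefix, seq_len(n))
    pat <- matrix(1L, n, nrow(map)); mat <- matrix(1L, n, nrow(map))
    for (chr in seq_len(nchr)) {
      ok <- nonlethal_idx[[chr]]
      pat[, chr_idx[[chr]]] <-
        pool[[chr]][sample(ok, n, replace = TRUE), , drop = FALSE]
      mat[, chr_idx[[chr]]] <-
        pool[[chr]][sample(ok, n, replace = TRUE), , drop = FALSE]
    }
    # exact carrier placement per lethal: round(2fn) distinct heterozygous
    # carriers, with the carrier copy split evenly between the paternal and
    # maternal phase so the maternal-chromosome frequency (the scan's
    # estimation target) is realized at f exactly, not up to a label coin
    for (li in seq_along(lethals)) {
      ncar <- round(2 * lethals[[li]]$target_frequency * n)
      n_mat <- round(lethals[[li]]$target_frequency * n)
      carriers <- sample.int(n, ncar)
      lstr <- pool[[lethal_chr[li]]][lethal_founder[li], , drop = TRUE]
      to_pat <- seq_len(ncar) <= ncar - n_mat
      pat[carriers[to_pat], chr_idx[[lethal_chr[li]]]] <-
        matrix(lstr, sum(to_pat), m, byrow = TRUE)
      mat[carriers[!to_pat], chr_idx[[lethal_chr[li]]]] <-
        matrix(lstr, sum(!to_pat), m, byrow = TRUE)
    }
    list(id = ids, pat = pat, mat = mat)
  }

  sires <- draw_parent_stratum(config$n_sires, "S")
  mgs <- draw_parent_stratum(config$n_mgs, "G")

  # dams: paternal gamete from a random MGS, maternal chromosome from the
  # anonymous population pool (lethal founder with probability f)
  nd <- config$n_dams
  dam_id <- sprintf("D%05d", seq_len(nd))
  dam_sire <- sample(mgs$id, nd, replace = TRUE)
  di <- match(dam_sire, mgs$id)
  dam_pat <- matrix(1L, nd, nrow(map)); dam_mat <- matrix(1L, nd, nrow(map))
  for (chr in seq_len(nchr)) {
    idx <- chr_idx[[chr]]
    dam_pat[, idx] <- make_gametes(mgs$pat[di, idx, drop = FALSE],
                                   mgs$mat[di, idx, drop = FALSE],
                                   map$position_bp[idx],
                                   config$recombination_rate_per_bp)
    lis <- which(lethal_chr == chr)
    fsum <- sum(vapply(lis, function(li) lethals[[li]]$target_frequency, 0))
    u <- stats::runif(nd)
    draw <- sample(nonlethal_idx[[chr]], nd, replace = TRUE)
    cum <- 0
    for (li in lis) {
      f <- lethals[[li]]$target_frequency
      draw[u >= cum & u < cum + f] <- lethal_founder[li]
      cum <- cum + f
    }
    dam_mat[, idx] <- pool[[chr]][draw, , drop = FALSE]
    if (fsum >= 1) stop_config("combined lethal frequencies exceed 1")
  }

  # matings and gene drop
  mating_sire <- sample(sires$id, nd, replace = TRUE)
  n_off <- stats::rpois(nd, config$progeny_per_mating_mean)
  off_dam <- rep(seq_len(nd), n_off)
  np <- length(off_dam)
  if (np == 0L) stop_config("no progeny simulated; increase n_dams or mean")
  prog_id <- sprintf("P%06d", seq_len(np))
  si <- match(mating_sire[off_dam], sires$id)
  prog_pat <- matrix(1L, np, nrow(map)); prog_mat <- matrix(1L, np, nrow(map))
  for (chr in seq_len(nchr)) {
    idx <- chr_idx[[chr]]
    prog_pat[, idx] <- make_gametes(sires$pat[si, idx, drop = FALSE],
                                    sires$mat[si, idx, drop = FALSE],
                                    map$position_bp[idx],
                                    config$recombination_rate_per_bp)
    prog_mat[, idx] <- make_gametes(dam_pat[off_dam, idx, drop = FALSE],
                                    dam_mat[off_dam, idx, drop = FALSE],
                                    map$position_bp[idx],
                                    config$recombination_rate_per_bp)
  }

  # carrier truth (identity-by-state at the lethal window) and survival
  copies_of <- function(pat, mat, li) {
    idx <- chr_idx[[lethal_chr[li]]][win_idx_local[[li]]]
    (window_string(pat, idx) == lethal_key[li]) +
      (window_string(mat, idx) == lethal_key[li])
  }
  died <- rep(FALSE, np)
  truth <- list()
  for (li in seq_along(lethals)) {
    pen <- lethals[[li]]$penetrance
    hom <- copies_of(prog_pat, prog_mat, li) == 2L
    died <- died | (hom & stats::runif(np) < pen)
  }
  for (li in seq_along(lethals)) {
    truth[[li]] <- rbind(
      data.frame(animal_id = sires$id, role = "sire",
                 lethal_id = lethal_ids[li],
                 copies = copies_of(sires$pat, sires$mat, li),
                 died = FALSE, genotyped = TRUE, stringsAsFactors = FALSE),
      data.frame(animal_id = mgs$id, role = "mgs",
                 lethal_id = lethal_ids[li],
                 copies = copies_of(mgs$pat, mgs$mat, li),
                 died = FALSE, genotyped = TRUE, stringsAsFactors = FALSE),
      data.frame(animal_id = dam_id, role = "dam",
                 lethal_id = lethal_ids[li],
                 copies = copies_of(dam_pat, dam_mat, li),
                 died = FALSE, genotyped = config$emit_dam_genotypes,
                 stringsAsFactors = FALSE),
      data.frame(animal_id = prog_id, role = "progeny",
                 lethal_id = lethal_ids[li],
                 copies = copies_of(prog_pat, prog_mat, li),
                 died = died, genotyped = !died, stringsAsFactors = FALSE))
  }
  carrier_truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(animal_id = character(0), role = character(0),
               lethal_id = character(0), copies = integer(0),
               died = logical(0), genotyped = logical(0))

  parity <- ifelse(stats::runif(nd) < config$heifer_fraction, "heifer", "cow")
  pedigree <- rbind(
    data.frame(animal_id = sires$id, sire_id = NA_character_,
               mgs_id = NA_character_, dam_id = NA_character_, sex = "M",
               parity_class = NA_character_, role = "sire",
               stringsAsFactors = FALSE),
    data.frame(animal_id = mgs$id, sire_id = NA_character_,
               mgs_id = NA_character_, dam_id = NA_character_, sex = "M",
               parity_class = NA_character_, role = "mgs",
               stringsAsFactors = FALSE),
    data.frame(animal_id = dam_id, sire_id = dam_sire,
               mgs_id = NA_character_, dam_id = NA_character_, sex = "F",
               parity_class = parity, role = "dam",
               stringsAsFactors = FALSE),
    data.frame(animal_id = prog_id, sire_id = mating_sire[off_dam],
               mgs_id = dam_sire[off_dam], dam_id = dam_id[off_dam],
               sex = sample(c("M", "F"), np, replace = TRUE),
               parity_class = NA_character_, role = "progeny",
               stringsAsFactors = FALSE))

  keep <- !died
  geno_id <- c(sires$id, mgs$id, if (config$emit_dam_genotypes) dam_id,
               prog_id[keep])
  geno_pat <- rbind(sires$pat, mgs$pat,
                    if (config$emit_dam_genotypes) dam_pat,
                    prog_pat[keep, , drop = FALSE])
  geno_mat <- rbind(sires$mat, mgs$mat,
                    if (config$emit_dam_genotypes) dam_mat,
                    prog_mat[keep, , drop = FALSE])
  genotypes <- phased_genotypes(geno_id, geno_pat, geno_mat, map)

  lethal_windows <- if (length(lethals)) data.frame(
    lethal_id = lethal_ids,
    chromosome = lethal_chr,
    start_marker = vapply(lethals, `[[`, 1L, "window_start_marker"),
    end_marker = vapply(seq_along(lethals), function(li)
      max(win_idx_local[[li]]), integer(1)),
    start_bp = vapply(seq_along(lethals), function(li)
      map$position_bp[chr_idx[[lethal_chr[li]]][min(win_idx_local[[li]])]],
      integer(1)),
    end_bp = vapply(seq_along(lethals), function(li)
      map$position_bp[chr_idx[[lethal_chr[li]]][max(win_idx_local[[li]])]],
      integer(1)),
    haplotype = lethal_key,
    stringsAsFactors = FALSE
  ) else data.frame(lethal_id = character(0), chromosome = integer(0),
                    start_marker = integer(0), end_marker = integer(0),
                    start_bp = integer(0), end_bp = integer(0),
                    haplotype = character(0))

  structure(list(pedigree = pedigree, genotypes = genotypes,
                 carrier_truth = carrier_truth,
                 lethal_windows = lethal_windows),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  r <- table(x$pedigree$role)
  cat(sprintf(
    "sim_population: %s sires, %s MGS, %s dams, %s progeny (%d genotyped animals); %d lethal window(s)\n",
    r[["sire"]], r[["mgs"]], r[["dam"]], r[["progeny"]],
    length(x$genotypes$animal_id), nrow(x$lethal_windows)))
  invisible(x)
}

#' Simulate insemination records with conception outcomes
#'
#' Generates `insems_per_dam` inseminations per dam, each with a bull drawn
#' at random from the sire stratum. The conception outcome is 1 with
#' probability `mu_parity * (1 - P(conceptus homozygous lethal) * penetrance)`
#' for every embedded lethal whose `fertility_effect` is on, where
#' `P(homozygous) = (bull copies / 2) * (dam copies / 2)` from the true
#' diplotypes in `carrier_truth`.
#'
#' @param pedigree pedigree from [simulate_population()] (needs the `role`
#'   and `parity_class` columns).
#' @param carrier_truth carrier truth table from [simulate_population()].
#' @param config the [simulation_config()] used for the population.
#' @return a `data.frame` with columns `bull_id`, `cow_id`, `cow_sire_id`,
#'   `parity_class`, `outcome`.
#' @export
simulate_inseminations <- function(pedigree, carrier_truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  dams <- pedigree[pedigree$role == "dam", , drop = FALSE]
  bulls <- pedigree$animal_id[pedigree$role == "sire"]
  n <- nrow(dams) * config$insems_per_dam
  cow <- rep(dams$animal_id, each = config$insems_per_dam)
  cow_sire <- rep(dams$sire_id, each = config$insems_per_dam)
  parity <- rep(dams$parity_class, each = config$insems_per_dam)
  bull <- sample(bulls, n, replace = TRUE)
  mu <- ifelse(parity == "heifer", config$mu_heifer, config$mu_cow)
  p_success <- mu
  for (li in seq_along(config$lethal_specs)) {
    ls <- config$lethal_specs[[li]]
    if (!ls$fertility_effect) next
    id <- sprintf("LH%d", li)
    ct <- carrier_truth[carrier_truth$lethal_id == id, , drop = FALSE]
    copies <- stats::setNames(ct$copies, ct$animal_id)
    p_hom <- (copies[bull] / 2) * (copies[cow] / 2)
    p_success <- p_success * (1 - p_hom * ls$penetrance)
  }
  data.frame(bull_id = bull, cow_id = cow, cow_sire_id = cow_sire,
             parity_class = parity,
             outcome = as.integer(stats::runif(n) < p_success),
             stringsAsFactors = FALSE)
}
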