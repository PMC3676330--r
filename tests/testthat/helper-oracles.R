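# Monte-Carlo transmission oracle for the expected homozygote count.
# Samples the transmission process conceptus by conceptus, independently of
# the closed-form expectation: the sire transmits the haplotype with his
# transmission probability; the (ungenotyped) dam carries it paternally with
# her sire's transmission probability and maternally with the population
# frequency, and passes a uniformly chosen chromosome copy. Draws are
# allocated across mating groups in proportion to group size, about
# `draws` conceptuses in total. Returns the estimated expectation and its
# binomial standard error.
mc_expected_homozygotes <- function(groups, f_k, draws = 1e6,
                                    use_dam = FALSE) {
  reps <- max(1L, round(draws / sum(groups$n_ij)))
  E_hat <- 0; var_hat <- 0
  for (g in seq_len(nrow(groups))) {
    m <- groups$n_ij[g] * reps
    sire_t <- runif(m) < groups$p_ik[g]
    dam_t <- if (use_dam) {
      runif(m) < groups$r_jk[g]
    } else {
      pat_slot <- runif(m) < groups$q_jk[g]
      mat_slot <- runif(m) < f_k
      ifelse(runif(m) < 0.5, pat_slot, mat_slot)
    }
    p_hat <- mean(sire_t & dam_t)
    E_hat <- E_hat + groups$n_ij[g] * p_hat
    var_hat <- var_hat + groups$n_ij[g]^2 * p_hat * (1 - p_hat) / m
  }
  list(E = E_hat, se = sqrt(var_hat))
}

# Random small mating-group tables honouring the carrier-sire restriction
# (p_ik > 0 everywhere).
random_groups <- function(n_groups = 5, use_dam = FALSE) {
  g <- data.frame(n_ij = sample(1:40, n_groups, replace = TRUE),
                  p_ik = sample(c(0.5, 1), n_groups, replace = TRUE,
                                prob = c(0.9, 0.1)),
                  q_jk = sample(c(0, 0.5, 1), n_groups, replace = TRUE,
                                prob = c(0.5, 0.4, 0.1)))
  if (use_dam)
    g$r_jk <- sample(c(0, 0.5, 1), n_groups, replace = TRUE,
                     prob = c(0.5, 0.4, 0.1))
  g
}

# Brute-force reference for the carrier-het / control-absent variant filter:
# checks the genotype pattern site by site with explicit loops.
brute_force_pattern <- function(variants, carriers, controls) {
  keep <- logical(nrow(variants$sites))
  for (i in seq_along(keep)) {
    ok <- TRUE
    for (a in carriers) {
      g <- variants$geno[i, a]
      if (is.na(g) || g != 1L) { ok <- FALSE; break }
    }
    if (ok) for (a in controls) {
      g <- variants$geno[i, a]
      if (is.na(g) || g != 0L) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  keep
}
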