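#' Minor-allele-frequency marker filter
#'
#' Computes the minor allele frequency of every marker over all animals
#' pooled (across breeds, when a breed label is present) and removes markers
#' whose MAF is strictly below the threshold. Monomorphic markers have MAF 0
#' and are removed, not errored. The boundary follows the "lower than"
#' convention: a marker at exactly the threshold is retained.
#'
#' @param genotypes a [phased_genotypes()] object.
#' @param map marker map to filter (defaults to `genotypes$map`).
#' @param threshold MAF below which a marker is discarded (default 0.03).
#' @param breed_labels optional per-animal breed labels; kept for reporting
#'   only — frequencies are pooled over breeds.
#' @return the map restricted to retained markers.
#' @export
filter_maf <- function(genotypes, map = genotypes$map, threshold = 0.03,
                       breed_labels = NULL) {
  stopifnot(inherits(genotypes, "phased_genotypes"))
  if (length(genotypes$animal_id) < 1L)
    stop_config("MAF filter needs at least one animal")
  keep_ids <- map$marker_id
  f2 <- (colSums(genotypes$pat[, keep_ids, drop = FALSE] == 2L) +
           colSums(genotypes$mat[, keep_ids, drop = FALSE] == 2L)) /
    (2 * length(genotypes$animal_id))
  maf <- pmin(f2, 1 - f2)
  map[maf >= threshold, , drop = FALSE]
}

#' Hardy-Weinberg equilibrium marker filter
#'
#' Collapses phased haplotypes to diploid genotype counts per marker and
#' tests them against Hardy-Weinberg expectations computed from the observed
#' allele frequency, with a 1-df chi-square goodness-of-fit statistic (no
#' continuity correction). Markers with p strictly below `p_threshold` are
#' removed. With fewer than two animals the test is skipped with a warning
#' and the map is returned unchanged.
#'
#' @inheritParams filter_maf
#' @param p_threshold removal threshold on the HWE p-value (default 1e-4).
#' @return the map restricted to retained markers.
#' @export
filter_hwe <- function(genotypes, map = genotypes$map, p_threshold = 1e-4) {
  stopifnot(inherits(genotypes, "phased_genotypes"))
  n <- length(genotypes$animal_id)
  if (n < 2L) {
    warning("fewer than 2 animals: HWE QC skipped")
    return(map)
  }
  ids <- map$marker_id
  dose <- (genotypes$pat[, ids, drop = FALSE] == 2L) +
    (genotypes$mat[, ids, drop = FALSE] == 2L)
  n11 <- colSums(dose == 0L); n12 <- colSums(dose == 1L)
  n22 <- colSums(dose == 2L)
  p <- hwe_pvalue(n11, n12, n22)
  map[p >= p_threshold, , drop = FALSE]
}

#' HWE goodness-of-fit p-value from genotype counts
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' Hardy-Weinberg proportions derived from the observed allele frequency.
#' Monomorphic markers fit HWE exactly and return p = 1.
#'
#' @param n11,n12,n22 counts of the three genotype classes (hom allele 1,
#'   het, hom allele 2); vectors of equal length.
#' @return vector of upper-tail p-values.
#' @export
#' @examples
#' hwe_pvalue(25, 50, 25)   # exact HWE proportions -> 1
#' hwe_pvalue(50, 0, 50)    # no heterozygotes -> ~1.5e-23
hwe_pvalue <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  q <- (2 * n22 + n12) / (2 * n)
  e11 <- n * (1 - q)^2; e12 <- n * 2 * q * (1 - q); e22 <- n * q^2
  chi2 <- numeric(length(n))
  for (cell in list(cbind(n11, e11), cbind(n12, e12), cbind(n22, e22))) {
    term <- (cell[, 1] - cell[, 2])^2 / cell[, 2]
    term[cell[, 2] == 0] <- 0  # empty expected class: no contribution
    chi2 <- chi2 + term
  }
  stats::pchisq(unname(chi2), df = 1, lower.tail = FALSE)
}

#' Restrict the scan cohort to animals with genotyped sire and MGS
#'
#' The expectation formula needs the sire's and maternal grandsire's
#' genotypes, so progeny whose sire or MGS is absent from the genotype set
#' are excluded from the scan; the number excluded is reported with a
#' message.
#'
#' @param pedigree pedigree `data.frame` with `animal_id`, `sire_id`,
#'   `mgs_id` columns.
#' @param genotypes a [phased_genotypes()] object.
#' @return the pedigree rows (progeny only) eligible for the scan.
#' @export
eligible_progeny <- function(pedigree, genotypes) {
  gset <- genotypes$animal_id
  prog <- pedigree[!is.na(pedigree$sire_id) & !is.na(pedigree$mgs_id) &
                     pedigree$animal_id %in% gset, , drop = FALSE]
  ok <- prog$sire_id %in% gset & prog$mgs_id %in% gset
  if (any(!ok))
    message(sum(!ok),
            " animal(s) excluded: sire or maternal grandsire not genotyped")
  prog[ok, , drop = FALSE]
}
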