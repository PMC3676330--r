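#' Variant set container
#'
#' Sequence variants with per-animal genotypes, as consumed by the
#' carrier/control filter. Genotypes are dosage-coded: 0 homozygous
#' reference, 1 heterozygous, 2 homozygous alternate, `NA` missing.
#' Consequence and deleteriousness columns come from an upstream annotation
#' (external predictors are consumed, never computed here).
#'
#' @param sites `data.frame` with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `gene`, `consequence`, `sift_damaging`, `polyphen_damaging`.
#' @param geno integer matrix (variants x animals) of dosages, column names
#'   = animal ids.
#' @return an object of class `variant_set`.
#' @export
variant_set <- function(sites, geno) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(sites))
    stop_config("genotype matrix must have one row per variant site")
  if (is.null(colnames(geno)))
    stop_config("genotype matrix needs animal ids as column names")
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop_config("genotype dosages must be 0, 1, 2 or NA")
  structure(list(sites = sites, geno = geno), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d animals\n", nrow(x$sites),
              ncol(x$geno)))
  invisible(x)
}

#' Search region around a detected haplotype
#'
#' Causative mutations can sit several Mb outside the detected haplotype
#' when the mutation arose on a frequent haplotype in incomplete linkage
#' disequilibrium with the detected one, so the search region extends the
#' haplotype interval by a flank (default 6 Mb) on each side, clamped at the
#' chromosome start. The interval is half-open `[start, end)` in bp
#' internally and printed in Mb to one decimal.
#'
#' @param region a candidate region: list or one-row `data.frame` with
#'   `chromosome`, `start_bp`, `end_bp`.
#' @param flank_mb flank size in Mb (nonnegative).
#' @return list of class `search_region` with `chromosome`, `start_bp`,
#'   `end_bp`, `start_mb`, `end_mb`.
#' @export
#' @examples
#' define_search_region(list(chromosome = 21, start_bp = 20.2e6,
#'                           end_bp = 22.3e6))  # 14.2-28.3 Mb
define_search_region <- function(region, flank_mb = 6) {
  if (!is.numeric(flank_mb) || flank_mb < 0)
    stop_config("'flank_mb' must be nonnegative")
  start <- max(1, region$start_bp - flank_mb * 1e6)
  end <- region$end_bp + flank_mb * 1e6
  structure(list(chromosome = region$chromosome,
                 start_bp = start, end_bp = end,
                 start_mb = round(start / 1e6, 1),
                 end_mb = round(end / 1e6, 1)),
            class = "search_region")
}

#' @export
print.search_region <- function(x, ...) {
  cat(sprintf("search_region: chr%s %.1f-%.1f Mb\n", x$chromosome,
              x$start_mb, x$end_mb))
  invisible(x)
}

#' Carrier/control genotype-pattern filter
#'
#' Retains variants that are heterozygous in every carrier and homozygous
#' reference in every control. A lethal allele cannot be homozygous in a
#' live bull, so carrier hom-alt sites are rejected too. In strict mode
#' (default) a missing genotype fails the condition; with `lenient = TRUE`
#' missing genotypes are skipped. An empty control set retains every
#' carrier-het site, with a warning.
#'
#' @param variants a [variant_set()].
#' @param carriers,controls disjoint character vectors of animal ids; every
#'   id must be present in the variant set.
#' @param region optional [define_search_region()] result (or any list with
#'   `chromosome`, `start_bp`, `end_bp`): variants outside `[start, end)`
#'   are dropped first.
#' @param lenient logical, see above.
#' @return the filtered [variant_set()].
#' @export
filter_genotype_pattern <- function(variants, carriers, controls,
                                    region = NULL, lenient = FALSE) {
  stopifnot(inherits(variants, "variant_set"))
  if (length(carriers) == 0L) stop_config("carrier set must not be empty")
  if (length(intersect(carriers, controls)))
    stop_config("carrier and control sets must be disjoint")
  absent <- setdiff(c(carriers, controls), colnames(variants$geno))
  if (length(absent))
    stop_config("animal id absent from VCF: %s", absent[1L])
  if (length(controls) == 0L)
    warning("empty control set: retaining all carrier-het sites")
  sites <- variants$sites
  geno <- variants$geno
  if (!is.null(region)) {
    inside <- sites$chrom == region$chromosome &
      sites$pos >= region$start_bp & sites$pos < region$end_bp
    sites <- sites[inside, , drop = FALSE]
    geno <- geno[inside, , drop = FALSE]
  }
  gc_ <- geno[, carriers, drop = FALSE]
  gn <- geno[, controls, drop = FALSE]
  if (lenient) {
    carrier_ok <- apply(gc_, 1L, function(g) all(g[!is.na(g)] == 1L))
    control_ok <- if (length(controls))
      apply(gn, 1L, function(g) all(g[!is.na(g)] == 0L)) else TRUE
  } else {
    carrier_ok <- rowSums(gc_ == 1L, na.rm = TRUE) == length(carriers) &
      !apply(gc_, 1L, anyNA)
    control_ok <- if (length(controls))
      rowSums(gn == 0L, na.rm = TRUE) == length(controls) &
        !apply(gn, 1L, anyNA) else TRUE
  }
  keep <- carrier_ok & control_ok
  variant_set(sites[keep, , drop = FALSE], geno[keep, , drop = FALSE])
}

#' Protein-consequence filter for candidate variants
#'
#' Keeps variants predicted to alter the protein: stop gain/loss, frameshift
#' and essential-splice variants unconditionally, and missense variants only
#' when flagged damaging by both external predictors (the two boolean
#' annotation columns). Synonymous and non-coding classes are dropped.
#' Candidates without an annotation entry are retained with class
#' `"unknown"` and a warning rather than silently dropped.
#'
#' @param candidates a [variant_set()].
#' @param annotation optional annotation `data.frame` with columns `chrom`,
#'   `pos`, `alt`, `gene`, `consequence`, `sift_damaging`,
#'   `polyphen_damaging`, joined on (chrom, pos, alt). If omitted, the same
#'   columns of `candidates$sites` are used.
#' @return the filtered [variant_set()], with annotation columns filled in.
#' @export
filter_consequence <- function(candidates, annotation = NULL) {
  stopifnot(inherits(candidates, "variant_set"))
  sites <- candidates$sites
  if (!is.null(annotation)) {
    key <- function(d) paste(d$chrom, d$pos, d$alt, sep = ":")
    m <- match(key(sites), key(annotation))
    sites$gene <- annotation$gene[m]
    sites$consequence <- annotation$consequence[m]
    sites$sift_damaging <- annotation$sift_damaging[m]
    sites$polyphen_damaging <- annotation$polyphen_damaging[m]
  }
  if (is.null(sites$consequence))
    stop_config("no consequence annotation available")
  unknown <- is.na(sites$consequence)
  if (any(unknown)) {
    warning(sum(unknown), " candidate(s) without annotation retained as 'unknown'")
    sites$consequence[unknown] <- "unknown"
  }
  always <- sites$consequence %in% c("stop_gain", "stop_loss", "frameshift",
                                     "splice")
  missense_ok <- sites$consequence == "missense" &
    !is.na(sites$sift_damaging) & !is.na(sites$polyphen_damaging) &
    sites$sift_damaging & sites$polyphen_damaging
  keep <- always | missense_ok | sites$consequence == "unknown"
  variant_set(sites[keep, , drop = FALSE],
              candidates$geno[keep, , drop = FALSE])
}

#' Haplotype-association check on a key-ancestor panel
#'
#' Validates a candidate variant against the window diplotypes of a panel of
#' key ancestors genotyped for both. A haplotype is called associated with
#' the variant when it occurs only in animals carrying the alternate allele.
#' The check flags three situations seen with real candidates: association
#' with more than one haplotype; a live hom-alt animal, which eliminates the
#' candidate outright (a lethal allele cannot be homozygous in a genotyped
#' adult); and carriers of the target haplotype lacking the variant (or
#' haplotype homozygotes that are merely heterozygous), indicating an
#' ancestral version of the haplotype without the mutation still segregates.
#'
#' @param variant_geno named integer vector of dosages (0/1/2, `NA` allowed)
#'   over the panel.
#' @param diplotypes `data.frame` with columns `animal_id`, `hap1`, `hap2`
#'   (window haplotype labels of the two chromosome copies).
#' @param target_hap label of the haplotype the variant is a candidate for.
#' @return list with `associated` (labels), `status` (`"exclusive
#'   association"`, `"multiple association"` or `"eliminated"`),
#'   `hom_alt_animals`, `ancestral_segregating` (logical) and
#'   `ancestral_animals`.
#' @export
haplotype_association_check <- function(variant_geno, diplotypes, target_hap) {
  ids <- intersect(names(variant_geno), diplotypes$animal_id)
  if (!length(ids))
    stop_config("no animal shared between variant panel and diplotype panel")
  d <- diplotypes[match(ids, diplotypes$animal_id), , drop = FALSE]
  g <- variant_geno[ids]
  has_alt <- !is.na(g) & g >= 1L
  haps <- unique(c(d$hap1, d$hap2))
  carried_by <- function(h) d$hap1 == h | d$hap2 == h
  associated <- haps[vapply(haps, function(h) {
    carr <- carried_by(h)
    any(carr & has_alt) && all(has_alt[carr])
  }, logical(1))]
  hom_alt <- ids[!is.na(g) & g == 2L]
  copies_target <- (d$hap1 == target_hap) + (d$hap2 == target_hap)
  ancestral <- ids[copies_target > ifelse(is.na(g), 2L, g)]
  status <- if (length(hom_alt)) "eliminated"
  else if (length(associated) > 1L) "multiple association"
  else if (length(associated) == 1L) "exclusive association"
  else "no association"
  list(associated = associated, status = status,
       hom_alt_animals = hom_alt,
       ancestral_segregating = length(ancestral) > 0L,
       ancestral_animals = ancestral)
}
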