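#' Phased genotype container
#'
#' Holds two labelled haplotypes (paternal and maternal) per animal over an
#' ordered marker map. Alleles are coded as integers 1 and 2, matching the
#' A/B coding of SNP beadchips. The paternal/maternal labels are taken from
#' upstream phasing (family-based phasing makes them reliable when sire and
#' maternal grandsire are genotyped); haplotype frequencies downstream are
#' counted on the maternal copies only.
#'
#' @param animal_id character vector of unique animal identifiers.
#' @param pat,mat integer matrices (animals x markers) of allele codes 1/2;
#'   `pat` is the paternally inherited chromosome copy.
#' @param map marker map `data.frame` as produced by [simulate_marker_map()],
#'   with columns `marker_id`, `chromosome`, `position_bp`.
#' @return an object of class `phased_genotypes`: a list with elements
#'   `animal_id`, `pat`, `mat`, `map`.
#' @export
phased_genotypes <- function(animal_id, pat, mat, map) {
  animal_id <- as.character(animal_id)
  if (anyDuplicated(animal_id))
    stop_config("duplicate animal id: %s",
                animal_id[duplicated(animal_id)][1L])
  pat <- as.matrix(pat); mat <- as.matrix(mat)
  storage.mode(pat) <- "integer"; storage.mode(mat) <- "integer"
  if (nrow(pat) != length(animal_id) || nrow(mat) != length(animal_id))
    stop_config("haplotype matrices must have one row per animal")
  if (ncol(pat) != nrow(map) || ncol(mat) != nrow(map))
    stop_config("haplotype length %d does not match map with %d markers",
                ncol(pat), nrow(map))
  bad <- !(c(pat, mat) %in% c(1L, 2L))
  if (any(bad)) stop_config("unknown allele code; alleles must be 1 or 2")
  rownames(pat) <- rownames(mat) <- animal_id
  colnames(pat) <- colnames(mat) <- map$marker_id
  structure(list(animal_id = animal_id, pat = pat, mat = mat, map = map),
            class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat(sprintf("phased_genotypes: %d animals x %d markers on %d chromosome(s)\n",
              length(x$animal_id), nrow(x$map), length(unique(x$map$chromosome))))
  invisible(x)
}

#' Subset a phased genotype set
#'
#' @param x a `phased_genotypes` object.
#' @param animals optional character vector of animal ids to keep.
#' @param markers optional character vector of marker ids to keep (the map is
#'   subset accordingly, preserving order).
#' @return a `phased_genotypes` object.
#' @export
subset_phased <- function(x, animals = NULL, markers = NULL) {
  stopifnot(inherits(x, "phased_genotypes"))
  ai <- x$animal_id
  if (!is.null(animals)) {
    missing <- setdiff(animals, ai)
    if (length(missing))
      stop_config("animal id not in genotype set: %s", missing[1L])
    ai <- ai[ai %in% animals]
  }
  map <- x$map
  if (!is.null(markers)) map <- map[map$marker_id %in% markers, , drop = FALSE]
  phased_genotypes(ai,
                   x$pat[ai, map$marker_id, drop = FALSE],
                   x$mat[ai, map$marker_id, drop = FALSE],
                   map)
}
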