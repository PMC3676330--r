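#' Read and write phased genotypes as TSV
#'
#' The phased TSV dialect has a header line and three columns: `animal_id`,
#' `copy` (`paternal` or `maternal`) and `alleles`, the concatenated allele
#' codes (1/2) over all markers in map order. Two rows per animal.
#'
#' @param x a [phased_genotypes()] object.
#' @param path file path.
#' @return `write_phased` returns `path` invisibly; `read_phased` returns a
#'   [phased_genotypes()] object.
#' @export
write_phased <- function(x, path) {
  stopifnot(inherits(x, "phased_genotypes"))
  out <- data.frame(
    animal_id = rep(x$animal_id, each = 2L),
    copy = rep(c("paternal", "maternal"), length(x$animal_id)),
    alleles = as.vector(rbind(do.call(paste0, as.data.frame(x$pat)),
                              do.call(paste0, as.data.frame(x$mat)))),
    stringsAsFactors = FALSE)
  write_tsv_report(out, path)
}

#' @rdname write_phased
#' @param map marker map the haplotype strings are ordered by.
#' @export
read_phased <- function(path, map) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", comment.char = "")
  need <- c("animal_id", "copy", "alleles")
  if (!all(need %in% names(tab)))
    stop_config("phased TSV must have columns %s", paste(need, collapse = ", "))
  nm <- nrow(map)
  bad_len <- which(nchar(tab$alleles) != nm)
  if (length(bad_len))
    stop_config("line %d: haplotype length %d does not match map (%d markers)",
                bad_len[1L] + 1L, nchar(tab$alleles)[bad_len[1L]], nm)
  bad_code <- which(grepl("[^12]", tab$alleles))
  if (length(bad_code))
    stop_config("line %d: unknown allele code in haplotype string",
                bad_code[1L] + 1L)
  pat_rows <- tab[tab$copy == "paternal", , drop = FALSE]
  mat_rows <- tab[tab$copy == "maternal", , drop = FALSE]
  dup <- which(duplicated(pat_rows$animal_id))
  if (length(dup))
    stop_config("duplicate animal id '%s' in phased TSV",
                pat_rows$animal_id[dup[1L]])
  if (!identical(pat_rows$animal_id, mat_rows$animal_id))
    stop_config("each animal needs one paternal and one maternal row")
  to_mat <- function(s)
    matrix(as.integer(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE)),
           nrow = length(s), ncol = nm, byrow = TRUE)
  phased_genotypes(pat_rows$animal_id, to_mat(pat_rows$alleles),
                   to_mat(mat_rows$alleles), map)
}

#' Read and write pedigree TSV
#'
#' Tab-separated with header: `animal_id`, `sire_id`, `mgs_id`, `dam_id`,
#' `sex`, `parity_class` and optionally `role`. Missing parents are empty
#' fields (read back as `NA`).
#'
#' @param pedigree pedigree `data.frame`.
#' @param path file path.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- pedigree
  for (j in seq_along(out)) out[[j]][is.na(out[[j]])] <- ""
  write_tsv_report(out, path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  tab <- read_tsv_table(path)
  if (!all(c("animal_id", "sire_id", "mgs_id") %in% names(tab)))
    stop_config("pedigree TSV must have animal_id, sire_id, mgs_id columns")
  for (j in seq_along(tab))
    if (is.character(tab[[j]])) tab[[j]][tab[[j]] == ""] <- NA_character_
  dup <- which(duplicated(tab$animal_id))
  if (length(dup))
    stop_config("line %d: duplicate animal id '%s'", dup[1L] + 1L,
                tab$animal_id[dup[1L]])
  tab
}

#' Export phased genotypes as a VCF with phased GT fields
#'
#' Writes a minimal VCF 4.2 with one record per marker and phased genotypes
#' `a|b`, where the paternal allele comes first. Allele code 1 maps to REF
#' (`A`) and allele code 2 to ALT (`B` beadchip allele, written as base `C`),
#' so GT `1|0` means the paternal copy carries the ALT (code 2) allele.
#'
#' @param x a [phased_genotypes()] object.
#' @param path file path.
#' @export
write_phased_vcf <- function(x, path) {
  stopifnot(inherits(x, "phased_genotypes"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=lethalscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$animal_id), collapse = "\t")), con)
  gt <- matrix(paste(t(x$pat) - 1L, t(x$mat) - 1L, sep = "|"),
               nrow = nrow(x$map))
  body <- paste(x$map$chromosome,
                format(x$map$position_bp, scientific = FALSE, trim = TRUE),
                x$map$marker_id, "A", "C", ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read phased genotypes from a VCF
#'
#' Reads a VCF with phased GT fields (`a|b`) and converts it to a
#' [phased_genotypes()] object under the convention that the first GT allele
#' is the paternal copy and VCF allele 0/1 maps to allele code 1/2.
#'
#' @param path VCF file path.
#' @param map marker map; VCF records are matched to it by marker id.
#' @return a [phased_genotypes()] object.
#' @export
read_vcf_genotypes <- function(path, map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ord <- match(map$marker_id, rownames(gt))
  if (anyNA(ord))
    stop_config("VCF is missing marker %s", map$marker_id[which(is.na(ord))[1L]])
  gt <- gt[ord, , drop = FALSE]
  if (any(!grepl("|", gt, fixed = TRUE)))
    stop_config("VCF genotypes must be phased ('|' separator)")
  pat <- t(matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))) + 1L
  mat <- t(matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))) + 1L
  phased_genotypes(colnames(gt), pat, mat, map)
}

#' Read and write insemination records as TSV
#'
#' @param insems insemination `data.frame` (`bull_id`, `cow_id`,
#'   `cow_sire_id`, `parity_class`, `outcome`).
#' @param path file path.
#' @export
write_inseminations <- function(insems, path) write_tsv_report(insems, path)

#' @rdname write_inseminations
#' @export
read_inseminations <- function(path) {
  tab <- read_tsv_table(path)
  need <- c("bull_id", "cow_id", "cow_sire_id", "parity_class", "outcome")
  if (!all(need %in% names(tab)))
    stop_config("insemination TSV must have columns %s",
                paste(need, collapse = ", "))
  if (!all(tab$outcome %in% c(0L, 1L)))
    stop_config("insemination outcomes must be 0/1")
  tab
}
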