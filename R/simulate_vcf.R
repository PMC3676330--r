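#' Simulate sequence variants for carrier and control bulls
#'
#' Emits background variants whose genotypes are independent of carrier
#' status (allele frequencies drawn uniformly in `[0.05, 0.5]`, dosages
#' binomial per animal) plus, when `causative` is given, exactly one
#' causative variant heterozygous in every carrier and absent (homozygous
#' reference) in every control. Consequence classes and deleteriousness
#' flags are attached so the downstream consequence filter can be exercised;
#' the causative variant is a stop gain by default.
#'
#' @param region a [define_search_region()] result or list with
#'   `chromosome`, `start_bp`, `end_bp`; all positions fall inside it.
#' @param carrier_ids,control_ids disjoint, non-empty carrier set and
#'   control set.
#' @param causative `NULL` for no causative variant, or a list with optional
#'   elements `pos` (default: region midpoint), `gene`, `consequence`.
#' @param n_background number of background variants.
#' @param seed integer seed; the emitted records are byte-identical for the
#'   same arguments.
#' @return a [variant_set()] with annotation columns filled.
#' @export
simulate_vcf <- function(region, carrier_ids, control_ids, causative = NULL,
                         n_background = 50, seed = 1L) {
  if (length(carrier_ids) == 0L) stop_config("carrier set must not be empty")
  if (length(intersect(carrier_ids, control_ids)))
    stop_config("carrier and control sets must be disjoint")
  set.seed(seed)
  animals <- c(carrier_ids, control_ids)
  n_an <- length(animals)
  span <- region$end_bp - region$start_bp
  pos <- sort(sample.int(span - 1L, n_background)) + region$start_bp
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_background, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  csq_pool <- c("intergenic", "synonymous", "missense", "intron")
  csq <- sample(csq_pool, n_background, replace = TRUE,
                prob = c(0.5, 0.2, 0.2, 0.1))
  af <- stats::runif(n_background, 0.05, 0.5)
  geno <- matrix(stats::rbinom(n_background * n_an, 2L, rep(af, n_an)),
                 nrow = n_background, dimnames = list(NULL, animals))
  sift <- ifelse(csq == "missense", stats::runif(n_background) < 0.3, FALSE)
  poly <- ifelse(csq == "missense", stats::runif(n_background) < 0.3, FALSE)
  sites <- data.frame(chrom = region$chromosome, pos = pos, ref = ref,
                      alt = alt,
                      gene = sprintf("BG%03d", seq_len(n_background)),
                      consequence = csq, sift_damaging = sift,
                      polyphen_damaging = poly, stringsAsFactors = FALSE)
  if (!is.null(causative)) {
    cpos <- causative$pos %||%
      floor((region$start_bp + region$end_bp) / 2)
    cref <- sample(bases, 1L)
    crow <- data.frame(chrom = region$chromosome, pos = cpos, ref = cref,
                       alt = sample(setdiff(bases, cref), 1L),
                       gene = causative$gene %||% "CAND1",
                       consequence = causative$consequence %||% "stop_gain",
                       sift_damaging = TRUE, polyphen_damaging = TRUE,
                       stringsAsFactors = FALSE)
    cgeno <- matrix(ifelse(animals %in% carrier_ids, 1L, 0L), nrow = 1L,
                    dimnames = list(NULL, animals))
    ord <- order(c(sites$pos, cpos))
    sites <- rbind(sites, crow)[ord, , drop = FALSE]
    geno <- rbind(geno, cgeno)[ord, , drop = FALSE]
    rownames(sites) <- NULL
  }
  variant_set(sites, geno)
}

#' Write a variant set as a VCF 4.2 file
#'
#' Annotation travels in the INFO keys `GENE`, `CSQ` (consequence class) and
#' `DEL` (two 0/1 flags, external deleteriousness predictors). Genotypes are
#' unphased dosage GTs (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param variants a [variant_set()].
#' @param path file path.
#' @export
write_variant_vcf <- function(variants, path) {
  stopifnot(inherits(variants, "variant_set"))
  s <- variants$sites
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(gt_code[as.character(variants$geno)], nrow = nrow(s))
  gt[is.na(gt)] <- "./."
  info <- sprintf("GENE=%s;CSQ=%s;DEL=%d,%d",
                  s$gene %||% ".", s$consequence %||% ".",
                  as.integer(s$sift_damaging %||% FALSE),
                  as.integer(s$polyphen_damaging %||% FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=lethalscan",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=DEL,Number=2,Type=Integer,Description="Damaging flags (SIFT-like, PolyPhen-like)">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(variants$geno)), collapse = "\t")), con)
  body <- paste(s$chrom, format(s$pos, scientific = FALSE, trim = TRUE),
                ".", s$ref, s$alt, ".", "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a variant set from a VCF file
#'
#' Parses GT fields into dosages and recovers the `GENE`/`CSQ`/`DEL`
#' annotation written by [write_variant_vcf()] when present.
#'
#' @param path VCF file path.
#' @return a [variant_set()].
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = list(NULL, colnames(gt)))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  grab <- function(key) {
    hit <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]*"),
                                        fix$INFO))
    val <- rep(NA_character_, nrow(fix))
    got <- grepl(paste0(key, "="), fix$INFO)
    val[got] <- sub(paste0(".*", key, "="), "",
                    regmatches(fix$INFO,
                               regexpr(paste0(key, "=[^;]*"), fix$INFO)))
    val
  }
  gene <- grab("GENE"); csq <- grab("CSQ"); del <- grab("DEL")
  del_mat <- do.call(rbind, lapply(strsplit(del, ","), function(x)
    if (length(x) == 2L) as.integer(x) else c(NA_integer_, NA_integer_)))
  sites <- data.frame(chrom = type.convert(fix$CHROM, as.is = TRUE),
                      pos = as.integer(fix$POS), ref = fix$REF,
                      alt = fix$ALT, gene = gene, consequence = csq,
                      sift_damaging = del_mat[, 1L] == 1L,
                      polyphen_damaging = del_mat[, 2L] == 1L,
                      stringsAsFactors = FALSE)
  variant_set(sites, dose)
}
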