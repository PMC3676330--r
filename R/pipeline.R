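#' Run the full detection pipeline on simulated data
#'
#' Chains the stages in the order a real screen runs them: simulate (or
#' load) a population, apply marker QC, scan the genome for
#' deficit-of-homozygotes haplotypes, merge significant windows into
#' candidate regions, quantify the conception-rate loss in matings at risk
#' for each region, and filter sequence variants of carrier versus control
#' bulls inside the flanked region. Writes four tab-separated reports plus a
#' JSON run manifest into `out_dir`; with a fixed configuration the whole
#' bundle is byte-identical across reruns. When the scan finds no region the
#' fertility and variant stages are skipped with a notice.
#'
#' @param out_dir output directory (created if needed).
#' @param sim a [simulation_config()] describing the demo population.
#' @param scan a [scan_config()].
#' @param flank_mb search-region flank for the variant stage.
#' @param n_vcf_carriers,n_vcf_controls how many carrier/control bulls enter
#'   the simulated sequencing panel.
#' @param n_background background variants in the simulated VCF.
#' @return (invisibly) a list with elements `scan`, `regions`, `fertility`,
#'   `candidates` and the report paths.
#' @export
run_pipeline <- function(out_dir, sim = simulation_config(), scan = scan_config(),
                         flank_mb = 6, n_vcf_carriers = 2,
                         n_vcf_controls = 10, n_background = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  map <- stage("simulate", simulate_marker_map(sim))
  pop <- stage("simulate", {
    p <- simulate_population(map, sim)
    p$inseminations <- simulate_inseminations(p$pedigree, p$carrier_truth, sim)
    p
  })
  qc_map <- stage("qc", {
    m1 <- filter_maf(pop$genotypes)
    m2 <- filter_hwe(pop$genotypes, m1)
    message(nrow(map) - nrow(m2), " marker(s) removed by QC, ",
            nrow(m2), " kept")
    m2
  })
  geno <- stage("qc", subset_phased(pop$genotypes, markers = qc_map$marker_id))
  scan_res <- stage("scan", scan_genome(geno, pop$pedigree, scan))
  regions <- stage("scan", merge_windows(scan_res, scan))
  paths <- list(scan = file.path(out_dir, "scan.tsv"),
                regions = file.path(out_dir, "regions.tsv"),
                fertility = file.path(out_dir, "fertility.tsv"),
                candidates = file.path(out_dir, "candidates.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  scan_out <- scan_res
  scan_out$p <- format_p_sci(scan_out$p)
  write_tsv_report(scan_out, paths$scan)
  reg_out <- regions
  reg_out$p <- format_p_sci(reg_out$p)
  write_tsv_report(reg_out, paths$regions)

  fertility <- NULL; candidates <- NULL
  if (nrow(regions) == 0L) {
    message("scan found no candidate region: fertility and variant stages skipped")
  } else {
    fertility <- stage("fertility", {
      rows <- lapply(seq_len(nrow(regions)), function(i) {
        status <- region_carrier_status(geno, scan_res, regions[i, ], scan)
        cl <- classify_matings(pop$inseminations, status)
        h <- estimate_loss(cl, "heifer")
        cw <- estimate_loss(cl, "cow")
        data.frame(region = sprintf("chr%d:%.1f-%.1f",
                                    regions$chromosome[i],
                                    regions$start_mb[i], regions$end_mb[i]),
                   heifer_n_at_risk = h$n_at_risk,
                   heifer_loss_pct = round(h$loss_pct, 2),
                   heifer_stars = h$stars,
                   cow_n_at_risk = cw$n_at_risk,
                   cow_loss_pct = round(cw$loss_pct, 2),
                   cow_stars = cw$stars, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    write_tsv_report(fertility, paths$fertility)
    candidates <- stage("variant_filter", {
      status <- region_carrier_status(geno, scan_res, regions[1L, ], scan)
      bulls <- pop$pedigree$animal_id[pop$pedigree$role == "sire"]
      car <- utils::head(bulls[status[bulls]], n_vcf_carriers)
      ctl <- utils::head(bulls[!status[bulls]], n_vcf_controls)
      sr <- define_search_region(regions[1L, ], flank_mb)
      vcf <- simulate_vcf(sr, car, ctl,
                          causative = list(gene = "CAND1"),
                          n_background = n_background, seed = sim$seed + 3L)
      cand <- filter_genotype_pattern(vcf, car, ctl, region = sr)
      cand <- filter_consequence(cand)
      cand$sites
    })
    write_tsv_report(candidates, paths$candidates)
  }
  manifest <- list(package = "lethalscan",
                   version = as.character(utils::packageVersion("lethalscan")),
                   seed = sim$seed,
                   parameters = list(
                     scan = unclass(scan),
                     simulation = unclass(sim[setdiff(names(sim),
                                                      "lethal_specs")]),
                     n_lethals = length(sim$lethal_specs),
                     flank_mb = flank_mb),
                   n_markers_post_qc = nrow(qc_map),
                   n_regions = nrow(regions))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(scan = scan_res, regions = regions, fertility = fertility,
                 candidates = candidates, paths = paths))
}

# Carrier status (named logical over all genotyped animals) for the most
# significant haplotype of a merged region.
region_carrier_status <- function(geno, scan_res, region, scan) {
  rows <- scan_res[scan_res$chromosome == region$chromosome &
                     scan_res$start_bp >= region$start_bp &
                     scan_res$end_bp <= region$end_bp &
                     scan_res$deficit, , drop = FALSE]
  best <- rows[which.min(rows$p), , drop = FALSE]
  idx_chr <- which(geno$map$chromosome == best$chromosome)
  cols <- idx_chr[best$window:(best$window + scan$window_size - 1L)]
  kp <- window_string(geno$pat, cols)
  km <- window_string(geno$mat, cols)
  stats::setNames(kp == best$haplotype | km == best$haplotype,
                  geno$animal_id)
}

#' Recompute deficit-test p-values for printed (E, O) pairs
#'
#' Regression harness: applies [deficit_test()] to each expected/observed
#' homozygote pair of a published scan table and formats the p-values in
#' 2-significant-figure scientific notation for direct comparison with the
#' printed column.
#'
#' @param pairs `data.frame` with columns `expected` and `observed`.
#' @return `pairs` with added columns `chi2`, `p`, `p_sci`.
#' @export
#' @examples
#' recompute_table1(data.frame(expected = c(49, 131), observed = c(0, 0)))
recompute_table1 <- function(pairs) {
  stopifnot(all(c("expected", "observed") %in% names(pairs)))
  if (any(pairs$expected <= 0) || any(pairs$observed < 0))
    stop_config("expected counts must be positive, observed nonnegative")
  tst <- deficit_test(pairs$observed, pairs$expected)
  pairs$chi2 <- tst$chi2
  pairs$p <- tst$p
  pairs$p_sci <- format_p_sci(tst$p)
  pairs
}
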