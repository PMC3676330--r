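#' Scan configuration
#'
#' Tuning parameters of the deficit-of-homozygotes window scan. The defaults
#' are the standard ones for 50k-density cattle data: 20-marker windows
#' (about 1-1.5 Mb) sliding by one marker, haplotypes considered only when
#' their maternal-chromosome frequency exceeds 1%, and a per-test
#' significance threshold of 1e-4 (no multiple-testing correction; see the
#' methods vignette for the caveat).
#'
#' @param window_size number of markers per window (n >= 2).
#' @param slide_step markers the window advances by.
#' @param min_haplotype_freq strict lower frequency bound: haplotypes with
#'   f <= this value are not tested.
#' @param p_threshold significance threshold on the deficit test.
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(window_size = 20, slide_step = 1,
                        min_haplotype_freq = 0.01, p_threshold = 1e-4) {
  assert_count(window_size, "window_size", min = 2L)
  assert_count(slide_step, "slide_step")
  if (!is.numeric(min_haplotype_freq) || min_haplotype_freq <= 0 ||
      min_haplotype_freq >= 1)
    stop_config("'min_haplotype_freq' must lie in (0, 1)")
  assert_prob(p_threshold, "p_threshold")
  structure(list(window_size = as.integer(window_size),
                 slide_step = as.integer(slide_step),
                 min_haplotype_freq = min_haplotype_freq,
                 p_threshold = p_threshold),
            class = "scan_config")
}

#' Enumerate window haplotypes as exact allele strings
#'
#' The haplotype key of a chromosome copy over a marker window is the exact
#' concatenated allele string (e.g. `"121"` for alleles 1,2,1); identity is
#' exact string match with no mismatch tolerance. Windows crossing a
#' chromosome boundary are not keyed: the function returns `NULL` with a
#' message (the genome scan simply skips them).
#'
#' @param phased a [phased_genotypes()] object.
#' @param window integer vector of marker indices into `phased$map` (must be
#'   contiguous markers of one chromosome).
#' @return a list with character vectors `pat` and `mat` (one key per
#'   chromosome copy, named by animal), or `NULL` for a boundary-crossing
#'   window.
#' @export
enumerate_window_haplotypes <- function(phased, window) {
  stopifnot(inherits(phased, "phased_genotypes"))
  chr <- unique(phased$map$chromosome[window])
  if (length(chr) != 1L) {
    message("window crosses a chromosome boundary: skipped")
    return(NULL)
  }
  list(pat = stats::setNames(window_string(phased$pat, window),
                             phased$animal_id),
       mat = stats::setNames(window_string(phased$mat, window),
                             phased$animal_id))
}

#' Animals with at least one progeny
#'
#' @param pedigree pedigree `data.frame`.
#' @return character vector of ids appearing as sire, dam or maternal
#'   grandsire of some animal.
#' @export
has_progeny_ids <- function(pedigree) {
  unique(stats::na.omit(c(pedigree$sire_id, pedigree$dam_id,
                          pedigree$mgs_id)))
}

#' Estimate haplotype frequencies on maternal chromosomes
#'
#' Haplotype frequencies are counted on the maternal chromosomes of animals
#' having at least one progeny; animals without progeny are excluded so that
#' frequency drift over generations does not bias the expectation. Over all
#' haplotypes of a window the frequencies sum to 1; haplotypes at or below
#' `min_freq` are dropped from the returned table (the rule is strictly
#' "higher than", so f = min_freq exactly is dropped).
#'
#' @param maternal_keys named character vector of maternal window keys (one
#'   per genotyped animal), as from [enumerate_window_haplotypes()].
#' @param pedigree pedigree `data.frame`, used to find animals with progeny.
#' @param min_freq strict lower frequency bound (default 0 keeps all).
#' @return `data.frame` with columns `haplotype`, `count`, `freq`, sorted by
#'   decreasing frequency. Empty, with a warning, when no keyed animal has
#'   progeny.
#' @export
estimate_frequencies <- function(maternal_keys, pedigree, min_freq = 0) {
  elig <- names(maternal_keys) %in% has_progeny_ids(pedigree)
  if (!any(elig)) {
    warning("no genotyped animal with progeny: no frequencies estimated")
    return(data.frame(haplotype = character(0), count = integer(0),
                      freq = numeric(0)))
  }
  tab <- sort(table(maternal_keys[elig]), decreasing = TRUE)
  out <- data.frame(haplotype = names(tab), count = as.integer(tab),
                    freq = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[out$freq > min_freq, , drop = FALSE]
}

#' Expected number of homozygotes for a haplotype
#'
#' Mendelian expectation of the number of progeny homozygous for haplotype k,
#' accumulated over mating groups (one group per sire x maternal-grandsire
#' combination with `n_ij` progeny). In the usual case the dam is not
#' genotyped and her genotype is inferred from her sire (the MGS) and the
#' population frequency: she carries k on her paternal chromosome with
#' probability `q_jk` and on her maternal chromosome with probability `f_k`,
#' transmitting each with 1/2, giving
#' \deqn{E(k) = \sum_{ij} n_{ij} \, p_{ik} \, (q_{jk} + f_k)/2.}
#' When the dam is genotyped her own transmission probability `r_jk` replaces
#' the inferred term and the expectation no longer depends on `f_k`:
#' \deqn{E(k) = \sum_{ij} n_{ij} \, p_{ik} \, r_{jk}.}
#' Recombination within the window is ignored in this counting. To keep the
#' expectation robust to frequency estimation error, only groups whose sire
#' carries at least one copy (`p_ik` > 0) are admitted; passing a group with
#' `p_ik = 0` is an error.
#'
#' @param groups `data.frame` of mating groups with columns `n_ij`, `p_ik`,
#'   `q_jk` (and `r_jk` when `use_dam`). Transmission probabilities must be
#'   0, 0.5 or 1 (from the diploid genotype of the parent).
#' @param f_k population frequency of haplotype k on maternal chromosomes.
#' @param use_dam logical: use the genotyped-dam formula.
#' @return the expected homozygote count (a nonnegative real).
#' @export
#' @examples
#' g <- data.frame(n_ij = 100, p_ik = 0.5, q_jk = 0.5)
#' expected_homozygotes(g, f_k = 0.1)  # 100 * 0.5 * (0.6/2) = 15
expected_homozygotes <- function(groups, f_k, use_dam = FALSE) {
  cols <- c("n_ij", "p_ik", "q_jk", if (use_dam) "r_jk")
  if (!all(cols %in% names(groups)))
    stop_config("groups must have columns %s", paste(cols, collapse = ", "))
  ok_tp <- function(x) all(x %in% c(0, 0.5, 1))
  if (!ok_tp(groups$p_ik) || !ok_tp(groups$q_jk) ||
      (use_dam && !ok_tp(groups$r_jk)))
    stop_config("transmission probabilities must be 0, 0.5 or 1")
  if (any(groups$n_ij < 1))
    stop_config("each mating group needs n_ij >= 1")
  if (any(groups$p_ik == 0))
    stop_config("groups with p_ik = 0 violate the carrier-sire restriction")
  assert_prob(f_k, "f_k")
  if (use_dam)
    sum(groups$n_ij * groups$p_ik * groups$r_jk)
  else
    sum(groups$n_ij * groups$p_ik * (groups$q_jk + f_k) / 2)
}

#' Observed number of homozygotes for a haplotype
#'
#' Counts progeny whose two window keys both equal k. The caller restricts
#' the key vectors to the progeny of the sire set used in the expectation.
#'
#' @param keys_pat,keys_mat character vectors of progeny window keys.
#' @param k haplotype key.
#' @return integer count.
#' @export
observed_homozygotes <- function(keys_pat, keys_mat, k) {
  sum(keys_pat == k & keys_mat == k)
}

#' One-cell chi-square test for a deficit of homozygotes
#'
#' Compares the observed homozygote count with its Mendelian expectation
#' using the one-cell chi-square statistic `(O - E)^2 / E` on 1 df with an
#' upper-tail p-value. The statistic is symmetric, but only a shortfall
#' (O < E) is biologically a deficit; the `deficit` flag records the
#' direction and candidate reporting is one-sided.
#'
#' @param O observed homozygote count (nonnegative integer).
#' @param E expected homozygote count; must be positive (for E = 0 the test
#'   is undefined and the haplotype is skipped by the scan).
#' @return list with `chi2`, `p`, and logical `deficit` (O < E).
#' @export
#' @examples
#' deficit_test(0, 49)   # p ~ 2.6e-12
#' deficit_test(24, 68)  # p ~ 9.5e-08
deficit_test <- function(O, E) {
  if (any(E <= 0)) stop_config("deficit test undefined for E <= 0")
  chi2 <- (O - E)^2 / E
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       deficit = O < E)
}

#' Genome-wide deficit-of-homozygotes scan
#'
#' Slides a window of `config$window_size` markers along every chromosome,
#' keys each chromosome copy by its exact allele string, estimates haplotype
#' frequencies on maternal chromosomes of animals with progeny, and tests
#' every haplotype above the frequency floor for a deficit of homozygous
#' progeny relative to the sire/MGS Mendelian expectation. Progeny whose
#' sire or MGS is not genotyped are excluded (with a message); haplotypes
#' whose carrier-sire expectation is zero are skipped.
#'
#' @param phased a [phased_genotypes()] object (QC'd).
#' @param pedigree pedigree `data.frame`.
#' @param config a [scan_config()].
#' @param use_dam logical: use the genotyped-dam expectation (restricts the
#'   scan to progeny whose dam is genotyped).
#' @return `data.frame` with one row per (window, haplotype) tested:
#'   `chromosome`, `window` (index of the first marker within its
#'   chromosome), `start_bp`, `end_bp`, `haplotype`, `freq`, `E`, `O`,
#'   `chi2`, `p`, `deficit`, sorted by (chromosome, window, p).
#' @export
scan_genome <- function(phased, pedigree, config = scan_config(),
                        use_dam = FALSE) {
  stopifnot(inherits(phased, "phased_genotypes"),
            inherits(config, "scan_config"))
  map <- phased$map
  prog <- eligible_progeny(pedigree, phased)
  if (use_dam) {
    prog <- prog[!is.na(prog$dam_id) &
                   prog$dam_id %in% phased$animal_id, , drop = FALSE]
  }
  out <- list()
  if (length(phased$animal_id) == 0L || nrow(prog) == 0L)
    return(empty_scan_result())
  elig_freq <- phased$animal_id %in% has_progeny_ids(pedigree)
  prog_row <- match(prog$animal_id, phased$animal_id)
  sire_ids <- unique(prog$sire_id)
  mgs_ids <- unique(prog$mgs_id)
  sire_row <- match(sire_ids, phased$animal_id)
  mgs_row <- match(mgs_ids, phased$animal_id)
  prog_sire <- match(prog$sire_id, sire_ids)
  prog_mgs <- match(prog$mgs_id, mgs_ids)
  if (use_dam) {
    dam_ids <- unique(prog$dam_id)
    dam_row <- match(dam_ids, phased$animal_id)
    prog_dam <- match(prog$dam_id, dam_ids)
  }
  n <- config$window_size
  for (chr in sort(unique(map$chromosome))) {
    idx_chr <- which(map$chromosome == chr)
    if (length(idx_chr) < n) next
    for (start in seq(1L, length(idx_chr) - n + 1L, by = config$slide_step)) {
      cols <- idx_chr[start:(start + n - 1L)]
      kp <- window_string(phased$pat, cols)
      km <- window_string(phased$mat, cols)
      tab <- table(km[elig_freq])
      freqs <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
      keep <- names(freqs)[freqs > config$min_haplotype_freq]
      if (!length(keep)) next
      # integer codes per distinct key: cheaper than string comparison in
      # the per-haplotype loop
      uk <- unique(c(kp, km))
      ikp <- match(kp, uk); ikm <- match(km, uk)
      sp <- ikp[sire_row]; sm <- ikm[sire_row]
      gp <- ikp[mgs_row]; gm <- ikm[mgs_row]
      pp <- ikp[prog_row]; pm <- ikm[prog_row]
      if (use_dam) { dp <- ikp[dam_row]; dm <- ikm[dam_row] }
      for (k in keep) {
        ik <- match(k, uk)
        p_sire <- ((sp == ik) + (sm == ik)) / 2
        p_prog <- p_sire[prog_sire]
        sel <- which(p_prog > 0)
        if (!length(sel)) next
        E <- if (use_dam) {
          r_dam <- ((dp == ik) + (dm == ik)) / 2
          sum(p_prog[sel] * r_dam[prog_dam[sel]])
        } else {
          q_mgs <- ((gp == ik) + (gm == ik)) / 2
          sum(p_prog[sel] * (q_mgs[prog_mgs[sel]] + freqs[[k]]) / 2)
        }
        if (E <= 0) next
        O <- sum(pp[sel] == ik & pm[sel] == ik)
        out[[length(out) + 1L]] <- list(chr, start, map$position_bp[cols[1L]],
                                        map$position_bp[cols[n]], k,
                                        freqs[[k]], E, O)
      }
    }
  }
  if (!length(out)) return(empty_scan_result())
  col <- function(j) vapply(out, `[[`, out[[1L]][[j]], j)
  res <- data.frame(chromosome = col(1L), window = col(2L),
                    start_bp = col(3L), end_bp = col(4L),
                    haplotype = col(5L), freq = col(6L), E = col(7L),
                    O = col(8L), stringsAsFactors = FALSE)
  tst <- deficit_test(res$O, res$E)
  res$chi2 <- tst$chi2
  res$p <- tst$p
  res$deficit <- tst$deficit
  res <- res[order(res$chromosome, res$window, res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_scan_result <- function() {
  data.frame(chromosome = integer(0), window = integer(0),
             start_bp = integer(0), end_bp = integer(0),
             haplotype = character(0), freq = numeric(0), E = numeric(0),
             O = integer(0), chi2 = numeric(0), p = numeric(0),
             deficit = logical(0))
}

#' Merge significant windows into candidate regions
#'
#' Within a chromosome, significant windows (deficit with p below the
#' threshold) sharing the chromosome-wide minimum observed homozygote count
#' are merged when consecutive: the region runs from the first marker of the
#' left-most window to the last marker of the right-most window. Separate
#' runs on one chromosome yield separate regions. Each region reports the E,
#' O, frequency and p of the most significant haplotype test in the run.
#'
#' @param results scan results from [scan_genome()].
#' @param config the [scan_config()] (for the significance threshold).
#' @return `data.frame` with columns `chromosome`, `start_bp`, `end_bp`,
#'   `start_mb`, `end_mb`, `n_windows`, `E`, `O`, `freq_pct`, `p`.
#' @export
merge_windows <- function(results, config = scan_config()) {
  sig <- results[results$deficit & results$p < config$p_threshold, ,
                 drop = FALSE]
  regions <- list()
  for (chr in sort(unique(sig$chromosome))) {
    s <- sig[sig$chromosome == chr, , drop = FALSE]
    minO <- min(s$O)
    s <- s[s$O == minO, , drop = FALSE]
    wins <- sort(unique(s$window))
    run_id <- cumsum(c(1L, diff(wins) > 1L))
    for (r in unique(run_id)) {
      w <- wins[run_id == r]
      rows <- s[s$window %in% w, , drop = FALSE]
      best <- rows[which.min(rows$p), , drop = FALSE]
      regions[[length(regions) + 1L]] <- data.frame(
        chromosome = chr,
        start_bp = min(rows$start_bp), end_bp = max(rows$end_bp),
        start_mb = round(min(rows$start_bp) / 1e6, 1),
        end_mb = round(max(rows$end_bp) / 1e6, 1),
        n_windows = length(w),
        E = best$E, O = best$O, freq_pct = round(100 * best$freq, 1),
        p = best$p)
    }
  }
  if (!length(regions))
    return(data.frame(chromosome = integer(0), start_bp = integer(0),
                      end_bp = integer(0), start_mb = numeric(0),
                      end_mb = numeric(0), n_windows = integer(0),
                      E = numeric(0), O = integer(0), freq_pct = numeric(0),
                      p = numeric(0)))
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Carrier-status concordance between two haplotypes or defects
#'
#' Computes the percentage of carriers of status `a` that also carry status
#' `b` (e.g. carriers of a known defect that also carry a detected
#' haplotype), plus the count of `b` carriers outside `a`.
#'
#' @param status_a,status_b logical vectors over the same animal set.
#' @return list with `pct_overlap` (rounded to the nearest integer), `n_a`,
#'   `n_overlap`, `n_b_only`.
#' @export
#' @examples
#' a <- rep(c(TRUE, FALSE), c(244, 8115))
#' b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(209, 35, 225, 7890))
#' carrier_concordance(a, b)$pct_overlap  # 86
carrier_concordance <- function(status_a, status_b) {
  if (length(status_a) != length(status_b))
    stop_config("status vectors must cover the same animal set")
  n_a <- sum(status_a)
  if (n_a == 0L) stop_config("concordance undefined: no carrier of status a")
  list(pct_overlap = round(100 * sum(status_a & status_b) / n_a),
       n_a = n_a, n_overlap = sum(status_a & status_b),
       n_b_only = sum(status_b & !status_a))
}
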