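#' Classify inseminations by bull and cow-sire carrier status
#'
#' Assigns every insemination to one of four groups from the carrier status
#' of the mated bull and of the cow's sire: matings at risk are carrier bull
#' x daughter of carrier sire (the conceptus is homozygous with probability
#' about 1/8). Records with unknown status for either animal are dropped and
#' the count is reported with a message, since only inseminations with known
#' status on both sides are informative.
#'
#' @param insems insemination `data.frame` (`bull_id`, `cow_sire_id`,
#'   `outcome`, `parity_class`, ...).
#' @param bull_status,sire_status named logical vectors: `TRUE` for carrier.
#'   Usually the same vector, indexed by bull id and cow-sire id.
#' @return the insemination table restricted to known-status records, with an
#'   added factor column `group` with levels `at_risk`
#'   (carrier x carrier-sire), `carrier_bull` (carrier x noncarrier-sire),
#'   `carrier_sire` (noncarrier x carrier-sire) and `control`
#'   (noncarrier x noncarrier-sire).
#' @export
classify_matings <- function(insems, bull_status, sire_status = bull_status) {
  bs <- bull_status[insems$bull_id]
  ss <- sire_status[insems$cow_sire_id]
  known <- !is.na(bs) & !is.na(ss)
  if (any(!known))
    message(sum(!known), " insemination(s) dropped: unknown carrier status")
  out <- insems[known, , drop = FALSE]
  bs <- bs[known]; ss <- ss[known]
  out$group <- factor(ifelse(bs & ss, "at_risk",
                             ifelse(bs, "carrier_bull",
                                    ifelse(ss, "carrier_sire", "control"))),
                      levels = c("at_risk", "carrier_bull", "carrier_sire",
                                 "control"))
  out
}

#' Conception-rate loss in matings at risk
#'
#' For one parity class, contrasts the conception rate of matings at risk
#' with the control group and tests the difference with a two-sample Welch
#' t-test on the 0/1 outcomes. The loss is reported in percentage points
#' (at-risk rate minus control rate, times 100). With no at-risk mating the
#' loss is reported as 0 with n = 0 and no test, matching how haplotypes
#' without observed at-risk matings are tabulated.
#'
#' @param classified output of [classify_matings()].
#' @param parity_class `"heifer"` or `"cow"`.
#' @param control `"clean"` (default) uses only
#'   noncarrier x noncarrier-sire matings as the control group; `"all"` uses
#'   every non-at-risk mating.
#' @return one-row `data.frame`: `parity_class`, `n_at_risk`, `rate_at_risk`,
#'   `rate_control`, `loss_pct`, `t`, `p`, `stars`.
#' @export
estimate_loss <- function(classified, parity_class = c("heifer", "cow"),
                          control = c("clean", "all")) {
  parity_class <- match.arg(parity_class)
  control <- match.arg(control)
  d <- classified[classified$parity_class == parity_class, , drop = FALSE]
  risk <- d$outcome[d$group == "at_risk"]
  ctrl <- if (control == "clean") d$outcome[d$group == "control"]
          else d$outcome[d$group != "at_risk"]
  if (length(risk) == 0L)
    return(data.frame(parity_class = parity_class, n_at_risk = 0L,
                      rate_at_risk = NA_real_,
                      rate_control = mean(ctrl), loss_pct = 0,
                      t = NA_real_, p = NA_real_, stars = "",
                      stringsAsFactors = FALSE))
  if (length(ctrl) == 0L)
    stop_config("no control mating in parity class '%s'", parity_class)
  loss <- mean(risk) - mean(ctrl)
  tt <- if (stats::var(risk) == 0 && stats::var(ctrl) == 0)
    list(statistic = 0, p.value = 1)
  else stats::t.test(risk, ctrl)
  data.frame(parity_class = parity_class, n_at_risk = length(risk),
             rate_at_risk = mean(risk), rate_control = mean(ctrl),
             loss_pct = 100 * loss,
             t = unname(tt$statistic), p = tt$p.value,
             stars = sig_stars(tt$p.value), stringsAsFactors = FALSE)
}

#' Expected conception-rate loss in matings at risk
#'
#' Under a fully penetrant recessive lethal, a mating between a carrier bull
#' and a daughter of a carrier sire produces a homozygous conceptus with
#' probability `(0.5 + f)/4`: the bull transmits with probability 1/2, and
#' the dam carries the haplotype paternally with probability 1/2 and
#' maternally with the population frequency `f`, transmitting either copy
#' with 1/2. The conception rate therefore drops by
#' \deqn{-\mu \, (0.5 + f_k)/4,} which tends to \eqn{-\mu/8} as
#' \eqn{f_k \to 0}. Returned as a (negative) fraction.
#'
#' @param f_k haplotype frequency in `[0, 0.5)`.
#' @param mu mean conception rate in `[0, 1]`.
#' @return expected loss as a fraction (multiply by 100 for points).
#' @export
#' @examples
#' expected_loss_at_risk(0, 0.50)  # -0.0625, i.e. -6.25 points
#' expected_loss_at_risk(0, 0.40)  # -0.05
expected_loss_at_risk <- function(f_k, mu) {
  if (any(f_k < 0 | f_k >= 0.5)) stop_config("'f_k' must lie in [0, 0.5)")
  assert_prob(mu, "mu")
  -mu * (0.5 + f_k) / 4
}

#' Expected fertility loss over all daughters of a carrier bull
#'
#' Averaged over all daughters of a carrier bull mated to random bulls, the
#' conception-rate decrease is \deqn{-0.5\,(0.5 + f_k)\, f_k\, \mu,} which is
#' an order of magnitude smaller than the at-risk loss for rare haplotypes —
#' the reason the scan contrasts matings at risk rather than daughter
#' fertility.
#'
#' @inheritParams expected_loss_at_risk
#' @return expected loss as a fraction.
#' @export
expected_loss_daughters <- function(f_k, mu) {
  if (any(f_k < 0 | f_k >= 0.5)) stop_config("'f_k' must lie in [0, 0.5)")
  assert_prob(mu, "mu")
  -0.5 * (0.5 + f_k) * f_k * mu
}

#' Fertility report for a set of haplotypes
#'
#' Convenience wrapper producing one report row per haplotype with the
#' at-risk mating counts and losses for both parity classes, in the layout
#' of a published fertility-loss table.
#'
#' @param insems insemination `data.frame`.
#' @param status_list named list of carrier-status vectors (one per
#'   haplotype), each a named logical vector over bull ids.
#' @param control control-group definition, see [estimate_loss()].
#' @return `data.frame` with columns `haplotype`, `heifer_n_at_risk`,
#'   `heifer_loss_pct`, `heifer_stars`, `cow_n_at_risk`, `cow_loss_pct`,
#'   `cow_stars`.
#' @export
fertility_table <- function(insems, status_list, control = "clean") {
  rows <- lapply(names(status_list), function(hap) {
    cl <- classify_matings(insems, status_list[[hap]])
    h <- estimate_loss(cl, "heifer", control)
    cw <- estimate_loss(cl, "cow", control)
    data.frame(haplotype = hap,
               heifer_n_at_risk = h$n_at_risk,
               heifer_loss_pct = round(h$loss_pct, 2),
               heifer_stars = h$stars,
               cow_n_at_risk = cw$n_at_risk,
               cow_loss_pct = round(cw$loss_pct, 2),
               cow_stars = cw$stars,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
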