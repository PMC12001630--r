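# Post-calling variant filters: GATK-style site hard filters plus the
# two depth-based criteria applied in R after calling.

#' Default hard-filter thresholds
#'
#' A site fails when any present annotation violates `QD < qd_min`,
#' `FS > fs_max`, `MQRankSum < mqranksum_min`,
#' `ReadPosRankSum < readpos_min`, or `SOR > sor_max`.
#'
#' @param qd_min,fs_max,mqranksum_min,readpos_min,sor_max Thresholds.
#' @return Named list of thresholds.
#' @export
hard_filter_thresholds <- function(qd_min = 20.0, fs_max = 20.0,
                                   mqranksum_min = -12.5, readpos_min = -8.0,
                                   sor_max = 5.0) {
  list(
    qd_min = qd_min, fs_max = fs_max, mqranksum_min = mqranksum_min,
    readpos_min = readpos_min, sor_max = sor_max
  )
}

#' Site-level hard filter on variant-quality annotations
#'
#' Missing annotations never fail a record (the VariantFiltration
#' convention); records with no annotations at all pass but are flagged
#' `unannotated`.
#'
#' @param variants Variant tibble (see [read_vcf()]).
#' @param thresholds From [hard_filter_thresholds()].
#' @return `variants` with logical `pass`, character `failed_filters`
#'   (comma-separated labels, `""` when passing) and logical
#'   `unannotated` columns added.
#' @export
site_hard_filter <- function(variants, thresholds = hard_filter_thresholds()) {
  checks <- list(
    QD = !is.na(variants$qd) & variants$qd < thresholds$qd_min,
    FS = !is.na(variants$fs) & variants$fs > thresholds$fs_max,
    MQRankSum = !is.na(variants$mq_rank_sum) & variants$mq_rank_sum < thresholds$mqranksum_min,
    ReadPosRankSum = !is.na(variants$read_pos_rank_sum) & variants$read_pos_rank_sum < thresholds$readpos_min,
    SOR = !is.na(variants$sor) & variants$sor > thresholds$sor_max
  )
  fail_mat <- do.call(cbind, checks)
  variants$failed_filters <- apply(fail_mat, 1, function(f) paste(names(checks)[f], collapse = ","))
  variants$pass <- rowSums(fail_mat) == 0
  variants$unannotated <- is.na(variants$qd) & is.na(variants$fs) &
    is.na(variants$mq_rank_sum) & is.na(variants$read_pos_rank_sum) & is.na(variants$sor)
  variants
}

# Per-record totals, treating missing per-sample values as absent.
variant_depth_totals <- function(variants) {
  dp_total <- vapply(variants$dp, function(d) sum(d, na.rm = TRUE), numeric(1))
  alt_ad_total <- vapply(variants$ad, function(m) {
    sum(m[, -1, drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  ad_total <- vapply(variants$ad, function(m) sum(m, na.rm = TRUE), numeric(1))
  evaluable <- vapply(seq_len(nrow(variants)), function(i) {
    any(!is.na(variants$ad[[i]])) || any(!is.na(variants$dp[[i]]))
  }, logical(1))
  list(dp_total = dp_total, alt_ad_total = alt_ad_total, ad_total = ad_total, evaluable = evaluable)
}

#' Lenient depth criterion
#'
#' Keeps a record iff the total depth across samples is at least
#' `dp_total_min` AND the total alternate-allele read support across
#' samples and alleles is at least `alt_ad_total_min`
#' (`DP_total >= 10 and ALT_AD_total > 0` at the defaults). Records
#' with no AD/DP information anywhere are unevaluable and dropped with
#' a message.
#'
#' @param variants Variant tibble.
#' @param dp_total_min Minimum summed per-sample DP.
#' @param alt_ad_total_min Minimum summed alternate AD.
#' @return Surviving records with `dp_total` and `alt_ad_total` columns
#'   added.
#' @export
filter_lenient <- function(variants, dp_total_min = 10, alt_ad_total_min = 1) {
  tot <- variant_depth_totals(variants)
  if (any(!tot$evaluable)) {
    message(sprintf("Dropping %d records with no AD/DP information.", sum(!tot$evaluable)))
  }
  variants$dp_total <- tot$dp_total
  variants$alt_ad_total <- tot$alt_ad_total
  keep <- tot$evaluable & tot$dp_total >= dp_total_min & tot$alt_ad_total >= alt_ad_total_min
  variants[keep, ]
}

#' Stringent per-allele depth criterion
#'
#' An alternate allele is *supported* in a sample iff its allele depth
#' is at least `ad_min`, OR its allele ratio `AD/DP` is at least
#' `ar_min` with `DP > dp_min_for_ar`
#' (`(AD >= 2) or (AR >= 0.1 and DP > 10)` at the defaults). An allele
#' is retained iff it is supported in at least one sample and the
#' recalculated total depth is at least `dp_total_recalc_min`; a record
#' is retained iff at least one of its alternate alleles is retained.
#' Samples with `DP = 0` (or missing DP) but nonzero AD contribute only
#' through the AD branch (the allele ratio is undefined there).
#'
#' The recalculated depth defaults to the sum over samples of the
#' per-sample AD sums (depth recomputed from allele depths); set
#' `recalc = "dp_sum"` to use the DP field instead.
#'
#' @param variants Variant tibble.
#' @param ad_min,ar_min,dp_min_for_ar,dp_total_recalc_min Thresholds.
#' @param recalc `"ad_sum"` (default) or `"dp_sum"`.
#' @return Surviving records with a `kept_alts` list-column of retained
#'   alternate-allele indices and `dp_total_recalc` added.
#' @export
filter_stringent <- function(variants, ad_min = 2, ar_min = 0.1,
                             dp_min_for_ar = 10, dp_total_recalc_min = 5,
                             recalc = c("ad_sum", "dp_sum")) {
  recalc <- match.arg(recalc)
  tot <- variant_depth_totals(variants)
  recalc_total <- if (recalc == "ad_sum") tot$ad_total else tot$dp_total

  kept <- lapply(seq_len(nrow(variants)), function(i) {
    m <- variants$ad[[i]]
    d <- variants$dp[[i]]
    n_alt <- ncol(m) - 1
    if (recalc_total[i] < dp_total_recalc_min) {
      return(integer(0))
    }
    keep <- vapply(seq_len(n_alt), function(a) {
      adv <- m[, a + 1]
      by_ad <- !is.na(adv) & adv >= ad_min
      ar_ok <- !is.na(adv) & !is.na(d) & d > dp_min_for_ar & (adv / d) >= ar_min
      any(by_ad | ar_ok)
    }, logical(1))
    which(keep)
  })
  variants$kept_alts <- kept
  variants$dp_total_recalc <- recalc_total
  variants[lengths(kept) > 0, ]
}
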