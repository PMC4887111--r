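#' Thresholds for the genotype-to-phenotype decision model
#'
#' The published decision model is qualitative: for PCG (autosomal recessive)
#' both a near-null and a large excess of retinoic acid production interfere
#' with ocular development, while for POAG both reduced and elevated
#' estradiol metabolism are plausible mechanisms (estradiol accumulation with
#' myocilin upregulation on the low side, ROS generation on the high side).
#' The numeric cut-offs are this package's operationalization, chosen to
#' separate the observed clusters of inferred activities: null (0),
#' heterozygote floor (50), normal (about 100), and excess (>= 122). All four
#' are configurable.
#'
#' @param retinol_low_max inferred retinol activity at or below this percent
#'   counts as pathogenically low for PCG (default 25).
#' @param retinol_high_min at or above this percent counts as pathogenic
#'   excess for PCG (default 120).
#' @param steroid_normal_low,steroid_normal_high inferred estradiol activity
#'   strictly inside \code{[low, high]} is considered normal for POAG
#'   (defaults 80 and 120).
#' @return validated named list of thresholds.
#' @export
classifierThresholds <- function(retinol_low_max = 25, retinol_high_min = 120,
                                 steroid_normal_low = 80,
                                 steroid_normal_high = 120) {
  if (retinol_low_max >= retinol_high_min)
    stop("retinol_low_max must be below retinol_high_min")
  if (steroid_normal_low >= steroid_normal_high)
    stop("steroid_normal_low must be below steroid_normal_high")
  list(retinol_low_max = retinol_low_max,
       retinol_high_min = retinol_high_min,
       steroid_normal_low = steroid_normal_low,
       steroid_normal_high = steroid_normal_high)
}

#' Predict phenotype consistency from inferred genotype activities
#'
#' Pure function of the inferred activity pair: a genotype is
#' PCG-consistent when its retinol metabolism is at or below
#' \code{retinol_low_max} (code RETINOL_NULL) or at or above
#' \code{retinol_high_min} (RETINOL_EXCESS); POAG-consistent when its
#' estradiol metabolism falls below \code{steroid_normal_low} (STEROID_LOW)
#' or above \code{steroid_normal_high} (STEROID_HIGH).
#'
#' @param retinol,steroid inferred genotype-level percent-of-wild-type
#'   activities (determinate; error on NA).
#' @param thresholds a [classifierThresholds()] list.
#' @param joag attach the informational digenic-MYOC code used for juvenile
#'   open-angle glaucoma reports.
#' @return list with \code{pcg_consistent}, \code{poag_consistent} and the
#'   \code{rationale} character vector of codes.
#' @export
predictPhenotype <- function(retinol, steroid,
                             thresholds = classifierThresholds(),
                             joag = FALSE) {
  if (is.na(retinol) || is.na(steroid))
    stop("indeterminate inferred activity; route to INCONCLUSIVE instead")
  codes <- character()
  if (retinol <= thresholds$retinol_low_max) {
    codes <- c(codes, "RETINOL_NULL")
  } else if (retinol >= thresholds$retinol_high_min) {
    codes <- c(codes, "RETINOL_EXCESS")
  } else {
    codes <- c(codes, "RETINOL_NORMAL")
  }
  if (steroid < thresholds$steroid_normal_low) {
    codes <- c(codes, "STEROID_LOW")
  } else if (steroid > thresholds$steroid_normal_high) {
    codes <- c(codes, "STEROID_HIGH")
  } else {
    codes <- c(codes, "STEROID_NORMAL")
  }
  if (joag) codes <- c(codes, "DIGENIC_MYOC_NOTE")
  list(pcg_consistent = any(codes %in% c("RETINOL_NULL", "RETINOL_EXCESS")),
       poag_consistent = any(codes %in% c("STEROID_LOW", "STEROID_HIGH")),
       rationale = codes)
}

#' Genotype-to-phenotype concordance verdict
#'
#' Combines an inferred activity with the reported genotype under the
#' decision model:
#' \itemize{
#'   \item indeterminate inferred activity: \code{INCONCLUSIVE};
#'   \item genotype not available: \code{PREDICTED}, carrying the
#'     hypothetical-homozygote prediction;
#'   \item reported PCG (recessive): \code{YES} when both alleles are
#'     defective (homozygote or compound heterozygote) and the prediction is
#'     PCG-consistent; a heterozygote with a wild-type partner is \code{NO}
#'     unless its inferred retinol activity reaches the excess threshold (a
#'     single wild-type dose supplies the necessary retinoic acid);
#'   \item reported POAG or JOAG: \code{YES} when the prediction is
#'     POAG-consistent, regardless of zygosity.
#' }
#'
#' @param inferred result of [inferGenotypeActivity()] (or a list with
#'   \code{retinol_pct_int}, \code{steroid_pct_int}, \code{indeterminate}).
#' @param genotype the genotype row (needs \code{zygosity} and
#'   \code{reported_phenotype}).
#' @param thresholds a [classifierThresholds()] list.
#' @return list with \code{outcome} (one of YES, NO, INCONCLUSIVE,
#'   PREDICTED), \code{rationale} codes and \code{reason_text}.
#' @export
concordance <- function(inferred, genotype,
                        thresholds = classifierThresholds()) {
  phen <- genotype$reported_phenotype
  if (is.na(phen) || !phen %in% PHENOTYPES)
    stop("genotype carries no reported phenotype")
  if (isTRUE(inferred$indeterminate)) {
    return(list(outcome = "INCONCLUSIVE", rationale = character(),
                reason_text = "partner allele not assayed"))
  }
  pred <- predictPhenotype(inferred$retinol_pct_int,
                           inferred$steroid_pct_int,
                           thresholds, joag = identical(phen, "JOAG"))
  zyg <- genotype$zygosity
  if (zyg == "NOT_AVAILABLE") {
    return(list(outcome = "PREDICTED", rationale = pred$rationale,
                reason_text = "genotype not reported; predicted for a homozygote"))
  }
  if (phen == "PCG") {
    if (zyg == "HETEROZYGOUS") {
      yes <- inferred$retinol_pct_int >= thresholds$retinol_high_min
      reason <- if (yes) "retinoic acid excess despite one wild-type allele"
                else "one wild-type allele supplies sufficient retinoic acid"
    } else {
      yes <- pred$pcg_consistent
      reason <- if (yes) "biallelic defect with pathogenic retinol activity"
                else "biallelic genotype but retinol activity in tolerated range"
    }
  } else {
    yes <- pred$poag_consistent
    reason <- if (yes) "estradiol metabolism outside normal band"
              else "estradiol metabolism within normal band"
  }
  list(outcome = if (yes) "YES" else "NO",
       rationale = pred$rationale, reason_text = reason)
}
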