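#' Round to nearest integer, halves away from zero
#'
#' Unlike \code{base::round} (banker's rounding), 0.5 always rounds away from
#' zero, which is the convention the genotype-level activity integers follow.
#'
#' @param x numeric.
#' @return numeric of the same length, integral-valued.
#' @export
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Infer genotype-level enzyme activity from per-allele measurements
#'
#' The central allelic dosage model: a genotype's retinol and
#' 17beta-estradiol metabolizing activity is the mean of its two alleles'
#' percent-of-wild-type activities, with the wild-type allele contributing
#' 100%, a null (frameshift/deletion) allele contributing 0%, and each
#' substrate computed independently. Specifically:
#' \itemize{
#'   \item homozygote: the allele activity itself;
#'   \item heterozygote (partner wild type): mean(allele, 100);
#'   \item compound heterozygote with an assayed or null partner:
#'     mean(allele1, allele2);
#'   \item compound heterozygote with an unassayed missense partner:
#'     indeterminate (no inference attempted);
#'   \item genotype not available: evaluated as a hypothetical homozygote.
#' }
#' Results are rounded to the nearest integer percent, halves away from zero.
#'
#' @param genotype one row of [genotypes()] (a list or single-row data.frame
#'   with \code{variant_id}, \code{zygosity}, \code{partner}).
#' @param catalog the [VariantCatalog-class] supplying allele activities.
#' @return list with integer \code{retinol_pct_int}, \code{steroid_pct_int}
#'   (NA when indeterminate) and logical \code{indeterminate}.
#' @examples
#' cat23 <- loadCatalog()
#' g <- genotypes(cat23)
#' inferGenotypeActivity(g[g$variant_id == "W57C" &
#'                         g$zygosity == "HETEROZYGOUS", ], cat23)
#' @export
inferGenotypeActivity <- function(genotype, catalog) {
  stopifnot(is(catalog, "VariantCatalog"))
  v <- catalog@variants
  id <- genotype$variant_id
  row <- v[v$variant_id == id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown variant: ", id)
  if (!isTRUE(row$assayed))
    stop("variant ", id, " has no assayed allele activity")
  a_ret <- row$retinol_pct
  a_ster <- row$steroid_pct
  zyg <- genotype$zygosity
  indeterminate <- FALSE
  if (zyg %in% c("HOMOZYGOUS", "NOT_AVAILABLE")) {
    ret <- a_ret; ster <- a_ster
  } else if (zyg == "HETEROZYGOUS") {
    ret <- mean(c(a_ret, 100)); ster <- mean(c(a_ster, 100))
  } else if (zyg == "COMPOUND_HET") {
    pid <- genotype$partner
    prow <- v[v$variant_id == pid, , drop = FALSE]
    if (nrow(prow) != 1L) stop("catalog error: unknown partner allele ", pid)
    if (isTRUE(prow$is_null_allele)) {
      ret <- mean(c(a_ret, 0)); ster <- mean(c(a_ster, 0))
    } else if (isTRUE(prow$assayed)) {
      ret <- mean(c(a_ret, prow$retinol_pct))
      ster <- mean(c(a_ster, prow$steroid_pct))
    } else {
      indeterminate <- TRUE; ret <- NA_real_; ster <- NA_real_
    }
  } else {
    stop("unknown zygosity: ", zyg)
  }
  list(retinol_pct_int = if (indeterminate) NA_real_ else roundHalfAway(ret),
       steroid_pct_int = if (indeterminate) NA_real_ else roundHalfAway(ster),
       indeterminate = indeterminate)
}

#' Infer activities for every genotype in a catalog
#'
#' Applies [inferGenotypeActivity()] to each genotype row and returns the
#' genotype table with \code{retinol_int}, \code{steroid_int} and
#' \code{indeterminate} columns appended.
#'
#' @param catalog a [VariantCatalog-class].
#' @return the genotype data.frame with inference columns added.
#' @export
inferCatalogActivities <- function(catalog) {
  stopifnot(is(catalog, "VariantCatalog"))
  g <- catalog@genotypes
  inf <- lapply(seq_len(nrow(g)), function(i)
    inferGenotypeActivity(g[i, ], catalog))
  g$retinol_int <- vapply(inf, `[[`, numeric(1), "retinol_pct_int")
  g$steroid_int <- vapply(inf, `[[`, numeric(1), "steroid_pct_int")
  g$indeterminate <- vapply(inf, `[[`, logical(1), "indeterminate")
  g
}
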