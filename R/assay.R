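#' Unpaired two-sample t-test on replicate values
#'
#' Thin wrapper around [stats::t.test()] defaulting to the pooled-variance
#' Student's test (df = n_a + n_b - 2, two-sided), with Welch's correction
#' available by flag. Degenerate zero-variance inputs, which \code{t.test}
#' refuses, are resolved explicitly: identical constant groups give
#' \code{t = 0, p = 1}; constant groups with different means give an infinite
#' statistic, \code{p = 0} and \code{degenerate = TRUE}.
#'
#' @param a,b numeric vectors of replicate values, each of length >= 2.
#' @param welch use Welch's unequal-variance test instead of Student's.
#' @return list with \code{t_stat}, \code{p_value}, \code{df},
#'   \code{degenerate}.
#' @export
twoSampleT <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 replicates")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t_stat = 0, p_value = 1,
                  df = length(a) + length(b) - 2, degenerate = FALSE))
    return(list(t_stat = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                df = length(a) + length(b) - 2, degenerate = TRUE))
  }
  tt <- tryCatch(stats::t.test(a, b, var.equal = !welch), error = identity)
  if (inherits(tt, "error")) {
    # both groups numerically constant (t.test: "data are essentially
    # constant"): no within-group variance to test against
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t_stat = 0, p_value = 1,
                  df = length(a) + length(b) - 2, degenerate = FALSE))
    return(list(t_stat = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                df = length(a) + length(b) - 2, degenerate = TRUE))
  }
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

checkWells <- function(wells, need_rl = FALSE) {
  required <- c("sample_id", "replicate", "role", "FL_RLU")
  miss <- setdiff(required, names(wells))
  if (length(miss))
    stop("well table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(wells$role %in% WELL_ROLES))
    stop("unknown well role(s): ",
         paste(setdiff(unique(wells$role), WELL_ROLES), collapse = ", "))
  if (any(wells$FL_RLU < 0)) stop("negative luminescence reading")
  if (need_rl) {
    if (!"RL_RLU" %in% names(wells)) stop("retinol assay wells need RL_RLU")
    divided <- wells$role %in% c("EMPTY_VECTOR", "WILD_TYPE", "VARIANT")
    if (any(wells$RL_RLU[divided] <= 0))
      stop("division error: RL_RLU must be > 0 for transfected wells")
  }
  invisible(wells)
}

# aggregate per-replicate percent-of-WT values into one estimate per sample,
# testing each sample's replicate percentages against the WT ones
aggregateEstimates <- function(pct_by_well, welch = FALSE) {
  wt <- pct_by_well$pct[pct_by_well$role == "WILD_TYPE"]
  ids <- unique(pct_by_well$sample_id)
  out <- lapply(ids, function(id) {
    x <- pct_by_well$pct[pct_by_well$sample_id == id]
    n <- length(x)
    tt <- if (n >= 2L && length(wt) >= 2L) twoSampleT(x, wt, welch = welch)
          else list(t_stat = NA_real_, p_value = NA_real_)
    data.frame(sample_id = id, mean_pct = mean(x),
               sem = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
               n = n, t_stat = tt$t_stat, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, out)
  rownames(est) <- NULL
  est
}

#' Normalize a 17beta-estradiol (luminogenic substrate) assay plate
#'
#' Implements the three-step arithmetic of the cell-based estradiol
#' metabolism assay: (1) the mean no-cell background luminescence is
#' subtracted from every test well; (2) the mean background-corrected
#' empty-vector signal is subtracted, removing endogenous activity; (3) each
#' replicate's net signal is expressed as percent of the mean wild-type net
#' signal. Negative per-replicate nets are clamped to zero before averaging,
#' so fully inactive variants report a hard 0.00 rather than noise-driven
#' negatives. Estimates are aggregated over replicates (mean, SEM, Student's
#' t against the wild-type replicates).
#'
#' @param wells data.frame of wells with columns \code{sample_id},
#'   \code{replicate}, \code{role} (one of NO_CELL_BACKGROUND, EMPTY_VECTOR,
#'   WILD_TYPE, VARIANT) and \code{FL_RLU}.
#' @param welch passed to [twoSampleT()].
#' @return data.frame, one row per wild-type/variant sample:
#'   \code{sample_id, mean_pct, sem, n, t_stat, p_value}.
#' @export
normalizeEstradiol <- function(wells, welch = FALSE) {
  checkWells(wells)
  if (sum(wells$role == "NO_CELL_BACKGROUND") < 1L)
    stop("need at least one no-cell background well")
  if (sum(wells$role == "EMPTY_VECTOR") < 1L)
    stop("need at least one empty-vector well")
  if (sum(wells$role == "WILD_TYPE") < 2L)
    stop("need at least two wild-type wells")
  bg <- mean(wells$FL_RLU[wells$role == "NO_CELL_BACKGROUND"])
  net <- wells$FL_RLU - bg
  ev <- mean(net[wells$role == "EMPTY_VECTOR"])
  test <- wells$role %in% c("WILD_TYPE", "VARIANT")
  net2 <- pmax(net[test] - ev, 0)
  wt_mean <- mean(net2[wells$role[test] == "WILD_TYPE"])
  if (wt_mean <= 0)
    stop("normalization error: mean wild-type net signal is not positive")
  pct <- data.frame(sample_id = wells$sample_id[test],
                    role = wells$role[test],
                    pct = 100 * net2 / wt_mean, stringsAsFactors = FALSE)
  aggregateEstimates(pct, welch = welch)
}

#' Normalize a retinol (dual-luciferase RARE reporter) assay plate
#'
#' Implements the kit's calculation for the retinoic-acid reporter readout,
#' in order: (1) the mean firefly signal of the negative control
#' (non-inducible construct) is subtracted from every transfected well;
#' (2) the mean corrected empty-vector firefly signal is subtracted;
#' (3) each well's corrected firefly value is divided by its own Renilla
#' value, cancelling per-well transfection efficiency; (4) ratios are
#' expressed as percent of the mean wild-type ratio. Negative corrected
#' firefly values are clamped to zero before division.
#'
#' @param wells data.frame of wells with columns \code{sample_id},
#'   \code{replicate}, \code{role} (NEGATIVE_CONTROL, EMPTY_VECTOR,
#'   WILD_TYPE, VARIANT), \code{FL_RLU} and \code{RL_RLU}.
#' @param welch passed to [twoSampleT()].
#' @return data.frame as for [normalizeEstradiol()].
#' @export
normalizeRetinol <- function(wells, welch = FALSE) {
  checkWells(wells, need_rl = TRUE)
  if (sum(wells$role == "NEGATIVE_CONTROL") < 1L)
    stop("need at least one negative-control well")
  if (sum(wells$role == "EMPTY_VECTOR") < 1L)
    stop("need at least one empty-vector well")
  if (sum(wells$role == "WILD_TYPE") < 2L)
    stop("need at least two wild-type wells")
  neg <- mean(wells$FL_RLU[wells$role == "NEGATIVE_CONTROL"])
  fl1 <- wells$FL_RLU - neg
  ev <- mean(fl1[wells$role == "EMPTY_VECTOR"])
  test <- wells$role %in% c("WILD_TYPE", "VARIANT")
  fl2 <- pmax(fl1[test] - ev, 0)
  ratio <- fl2 / wells$RL_RLU[test]
  wt_ratio <- mean(ratio[wells$role[test] == "WILD_TYPE"])
  if (wt_ratio <= 0)
    stop("normalization error: mean wild-type ratio is not positive")
  pct <- data.frame(sample_id = wells$sample_id[test],
                    role = wells$role[test],
                    pct = 100 * ratio / wt_ratio, stringsAsFactors = FALSE)
  aggregateEstimates(pct, welch = welch)
}
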