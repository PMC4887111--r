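#' Normalize a cycloheximide-chase densitometry time course
#'
#' Band intensities are quantified per lane as the CYP1B1/beta-actin ratio,
#' averaged over replicate transfections at each time point, and expressed as
#' a percentage of the wild-type level at the matching time point. Lanes with
#' a zero loading-control intensity are rejected with a warning. Each
#' sample/time cell is tested against the wild-type replicate ratios with an
#' unpaired t-test.
#'
#' @param measurements data.frame with columns \code{sample_id},
#'   \code{time_h}, \code{replicate}, \code{od_cyp1b1}, \code{od_actin}; the
#'   wild-type sample must be present at every time point with at least two
#'   replicates.
#' @param wt_id sample id of the wild-type reference (default \code{"WT"}).
#' @param welch passed to [twoSampleT()].
#' @return data.frame with one row per (sample, time point):
#'   \code{sample_id, time_h, percent_of_wt, sem, n, p_value}. The wild-type
#'   rows are 100 at every time point by construction.
#' @export
normalizeDensitometry <- function(measurements, wt_id = "WT", welch = FALSE) {
  required <- c("sample_id", "time_h", "replicate", "od_cyp1b1", "od_actin")
  miss <- setdiff(required, names(measurements))
  if (length(miss))
    stop("densitometry table missing column(s): ", paste(miss, collapse = ", "))
  if (!wt_id %in% measurements$sample_id)
    stop("wild-type sample '", wt_id, "' not present")
  bad <- measurements$od_actin <= 0
  if (any(bad)) {
    warning(sum(bad), " lane(s) rejected: zero loading-control intensity")
    measurements <- measurements[!bad, , drop = FALSE]
  }
  if (any(measurements$od_cyp1b1 < 0)) stop("negative band intensity")
  times <- sort(unique(measurements$time_h))
  wt_times <- unique(measurements$time_h[measurements$sample_id == wt_id])
  if (!all(times %in% wt_times))
    stop("wild-type not measured at time point(s): ",
         paste(setdiff(times, wt_times), collapse = ", "))
  measurements$ratio <- measurements$od_cyp1b1 / measurements$od_actin
  ids <- unique(measurements$sample_id)
  rows <- list()
  for (id in ids) {
    for (t in sort(unique(measurements$time_h[measurements$sample_id == id]))) {
      x <- measurements$ratio[measurements$sample_id == id &
                                measurements$time_h == t]
      w <- measurements$ratio[measurements$sample_id == wt_id &
                                measurements$time_h == t]
      pct <- 100 * mean(x) / mean(w)
      sem <- if (length(x) >= 2) 100 * stats::sd(x) / sqrt(length(x)) / mean(w)
             else NA_real_
      p <- if (length(x) >= 2 && length(w) >= 2)
             twoSampleT(x, w, welch = welch)$p_value else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = id, time_h = t, percent_of_wt = pct,
                   sem = sem, n = length(x), p_value = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a turnover profile as stable or unstable
#'
#' A sample is called \code{UNSTABLE} when, at one or more post-zero time
#' points, its level is below 100% of wild type with two-sided significance
#' below \code{alpha}; otherwise \code{STABLE}. The default
#' \code{alpha = 0.01} follows the significance level used for the published
#' chase experiments.
#'
#' @param profile a profile data.frame as returned by
#'   [normalizeDensitometry()], restricted to one sample (or pass
#'   \code{sample_id}).
#' @param alpha two-sided significance level.
#' @param sample_id optionally select one sample from a multi-sample profile.
#' @return \code{"STABLE"} or \code{"UNSTABLE"}.
#' @export
classifyStability <- function(profile, alpha = 0.01, sample_id = NULL) {
  if (!is.null(sample_id))
    profile <- profile[profile$sample_id == sample_id, , drop = FALSE]
  if (length(unique(profile$sample_id)) != 1L)
    stop("profile must contain exactly one sample; use sample_id=")
  post <- profile[profile$time_h > 0, , drop = FALSE]
  if (!nrow(post))
    stop("stability undefined: no post-zero time points")
  drop <- post$percent_of_wt < 100 & !is.na(post$p_value) &
    post$p_value < alpha
  if (any(drop)) "UNSTABLE" else "STABLE"
}
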