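# mean-preserving multiplicative lognormal noise at a given CV
lognormNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate a 17beta-estradiol assay plate
#'
#' Emulates the luminogenic-substrate readout: no-cell background wells, an
#' empty-vector baseline above background (endogenous activity), and
#' wild-type/variant wells whose net signal is proportional to the configured
#' true activity (percent of wild type). All readings carry multiplicative
#' lognormal noise at the stated CV; at zero CV the plate is exactly
#' invertible by [normalizeEstradiol()].
#'
#' @param true_activity_pct named numeric vector of variant activities in
#'   percent of wild type.
#' @param background_mean mean no-cell background luminescence (RLU).
#' @param empty_vector_extra empty-vector signal above background (RLU).
#' @param signal_per_pct net RLU per percent of wild-type activity.
#' @param noise_cv coefficient of variation of the multiplicative measurement
#'   noise.
#' @param replicates wells per sample (default 3, matching a technical
#'   triplicate).
#' @param seed integer seed; the plate is reproducible given the seed.
#' @return data.frame of wells (\code{sample_id, replicate, role, FL_RLU}).
#' @export
simulateEstradiolPlate <- function(true_activity_pct,
                                   background_mean = 200,
                                   empty_vector_extra = 300,
                                   signal_per_pct = 50,
                                   noise_cv = 0.1,
                                   replicates = 3,
                                   seed = 1) {
  stopifnot(all(true_activity_pct >= 0), background_mean >= 0,
            empty_vector_extra >= 0, noise_cv >= 0, replicates >= 1)
  set.seed(seed)
  samples <- c(BACKGROUND = NA, EMPTY_VECTOR = NA, WT = 100, true_activity_pct)
  rows <- list()
  for (i in seq_along(samples)) {
    id <- names(samples)[i]
    role <- switch(id, BACKGROUND = "NO_CELL_BACKGROUND",
                   EMPTY_VECTOR = "EMPTY_VECTOR",
                   WT = "WILD_TYPE", "VARIANT")
    base <- switch(role,
                   NO_CELL_BACKGROUND = background_mean,
                   EMPTY_VECTOR = background_mean + empty_vector_extra,
                   background_mean + empty_vector_extra +
                     signal_per_pct * samples[[i]])
    rows[[i]] <- data.frame(sample_id = id, replicate = seq_len(replicates),
                            role = role,
                            FL_RLU = base * lognormNoise(replicates, noise_cv),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a retinol (dual-luciferase) assay plate
#'
#' Emulates the retinoic-acid reporter design: a negative-control
#' (non-inducible firefly) baseline, empty-vector wells, and
#' wild-type/variant wells whose reporter-derived firefly signal is
#' proportional to the configured activity. Every transfected well draws its
#' own transfection-efficiency factor which multiplies both the
#' reporter-derived firefly component and the Renilla reading, so the FL/RL
#' division in [normalizeRetinol()] cancels it exactly; with zero measurement
#' noise the configured activities are recovered to machine precision
#' regardless of the efficiency CV. The empty-vector reporter signal above
#' the negative-control baseline defaults to zero, reflecting a host line
#' with essentially no endogenous CYP1B1.
#'
#' @param true_activity_pct named numeric vector, percent of wild type.
#' @param negative_control_fl firefly baseline of the non-inducible control
#'   construct (RLU).
#' @param empty_vector_extra reporter-derived empty-vector firefly signal
#'   above the negative-control baseline, before the efficiency factor
#'   (default 0).
#' @param signal_per_pct reporter firefly RLU per percent activity (at unit
#'   efficiency).
#' @param rl_mean mean Renilla reading at unit efficiency.
#' @param efficiency_cv per-well transfection-efficiency CV (lognormal).
#' @param noise_cv multiplicative measurement-noise CV applied to each
#'   reading.
#' @param replicates wells per sample.
#' @param seed integer seed.
#' @return data.frame of wells (\code{sample_id, replicate, role, FL_RLU,
#'   RL_RLU}).
#' @export
simulateRetinolPlate <- function(true_activity_pct,
                                 negative_control_fl = 150,
                                 empty_vector_extra = 0,
                                 signal_per_pct = 40,
                                 rl_mean = 5000,
                                 efficiency_cv = 0.3,
                                 noise_cv = 0.1,
                                 replicates = 3,
                                 seed = 1) {
  stopifnot(all(true_activity_pct >= 0), negative_control_fl >= 0,
            empty_vector_extra >= 0, efficiency_cv >= 0, noise_cv >= 0,
            replicates >= 1)
  set.seed(seed)
  samples <- c(NEG = NA, EMPTY_VECTOR = NA, WT = 100, true_activity_pct)
  rows <- list()
  for (i in seq_along(samples)) {
    id <- names(samples)[i]
    role <- switch(id, NEG = "NEGATIVE_CONTROL",
                   EMPTY_VECTOR = "EMPTY_VECTOR",
                   WT = "WILD_TYPE", "VARIANT")
    act <- switch(role, NEGATIVE_CONTROL = 0, EMPTY_VECTOR = 0, samples[[i]])
    eff <- lognormNoise(replicates, efficiency_cv)
    reporter <- if (role == "EMPTY_VECTOR") empty_vector_extra
                else if (role == "NEGATIVE_CONTROL") 0
                else empty_vector_extra + signal_per_pct * act
    fl <- (negative_control_fl + eff * reporter) *
      lognormNoise(replicates, noise_cv)
    rl <- rl_mean * eff * lognormNoise(replicates, noise_cv)
    rows[[i]] <- data.frame(sample_id = id, replicate = seq_len(replicates),
                            role = role, FL_RLU = fl, RL_RLU = rl,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cycloheximide-chase densitometry time course
#'
#' After translational arrest each sample's CYP1B1 band decays exponentially,
#' \code{od = initial * exp(-rate * t)}, while the beta-actin loading control
#' stays constant; both carry multiplicative lognormal noise. Defaults follow
#' the published chase design (samples at 0, 4, 8 and 12 h, triplicate
#' transfections).
#'
#' @param decay_rate named numeric vector of per-hour decay rates; must
#'   include the wild-type sample (\code{"WT"}).
#' @param initial_level band intensity at time 0 (common to all samples
#'   unless a named vector).
#' @param time_h time points in hours.
#' @param actin_level loading-control intensity.
#' @param noise_cv multiplicative noise CV.
#' @param replicates independent transfections per sample.
#' @param seed integer seed.
#' @return data.frame (\code{sample_id, time_h, replicate, od_cyp1b1,
#'   od_actin}).
#' @export
simulateChxTimecourse <- function(decay_rate,
                                  initial_level = 1000,
                                  time_h = c(0, 4, 8, 12),
                                  actin_level = 800,
                                  noise_cv = 0.05,
                                  replicates = 3,
                                  seed = 1) {
  stopifnot(all(decay_rate >= 0), is.unsorted(time_h) == FALSE,
            noise_cv >= 0, replicates >= 1)
  if (!"WT" %in% names(decay_rate))
    stop("decay_rate must include the wild-type sample 'WT'")
  init <- if (length(initial_level) == 1L)
            stats::setNames(rep(initial_level, length(decay_rate)),
                            names(decay_rate)) else initial_level
  set.seed(seed)
  rows <- list()
  for (id in names(decay_rate)) {
    for (t in time_h) {
      mu <- init[[id]] * exp(-decay_rate[[id]] * t)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = id, time_h = t, replicate = seq_len(replicates),
        od_cyp1b1 = mu * lognormNoise(replicates, noise_cv),
        od_actin = actin_level * lognormNoise(replicates, noise_cv),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate an idealized toy coarse-grained structure
#'
#' Builds a CA-only chain with the standard 3.8 Angstrom spacing between
#' consecutive alpha carbons: \code{HELIX} is an ideal alpha-helical spiral
#' (1.5 A rise, 100 degrees twist, 2.3 A radius), \code{EXTENDED} a
#' beta-strand-like zigzag, and \code{PALINDROME} a circular arc whose
#' geometry is exactly mirror-symmetric about the chain midpoint (so elastic
#' network fluctuation profiles are palindromic).
#'
#' @param n_res number of residues (>= 4).
#' @param geometry \code{"HELIX"}, \code{"EXTENDED"} or \code{"PALINDROME"}.
#' @return a [StructureModel-class] (CA_ONLY, poly-alanine, chain A).
#' @export
generateToyStructure <- function(n_res,
                                 geometry = c("HELIX", "EXTENDED",
                                              "PALINDROME")) {
  geometry <- match.arg(geometry)
  if (n_res < 4) stop("n_res must be at least 4")
  i <- seq_len(n_res)
  xyz <- switch(geometry,
    HELIX = {
      theta <- (i - 1) * 100 * pi / 180
      cbind(2.3 * cos(theta), 2.3 * sin(theta), (i - 1) * 1.5)
    },
    EXTENDED = {
      # polyproline-II-like extended spiral (3.8 A between neighbours);
      # non-planar so the elastic network keeps exactly 6 rigid-body modes
      theta <- (i - 1) * (-120) * pi / 180
      rise <- sqrt(3.8^2 - (2 * sin(pi / 3))^2)
      cbind(cos(theta), sin(theta), (i - 1) * rise)
    },
    PALINDROME = {
      # wide helix parameterized symmetrically about the chain midpoint:
      # chain reversal maps the structure onto itself by a 180-degree
      # rotation about the x-axis, so fluctuation profiles are palindromic
      radius <- 4
      dphi <- 40 * pi / 180
      rise <- sqrt(3.8^2 - (2 * radius * sin(dphi / 2))^2)
      phi <- (i - 1 - (n_res - 1) / 2) * dphi
      cbind(radius * cos(phi), radius * sin(phi),
            (i - 1 - (n_res - 1) / 2) * rise)
    })
  colnames(xyz) <- c("x", "y", "z")
  new("StructureModel",
      atoms = data.frame(chain = "A", resno = i, resid = "ALA", elety = "CA",
                         stringsAsFactors = FALSE),
      xyz = xyz, granularity = "CA_ONLY")
}

#' Generate a synthetic coordinate ensemble with known covariance
#'
#' Draws \code{n} members as the base structure plus correlated Gaussian
#' displacements: the displacement covariance is
#' \code{sum_k values[k] * v_k v_k^T} over the supplied (or seeded random
#' orthonormal) 3N-dimensional directions, so [ensemblePCA()] should recover
#' \code{values} as its leading variances.
#'
#' @param struct base [StructureModel-class] (or n x 3 matrix).
#' @param values numeric vector of displacement variances per mode
#'   (Angstrom^2).
#' @param directions optional 3N x k orthonormal matrix of displacement
#'   directions; random (orthonormalized Gaussian, seeded) if omitted.
#' @param n number of members.
#' @param seed integer seed.
#' @return list of n x 3 coordinate matrices.
#' @export
generateEnsemble <- function(struct, values, directions = NULL, n = 100,
                             seed = 1) {
  xyz <- if (is(struct, "StructureModel")) struct@xyz else as.matrix(struct)
  n3 <- 3 * nrow(xyz)
  k <- length(values)
  stopifnot(all(values >= 0), k >= 1, k <= n3, n >= 1)
  set.seed(seed)
  if (is.null(directions)) {
    directions <- qr.Q(qr(matrix(stats::rnorm(n3 * k), n3, k)))
  }
  stopifnot(nrow(directions) == n3, ncol(directions) == k)
  amp <- matrix(stats::rnorm(n * k), n, k) %*% diag(sqrt(values), k)
  base <- as.vector(t(xyz))
  lapply(seq_len(n), function(m) {
    matrix(base + directions %*% amp[m, ], ncol = 3, byrow = TRUE)
  })
}
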