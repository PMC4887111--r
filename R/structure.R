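#' Read a protein structure from a PDB file
#'
#' Parses standard ATOM records via \pkg{bio3d}, selects one chain, resolves
#' alternate locations to the highest-occupancy copy, and reduces to the
#' requested granularity. Unresolved residues are simply absent from the
#' model; at \code{CA_ONLY} granularity residues lacking an alpha carbon are
#' skipped with a warning.
#'
#' @param path PDB file.
#' @param chain chain identifier (default \code{"A"}).
#' @param granularity \code{"CA_ONLY"} (one site per residue) or
#'   \code{"HEAVY_ATOM"} (all non-hydrogen atoms).
#' @return a [StructureModel-class].
#' @export
readStructure <- function(path, chain = "A",
                          granularity = c("CA_ONLY", "HEAVY_ATOM")) {
  granularity <- match.arg(granularity)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stop("chain ", chain, " not present in ", path)
  # alternate locations: keep the highest-occupancy copy of each atom
  if (any(!is.na(at$alt))) {
    key <- paste(at$resno, at$insert, at$elety)
    at <- at[order(key, -replace(at$o, is.na(at$o), 1)), , drop = FALSE]
    at <- at[!duplicated(paste(at$resno, at$insert, at$elety)), , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }
  if (granularity == "CA_ONLY") {
    all_res <- unique(at$resno)
    at <- at[at$elety == "CA", , drop = FALSE]
    missing <- setdiff(all_res, at$resno)
    if (length(missing))
      warning(length(missing), " residue(s) lack a CA atom and were skipped: ",
              paste(missing, collapse = ", "))
  } else {
    at <- at[substr(at$elety, 1, 1) != "H", , drop = FALSE]
  }
  at <- at[order(at$resno), , drop = FALSE]
  new("StructureModel",
      atoms = data.frame(chain = at$chain, resno = as.integer(at$resno),
                         resid = at$resid, elety = at$elety,
                         stringsAsFactors = FALSE),
      xyz = cbind(x = at$x, y = at$y, z = at$z),
      granularity = granularity)
}

#' Write a structure model to a PDB file
#'
#' @param struct a [StructureModel-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(struct, path) {
  stopifnot(is(struct, "StructureModel"))
  a <- struct@atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(struct@xyz)),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = a$chain)
  invisible(path)
}

#' Build the anisotropic network model Hessian
#'
#' Distance-cutoff elastic network with uniform spring constant: for every
#' site pair within \code{cutoff}, the off-diagonal 3x3 block is
#' \code{-gamma * (r_ij r_ij^T) / |r_ij|^2}; diagonal blocks are minus the
#' sum of the row's off-diagonal blocks, making the matrix symmetric positive
#' semidefinite with exactly six zero eigenvalues for a connected contact
#' graph.
#'
#' @param struct a [StructureModel-class] or an n x 3 coordinate matrix.
#' @param cutoff contact cutoff in Angstrom (default 15, the usual choice for
#'   CA-only networks; 8 is customary for heavy-atom models).
#' @param gamma uniform spring constant (arbitrary units).
#' @return 3N x 3N symmetric numeric matrix.
#' @export
buildHessian <- function(struct, cutoff = 15, gamma = 1) {
  xyz <- if (is(struct, "StructureModel")) struct@xyz else as.matrix(struct)
  n <- nrow(xyz)
  if (n < 2) stop("need at least 2 sites")
  if (cutoff <= 0) stop("cutoff must be positive")
  d <- as.matrix(stats::dist(xyz))
  contact <- d > 0 & d <= cutoff
  comp <- contactComponents(contact)
  if (max(comp) > 1L)
    stop("disconnected contact graph at cutoff ", cutoff, ": ",
         max(comp), " components of sizes ",
         paste(tabulate(comp), collapse = ", "))
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (!contact[i, j]) next
      rij <- xyz[j, ] - xyz[i, ]
      blk <- -gamma * tcrossprod(rij) / sum(rij^2)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  H
}

# connected components of a logical adjacency matrix (BFS)
contactComponents <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Normal modes of an elastic network
#'
#' Dense symmetric eigen-decomposition of the ANM Hessian, returned with
#' eigenvalues ascending so that modes 1-6 are the rigid-body translations
#' and rotations and mode 7 is the first internal motion.
#'
#' @param struct a [StructureModel-class] (or coordinate matrix, in which
#'   case residue numbers default to 1..N).
#' @param cutoff,gamma passed to [buildHessian()].
#' @return a [ModeSet-class].
#' @export
enmModes <- function(struct, cutoff = 15, gamma = 1) {
  H <- buildHessian(struct, cutoff = cutoff, gamma = gamma)
  resno <- if (is(struct, "StructureModel")) unique(struct@atoms$resno)
           else seq_len(nrow(as.matrix(struct)))
  e <- eigen(H, symmetric = TRUE)
  ord <- rev(seq_along(e$values))
  new("ModeSet", values = e$values[ord],
      vectors = e$vectors[, ord, drop = FALSE],
      resno = as.integer(resno))
}

#' Per-residue RMSF from a range of normal modes
#'
#' For residue i and modes k in \code{mode_range}, the fluctuation is
#' \code{sqrt(mean_k |e_k(i)|^2 / lambda_k)}, where \code{|e_k(i)|^2} sums the
#' residue's three Cartesian components of eigenvector k. The default range
#' 7:9 averages the first three internal modes; selecting a rigid-body mode
#' (near-zero eigenvalue) is an error.
#'
#' @param modes a [ModeSet-class].
#' @param mode_range integer vector of 1-based mode indices (default
#'   \code{7:9}).
#' @param tol eigenvalues below \code{tol} times the spectral maximum count
#'   as rigid-body.
#' @return a [FlexProfile-class].
#' @export
modeRMSF <- function(modes, mode_range = 7:9, tol = 1e-8) {
  stopifnot(is(modes, "ModeSet"))
  vals <- modes@values
  if (any(mode_range < 1 | mode_range > length(vals)))
    stop("mode_range outside the spectrum")
  if (any(vals[mode_range] < tol * max(abs(vals))))
    stop("rigid-body mode selected: near-zero eigenvalue in mode_range")
  n <- length(modes@resno)
  msf <- numeric(n)
  for (k in mode_range) {
    ek <- matrix(modes@vectors[, k], ncol = 3, byrow = TRUE)
    msf <- msf + rowSums(ek^2) / vals[k]
  }
  new("FlexProfile", rmsf = sqrt(msf / length(mode_range)),
      resno = modes@resno, modes = as.integer(mode_range))
}

#' Per-residue log2 flexibility ratio between mutant and wild type
#'
#' \code{log2((rmsf_mut + eps) / (rmsf_wt + eps))} on the common residue set;
#' positive values indicate increased flexibility in the mutant. Residues
#' present in only one profile are dropped and reported via a message.
#'
#' @param mutant,wt [FlexProfile-class] objects.
#' @param epsilon ratio guard added to both numerator and denominator.
#' @return data.frame with columns \code{resno}, \code{log2_ratio}.
#' @export
log2FlexRatio <- function(mutant, wt, epsilon = 1e-9) {
  stopifnot(is(mutant, "FlexProfile"), is(wt, "FlexProfile"))
  common <- intersect(mutant@resno, wt@resno)
  if (!length(common)) stop("no residues in common between the profiles")
  dropped <- length(union(mutant@resno, wt@resno)) - length(common)
  if (dropped > 0)
    message(dropped, " residue(s) present in only one profile were dropped")
  fm <- mutant@rmsf[match(common, mutant@resno)]
  fw <- wt@rmsf[match(common, wt@resno)]
  data.frame(resno = common,
             log2_ratio = log2((fm + epsilon) / (fw + epsilon)))
}

#' Summarize a flexibility-ratio profile over named segments
#'
#' Cytochrome P450 structures are conventionally described in terms of
#' helix/loop blocks (B-C loop, F-G region, ...) that gate active-site
#' access. Given named residue ranges, returns each block's mean, min and
#' max log2 ratio, ranked by absolute mean. Blocks that resolve to no
#' residues are excluded with a warning.
#'
#' @param ratio data.frame from [log2FlexRatio()].
#' @param segments data.frame with columns \code{name}, \code{start},
#'   \code{end} (residue numbers, inclusive); see [defaultSegments()].
#' @return data.frame with one row per block: \code{name, n_res, mean, min,
#'   max}, ordered by decreasing \code{abs(mean)}.
#' @export
summarizeSegments <- function(ratio, segments) {
  stopifnot(all(c("name", "start", "end") %in% names(segments)))
  if (anyDuplicated(segments$name)) stop("segment names must be unique")
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    sel <- ratio$resno >= segments$start[i] & ratio$resno <= segments$end[i]
    if (!any(sel)) return(NULL)
    data.frame(name = segments$name[i], n_res = sum(sel),
               mean = mean(ratio$log2_ratio[sel]),
               min = min(ratio$log2_ratio[sel]),
               max = max(ratio$log2_ratio[sel]), stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty))
    warning("segment(s) with no residues excluded: ",
            paste(segments$name[empty], collapse = ", "))
  out <- do.call(rbind, rows[!empty])
  if (is.null(out)) stop("no segment resolved to any residue")
  out <- out[order(-abs(out$mean)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default cytochrome P450 segment definitions for CYP1B1 numbering
#'
#' Approximate residue ranges for the classical P450 blocks, derived from
#' secondary-structure conventions for the CYP1 family. They are a
#' convenience default only and are not authoritative: segment boundaries
#' should be supplied explicitly for quantitative work.
#'
#' @return data.frame with columns \code{name}, \code{start}, \code{end}.
#' @export
defaultSegments <- function() {
  utils::read.delim(system.file("extdata", "cyp1b1_segments.tsv",
                                package = "cypdose", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

# optimal rigid-body superposition (Kabsch, via SVD); returns the rotated
# and translated copy of P fitted onto Q
kabschFit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P0 %*% t(R), 2, cq, `+`)
}

#' Least-squares superposition of an ensemble onto a reference
#'
#' Each member is rigid-body fitted (optimal rotation and translation, SVD
#' solution of the orthogonal Procrustes problem) onto the reference
#' coordinates; the fitted RMSD never exceeds the unfitted one.
#'
#' @param ensemble list of n x 3 coordinate matrices with equal atom counts.
#' @param reference n x 3 matrix (or [StructureModel-class]); defaults to the
#'   first member.
#' @return list with \code{fitted} (list of matrices) and \code{rmsd}
#'   (numeric vector of post-fit RMSDs).
#' @export
superposeEnsemble <- function(ensemble, reference = NULL) {
  if (is(reference, "StructureModel")) reference <- reference@xyz
  if (is.null(reference)) reference <- ensemble[[1]]
  n <- nrow(reference)
  if (n < 3) stop("need at least 3 atoms to superpose")
  fitted <- lapply(ensemble, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != n) stop("ensemble members must have equal atom counts")
    kabschFit(m, reference)
  })
  rmsd <- vapply(fitted, function(m) sqrt(mean(rowSums((m - reference)^2))),
                 numeric(1))
  list(fitted = fitted, rmsd = rmsd)
}

#' Principal component analysis of a fitted structural ensemble
#'
#' Flattens each member to a 3N-vector, takes the covariance over members,
#' and eigen-decomposes it. Component variances are returned in descending
#' order with centred projections of every member on the leading components.
#' An ensemble of identical members yields all-zero variances.
#'
#' @param fitted list of n x 3 coordinate matrices (typically the
#'   \code{fitted} element of [superposeEnsemble()]).
#' @param n_components number of leading components to keep projections for.
#' @return a [PCAResult-class].
#' @export
ensemblePCA <- function(fitted, n_components = 3) {
  if (length(fitted) < 3) stop("need at least 3 ensemble members")
  X <- t(vapply(fitted, function(m) as.vector(t(m)),
                numeric(3 * nrow(fitted[[1]]))))
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  k <- min(n_components, ncol(X))
  new("PCAResult", variances = vals,
      projections = Xc %*% e$vectors[, seq_len(k), drop = FALSE])
}

#' Scalar PC1-PC3 summary of an ensemble's essential dynamics
#'
#' Reduces a [PCAResult-class] to a triple of scalars, one per leading
#' component, for cross-structure comparison with [pcDistance()]. The default
#' summary is the component variance (eigenvalue); the mean projection is
#' selectable but is zero by construction for a centred single-ensemble PCA
#' and only meaningful when members are projected on a common basis.
#'
#' @param pca a [PCAResult-class].
#' @param method \code{"variance"} or \code{"meanProjection"}.
#' @return numeric length-3 vector (PC1, PC2, PC3).
#' @export
pcSummary <- function(pca, method = c("variance", "meanProjection")) {
  stopifnot(is(pca, "PCAResult"))
  method <- match.arg(method)
  if (method == "variance") {
    out <- pca@variances[1:3]
  } else {
    out <- colMeans(pca@projections[, 1:3, drop = FALSE])
  }
  unname(out)
}

#' Euclidean distance between two PC summary triples
#'
#' \code{sqrt(sum_k (PCk_a - PCk_b)^2)} over the first three principal
#' components; small distances indicate similar essential dynamics.
#'
#' @param a,b numeric length-3 summaries (see [pcSummary()]).
#' @return non-negative scalar.
#' @export
pcDistance <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3)
  sqrt(sum((a - b)^2))
}

#' Relabel a mutated residue and prune to shared atoms
#'
#' Convenience for preparing mutant/wild-type model pairs from a single
#' structure: the residue at \code{resno} is relabelled to \code{new_aa}, and
#' at heavy-atom granularity only atoms common to both residue types are
#' retained (an explicit approximation of rebuilding the side chain). At
#' CA-only granularity the coordinates are unchanged, so the elastic network
#' is identical by construction and comparisons require externally built
#' mutant coordinates.
#'
#' @param struct a [StructureModel-class].
#' @param resno residue number to mutate.
#' @param new_aa three-letter residue code of the substitute.
#' @return a modified [StructureModel-class].
#' @export
substituteAndPrune <- function(struct, resno, new_aa) {
  stopifnot(is(struct, "StructureModel"))
  sel <- struct@atoms$resno == resno
  if (!any(sel)) stop("residue ", resno, " not in structure")
  atoms <- struct@atoms
  xyz <- struct@xyz
  if (struct@granularity == "HEAVY_ATOM") {
    keep_names <- intersect(residueAtomNames(unique(atoms$resid[sel])[1]),
                            residueAtomNames(new_aa))
    drop <- sel & !atoms$elety %in% keep_names
    atoms <- atoms[!drop, , drop = FALSE]
    xyz <- xyz[!drop, , drop = FALSE]
    sel <- atoms$resno == resno
  }
  atoms$resid[sel] <- new_aa
  new("StructureModel", atoms = atoms, xyz = xyz,
      granularity = struct@granularity)
}

# heavy-atom names of the standard residues (backbone + side chain)
residueAtomNames <- function(resid) {
  bb <- c("N", "CA", "C", "O")
  sc <- switch(toupper(resid),
    GLY = character(),
    ALA = "CB",
    SER = c("CB", "OG"),
    CYS = c("CB", "SG"),
    THR = c("CB", "OG1", "CG2"),
    VAL = c("CB", "CG1", "CG2"),
    LEU = c("CB", "CG", "CD1", "CD2"),
    ILE = c("CB", "CG1", "CG2", "CD1"),
    MET = c("CB", "CG", "SD", "CE"),
    PRO = c("CB", "CG", "CD"),
    PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
    TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
            "CH2"),
    ASP = c("CB", "CG", "OD1", "OD2"),
    GLU = c("CB", "CG", "CD", "OE1", "OE2"),
    ASN = c("CB", "CG", "OD1", "ND2"),
    GLN = c("CB", "CG", "CD", "OE1", "NE2"),
    HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    LYS = c("CB", "CG", "CD", "CE", "NZ"),
    ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    stop("unknown residue type: ", resid))
  c(bb, sc)
}
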