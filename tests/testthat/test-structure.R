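pdbLine <- function(serial, name, alt, resid, chain, resno, x, y, z, occ) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, paste0(" ", name), alt, resid, chain, resno, x, y, z,
          occ, 0)
}

test_that("PDB parsing selects chain, resolves altlocs, skips CA-less residues", {
  s <- generateToyStructure(30, "HELIX")
  tmp <- tempfile(fileext = ".pdb")
  writeStructure(s, tmp)
  back <- readStructure(tmp)
  expect_equal(nrow(coords(back)), 30)
  # fixed-width round trip preserves coordinates to 1e-3 A
  expect_equal(unname(coords(back)), unname(coords(s)), tolerance = 1e-3)
  # a residue represented only by backbone N is skipped with a warning
  noca <- c(pdbLine(1, "CA", " ", "ALA", "A", 1, 0, 0, 0, 1),
            pdbLine(2, "N", " ", "ALA", "A", 2, 3.8, 0, 0, 1),
            pdbLine(3, "CA", " ", "ALA", "A", 3, 7.6, 1, 0, 1),
            "END")
  writeLines(noca, tmp)
  expect_warning(s2 <- readStructure(tmp), "lack a CA")
  expect_equal(nrow(coords(s2)), 2)
  # alternate locations resolve to the highest occupancy
  alt <- c(pdbLine(1, "CA", "A", "ALA", "A", 1, 0, 0, 0, 0.3),
           pdbLine(2, "CA", "B", "ALA", "A", 1, 9, 9, 9, 0.7),
           pdbLine(3, "CA", " ", "ALA", "A", 2, 3.8, 0, 0, 1),
           pdbLine(4, "CA", " ", "ALA", "A", 3, 7.6, 1, 0, 1),
           "END")
  writeLines(alt, tmp)
  s3 <- readStructure(tmp)
  expect_equal(unname(coords(s3)[1, ]), c(9, 9, 9))
  # absent chain errors
  expect_error(readStructure(tmp, chain = "Z"), "chain Z")
})

test_that("two-particle Hessian matches the closed form", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 2.5))
  gamma <- 1.7
  H <- buildHessian(xyz, cutoff = 15, gamma = gamma)
  u <- c(0, 0, 1)
  blk <- gamma * tcrossprod(u)
  expect_equal(H, rbind(cbind(blk, -blk), cbind(-blk, blk)),
               ignore_attr = TRUE)
  ev <- eigen(H, symmetric = TRUE)$values
  expect_equal(max(ev), 2 * gamma, tolerance = 1e-12)
  expect_equal(sort(abs(ev))[1:5], rep(0, 5), tolerance = 1e-12)
})

test_that("analytic Hessian agrees with a numerical second-derivative oracle", {
  set.seed(21)
  xyz <- coords(generateToyStructure(6, "HELIX")) + rnorm(18, sd = 0.2)
  H <- buildHessian(xyz, cutoff = 8, gamma = 1)
  Hnum <- numericalHessian(xyz, cutoff = 8, gamma = 1)
  expect_equal(H, Hnum, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("Hessians are symmetric positive semidefinite with 6 zero modes", {
  for (g in c("HELIX", "EXTENDED", "PALINDROME")) {
    s <- generateToyStructure(15, g)
    H <- buildHessian(s)
    expect_equal(H, t(H))
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-8))
    expect_equal(nZeroModes(enmModes(s)), 6)
  }
})

test_that("disconnected contact graphs are rejected with component counts", {
  far <- rbind(coords(generateToyStructure(5, "HELIX")),
               coords(generateToyStructure(5, "HELIX")) + 500)
  expect_error(buildHessian(far, cutoff = 15), "2 components")
})

test_that("eigenvalues agree with an independent dense solver to 1e-8", {
  s <- generateToyStructure(25, "HELIX")
  H <- buildHessian(s)
  m <- enmModes(s)
  # singular values of a symmetric PSD matrix equal its eigenvalues and are
  # computed through a different LAPACK factorization
  sv <- sort(svd(H)$d)
  scale <- max(sv)
  expect_lt(max(abs(modeValues(m) - sv)) / scale, 1e-8)
  # cross-check against the bio3d anisotropic network model
  tmp <- tempfile(fileext = ".pdb")
  writeStructure(s, tmp)
  s2 <- readStructure(tmp)
  nm <- bio3d::nma(bio3d::read.pdb(tmp, verbose = FALSE), ff = "anm",
                   cutoff = 15, mass = FALSE, temp = NULL)
  m2 <- enmModes(s2)
  expect_equal(modeValues(m2)[7:30], nm$L[7:30], tolerance = 1e-5)
  f <- rmsf(modeRMSF(m2, 7:9))
  f_bio3d <- bio3d::fluct.nma(nm, mode.inds = 7:9)
  expect_equal(3 * f^2, f_bio3d, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("mode RMSF matches direct evaluation and respects symmetry", {
  s <- generateToyStructure(12, "PALINDROME")
  m <- enmModes(s)
  f <- modeRMSF(m, 7:9)
  expect_equal(rmsf(f), bruteRMSF(m, 7:9), tolerance = 1e-8)
  # palindromic chain: mirror-equal fluctuations
  expect_equal(rmsf(f), rev(rmsf(f)), tolerance = 1e-6)
  # other ranges work and rigid modes are refused
  expect_silent(modeRMSF(m, 7:12))
  expect_error(modeRMSF(m, 5:9), "rigid-body")
  expect_error(modeRMSF(m, 30:40), "spectrum")
})

test_that("fluctuations are invariant under rigid motion of the input", {
  s <- generateToyStructure(10, "HELIX")
  f1 <- rmsf(modeRMSF(enmModes(s)))
  theta <- 0.83
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0), c(0, 0, 1))
  xyz2 <- coords(s) %*% t(R) + matrix(c(5, -3, 11), 10, 3, byrow = TRUE)
  f2 <- rmsf(modeRMSF(enmModes(xyz2)))
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("log2 flexibility ratios behave as exact elementwise log-ratios", {
  s <- generateToyStructure(10, "HELIX")
  f <- modeRMSF(enmModes(s))
  # identical profiles: all zeros
  expect_true(all(log2FlexRatio(f, f)$log2_ratio == 0))
  # doubling the profile: all +1 (up to the epsilon guard)
  f2 <- new("FlexProfile", rmsf = 2 * rmsf(f), resno = residueNumbers(f),
            modes = f@modes)
  expect_equal(log2FlexRatio(f2, f)$log2_ratio, rep(1, 10),
               tolerance = 1e-6)
  # random positive profiles match the direct formula, and swapping
  # mutant/wild type negates the profile
  set.seed(3)
  a <- new("FlexProfile", rmsf = runif(10, 0.1, 2), resno = 1:10,
           modes = 7:9)
  b <- new("FlexProfile", rmsf = runif(10, 0.1, 2), resno = 1:10,
           modes = 7:9)
  eps <- 1e-9
  expect_equal(log2FlexRatio(a, b, eps)$log2_ratio,
               log2((a@rmsf + eps) / (b@rmsf + eps)), tolerance = 1e-12)
  expect_equal(log2FlexRatio(a, b)$log2_ratio,
               -log2FlexRatio(b, a)$log2_ratio, tolerance = 1e-12)
  # partial overlap: intersection used, mismatches messaged
  bshift <- new("FlexProfile", rmsf = b@rmsf, resno = 6:15, modes = 7:9)
  expect_message(r <- log2FlexRatio(a, bshift), "dropped")
  expect_equal(r$resno, 6:10)
  none <- new("FlexProfile", rmsf = b@rmsf, resno = 11:20, modes = 7:9)
  expect_error(suppressMessages(log2FlexRatio(a, none)), "common")
})

test_that("segment summaries slice, rank and warn correctly", {
  segs <- data.frame(name = c("B-C", "F-G"), start = c(1, 6),
                     end = c(5, 10), stringsAsFactors = FALSE)
  zero <- data.frame(resno = 1:10, log2_ratio = 0)
  sm <- summarizeSegments(zero, segs)
  expect_true(all(sm$mean == 0))
  # +1 confined to one block ranks that block first
  prof <- zero; prof$log2_ratio[1:5] <- 1
  sm <- summarizeSegments(prof, segs)
  expect_equal(sm$name[1], "B-C")
  # random profile against a direct slicing oracle
  set.seed(4)
  prof$log2_ratio <- rnorm(10)
  sm <- summarizeSegments(prof, segs)
  for (i in seq_len(nrow(sm))) {
    sel <- prof$resno >= segs$start[segs$name == sm$name[i]] &
      prof$resno <= segs$end[segs$name == sm$name[i]]
    expect_equal(sm$mean[i], mean(prof$log2_ratio[sel]))
    expect_equal(sm$min[i], min(prof$log2_ratio[sel]))
    expect_equal(sm$max[i], max(prof$log2_ratio[sel]))
  }
  # out-of-range block excluded with a warning
  segs2 <- rbind(segs, data.frame(name = "H", start = 90, end = 99))
  expect_warning(sm2 <- summarizeSegments(prof, segs2), "excluded")
  expect_equal(nrow(sm2), 2)
  expect_error(suppressWarnings(summarizeSegments(prof, segs2[3, ])))
  segs$name[2] <- "B-C"
  expect_error(summarizeSegments(prof, segs), "unique")
})

test_that("superposition is optimal and agrees with bio3d's Kabsch fit", {
  s <- generateToyStructure(8, "HELIX")
  xyz <- coords(s)
  theta <- 1.1
  R <- rbind(c(cos(theta), 0, sin(theta)), c(0, 1, 0),
             c(-sin(theta), 0, cos(theta)))
  rot <- xyz %*% t(R) + matrix(c(1, 2, 3), 8, 3, byrow = TRUE)
  fit <- superposeEnsemble(list(rot), xyz)
  expect_lt(fit$rmsd[1], 1e-8)
  # fit RMSD never exceeds the unfitted RMSD
  set.seed(6)
  ens <- generateEnsemble(s, values = c(2, 0.5), n = 20, seed = 6)
  jig <- lapply(ens, function(m) m %*% t(R) + 4)
  fit2 <- superposeEnsemble(jig, xyz)
  unfitted <- vapply(jig, function(m) sqrt(mean(rowSums((m - xyz)^2))),
                     numeric(1))
  expect_true(all(fit2$rmsd <= unfitted + 1e-12))
  # independent Kabsch implementation
  ref_fit <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(xyz)),
                   matrix(as.vector(t(jig[[3]])), nrow = 1)))
  expect_equal(fit2$fitted[[3]],
               matrix(ref_fit, ncol = 3, byrow = TRUE), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(superposeEnsemble(list(xyz[1:2, ]), xyz[1:2, ]), "3 atoms")
})

test_that("ensemble PCA recovers planted covariance structure", {
  s <- generateToyStructure(10, "HELIX")
  # single displacement direction: exactly one nonzero variance
  ens1 <- generateEnsemble(s, values = 2, n = 50, seed = 1)
  p1 <- ensemblePCA(ens1)
  expect_gt(pcVariances(p1)[1], 0)
  expect_lt(pcVariances(p1)[2], 1e-12)
  # identical members: all variances zero
  same <- replicate(5, coords(s), simplify = FALSE)
  expect_true(all(pcVariances(ensemblePCA(same)) < 1e-12))
  # known 2-component covariance: top-2 variances within 10%
  ens2 <- generateEnsemble(s, values = c(4, 1), n = 500, seed = 11)
  p2 <- ensemblePCA(ens2)
  expect_equal(pcVariances(p2)[1:2], c(4, 1), tolerance = 0.1)
  expect_error(ensemblePCA(ens2[1:2]), "3 ensemble members")
})

test_that("principal component distances follow the Euclidean formula", {
  expect_equal(pcDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pcDistance(c(1, 2, 3), c(4, 6, 3)), 5)
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(pcDistance(a, b), sqrt(sum((a - b)^2)))
  }
  s <- generateToyStructure(10, "HELIX")
  pA <- ensemblePCA(generateEnsemble(s, c(4, 1, 0.25), n = 200, seed = 1))
  expect_equal(pcDistance(pcSummary(pA), pcSummary(pA)), 0)
  expect_length(pcSummary(pA, "meanProjection"), 3)
})

test_that("residue substitution relabels and prunes to shared atoms", {
  # a PHE residue reduced to a LEU keeps the shared ring-base atoms only
  atoms <- data.frame(
    chain = "A",
    resno = rep(1:2, c(4, 11)),
    resid = rep(c("ALA", "PHE"), c(4, 11)),
    elety = c("N", "CA", "C", "O",
              "N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
              "CZ"),
    stringsAsFactors = FALSE)
  xyz <- matrix(rnorm(45), ncol = 3)
  s <- new("StructureModel", atoms = atoms, xyz = xyz,
           granularity = "HEAVY_ATOM")
  mut <- substituteAndPrune(s, 2, "LEU")
  kept <- mut@atoms[mut@atoms$resno == 2, ]
  expect_setequal(kept$elety, c("N", "CA", "C", "O", "CB", "CG", "CD1",
                                "CD2"))
  expect_true(all(kept$resid == "LEU"))
  # CA-only models are relabelled without coordinate change
  ca <- generateToyStructure(5, "HELIX")
  mut2 <- substituteAndPrune(ca, 3, "GLY")
  expect_equal(coords(mut2), coords(ca))
  expect_error(substituteAndPrune(ca, 99, "GLY"), "not in structure")
})
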