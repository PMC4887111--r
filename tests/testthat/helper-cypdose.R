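# Independent oracles and small constructors shared across tests.

# numerical Hessian of the elastic network energy
# E = sum_contacts gamma/2 (|r_ij| - d0_ij)^2, central differences at the
# equilibrium geometry; independent of the analytic block construction
numericalHessian <- function(xyz, cutoff = 15, gamma = 1, h = 1e-5) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  d0 <- as.matrix(dist(xyz))
  contact <- d0 > 0 & d0 <= cutoff
  energy <- function(flat) {
    m <- matrix(flat, ncol = 3, byrow = TRUE)
    dd <- as.matrix(dist(m))
    sum(gamma / 2 * (dd[contact] - d0[contact])^2) / 2  # each pair twice
  }
  x0 <- as.vector(t(xyz))
  n3 <- 3 * n
  H <- matrix(0, n3, n3)
  for (i in seq_len(n3)) {
    for (j in i:n3) {
      ei <- ej <- rep(0, n3); ei[i] <- h; ej[j] <- h
      v <- (energy(x0 + ei + ej) - energy(x0 + ei - ej) -
              energy(x0 - ei + ej) + energy(x0 - ei - ej)) / (4 * h^2)
      H[i, j] <- v; H[j, i] <- v
    }
  }
  H
}

# direct scalar-loop evaluation of the mode-range RMSF formula
bruteRMSF <- function(modes, mode_range) {
  vals <- modeValues(modes)
  vecs <- modeVectors(modes)
  n <- length(residueNumbers(modes))
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in mode_range) {
      sq <- 0
      for (c in 0:2) sq <- sq + vecs[3 * (i - 1) + 1 + c, k]^2
      acc <- acc + sq / vals[k]
    }
    out[i] <- sqrt(acc / length(mode_range))
  }
  out
}

# closed-form pooled two-sample t
pooledT <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# spreadsheet-style three-step estradiol normalization oracle
handEstradiol <- function(wells) {
  bg <- mean(wells$FL_RLU[wells$role == "NO_CELL_BACKGROUND"])
  ev <- mean(wells$FL_RLU[wells$role == "EMPTY_VECTOR"] - bg)
  test <- wells[wells$role %in% c("WILD_TYPE", "VARIANT"), ]
  net <- pmax(test$FL_RLU - bg - ev, 0)
  wt <- mean(net[test$role == "WILD_TYPE"])
  pct <- 100 * net / wt
  tapply(pct, test$sample_id, mean)
}

# minimal single-variant catalog builder for property tests
toyCatalog <- function(ret, ster, zygosity = "HOMOZYGOUS",
                       partner = NULL, phenotype = "PCG",
                       partner_ret = NA, partner_ster = NA,
                       partner_null = FALSE, partner_assayed = NA) {
  if (is.null(partner))
    partner <- switch(zygosity, HOMOZYGOUS = "VAR1",
                      HETEROZYGOUS = "WILD_TYPE", NA)
  v <- data.frame(variant_id = "VAR1", position = 10L, wt_aa = "A",
                  mut_aa = "G", disease_category = "BOTH", in_panel = TRUE,
                  is_null_allele = FALSE, assayed = TRUE,
                  retinol_pct = ret, retinol_sem = 0, steroid_pct = ster,
                  steroid_sem = 0, stability_class = "STABLE",
                  stringsAsFactors = FALSE)
  if (!is.na(partner) && !partner %in% c("WILD_TYPE", "VAR1")) {
    v <- rbind(v, data.frame(
      variant_id = partner, position = 20L, wt_aa = "C", mut_aa = "S",
      disease_category = NA, in_panel = FALSE,
      is_null_allele = partner_null,
      assayed = !partner_null && !is.na(partner_ret),
      retinol_pct = if (partner_null) 0 else partner_ret,
      retinol_sem = 0,
      steroid_pct = if (partner_null) 0 else partner_ster,
      steroid_sem = 0, stability_class = NA, stringsAsFactors = FALSE))
  }
  g <- data.frame(variant_id = "VAR1", zygosity = zygosity,
                  partner = partner, partner_assayed = partner_assayed,
                  reported_phenotype = phenotype,
                  printed_retinol = NA_real_, printed_steroid = NA_real_,
                  printed_verdict = NA_character_, verdict_override = FALSE,
                  note = NA_character_, stringsAsFactors = FALSE)
  new("VariantCatalog", variants = v, genotypes = g)
}

emptyCatalog <- function() {
  v <- utils::read.delim(cypdoseFixture(), stringsAsFactors = FALSE)[0, ]
  new("VariantCatalog",
      variants = v[VARIANT_COLS_test()],
      genotypes = v[GENOTYPE_COLS_test()])
}

VARIANT_COLS_test <- function()
  c("variant_id", "position", "wt_aa", "mut_aa", "disease_category",
    "in_panel", "is_null_allele", "assayed",
    "retinol_pct", "retinol_sem", "steroid_pct", "steroid_sem",
    "stability_class")

GENOTYPE_COLS_test <- function()
  c("variant_id", "zygosity", "partner", "partner_assayed",
    "reported_phenotype", "printed_retinol", "printed_steroid",
    "printed_verdict", "verdict_override", "note")
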