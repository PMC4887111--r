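#' @import methods
NULL

VARIANT_COLS <- c("variant_id", "position", "wt_aa", "mut_aa", "disease_category",
                  "in_panel", "is_null_allele", "assayed",
                  "retinol_pct", "retinol_sem", "steroid_pct", "steroid_sem",
                  "stability_class")

GENOTYPE_COLS <- c("variant_id", "zygosity", "partner", "partner_assayed",
                   "reported_phenotype", "printed_retinol", "printed_steroid",
                   "printed_verdict", "verdict_override", "note")

DISEASE_CATEGORIES <- c("PCG_ONLY", "POAG_ONLY", "BOTH")
ZYGOSITIES <- c("HOMOZYGOUS", "HETEROZYGOUS", "COMPOUND_HET", "NOT_AVAILABLE", "NONE")
PHENOTYPES <- c("PCG", "POAG", "JOAG")
VERDICTS <- c("YES", "NO", "INCONCLUSIVE", "PREDICTED")
WELL_ROLES <- c("NO_CELL_BACKGROUND", "NEGATIVE_CONTROL", "EMPTY_VECTOR",
                "WILD_TYPE", "VARIANT")

#' VariantCatalog: CYP1B1 variants, allele activities and reported genotypes
#'
#' Container for the variant/allele/genotype catalog the pipeline operates on.
#' The \code{variants} slot holds one row per allele (missense variants assayed
#' in vitro, null frameshift/deletion alleles with activity inferred as 0, and
#' unassayed missense partner alleles) with percent-of-wild-type retinol and
#' 17beta-estradiol metabolizing activities and their SEMs. The
#' \code{genotypes} slot holds one row per reported genotype (zygosity,
#' partner allele, reported glaucoma phenotype) together with the published
#' genotype-level inferred activities and verdict tokens used for
#' agreement accounting.
#'
#' @slot variants data.frame, one row per allele.
#' @slot genotypes data.frame, one row per reported genotype.
#'
#' @seealso [loadCatalog()], [countCategories()], [inferCatalogActivities()]
#' @export
setClass("VariantCatalog",
  slots = c(variants = "data.frame", genotypes = "data.frame"),
  validity = function(object) {
    v <- object@variants
    g <- object@genotypes
    msg <- character()
    if (!all(VARIANT_COLS %in% names(v)))
      msg <- c(msg, paste("missing variant columns:",
                          paste(setdiff(VARIANT_COLS, names(v)), collapse = ", ")))
    if (!all(GENOTYPE_COLS %in% names(g)))
      msg <- c(msg, paste("missing genotype columns:",
                          paste(setdiff(GENOTYPE_COLS, names(g)), collapse = ", ")))
    if (length(msg)) return(msg)
    if (anyDuplicated(v$variant_id))
      msg <- c(msg, "duplicated variant_id in variants table")
    pct <- unlist(v[, c("retinol_pct", "retinol_sem", "steroid_pct", "steroid_sem")])
    if (any(pct < 0, na.rm = TRUE))
      msg <- c(msg, "negative activity percentage or SEM")
    nul <- v$is_null_allele %in% TRUE
    if (any(nul & (v$retinol_pct != 0 | v$steroid_pct != 0), na.rm = TRUE))
      msg <- c(msg, "null alleles must carry 0% activities")
    bad <- !is.na(v$disease_category) & !v$disease_category %in% DISEASE_CATEGORIES
    if (any(bad)) msg <- c(msg, "unknown disease_category")
    if (nrow(g)) {
      if (!all(g$zygosity %in% setdiff(ZYGOSITIES, "NONE")))
        msg <- c(msg, "unknown zygosity token in genotypes")
      if (!all(is.na(g$reported_phenotype) | g$reported_phenotype %in% PHENOTYPES))
        msg <- c(msg, "unknown reported phenotype")
      het <- g$zygosity == "HETEROZYGOUS"
      if (any(het & g$partner != "WILD_TYPE", na.rm = TRUE))
        msg <- c(msg, "heterozygous genotypes must have a WILD_TYPE partner")
      ch <- g$zygosity == "COMPOUND_HET"
      if (any(ch & g$partner == "WILD_TYPE", na.rm = TRUE))
        msg <- c(msg, "compound heterozygotes cannot have a WILD_TYPE partner")
      known <- c(v$variant_id, "WILD_TYPE")
      if (!all(is.na(g$partner) | g$partner %in% known))
        msg <- c(msg, "genotype references an unknown partner allele")
      if (!all(g$variant_id %in% v$variant_id))
        msg <- c(msg, "genotype references an unknown variant")
    }
    if (length(msg)) msg else TRUE
  }
)

#' StructureModel: coarse protein coordinate model
#'
#' One site per row of \code{atoms}; for CA_ONLY granularity a site is a
#' residue represented by its alpha carbon, for HEAVY_ATOM every non-hydrogen
#' atom is a site. Coordinates are in Angstrom.
#'
#' @slot atoms data.frame with columns chain, resno, resid, elety.
#' @slot xyz numeric matrix (n sites x 3), Angstrom.
#' @slot granularity "CA_ONLY" or "HEAVY_ATOM".
#' @export
setClass("StructureModel",
  slots = c(atoms = "data.frame", xyz = "matrix", granularity = "character"),
  validity = function(object) {
    msg <- character()
    if (!all(c("chain", "resno", "resid", "elety") %in% names(object@atoms)))
      msg <- c(msg, "atoms must have chain, resno, resid, elety columns")
    if (ncol(object@xyz) != 3) msg <- c(msg, "xyz must have 3 columns")
    if (nrow(object@xyz) != nrow(object@atoms))
      msg <- c(msg, "xyz and atoms row counts differ")
    if (!all(is.finite(object@xyz))) msg <- c(msg, "non-finite coordinates")
    if (!object@granularity %in% c("CA_ONLY", "HEAVY_ATOM"))
      msg <- c(msg, "granularity must be CA_ONLY or HEAVY_ATOM")
    if (object@granularity == "CA_ONLY" &&
        anyDuplicated(paste(object@atoms$chain, object@atoms$resno)))
      msg <- c(msg, "duplicate residue numbers within a chain")
    if (length(msg)) msg else TRUE
  }
)

#' ModeSet: eigen-decomposition of an elastic network Hessian
#'
#' Eigenvalues are stored in ascending order; for a connected structure the
#' first six are numerically zero (rigid-body translations and rotations) and
#' mode numbering follows the convention that mode 7 is the first internal
#' mode.
#'
#' @slot values numeric, ascending eigenvalues (arbitrary spring units).
#' @slot vectors 3N x 3N matrix of orthonormal eigenvectors (columns).
#' @slot resno residue numbers of the underlying sites.
#' @export
setClass("ModeSet",
  slots = c(values = "numeric", vectors = "matrix", resno = "integer"),
  validity = function(object) {
    msg <- character()
    n3 <- length(object@values)
    if (!identical(dim(object@vectors), c(n3, n3)))
      msg <- c(msg, "eigenvector matrix must be square, one column per mode")
    if (is.unsorted(object@values, strictly = FALSE))
      msg <- c(msg, "eigenvalues must be ascending")
    if (n3 != 3L * length(object@resno))
      msg <- c(msg, "dimension must be 3 x number of residues")
    dev <- max(abs(crossprod(object@vectors) - diag(n3)))
    if (dev > 1e-8)
      msg <- c(msg, sprintf("eigenvectors not orthonormal (max deviation %.2e)", dev))
    if (length(msg)) msg else TRUE
  }
)

#' FlexProfile: per-residue fluctuation amplitudes from selected normal modes
#'
#' @slot rmsf numeric, non-negative per-residue RMSF (arbitrary units).
#' @slot resno residue numbers.
#' @slot modes integer, the (1-based) mode indices averaged.
#' @export
setClass("FlexProfile",
  slots = c(rmsf = "numeric", resno = "integer", modes = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@rmsf) != length(object@resno))
      msg <- c(msg, "rmsf and resno lengths differ")
    if (any(object@rmsf < 0)) msg <- c(msg, "negative fluctuation")
    if (length(msg)) msg else TRUE
  }
)

#' PCAResult: principal components of a structural ensemble
#'
#' @slot variances numeric, non-negative component variances, descending.
#' @slot projections matrix, per-member centred projections (members x kept PCs).
#' @export
setClass("PCAResult",
  slots = c(variances = "numeric", projections = "matrix"),
  validity = function(object) {
    msg <- character()
    if (any(object@variances < -1e-10)) msg <- c(msg, "negative variance")
    if (is.unsorted(rev(object@variances))) msg <- c(msg, "variances must be descending")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn VariantCatalog-class compact display
#' @param object a \code{VariantCatalog}
#' @export
setMethod("show", "VariantCatalog", function(object) {
  v <- object@variants
  cat("VariantCatalog with", sum(v$in_panel %in% TRUE), "panel variants,",
      nrow(v), "alleles,", nrow(object@genotypes), "reported genotypes\n")
  cc <- countCategories(object)
  cat(sprintf("  categories: %d PCG-only, %d POAG-only, %d both\n",
              cc[["n_pcg_only"]], cc[["n_poag_only"]], cc[["n_both"]]))
})

#' @describeIn StructureModel-class compact display
#' @param object a \code{StructureModel}
#' @export
setMethod("show", "StructureModel", function(object) {
  cat("StructureModel:", nrow(object@atoms), "sites (",
      object@granularity, "),", length(unique(object@atoms$resno)), "residues\n")
})

#' @describeIn ModeSet-class compact display
#' @param object a \code{ModeSet}
#' @export
setMethod("show", "ModeSet", function(object) {
  cat("ModeSet:", length(object@values), "modes over",
      length(object@resno), "residues;",
      nZeroModes(object), "rigid-body modes\n")
})

#' @describeIn FlexProfile-class compact display
#' @param object a \code{FlexProfile}
#' @export
setMethod("show", "FlexProfile", function(object) {
  cat("FlexProfile over modes", paste(range(object@modes), collapse = "-"),
      "for", length(object@rmsf), "residues\n")
})

#' @describeIn PCAResult-class compact display
#' @param object a \code{PCAResult}
#' @export
setMethod("show", "PCAResult", function(object) {
  cat("PCAResult:", nrow(object@projections), "members;",
      "top variances:", paste(signif(utils::head(object@variances, 3), 4),
                              collapse = ", "), "\n")
})

#' Accessors for catalog and structure containers
#'
#' \code{variants()} and \code{genotypes()} return the allele and genotype
#' tables of a \code{VariantCatalog}; \code{coords()} the coordinate matrix of
#' a \code{StructureModel}; \code{residueNumbers()} the residue numbering of a
#' structure-derived object; \code{rmsf()} the per-residue fluctuation of a
#' \code{FlexProfile}; \code{modeValues()}/\code{modeVectors()} the spectrum of
#' a \code{ModeSet}; \code{pcVariances()}/\code{pcProjections()} the components
#' of a \code{PCAResult}.
#'
#' @param x the container object.
#' @return The corresponding slot, copied.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setMethod("variants", "VariantCatalog", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setMethod("genotypes", "VariantCatalog", function(x) x@genotypes)

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "StructureModel", function(x) x@xyz)

#' @rdname accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))
#' @rdname accessors
#' @export
setMethod("residueNumbers", "StructureModel", function(x) unique(x@atoms$resno))
#' @rdname accessors
#' @export
setMethod("residueNumbers", "ModeSet", function(x) x@resno)
#' @rdname accessors
#' @export
setMethod("residueNumbers", "FlexProfile", function(x) x@resno)

#' @rdname accessors
#' @export
setGeneric("rmsf", function(x) standardGeneric("rmsf"))
#' @rdname accessors
#' @export
setMethod("rmsf", "FlexProfile", function(x) x@rmsf)

#' @rdname accessors
#' @export
setGeneric("modeValues", function(x) standardGeneric("modeValues"))
#' @rdname accessors
#' @export
setMethod("modeValues", "ModeSet", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("modeVectors", function(x) standardGeneric("modeVectors"))
#' @rdname accessors
#' @export
setMethod("modeVectors", "ModeSet", function(x) x@vectors)

#' @rdname accessors
#' @export
setGeneric("pcVariances", function(x) standardGeneric("pcVariances"))
#' @rdname accessors
#' @export
setMethod("pcVariances", "PCAResult", function(x) x@variances)

#' @rdname accessors
#' @export
setGeneric("pcProjections", function(x) standardGeneric("pcProjections"))
#' @rdname accessors
#' @export
setMethod("pcProjections", "PCAResult", function(x) x@projections)

#' Number of numerically zero (rigid-body) modes
#'
#' @param x a \code{ModeSet}
#' @param tol eigenvalues with absolute value below \code{tol} times the
#'   largest eigenvalue are counted as rigid-body modes.
#' @return integer count; 6 for any connected three-dimensional structure.
#' @export
nZeroModes <- function(x, tol = 1e-8) {
  stopifnot(is(x, "ModeSet"))
  scale <- max(abs(x@values))
  if (scale == 0) return(length(x@values))
  sum(abs(x@values) < tol * scale)
}
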