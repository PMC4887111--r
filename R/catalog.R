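#' Load a variant/allele/genotype catalog from TSV
#'
#' Reads the tab-separated catalog format documented in
#' \code{system.file("extdata", "catalog_schema.md", package = "cypdose")}:
#' one row per (variant, reported genotype) pair, with allele-level activity
#' columns repeated on each genotype row, plus optional allele-only rows
#' (zygosity \code{NONE}) for partner alleles that carry no genotype of their
#' own (null frameshift/deletion alleles, unassayed missense partners).
#'
#' The bundled fixture \code{cyp1b1_table1.tsv} transcribes the published
#' 23-variant CYP1B1 panel: percent-of-wild-type retinol and
#' 17beta-estradiol activities with SEMs, reported genotypes and phenotypes,
#' published genotype-level inferred activities and verdicts, and published
#' protein stability labels.
#'
#' @param path path to a TSV file; defaults to the bundled CYP1B1 panel.
#' @return a [VariantCatalog-class] object.
#' @examples
#' cat23 <- loadCatalog()
#' countCategories(cat23)
#' @export
loadCatalog <- function(path = cypdoseFixture()) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  required <- c("variant_id", "disease_category", "is_null_allele",
                "retinol_pct", "retinol_sem", "steroid_pct", "steroid_sem",
                "zygosity", "partner", "reported_phenotype")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("catalog schema error: missing column(s) ", paste(miss, collapse = ", "))
  for (col in c("in_panel", "assayed", "partner_assayed", "stability_class",
                "printed_retinol", "printed_steroid", "printed_verdict",
                "verdict_override", "note", "position", "wt_aa", "mut_aa")) {
    if (!col %in% names(tab)) tab[[col]] <- NA
  }
  num <- c("retinol_pct", "retinol_sem", "steroid_pct", "steroid_sem",
           "printed_retinol", "printed_steroid", "position")
  for (col in num) tab[[col]] <- as.numeric(tab[[col]])
  pct <- unlist(tab[c("retinol_pct", "retinol_sem", "steroid_pct", "steroid_sem")])
  if (any(pct < 0, na.rm = TRUE))
    stop("catalog validation error: negative activity percentage or SEM")
  badz <- setdiff(unique(tab$zygosity), ZYGOSITIES)
  if (length(badz))
    stop("catalog parse error: unknown zygosity token(s) ",
         paste(badz, collapse = ", "))

  first <- !duplicated(tab$variant_id)
  variants <- tab[first, VARIANT_COLS]
  rownames(variants) <- NULL
  geno <- tab[tab$zygosity != "NONE", GENOTYPE_COLS, drop = FALSE]
  rownames(geno) <- NULL
  new("VariantCatalog", variants = variants, genotypes = geno)
}

#' Write a catalog back to the one-row-per-genotype TSV format
#'
#' Inverse of [loadCatalog()]: genotype rows are written with their variant's
#' allele columns attached, and alleles without any genotype record are
#' appended as allele-only rows (zygosity \code{NONE}).
#'
#' @param catalog a [VariantCatalog-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "VariantCatalog"))
  v <- catalog@variants
  g <- catalog@genotypes
  rows <- merge(g, v, by = "variant_id", sort = FALSE)
  orphan <- v[!v$variant_id %in% g$variant_id, , drop = FALSE]
  if (nrow(orphan)) {
    for (col in setdiff(GENOTYPE_COLS, "variant_id")) orphan[[col]] <- NA
    orphan$zygosity <- "NONE"
    rows <- rbind(rows[union(VARIANT_COLS, GENOTYPE_COLS)],
                  orphan[union(VARIANT_COLS, GENOTYPE_COLS)])
  } else {
    rows <- rows[union(VARIANT_COLS, GENOTYPE_COLS)]
  }
  cols <- c(VARIANT_COLS[1:13], setdiff(GENOTYPE_COLS, "variant_id"))
  utils::write.table(rows[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Path to the bundled CYP1B1 variant panel fixture
#'
#' @return file path of the TSV shipped with the package.
#' @export
cypdoseFixture <- function() {
  system.file("extdata", "cyp1b1_table1.tsv", package = "cypdose",
              mustWork = TRUE)
}

#' Count panel variants per disease category
#'
#' Panel variants are partitioned by where they have been reported:
#' exclusively in primary congenital glaucoma (PCG), exclusively in
#' (juvenile) open-angle glaucoma (POAG/JOAG), or in both.
#'
#' @param catalog a [VariantCatalog-class].
#' @return named integer vector \code{(n_pcg_only, n_poag_only, n_both)};
#'   the three counts always sum to the panel size.
#' @export
countCategories <- function(catalog) {
  stopifnot(is(catalog, "VariantCatalog"))
  v <- catalog@variants
  v <- v[v$in_panel %in% TRUE, , drop = FALSE]
  c(n_pcg_only  = sum(v$disease_category == "PCG_ONLY"),
    n_poag_only = sum(v$disease_category == "POAG_ONLY"),
    n_both      = sum(v$disease_category == "BOTH"))
}

#' Count variants labelled unstable in the bundled turnover annotations
#'
#' The fixture carries the published stable/unstable label assigned to each
#' panel variant from cycloheximide-chase time courses, so the published count
#' is testable independently of the package's own decision rule
#' ([classifyStability()]).
#'
#' @param catalog a [VariantCatalog-class].
#' @return named integer vector \code{(n_stable, n_unstable)}.
#' @export
countStability <- function(catalog) {
  stopifnot(is(catalog, "VariantCatalog"))
  v <- catalog@variants
  v <- v[v$in_panel %in% TRUE, , drop = FALSE]
  c(n_stable   = sum(v$stability_class == "STABLE", na.rm = TRUE),
    n_unstable = sum(v$stability_class == "UNSTABLE", na.rm = TRUE))
}
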