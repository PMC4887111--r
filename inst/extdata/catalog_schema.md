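# Catalog TSV schema

Tab-separated, UTF-8, header row required. One row per (variant, reported
genotype) pair; alleles that carry no genotype record of their own (null
frameshift/deletion partner alleles, unassayed missense partners) appear as
allele-only rows with `zygosity = NONE`. Missing values are written `NA`.

Allele-level columns (repeated on every row of the same variant):

| column            | type    | meaning |
|-------------------|---------|---------|
| `variant_id`      | string  | protein-level variant label (e.g. `W57C`) or allele descriptor for non-missense alleles (e.g. `R355fsX69`) |
| `position`        | integer | residue index, 1-based protein numbering (`NA` for frameshift/deletion alleles) |
| `wt_aa`, `mut_aa` | string  | one-letter amino acid codes; must differ |
| `disease_category`| enum    | `PCG_ONLY`, `POAG_ONLY`, `BOTH` (`NA` for partner-only alleles) |
| `in_panel`        | logical | TRUE for the assayed study panel |
| `is_null_allele`  | logical | frameshift/deletion allele; implies 0% activities |
| `assayed`         | logical | allele activity measured in vitro (FALSE for null and unassayed partner alleles) |
| `retinol_pct`, `retinol_sem` | numeric >= 0 | retinol metabolizing activity, percent of wild type, with SEM |
| `steroid_pct`, `steroid_sem` | numeric >= 0 | 17beta-estradiol metabolizing activity, percent of wild type, with SEM |
| `stability_class` | enum    | published cycloheximide-chase label: `STABLE` / `UNSTABLE` |

Genotype-level columns (`NA` on allele-only rows):

| column              | type    | meaning |
|---------------------|---------|---------|
| `zygosity`          | enum    | `HOMOZYGOUS`, `HETEROZYGOUS`, `COMPOUND_HET`, `NOT_AVAILABLE`, or `NONE` for allele-only rows |
| `partner`           | string  | `WILD_TYPE`, another `variant_id`, or `NA` |
| `partner_assayed`   | logical | whether the partner allele's activity was measured |
| `reported_phenotype`| enum    | `PCG`, `POAG`, `JOAG` |
| `printed_retinol`, `printed_steroid` | integer | published genotype-level inferred activities (percent of wild type) used for agreement accounting |
| `printed_verdict`   | enum    | published concordance token: `YES`, `NO`, `INCONCLUSIVE`, `PREDICTED`; `NA` where no verdict was furnished |
| `verdict_override`  | logical | TRUE where the published verdict contradicts the printed numbers under any fixed rule set; such rows are excluded from agreement scoring and surfaced by `runPipeline()` |
| `note`              | string  | free-text qualifier |
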