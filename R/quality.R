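#' Substitutions between a cDNA and its genomic exons
#'
#' Counts aligned columns where both residues are informative (non-gap,
#' non-N) as comparable sites, and mismatches among them as substitutions.
#' Unaligned inputs are first aligned with [global_pairwise_align()].
#'
#' @param cdna,genomic Nucleotide strings; pre-aligned (equal length, gaps
#'   allowed) when `aligned = TRUE`.
#' @param aligned Set `TRUE` when the inputs are already aligned.
#' @param ... Scores passed to [global_pairwise_align()].
#' @return One-row tibble: `substitutions`, `sites`.
#' @export
pair_substitutions <- function(cdna, genomic, aligned = FALSE, ...) {
  if (!aligned) {
    al <- global_pairwise_align(gsub("-", "", cdna), gsub("-", "", genomic),
                                ...)
    cdna <- al$a; genomic <- al$b
  }
  a <- strsplit(toupper(cdna), "")[[1]]
  b <- strsplit(toupper(genomic), "")[[1]]
  if (length(a) != length(b)) abort("aligned sequences of unequal length")
  use <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
  if (!any(use)) abort("no comparable sites")
  tibble(substitutions = sum(a[use] != b[use]), sites = sum(use))
}

#' Genome-quality summary from per-gene substitution counts
#'
#' Sums per-gene cDNA-vs-genomic substitution fractions into a per-species
#' total, a substitution rate (percent, two decimals) and an identity
#' (percent, one decimal) — the layout of assembly-quality report tables.
#' Genes missing for a species are simply omitted from the sums.
#'
#' @param per_gene Tibble with columns `gene`, `substitutions`, `sites`,
#'   and optionally `species` (grouped when present).
#' @return Tibble: `species` (if given), `n_genes`, `total_substitutions`,
#'   `total_sites`, `rate_percent`, `identity_percent`.
#' @export
species_quality <- function(per_gene) {
  need <- c("substitutions", "sites")
  if (!all(need %in% names(per_gene)))
    abort("per_gene needs columns substitutions, sites")
  if (any(per_gene$substitutions > per_gene$sites))
    abort("substitutions exceed sites")
  if (nrow(per_gene) == 0) abort("need at least one gene")
  grp <- if ("species" %in% names(per_gene)) "species" else character()
  per_gene |>
    group_by(dplyr::across(dplyr::all_of(grp))) |>
    summarise(n_genes = n(),
              total_substitutions = sum(.data$substitutions),
              total_sites = sum(.data$sites),
              rate_percent =
                round_half_up(100 * total_substitutions / total_sites, 2),
              identity_percent =
                round_half_up(100 - 100 * total_substitutions / total_sites,
                              1),
              .groups = "drop")
}
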