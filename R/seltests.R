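#' Regional rate table for a gene family
#'
#' For each annotated region: varied/total site counts plus mean pairwise
#' Jukes-Cantor and (gamma-corrected) Tamura-Nei distances with bootstrap
#' standard errors, and a pooled `noncoding` row (flank5, intron1, intron2,
#' exon3, flank3 concatenated) serving as the "entire gene except coding
#' region" reference of acceleration tests.
#'
#' @param aln Full-gene nucleotide [alignment()] (>= 2 genes).
#' @param regions Region tibble (see [read_region_table()]).
#' @param region_names Regions to tabulate.
#' @param gamma_shape Gamma shape for the TN distance.
#' @param bootstrap_reps,seed Bootstrap options (see
#'   [mean_pairwise_distance()]).
#' @param include_noncoding Append the pooled noncoding row.
#' @return Tibble: `region`, `varied`, `total`, `jc`, `jc_se`, `tn`,
#'   `tn_se`, `n_pairs`. Regions with no surviving columns get `NA` values.
#' @export
region_rate_table <- function(aln, regions,
                              region_names = canonical_regions,
                              gamma_shape = Inf, bootstrap_reps = 0,
                              seed = NULL, include_noncoding = TRUE) {
  if (length(aln) < 2) abort("need at least two genes")
  todo <- region_names
  if (include_noncoding) todo <- c(todo, "noncoding")
  rows <- lapply(seq_along(todo), function(k) {
    rg <- todo[k]
    sub <- slice_region(aln, regions, rg)
    cd <- complete_deletion(sub)
    if (aln_width(cd) == 0)
      return(tibble(region = rg, varied = NA_integer_, total = 0L,
                    jc = NA_real_, jc_se = NA_real_, tn = NA_real_,
                    tn_se = NA_real_, n_pairs = NA_integer_))
    cnt <- count_sites(cd, apply_deletion = FALSE)
    sd_seed <- if (is.null(seed)) NULL else seed + k
    est_jc <- mean_pairwise_distance(cd, "jc",
                                     bootstrap_reps = bootstrap_reps,
                                     seed = sd_seed)
    est_tn <- mean_pairwise_distance(cd, "tn", gamma_shape = gamma_shape,
                                     bootstrap_reps = bootstrap_reps,
                                     seed = sd_seed)
    tibble(region = rg, varied = cnt$varied, total = cnt$total,
           jc = est_jc$value, jc_se = est_jc$se,
           tn = est_tn$value, tn_se = est_tn$se,
           n_pairs = est_jc$n_pairs)
  })
  bind_rows(rows)
}

as_counts <- function(x) {
  if (is.data.frame(x)) return(c(varied = x$varied[1], total = x$total[1]))
  if (is.numeric(x) && length(x) == 2)
    return(c(varied = x[[1]], total = x[[2]]))
  abort("counts must be a count_sites() tibble or c(varied, total)")
}

#' Fisher exact test for regional rate acceleration
#'
#' Two-sided Fisher's exact test on the 2x2 table of varied vs non-varied
#' sites in a focal region against a reference region (conventionally the
#' pooled noncoding part of the gene). Optionally reports the fold change
#' of the corresponding mean distances via [fold_ratio()].
#'
#' @param counts_focal,counts_reference [count_sites()] tibbles or
#'   `c(varied, total)` vectors.
#' @param dist_focal,dist_reference Optional named numeric vectors of mean
#'   distances (e.g. `c(jc = 0.235, tn = 0.442)`); matching names are
#'   ratioed.
#' @return One-row tibble: counts, `p_value`, and one `ratio_<name>` column
#'   per supplied distance.
#' @export
acceleration_test <- function(counts_focal, counts_reference,
                              dist_focal = NULL, dist_reference = NULL) {
  f <- as_counts(counts_focal)
  r <- as_counts(counts_reference)
  if (f[["total"]] == 0 || r[["total"]] == 0) abort("zero total sites")
  tab <- matrix(c(f[["varied"]], f[["total"]] - f[["varied"]],
                  r[["varied"]], r[["total"]] - r[["varied"]]),
                nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  out <- tibble(varied_focal = f[["varied"]], total_focal = f[["total"]],
                varied_reference = r[["varied"]],
                total_reference = r[["total"]], p_value = p)
  if (!is.null(dist_focal)) {
    shared <- intersect(names(dist_focal), names(dist_reference))
    for (nm in shared)
      out[[paste0("ratio_", nm)]] <-
        fold_ratio(dist_focal[[nm]], dist_reference[[nm]])
  }
  out
}

#' Per-group dn/ds summary
#'
#' Mean pairwise dn and ds (with bootstrap SEs) and their ratio, per named
#' group of codon alignments — the purifying-selection summary layout.
#'
#' @param groups Named list of codon-framed [alignment()]s (each >= 2
#'   sequences).
#' @param kappa,bootstrap_reps,seed As in [dnds()].
#' @return Tibble: `group`, `n_seqs`, `dn`, `dn_se`, `ds`, `ds_se`,
#'   `dnds_ratio` (two decimals; `NA` when ds is 0 or undefined).
#' @export
group_dnds_summary <- function(groups, kappa = 1, bootstrap_reps = 0,
                               seed = NULL) {
  if (is.null(names(groups))) abort("groups must be a named list")
  rows <- lapply(seq_along(groups), function(k) {
    g <- names(groups)[k]
    est <- dnds(groups[[k]], kappa = kappa, bootstrap_reps = bootstrap_reps,
                seed = if (is.null(seed)) NULL else seed + k)
    ratio <- if (!is.na(est$ds) && !is.na(est$dn) && est$ds > 0)
      round_half_up(est$dn / est$ds, 2) else NA_real_
    tibble(group = g, n_seqs = length(groups[[k]]), dn = est$dn,
           dn_se = est$dn_se, ds = est$ds, ds_se = est$ds_se,
           dnds_ratio = ratio)
  })
  bind_rows(rows)
}

#' One-sided Fisher exact test for positive selection in a codon pair
#'
#' Tests whether the nonsynonymous difference proportion exceeds the
#' synonymous one, on the 2x2 table
#' `[[round(Nd), round(N - Nd)], [round(Sd), round(S - Sd)]]` built from
#' [ng_counts()] (fractional counts rounded to the nearest integer).
#'
#' @param a,b Codon strings, or pass a precomputed [ng_counts()] tibble as
#'   `counts`.
#' @param kappa Transition/transversion site-counting weight.
#' @param counts Optional precomputed [ng_counts()] row.
#' @return P-value.
#' @export
positive_selection_test <- function(a = NULL, b = NULL, kappa = 1,
                                    counts = NULL) {
  if (is.null(counts)) counts <- ng_counts(a, b, kappa)
  tab <- matrix(c(round(counts$Nd), round(counts$N - counts$Nd),
                  round(counts$Sd), round(counts$S - counts$Sd)),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) abort("negative cell in selection table")
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Pairwise dn/ds matrix with positive-selection stars
#'
#' For every sequence pair of a codon alignment: dn, ds, their ratio
#' rounded to one decimal (`NA` where ds = 0, printed as a dash in report
#' tables), and the one-sided positive-selection P-value with a `significant`
#' flag at P < 0.05.
#'
#' @param aln Codon-framed [alignment()] (>= 2 sequences).
#' @param kappa Site-counting weight.
#' @param alpha Significance threshold for the star flag.
#' @return Long tibble: `id_a`, `id_b`, `dn`, `ds`, `dnds_ratio`,
#'   `p_value`, `significant`.
#' @export
pairwise_dnds_matrix <- function(aln, kappa = 1, alpha = 0.05) {
  if (length(aln) < 2) abort("need at least two sequences")
  aln <- complete_deletion(aln)
  ids <- names(aln)
  pairs <- utils::combn(length(ids), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    cnt <- ng_counts(unclass(aln)[[i]], unclass(aln)[[j]], kappa)
    est <- dnds_from_totals(cnt$S, cnt$N, cnt$Sd, cnt$Nd)
    ratio <- if (!is.na(est[["ds"]]) && !is.na(est[["dn"]]) &&
                 est[["ds"]] > 0)
      round_half_up(est[["dn"]] / est[["ds"]], 1) else NA_real_
    p <- positive_selection_test(counts = cnt)
    tibble(id_a = ids[i], id_b = ids[j], dn = est[["dn"]], ds = est[["ds"]],
           dnds_ratio = ratio, p_value = p, significant = p < alpha)
  })
  bind_rows(rows)
}

#' Render a pairwise dn/ds matrix in lower-triangular report form
#'
#' @param tbl Output of [pairwise_dnds_matrix()].
#' @return Character matrix with `-` for undefined ratios and `*` appended
#'   at significant pairs.
#' @export
format_dnds_matrix <- function(tbl) {
  ids <- unique(c(tbl$id_a, tbl$id_b))
  m <- matrix("", length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(tbl))) {
    val <- if (is.na(tbl$dnds_ratio[k])) "-" else
      format(tbl$dnds_ratio[k], nsmall = 1)
    if (isTRUE(tbl$significant[k])) val <- paste0(val, "*")
    m[tbl$id_b[k], tbl$id_a[k]] <- val
  }
  m
}
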