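BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

genetic_code <- function() Biostrings::GENETIC_CODE

is_stop <- function(codon) genetic_code()[codon] == "*"

is_transition <- function(from, to) {
  (from %in% PURINES) == (to %in% PURINES)
}

split_codons <- function(s) {
  v <- strsplit(s, "")[[1]]
  if (length(v) %% 3 != 0) abort("sequence length not divisible by 3")
  vapply(seq_len(length(v) / 3),
         function(k) paste(v[(3 * k - 2):(3 * k)], collapse = ""), "")
}

.ng_cache <- new.env(parent = emptyenv())

# expected synonymous-site count of one codon under the modified NG scheme:
# at each position the three single-base changes are weighted kappa
# (transition) or 1 (each transversion); changes to stop codons count as
# nonsynonymous. Returns a value in [0, 3]. Cached per kappa.
codon_syn_sites <- function(codon, kappa = 1) {
  key <- paste0("s_", kappa)
  tab <- .ng_cache[[key]]
  if (is.null(tab)) {
    tab <- new.env(parent = emptyenv())
    .ng_cache[[key]] <- tab
  }
  hit <- tab[[codon]]
  if (!is.null(hit)) return(hit)
  val <- codon_syn_sites_impl(codon, kappa)
  tab[[codon]] <- val
  val
}

codon_syn_sites_impl <- function(codon, kappa = 1) {
  gc <- genetic_code()
  aa <- gc[[codon]]
  v <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    wsum <- 0; wsyn <- 0
    for (b in setdiff(BASES, v[pos])) {
      w <- if (is_transition(v[pos], b)) kappa else 1
      mut <- v; mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      wsum <- wsum + w
      if (gc[[mutc]] != "*" && gc[[mutc]] == aa) wsyn <- wsyn + w
    }
    s <- s + wsyn / wsum
  }
  s
}

# synonymous/nonsynonymous difference counts between two codons, averaged
# with equal weight over all minimal mutational pathways; pathways passing
# through a stop codon are excluded (if every pathway is blocked, all are
# used). Returns c(Sd, Nd).
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(Sd = 0, Nd = 0))
  key <- paste0("d_", c1, c2)
  hit <- .ng_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code()
  v1 <- strsplit(c1, "")[[1]]
  v2 <- strsplit(c2, "")[[1]]
  pos <- which(v1 != v2)
  perms <- permutations_of(pos)
  path_counts <- lapply(perms, function(ord) {
    cur <- v1
    syn <- 0; nsyn <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- v2[p]
      ca <- gc[[paste(cur, collapse = "")]]
      cb <- gc[[paste(nxt, collapse = "")]]
      if (cb == "*" && !identical(paste(nxt, collapse = ""), c2))
        blocked <- TRUE
      if (!is.na(ca) && !is.na(cb) && ca == cb) syn <- syn + 1
      else nsyn <- nsyn + 1
      cur <- nxt
    }
    list(syn = syn, nsyn = nsyn, blocked = blocked)
  })
  ok <- !vapply(path_counts, `[[`, TRUE, "blocked")
  use <- if (any(ok)) path_counts[ok] else path_counts
  val <- c(Sd = mean(vapply(use, `[[`, 0, "syn")),
           Nd = mean(vapply(use, `[[`, 0, "nsyn")))
  .ng_cache[[key]] <- val
  val
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out <- c(out, list(c(x[i], rest)))
  out
}

check_codon_row <- function(codons, id = "sequence") {
  stops <- which(vapply(codons, function(cd) genetic_code()[[cd]] == "*", TRUE))
  if (length(stops))
    abort(sprintf("internal stop codon in %s at codon %d (%s)",
                  id, stops[1], codons[stops[1]]))
  invisible(codons)
}

#' Nei-Gojobori site and difference counts for a codon sequence pair
#'
#' Modified Nei-Gojobori counting: expected synonymous/nonsynonymous site
#' totals use a transition/transversion weight `kappa` (`kappa = 1` is the
#' unweighted original), averaged over both sequences; synonymous and
#' nonsynonymous differences are averaged with equal weights over all
#' minimal mutational pathways between differing codons, excluding pathways
#' through stop codons.
#'
#' @param a,b Complete-deleted, in-frame codon strings without internal
#'   stop codons.
#' @param kappa Transition/transversion weight for expected-site counting.
#' @return One-row tibble: `S`, `N`, `Sd`, `Nd`, `n_codons`.
#' @export
ng_counts <- function(a, b, kappa = 1) {
  ca <- split_codons(toupper(a))
  cb <- split_codons(toupper(b))
  if (length(ca) != length(cb)) abort("codon rows of unequal length")
  if (any(grepl("[^ACGT]", c(ca, cb))))
    abort("codon rows must be complete-deleted (A/C/G/T only)")
  check_codon_row(ca, "first sequence")
  check_codon_row(cb, "second sequence")
  per <- ng_per_codon(ca, cb, kappa)
  tibble(S = sum(per$S), N = sum(per$N), Sd = sum(per$Sd), Nd = sum(per$Nd),
         n_codons = length(ca))
}

# per-codon-column S, N, Sd, Nd (S/N averaged over the two rows); additive
# over columns, which is what the codon bootstrap resamples
ng_per_codon <- function(ca, cb, kappa) {
  S <- vapply(seq_along(ca), function(k)
    (codon_syn_sites(ca[k], kappa) + codon_syn_sites(cb[k], kappa)) / 2,
    numeric(1))
  N <- 3 - S
  d <- vapply(seq_along(ca), function(k) codon_pair_diffs(ca[k], cb[k]),
              numeric(2))
  list(S = S, N = N, Sd = d["Sd", ], Nd = d["Nd", ])
}

dnds_from_totals <- function(S, N, Sd, Nd) {
  ps <- Sd / S
  pn <- Nd / N
  c(dn = unname(jc_distance(pn)), ds = unname(jc_distance(ps)))
}

#' Synonymous and nonsynonymous distances (dn, ds) of a codon alignment
#'
#' Proportions `pn = Nd/N` and `ps = Sd/S` from [ng_counts()] are corrected
#' with the Jukes-Cantor formula. For more than two rows, `dn` and `ds` are
#' arithmetic means over all pairs. Standard errors come from bootstrap
#' resampling of codon columns. Saturated proportions (`>= 0.75`) yield `NA`.
#'
#' @param aln A codon-framed nucleotide [alignment()].
#' @param kappa Transition/transversion weight for site counting.
#' @param bootstrap_reps Codon-bootstrap replicates (0 = no SE).
#' @param seed Seed, required when bootstrapping.
#' @return One-row tibble: `dn`, `dn_se`, `ds`, `ds_se`, `n_pairs`,
#'   `n_codons`.
#' @export
dnds <- function(aln, kappa = 1, bootstrap_reps = 0, seed = NULL) {
  if (length(aln) < 2) abort("need at least two sequences")
  if (bootstrap_reps > 0 && is.null(seed))
    abort("seed is required when bootstrapping")
  aln <- complete_deletion(aln)
  rows <- lapply(unclass(aln), function(s) split_codons(s))
  nc <- length(rows[[1]])
  if (nc == 0) abort("no codons survive complete deletion")
  for (id in names(rows)) check_codon_row(rows[[id]], id)
  n <- length(rows)
  pairs <- utils::combn(n, 2)
  per_pair <- lapply(seq_len(ncol(pairs)), function(k)
    ng_per_codon(rows[[pairs[1, k]]], rows[[pairs[2, k]]], kappa))
  pair_dnds <- function(cols) {
    vals <- vapply(per_pair, function(pp)
      dnds_from_totals(sum(pp$S[cols]), sum(pp$N[cols]),
                       sum(pp$Sd[cols]), sum(pp$Nd[cols])), numeric(2))
    c(dn = mean(vals["dn", ]), ds = mean(vals["ds", ]))
  }
  est <- pair_dnds(seq_len(nc))
  dn_se <- ds_se <- NA_real_
  if (bootstrap_reps > 0) {
    reps <- with_seed(seed, {
      vapply(seq_len(bootstrap_reps), function(r)
        pair_dnds(sample.int(nc, nc, replace = TRUE)), numeric(2))
    })
    dn_se <- stats::sd(reps["dn", ], na.rm = TRUE)
    ds_se <- stats::sd(reps["ds", ], na.rm = TRUE)
  }
  tibble(dn = est[["dn"]], dn_se = dn_se, ds = est[["ds"]], ds_se = ds_se,
         n_pairs = ncol(pairs), n_codons = nc)
}
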