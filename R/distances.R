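#' Proportion of differing sites between two aligned rows
#'
#' @param a,b Equal-length, complete-deleted gapless strings.
#' @return Mismatches / length.
#' @export
p_distance <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv)) abort("rows of unequal length")
  if (length(av) == 0) abort("zero-length rows")
  mean(av != bv)
}

#' Jukes-Cantor distance from a proportion of differing sites
#'
#' `d = -(3/4) log(1 - (4/3) p)`. Saturated inputs (`p >= 0.75`) yield `NA`
#' rather than an error so report tables can print a dash.
#'
#' @param p Proportion(s) of differing sites, in `[0, 1]`.
#' @return Substitutions per site (vectorized; `NA` at saturation).
#' @export
jc_distance <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p must lie in [0, 1]")
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# log-or-gamma transform: -log(x) when shape infinite, a*(x^(-1/a)-1) otherwise
neg_log_gamma <- function(x, gamma_shape) {
  if (is.infinite(gamma_shape)) -log(x)
  else gamma_shape * (x^(-1 / gamma_shape) - 1)
}

# TN93 distance from pair summary counts
# counts: named list nAG, nCT, nTV, L, base counts over both rows (A,C,G,T)
tn_from_counts <- function(nAG, nCT, nTV, base_counts, L, gamma_shape = Inf) {
  if (L == 0) return(NA_real_)
  f <- base_counts / sum(base_counts)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  P1 <- nAG / L; P2 <- nCT / L; Q <- nTV / L
  if (gA * gG * gC * gT == 0) {
    # degenerate composition: fall back only when no substitutions observed
    if (nAG + nCT + nTV == 0) return(0)
    return(NA_real_)
  }
  x1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
  x2 <- 1 - gY * P2 / (2 * gC * gT) - Q / (2 * gY)
  x3 <- 1 - Q / (2 * gR * gY)
  if (any(c(x1, x2, x3) <= 0)) return(NA_real_)
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  d <- k1 * neg_log_gamma(x1, gamma_shape) +
       k2 * neg_log_gamma(x2, gamma_shape) +
       k3 * neg_log_gamma(x3, gamma_shape)
  max(d, 0)
}

pair_tn_counts <- function(av, bv) {
  ts1 <- sum((av == "A" & bv == "G") | (av == "G" & bv == "A"))
  ts2 <- sum((av == "C" & bv == "T") | (av == "T" & bv == "C"))
  diff <- sum(av != bv)
  bc <- table(factor(c(av, bv), levels = c("A", "C", "G", "T")))
  list(nAG = ts1, nCT = ts2, nTV = diff - ts1 - ts2,
       base_counts = as.numeric(stats::setNames(as.vector(bc), names(bc))) |>
         stats::setNames(c("A", "C", "G", "T")),
       L = length(av))
}

#' Tamura-Nei (TN93) distance between two rows, with optional gamma rates
#'
#' Base frequencies are estimated from the pair itself. With a finite gamma
#' shape `a`, each `-log(x)` term of the TN93 formula is replaced by its
#' gamma-rates transform `a (x^(-1/a) - 1)`; `gamma_shape = Inf` recovers
#' plain TN93. Arguments outside the formula's domain yield `NA`
#' (saturation), not an error.
#'
#' @param a,b Equal-length complete-deleted nucleotide strings.
#' @param gamma_shape Positive gamma shape parameter, or `Inf`.
#' @return Substitutions per site, or `NA`.
#' @export
tn_distance <- function(a, b, gamma_shape = Inf) {
  if (gamma_shape <= 0) abort("gamma_shape must be positive")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv)) abort("rows of unequal length")
  if (length(av) == 0) abort("zero-length rows")
  cc <- pair_tn_counts(av, bv)
  tn_from_counts(cc$nAG, cc$nCT, cc$nTV, cc$base_counts, cc$L, gamma_shape)
}

#' Count varied and total sites of an alignment
#'
#' "Varied" columns hold at least two distinct residues; "total" is the
#' column count surviving complete deletion. These are the 2x2 inputs of the
#' regional acceleration test.
#'
#' @param aln A [alignment()] object.
#' @param apply_deletion Run [complete_deletion()] first (default `TRUE`).
#' @return Tibble with columns `varied` and `total`.
#' @export
count_sites <- function(aln, apply_deletion = TRUE) {
  if (apply_deletion) aln <- complete_deletion(aln)
  m <- aln_matrix(aln)
  if (ncol(m) == 0) abort("no columns survive complete deletion")
  varied <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  tibble(varied = as.integer(varied), total = ncol(m))
}

# per-pair distance from an integer-coded matrix (1..4 = ACGT) and a column
# index vector; used by both the plain and the bootstrap paths
pair_dist_coded <- function(xi, xj, cols, method, gamma_shape) {
  a <- xi[cols]; b <- xj[cols]
  if (method == "p") return(mean(a != b))
  if (method == "jc") return(jc_distance(mean(a != b)))
  ts1 <- sum((a == 1L & b == 3L) | (a == 3L & b == 1L))  # A<->G
  ts2 <- sum((a == 2L & b == 4L) | (a == 4L & b == 2L))  # C<->T
  diff <- sum(a != b)
  bc <- tabulate(c(a, b), nbins = 4)
  tn_from_counts(ts1, ts2, diff - ts1 - ts2,
                 stats::setNames(bc[c(1, 2, 3, 4)], c("A", "C", "G", "T")),
                 length(a), gamma_shape)
}

code_alignment <- function(aln) {
  m <- aln_matrix(aln)
  x <- matrix(match(m, c("A", "C", "G", "T")), nrow(m))
  rownames(x) <- rownames(m)
  x
}

#' Pairwise distance matrix of an alignment
#'
#' Complete deletion is applied once to the whole alignment before any
#' distance is computed (shared-site convention of regional rate tables).
#'
#' @param aln A nucleotide [alignment()].
#' @param method `"jc"`, `"tn"` or `"p"`.
#' @param gamma_shape Gamma shape for `method = "tn"`; `Inf` disables.
#' @return Symmetric numeric matrix (`NA` where saturated).
#' @export
distance_matrix <- function(aln, method = c("jc", "tn", "p"),
                            gamma_shape = Inf) {
  method <- match.arg(method)
  aln <- complete_deletion(aln)
  x <- code_alignment(aln)
  n <- nrow(x)
  if (ncol(x) == 0) abort("no columns survive complete deletion")
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  cols <- seq_len(ncol(x))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- pair_dist_coded(x[i, ], x[j, ], cols, method,
                                          gamma_shape)
  d
}

#' Mean pairwise evolutionary distance with bootstrap standard error
#'
#' Arithmetic mean of all pairwise distances after complete deletion (the
#' "average distance" convention of regional rate tables). The standard
#' error is the standard deviation of the mean over column-resampled
#' bootstrap replicates.
#'
#' @inheritParams distance_matrix
#' @param bootstrap_reps Number of bootstrap replicates (0 = no SE). Rate
#'   tables conventionally use 2000.
#' @param seed Seed for the resampling; required when `bootstrap_reps > 0`.
#' @return One-row tibble: `method`, `gamma_shape`, `value`, `se`,
#'   `n_pairs`, `sites_used`. If any pairwise distance is undefined the
#'   value is `NA` and the offending pairs are listed in the list-column
#'   `undefined_pairs`.
#' @export
mean_pairwise_distance <- function(aln, method = c("jc", "tn", "p"),
                                   gamma_shape = Inf, bootstrap_reps = 0,
                                   seed = NULL) {
  method <- match.arg(method)
  if (length(aln) < 2) abort("need at least two sequences")
  if (bootstrap_reps > 0 && is.null(seed))
    abort("seed is required when bootstrapping")
  aln <- complete_deletion(aln)
  x <- code_alignment(aln)
  L <- ncol(x)
  if (L == 0) abort("no columns survive complete deletion")
  n <- nrow(x)
  pairs <- utils::combn(n, 2)
  cols <- seq_len(L)
  dvals <- apply(pairs, 2, function(ij)
    pair_dist_coded(x[ij[1], ], x[ij[2], ], cols, method, gamma_shape))
  undef <- which(is.na(dvals))
  undef_pairs <- if (length(undef))
    list(tibble(id_a = rownames(x)[pairs[1, undef]],
                id_b = rownames(x)[pairs[2, undef]]))
  else list(tibble(id_a = character(), id_b = character()))
  value <- if (length(undef)) NA_real_ else mean(dvals)
  se <- NA_real_
  if (bootstrap_reps > 0 && !is.na(value)) {
    reps <- with_seed(seed, {
      vapply(seq_len(bootstrap_reps), function(r) {
        cc <- sample.int(L, L, replace = TRUE)
        mean(apply(pairs, 2, function(ij)
          pair_dist_coded(x[ij[1], ], x[ij[2], ], cc, method, gamma_shape)))
      }, numeric(1))
    })
    se <- stats::sd(reps, na.rm = TRUE)
  }
  if (bootstrap_reps > 0 && !is.na(value) && value == 0) se <- se %||% 0
  tibble(method = method, gamma_shape = gamma_shape, value = value, se = se,
         n_pairs = ncol(pairs), sites_used = L,
         undefined_pairs = undef_pairs)
}
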