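# Independent oracles used by the tests. These deliberately re-derive
# results by brute force / closed form, without touching the package's own
# implementation paths.

# ---- exhaustive global alignment score (sequences of length <= 7) --------
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, (if (av[i] == bv[j]) match else mismatch) +
                    rec(i + 1, j + 1))
    if (i <= length(av)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# ---- Nei-Gojobori oracle --------------------------------------------------
# Direct enumeration, independent of the package's cached tables.
GC_TAB <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GC_TAB)[GC_TAB != "*"]

oracle_syn_sites <- function(codon, kappa = 1) {
  v <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    num <- 0; den <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == v[pos]) next
      purine <- function(x) x %in% c("A", "G")
      w <- if (purine(b) == purine(v[pos])) kappa else 1
      mut <- v; mut[pos] <- b
      den <- den + w
      aa <- GC_TAB[[paste(mut, collapse = "")]]
      if (aa != "*" && aa == GC_TAB[[codon]]) num <- num + w
    }
    total <- total + num / den
  }
  total
}

# all orderings of substitutions between two codons; pathways through stop
# codons dropped (all retained if every pathway is blocked)
oracle_pair_diffs <- function(c1, c2) {
  v1 <- strsplit(c1, "")[[1]]
  v2 <- strsplit(c2, "")[[1]]
  pos <- which(v1 != v2)
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    idx <- seq_along(pos)
    ords <- list()
    gen <- function(prefix, rest) {
      if (!length(rest)) { ords[[length(ords) + 1]] <<- pos[prefix]; return() }
      for (r in seq_along(rest)) gen(c(prefix, rest[r]), rest[-r])
    }
    gen(integer(), idx)
    ords
  }
  paths <- lapply(perms, function(ord) {
    cur <- v1; syn <- 0; nsyn <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- v2[p]
      a1 <- GC_TAB[[paste(cur, collapse = "")]]
      a2 <- GC_TAB[[paste(nxt, collapse = "")]]
      if (a2 == "*" && paste(nxt, collapse = "") != c2) blocked <- TRUE
      if (a1 == a2) syn <- syn + 1 else nsyn <- nsyn + 1
      cur <- nxt
    }
    c(syn = syn, nsyn = nsyn, blocked = as.numeric(blocked))
  })
  keep <- vapply(paths, function(p) p[["blocked"]] == 0, TRUE)
  if (!any(keep)) keep <- rep(TRUE, length(paths))
  use <- paths[keep]
  c(Sd = mean(vapply(use, `[[`, 0, "syn")),
    Nd = mean(vapply(use, `[[`, 0, "nsyn")))
}

# ---- expected p-distance under the simulator's substitution model --------
# The event process is a continuous-time chain with total rate `rate` per
# site and transition probability kappa/(kappa+2) per event (K2P). The
# expected proportion of differing sites after total divergence time t is
# 1 - sum_j pi_j P_jj(t), computed by numeric eigendecomposition.
expected_p_k2p <- function(rate, t, kappa) {
  a <- rate * kappa / (kappa + 2)   # transition rate
  b <- rate / (kappa + 2)           # each transversion rate
  # order A C G T; transitions A<->G, C<->T
  Q <- matrix(b, 4, 4)
  Q[1, 3] <- Q[3, 1] <- a
  Q[2, 4] <- Q[4, 2] <- a
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  e <- eigen(Q)
  P <- e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors)
  1 - mean(diag(P))
}

# ---- fixtures -------------------------------------------------------------
# peptide matching the default WAP spacing profile exactly
wap_fixture_peptide <- function(pre = "AAA", post = "AA") {
  paste0(pre, "C", "QQQQQQQ", "C", "DDDDDD", "C", "EEEEE", "C", "FFFF",
         "CC", "GGGG", "C", "HHH", "C", post)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(seqs) {
  p <- tempfile(fileext = ".fasta")
  con <- file(p, "w")
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  close(con)
  p
}
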