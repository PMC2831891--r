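# integer base coding 1..4 = A C G T
TS_PARTNER <- c(3L, 4L, 1L, 2L)
TV_PARTNERS <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

codon_index <- function(b1, b2, b3) (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3

codon_aa_table <- function() {
  tab <- .ng_cache[["aa_by_index"]]
  if (!is.null(tab)) return(tab)
  gc <- genetic_code()
  tab <- character(64)
  for (b1 in 1:4) for (b2 in 1:4) for (b3 in 1:4)
    tab[codon_index(b1, b2, b3)] <-
      gc[[paste(BASES[c(b1, b2, b3)], collapse = "")]]
  .ng_cache[["aa_by_index"]] <- tab
  tab
}

#' Configuration of a simulated trappin-like gene family
#'
#' Defines the generating conditions: a three-exon ~2.1-kb gene with seven
#' annotated regions, noncoding regions evolving at a base clock rate with
#' per-region multipliers and a transition bias, coding subregions (signal
#' peptide in exon 1; TGS then WAP filling exon 2) evolving codon-wise with
#' per-domain dn/ds targets (`omega`), down a rooted tree whose branch
#' lengths are in My. No indels are generated, so descendants stay aligned.
#'
#' @param region_lengths Named lengths (nt) of the seven canonical regions.
#' @param signal_length,tgs_length,wap_length Coding subregion lengths;
#'   `tgs_length + wap_length` must fill exon2, and all must be multiples
#'   of 3.
#' @param base_rate Noncoding substitution rate, substitutions/site/My.
#' @param region_multipliers Named per-region rate multipliers.
#' @param omega dn/ds targets for `signal`, `TGS`, `WAP`.
#' @param kappa_sim Transition/transversion rate-class bias (K2P-style).
#' @param tree Rooted `ape::phylo` with branch lengths in My; leaves become
#'   gene ids.
#' @param seed Integer seed; the same config yields bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(region_lengths = c(flank5 = 300, exon1 = 90,
                                          intron1 = 400, exon2 = 450,
                                          intron2 = 500, exon3 = 200,
                                          flank3 = 300),
                       signal_length = 60, tgs_length = 300,
                       wap_length = 150,
                       base_rate = 0.0017,
                       region_multipliers = c(flank5 = 1, exon1 = 0.5,
                                              intron1 = 1, exon2 = 4,
                                              intron2 = 1, exon3 = 1,
                                              flank3 = 1),
                       omega = c(signal = 0.5, TGS = 1, WAP = 1),
                       kappa_sim = 2,
                       tree = pectinate_family_tree(),
                       seed = 1L) {
  if (!all(canonical_regions %in% names(region_lengths)))
    abort("region_lengths must name all seven canonical regions")
  if (any(c(signal_length, tgs_length, wap_length) %% 3 != 0))
    abort("coding subregion lengths must be multiples of 3")
  if (signal_length > region_lengths[["exon1"]])
    abort("signal peptide longer than exon1")
  if (tgs_length + wap_length != region_lengths[["exon2"]])
    abort("TGS + WAP must fill exon2")
  if (base_rate < 0 || any(region_multipliers < 0) || any(omega <= 0))
    abort("rates and multipliers must be non-negative, omega positive")
  if (!inherits(tree, "phylo") || !ape::is.rooted(tree))
    abort("tree must be a rooted phylo with branch lengths in My")
  structure(list(region_lengths = region_lengths[canonical_regions],
                 signal_length = signal_length, tgs_length = tgs_length,
                 wap_length = wap_length, base_rate = base_rate,
                 region_multipliers = region_multipliers,
                 omega = omega, kappa_sim = kappa_sim, tree = tree,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Pectinate gene-family tree from duplication ages
#'
#' A ladder of duplications at the given ages (Mya, strictly decreasing),
#' yielding `length(ages) + 1` genes on a strict clock.
#'
#' @param ages Duplication ages, Mya.
#' @param labels Leaf labels (default `g1`, `g2`, ...).
#' @return Rooted ultrametric `ape::phylo` with branch lengths in My.
#' @export
pectinate_family_tree <- function(ages = c(15.9, 13, 10, 7, 4),
                                  labels = paste0("g", seq_len(length(ages) + 1))) {
  if (any(diff(ages) >= 0)) abort("ages must be strictly decreasing")
  n <- length(ages)
  nwk <- sprintf("(%s:%g,%s:%g)", labels[n], ages[n], labels[n + 1], ages[n])
  if (n > 1)
    for (k in (n - 1):1)
      nwk <- sprintf("(%s:%g,%s:%g)", labels[k], ages[k], nwk,
                     ages[k] - ages[k + 1])
  ape::read.tree(text = paste0(nwk, ";"))
}

# segment map: tibble(segment, start(0-based), end, kind, host_region)
config_segments <- function(cfg) {
  rl <- cfg$region_lengths
  starts <- cumsum(c(0, rl))[seq_along(rl)]
  names(starts) <- names(rl)
  seg <- list()
  add <- function(name, s, e, kind, host)
    seg[[length(seg) + 1]] <<- tibble(segment = name, start = s, end = e,
                                      kind = kind, host = host)
  add("signal", starts[["exon1"]], starts[["exon1"]] + cfg$signal_length,
      "coding", "exon1")
  if (cfg$signal_length < rl[["exon1"]])
    add("exon1nc", starts[["exon1"]] + cfg$signal_length,
        starts[["exon1"]] + rl[["exon1"]], "noncoding", "exon1")
  add("TGS", starts[["exon2"]], starts[["exon2"]] + cfg$tgs_length,
      "coding", "exon2")
  add("WAP", starts[["exon2"]] + cfg$tgs_length,
      starts[["exon2"]] + rl[["exon2"]], "coding", "exon2")
  for (r in c("flank5", "intron1", "intron2", "exon3", "flank3"))
    add(r, starts[[r]], starts[[r]] + rl[[r]], "noncoding", r)
  bind_rows(seg) |> arrange(.data$start)
}

# region annotation table shared by every simulated gene
config_region_table <- function(cfg, ids) {
  rl <- cfg$region_lengths
  starts <- cumsum(c(0, rl))[seq_along(rl)]
  names(starts) <- names(rl)
  one <- bind_rows(
    tibble(region = names(rl), start = unname(starts),
           end = unname(starts + rl)),
    tibble(region = "signal", start = starts[["exon1"]],
           end = starts[["exon1"]] + cfg$signal_length),
    tibble(region = "TGS", start = starts[["exon2"]],
           end = starts[["exon2"]] + cfg$tgs_length),
    tibble(region = "WAP", start = starts[["exon2"]] + cfg$tgs_length,
           end = starts[["exon2"]] + rl[["exon2"]]))
  tidyr::crossing(gene_id = ids, one) |>
    select("gene_id", "region", "start", "end") |>
    arrange(.data$gene_id, .data$start)
}

sample_base <- function(cur, kappa) {
  if (stats::runif(1) < kappa / (kappa + 2)) TS_PARTNER[cur]
  else TV_PARTNERS[[cur]][sample.int(2, 1)]
}

# evolve one segment of the integer-coded gene along one branch; returns
# list(seq, nsub)
evolve_segment <- function(seq, s0, s1, kind, rate, t, kappa, omega, aa_tab) {
  idx <- (s0 + 1):s1
  L <- length(idx)
  m <- stats::rpois(L, rate * t)
  sites <- rep(idx, m)
  if (!length(sites)) return(list(seq = seq, nsub = 0L))
  sites <- sites[sample.int(length(sites))]
  nsub <- 0L
  for (site in sites) {
    cur <- seq[site]
    prop <- sample_base(cur, kappa)
    if (kind == "noncoding") {
      seq[site] <- prop
      nsub <- nsub + 1L
      next
    }
    codon_pos <- ((site - s0 - 1L) %% 3L) + 1L
    c0 <- site - codon_pos + 1L
    cod <- seq[c0:(c0 + 2L)]
    old_aa <- aa_tab[codon_index(cod[1], cod[2], cod[3])]
    new <- cod
    new[codon_pos] <- prop
    if (aa_tab[codon_index(new[1], new[2], new[3])] == "*") {
      # resample among non-stop alternatives
      alts <- setdiff(1:4, cur)
      ok <- alts[vapply(alts, function(b) {
        nn <- cod; nn[codon_pos] <- b
        aa_tab[codon_index(nn[1], nn[2], nn[3])] != "*"
      }, TRUE)]
      w <- ifelse(ok == TS_PARTNER[cur], kappa, 1)
      prop <- ok[sample.int(length(ok), 1, prob = w)]
      new[codon_pos] <- prop
    }
    new_aa <- aa_tab[codon_index(new[1], new[2], new[3])]
    p_accept <- if (new_aa == old_aa) min(1, 1 / omega) else min(1, omega)
    if (stats::runif(1) < p_accept) {
      seq[site] <- prop
      nsub <- nsub + 1L
    }
  }
  list(seq = seq, nsub = nsub)
}

random_ancestor <- function(cfg, segments, aa_tab) {
  L <- sum(cfg$region_lengths)
  seq <- sample.int(4L, L, replace = TRUE)
  for (k in which(segments$kind == "coding")) {
    idx <- (segments$start[k] + 1):segments$end[k]
    for (c0 in idx[seq(1, length(idx), by = 3)]) {
      repeat {
        cod <- sample.int(4L, 3L, replace = TRUE)
        if (aa_tab[codon_index(cod[1], cod[2], cod[3])] != "*") break
      }
      seq[c0:(c0 + 2L)] <- cod
    }
  }
  seq
}

#' Simulate a trappin-like gene family with known truth
#'
#' Draws a stop-codon-free ancestral gene and evolves it down the config's
#' tree: noncoding sites mutate as Poisson events with a K2P-style
#' transition bias; coding sites mutate by codon-aware proposals with
#' nonsynonymous changes accepted with probability `omega` (or synonymous
#' ones thinned by `1/omega` when `omega > 1`), proposals creating stop
#' codons resampled. No indels are generated, so the emitted family is
#' intrinsically aligned.
#'
#' @param config A [sim_config()].
#' @return A `sim_family` list: `alignment` (full-gene [alignment()]),
#'   `regions` (annotation tibble), `genes` (tibble id/species/seq), and
#'   `truth` (generating tree as newick, per-branch per-segment realized
#'   substitution counts, config echo).
#' @export
simulate_family <- function(config) {
  if (!inherits(config, "sim_config")) abort("config must be a sim_config()")
  aa_tab <- codon_aa_table()
  segments <- config_segments(config)
  tree <- ape::reorder.phylo(config$tree, "cladewise")
  with_seed(config$seed, {
    anc <- random_ancestor(config, segments, aa_tab)
    n_tip <- ape::Ntip(tree)
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[n_tip + 1L]] <- anc
    counts <- list()
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t <- tree$edge.length[e]
      seq <- seqs[[parent]]
      for (k in seq_len(nrow(segments))) {
        host <- segments$host[k]
        rate <- config$base_rate * config$region_multipliers[[host]]
        omega <- if (segments$kind[k] == "coding")
          config$omega[[segments$segment[k]]] else 1
        ev <- evolve_segment(seq, segments$start[k], segments$end[k],
                             segments$kind[k], rate, t, config$kappa_sim,
                             omega, aa_tab)
        seq <- ev$seq
        counts[[length(counts) + 1]] <-
          tibble(edge = e,
                 child = if (child <= n_tip) tree$tip.label[child]
                         else paste0("node", child),
                 segment = segments$segment[k], branch_my = t,
                 substitutions = ev$nsub,
                 sites = segments$end[k] - segments$start[k])
      }
      seqs[[child]] <- seq
    }
    ids <- tree$tip.label
    strings <- vapply(seq_len(n_tip), function(i)
      paste(BASES[seqs[[i]]], collapse = ""), "")
    aln <- alignment(stats::setNames(strings, ids), type = "dna")
    structure(list(
      alignment = aln,
      regions = config_region_table(config, ids),
      genes = tibble(id = ids, species = ids, seq = strings),
      truth = list(tree_newick = ape::write.tree(tree),
                   counts = bind_rows(counts), config = config)),
      class = "sim_family")
  })
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("<sim_family> %d genes x %d nt, seed %d\n",
              length(x$alignment), aln_width(x$alignment),
              x$truth$config$seed))
  invisible(x)
}

#' Acceleration study scenario
#'
#' A six-gene family (ladder of duplications at 15.9, 13, 10, 7 and 4 Mya)
#' whose exon 2 evolves at `multiplier_exon2` times the noncoding rate with
#' neutral coding acceptance, the setting probed by the regional
#' acceleration test. With multiplier 1 the exon evolves at the background
#' rate (the null).
#'
#' @param multiplier_exon2 Exon-2 rate multiplier (> 0).
#' @param seed Integer seed.
#' @return A `sim_family`.
#' @export
make_acceleration_scenario <- function(multiplier_exon2 = 4, seed = 1L) {
  if (multiplier_exon2 <= 0) abort("multiplier must be positive")
  cfg <- sim_config(
    region_multipliers = c(flank5 = 1, exon1 = 1, intron1 = 1,
                           exon2 = multiplier_exon2, intron2 = 1,
                           exon3 = 1, flank3 = 1),
    omega = c(signal = 1, TGS = 1, WAP = 1),
    seed = seed)
  simulate_family(cfg)
}

#' Duplication-dating scenario
#'
#' Strict-clock family with an outgroup splitting at `calibration_time` and
#' one within-species duplication at `duplication_time`, all regions at the
#' background rate.
#'
#' @param duplication_time,calibration_time Ages in Mya
#'   (`duplication_time <= calibration_time`).
#' @param seed Integer seed.
#' @param base_rate Background rate, substitutions/site/My.
#' @return A `sim_family` with leaves `in_g1`, `in_g2`, `out`.
#' @export
make_dating_scenario <- function(duplication_time = 15,
                                 calibration_time = 96.2, seed = 1L,
                                 base_rate = 0.0017) {
  if (duplication_time > calibration_time)
    abort("duplication must not predate the calibration split")
  nwk <- sprintf("((in_g1:%g,in_g2:%g):%g,out:%g);",
                 duplication_time, duplication_time,
                 calibration_time - duplication_time, calibration_time)
  cfg <- sim_config(
    region_multipliers = c(flank5 = 1, exon1 = 1, intron1 = 1, exon2 = 1,
                           intron2 = 1, exon3 = 1, flank3 = 1),
    omega = c(signal = 1, TGS = 1, WAP = 1),
    base_rate = base_rate,
    tree = ape::read.tree(text = nwk), seed = seed)
  simulate_family(cfg)
}

#' Estimate a duplication date from a simulated (or real) family
#'
#' The standard clock pipeline: pooled noncoding alignment, distance
#' matrix, NJ, rooting on the outgroup, linearization, dating against the
#' outgroup calibration, then the age of the `pair`'s split.
#'
#' @param fam A `sim_family` (or a list with `alignment` and `regions`).
#' @param pair Two leaf labels whose split is dated.
#' @param outgroup Outgroup leaf label(s).
#' @param calibration_time Age (Mya) of the ingroup/outgroup split.
#' @param method,gamma_shape Distance options (see [distance_matrix()]).
#' @return Estimated age of the pair's split, Mya.
#' @export
estimate_duplication_date <- function(fam, pair = c("in_g1", "in_g2"),
                                      outgroup = "out",
                                      calibration_time = 96.2,
                                      method = "jc", gamma_shape = Inf) {
  nc <- slice_region(fam$alignment, fam$regions, "noncoding")
  d <- distance_matrix(nc, method = method, gamma_shape = gamma_shape)
  tr <- nj_tree(d) |> root_tree(outgroup) |> linearize()
  dating <- date_nodes(tr, calibration(setdiff(rownames(d), outgroup)[1],
                                       outgroup, calibration_time))
  node_date(dating, pair[1], pair[2])
}

#' Write a simulated family to plain-text files
#'
#' Emits `alignment.fasta`, `regions.tsv`, `truth.nwk`,
#' `truth_counts.tsv` and `config.tsv` into `dir`.
#'
#' @param fam A `sim_family`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_family <- function(fam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- fam$truth$config
  hdr <- sprintf("seed=%d base_rate=%g kappa_sim=%g", cfg$seed,
                 cfg$base_rate, cfg$kappa_sim)
  write_aligned_fasta(fam$alignment, file.path(dir, "alignment.fasta"),
                      header = hdr)
  readr::write_tsv(fam$regions, file.path(dir, "regions.tsv"))
  writeLines(fam$truth$tree_newick, file.path(dir, "truth.nwk"))
  readr::write_tsv(fam$truth$counts, file.path(dir, "truth_counts.tsv"))
  cfg_tbl <- tibble(
    key = c("seed", "base_rate", "kappa_sim",
            paste0("len_", names(cfg$region_lengths)),
            paste0("mult_", names(cfg$region_multipliers)),
            paste0("omega_", names(cfg$omega))),
    value = c(cfg$seed, cfg$base_rate, cfg$kappa_sim,
              unname(cfg$region_lengths), unname(cfg$region_multipliers),
              unname(cfg$omega)))
  readr::write_tsv(cfg_tbl, file.path(dir, "config.tsv"))
  invisible(dir)
}
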