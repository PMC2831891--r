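test_that("the simulator is deterministic in its seed", {
  f1 <- make_acceleration_scenario(4, seed = 7)
  f2 <- make_acceleration_scenario(4, seed = 7)
  expect_identical(unclass(f1$alignment), unclass(f2$alignment))
  expect_identical(f1$truth$counts, f2$truth$counts)
  f3 <- make_acceleration_scenario(4, seed = 8)
  expect_false(identical(unclass(f1$alignment), unclass(f3$alignment)))
})

test_that("a zero base rate leaves every leaf identical to the root", {
  cfg <- sim_config(base_rate = 0, seed = 3)
  fam <- simulate_family(cfg)
  seqs <- unique(unname(unclass(fam$alignment)))
  expect_length(seqs, 1)
  expect_true(all(fam$truth$counts$substitutions == 0))
})

test_that("no emitted coding region contains an internal stop codon", {
  for (seed in 1:5) {
    fam <- make_acceleration_scenario(4, seed = seed)
    for (rg in c("signal", "TGS", "WAP")) {
      sub <- slice_region(fam$alignment, fam$regions, rg, is_codon = TRUE)
      for (row in unclass(sub)) {
        codons <- trappinevo:::split_codons(row)
        expect_false(any(Biostrings::GENETIC_CODE[codons] == "*"),
                     label = paste("stop codon in", rg, "seed", seed))
      }
    }
  }
})

test_that("neutral coding evolution is recovered as dn/ds near one", {
  cfg <- sim_config(
    region_lengths = c(flank5 = 3, exon1 = 6, intron1 = 3, exon2 = 9000,
                       intron2 = 3, exon3 = 3, flank3 = 3),
    signal_length = 6, tgs_length = 4500, wap_length = 4500,
    region_multipliers = c(flank5 = 1, exon1 = 1, intron1 = 1, exon2 = 1,
                           intron2 = 1, exon3 = 1, flank3 = 1),
    omega = c(signal = 1, TGS = 1, WAP = 1), kappa_sim = 2,
    tree = ape::read.tree(text = "(a:25,b:25);"), seed = 1)
  fam <- simulate_family(cfg)
  ex2 <- slice_region(fam$alignment, fam$regions, "exon2")
  est <- dnds(ex2, kappa = 2)
  ratio <- est$dn / est$ds
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("noncoding divergence matches the closed-form expectation", {
  # mean p-distance over seeds vs the K2P transition-probability matrix
  rate <- 0.0017; t_split <- 40; kappa <- 2
  nwk <- sprintf("(a:%g,b:%g);", t_split, t_split)
  p_hat <- vapply(1:100, function(s) {
    cfg <- sim_config(
      region_lengths = c(flank5 = 200, exon1 = 6, intron1 = 3, exon2 = 6,
                         intron2 = 3, exon3 = 3, flank3 = 3),
      signal_length = 6, tgs_length = 3, wap_length = 3,
      region_multipliers = c(flank5 = 1, exon1 = 1, intron1 = 1,
                             exon2 = 1, intron2 = 1, exon3 = 1,
                             flank3 = 1),
      omega = c(signal = 1, TGS = 1, WAP = 1), kappa_sim = kappa,
      tree = ape::read.tree(text = nwk), seed = s)
    fam <- simulate_family(cfg)
    fl <- slice_region(fam$alignment, fam$regions, "flank5")
    p_distance(unclass(fl)[[1]], unclass(fl)[[2]])
  }, numeric(1))
  expected <- expected_p_k2p(rate, 2 * t_split, kappa)
  se <- stats::sd(p_hat) / sqrt(length(p_hat))
  expect_lt(abs(mean(p_hat) - expected), 3 * se + 1e-9)
})

test_that("realized substitution counts scale with region multipliers", {
  mults <- c(1, 2, 4)
  per_site <- vapply(mults, function(m) {
    tot <- vapply(1:100, function(s) {
      fam <- make_acceleration_scenario(m, seed = 600 + s)
      cnt <- fam$truth$counts
      sum(cnt$substitutions[cnt$segment %in% c("TGS", "WAP")]) / 450
    }, numeric(1))
    mean(tot)
  }, numeric(1))
  fit <- stats::lm(per_site ~ mults)
  # slope of subs/site against multiplier matches the 1x level within 10%
  expect_lt(abs(stats::coef(fit)[["mults"]] / per_site[1] - 1), 0.1)
})

test_that("simulated truth round-trips through plain-text serialization", {
  fam <- make_dating_scenario(12, 80, seed = 5)
  dir <- tempfile()
  write_sim_family(fam, dir)
  aln <- read_aligned_fasta(file.path(dir, "alignment.fasta"))
  expect_identical(unclass(aln), unclass(fam$alignment))
  regions <- read_region_table(file.path(dir, "regions.tsv"))
  expect_equal(as.data.frame(regions), as.data.frame(fam$regions))
  tr <- read_newick(file.path(dir, "truth.nwk"))
  expect_true(ape::all.equal.phylo(
    tr, ape::read.tree(text = fam$truth$tree_newick),
    use.edge.length = TRUE))
  counts <- readr::read_tsv(file.path(dir, "truth_counts.tsv"),
                            show_col_types = FALSE)
  expect_equal(sum(counts$substitutions), sum(fam$truth$counts$substitutions))
})

test_that("dating recovery degenerates gracefully and ignores the rate", {
  # duplication at the calibration age -> ratio about 1
  fam <- make_dating_scenario(96.2, 96.2, seed = 2)
  est <- estimate_duplication_date(fam)
  expect_gt(est / 96.2, 0.9)
  expect_lt(est / 96.2, 1.1)

  # doubling the clock rate cancels out of the dating
  f1 <- make_dating_scenario(15, 96.2, seed = 9, base_rate = 0.0017)
  f2 <- make_dating_scenario(15, 96.2, seed = 9, base_rate = 0.0034)
  e1 <- estimate_duplication_date(f1)
  e2 <- estimate_duplication_date(f2)
  expect_lt(abs(e1 - e2) / e1, 0.35)   # same target, independent noise
  expect_error(make_dating_scenario(100, 96.2), "predate")
})

test_that("simulator configuration is validated", {
  expect_error(sim_config(signal_length = 61), "multiples of 3")
  expect_error(sim_config(tgs_length = 299), "multiples of 3|fill exon2")
  expect_error(sim_config(base_rate = -1), "non-negative")
  expect_error(pectinate_family_tree(c(5, 10)), "decreasing")
})
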