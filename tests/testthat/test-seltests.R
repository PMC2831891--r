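test_that("acceleration test matches exact hypergeometric P-values", {
  # equal proportions
  expect_equal(acceleration_test(c(1, 12), c(1, 12))$p_value, 1)
  # margins (3,3) x (3,3): P = 2 / choose(6,3)
  expect_equal(acceleration_test(c(3, 3), c(0, 3))$p_value, 0.1,
               tolerance = 1e-12)
  expect_error(acceleration_test(c(0, 0), c(1, 10)), "zero total")
})

test_that("acceleration test is symmetric and agrees with enumeration", {
  # exhaustive check against a direct hypergeometric enumerator for all
  # tables with small margins
  enum_p <- function(v1, n1, v2, n2) {
    k <- v1 + v2
    support <- max(0, k - n2):min(n1, k)
    probs <- stats::dhyper(support, n1, n2, k)
    sum(probs[probs <= stats::dhyper(v1, n1, n2, k) * (1 + 1e-7)])
  }
  set.seed(4)
  for (rep in 1:25) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    v1 <- sample(0:n1, 1); v2 <- sample(0:n2, 1)
    p <- acceleration_test(c(v1, n1), c(v2, n2))$p_value
    expect_equal(p, enum_p(v1, n1, v2, n2), tolerance = 1e-9,
                 info = paste(v1, n1, v2, n2))
    p_swap <- acceleration_test(c(v2, n2), c(v1, n1))$p_value
    expect_equal(p, p_swap, tolerance = 1e-12)
  }
})

test_that("acceleration test reports formatted distance fold changes", {
  res <- acceleration_test(c(39, 201), c(87, 1691),
                           dist_focal = c(jc = 0.235, tn = 0.442),
                           dist_reference = c(jc = 0.054, tn = 0.079))
  expect_lt(res$p_value, 0.01)
  expect_equal(res$ratio_jc, 4.4)
  expect_equal(res$ratio_tn, 5.6)
})

test_that("regional rate table flags uniform-rate families as homogeneous", {
  fam <- make_acceleration_scenario(1, seed = 20)
  tbl <- region_rate_table(fam$alignment, fam$regions,
                           bootstrap_reps = 200, seed = 1)
  expect_true(all(c(trappinevo:::canonical_regions, "noncoding") %in%
                    tbl$region))
  wide <- tbl[tbl$region %in% c("exon2", "noncoding"), ]
  # under a uniform clock exon2 and noncoding should agree within 2 SE
  expect_lt(abs(wide$jc[1] - wide$jc[2]),
            2 * sqrt(sum(wide$jc_se^2)) + 0.01)
})

test_that("regional rate table is zero for identical genes", {
  aln <- alignment(c(g1 = strrep("ACGT", 70), g2 = strrep("ACGT", 70)))
  regions <- tidyr::crossing(
    gene_id = c("g1", "g2"),
    tibble::tibble(region = c("flank5", "exon1", "intron1", "exon2",
                              "intron2", "exon3", "flank3"),
                   start = seq(0, 240, by = 40),
                   end = seq(40, 280, by = 40)))
  tbl <- region_rate_table(aln, regions)
  expect_true(all(tbl$jc == 0))
  expect_true(all(tbl$varied == 0))
})

test_that("group dn/ds summary recovers neutrality and handles degeneracy", {
  cfg <- sim_config(
    region_lengths = c(flank5 = 3, exon1 = 6, intron1 = 3, exon2 = 1200,
                       intron2 = 3, exon3 = 3, flank3 = 3),
    signal_length = 6, tgs_length = 600, wap_length = 600,
    region_multipliers = c(flank5 = 1, exon1 = 1, intron1 = 1, exon2 = 1,
                           intron2 = 1, exon3 = 1, flank3 = 1),
    omega = c(signal = 1, TGS = 1, WAP = 1), kappa_sim = 1,
    tree = ape::read.tree(text = "((a:40,b:40):10,c:50);"), seed = 5)
  fam <- simulate_family(cfg)
  ex2 <- slice_region(fam$alignment, fam$regions, "exon2")
  out <- group_dnds_summary(list(fam = ex2), kappa = 1)
  expect_gt(out$dnds_ratio, 0.8)
  expect_lt(out$dnds_ratio, 1.2)

  same <- alignment(c(x = "ATGGCTAAACTG", y = "ATGGCTAAACTG"),
                    is_codon = TRUE)
  deg <- group_dnds_summary(list(g = same))
  expect_equal(deg$dn, 0)
  expect_equal(deg$ds, 0)
  expect_true(is.na(deg$dnds_ratio))
})

test_that("positive selection test builds the rounded 2x2 correctly", {
  # no nonsynonymous excess -> no rejection
  same <- positive_selection_test("ATGGCTAAACTG", "ATGGCTAAACTG")
  expect_gte(same, 0.5)
  # strong constructed excess
  tab_p <- stats::fisher.test(matrix(c(10, 90, 0, 100), 2, byrow = TRUE),
                              alternative = "greater")$p.value
  expect_lt(tab_p, 0.01)
  counts <- tibble::tibble(S = 100, N = 100, Sd = 0, Nd = 10)
  expect_equal(positive_selection_test(counts = counts), tab_p,
               tolerance = 1e-12)
})

test_that("pairwise dn/ds matrix flags selection and undefined ratios", {
  # omega = 5 simulated pair gives a large, starred ratio
  cfg <- sim_config(
    region_lengths = c(flank5 = 3, exon1 = 6, intron1 = 3, exon2 = 6000,
                       intron2 = 3, exon3 = 3, flank3 = 3),
    signal_length = 6, tgs_length = 3000, wap_length = 3000,
    region_multipliers = c(flank5 = 1, exon1 = 1, intron1 = 1, exon2 = 4,
                           intron2 = 1, exon3 = 1, flank3 = 1),
    omega = c(signal = 1, TGS = 5, WAP = 5), kappa_sim = 2,
    tree = ape::read.tree(text = "(a:25,b:25);"), seed = 7)
  fam <- simulate_family(cfg)
  ex2 <- slice_region(fam$alignment, fam$regions, "exon2")
  m <- pairwise_dnds_matrix(ex2, kappa = 2)
  expect_gt(m$dnds_ratio, 3)
  expect_true(m$significant)

  # ds = 0 pair -> undefined sentinel, rendered as a dash
  aln <- alignment(c(x = "ATGGCTAAA", y = "ATGGGTAAA"), is_codon = TRUE)
  m0 <- pairwise_dnds_matrix(aln)
  expect_true(is.na(m0$dnds_ratio))
  fm <- format_dnds_matrix(m0)
  expect_equal(fm["y", "x"], "-")
})

test_that("fold ratios follow the one-decimal / integer display rule", {
  expect_equal(fold_ratio(0.167, 0.053), 3.2)
  expect_equal(fold_ratio(0.220, 0.019), 12)  # >= 10 -> integer display
  expect_true(is.na(fold_ratio(0.1, 0)))
})
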