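test_that("aligned FASTA reading parses, normalizes case and validates", {
  p <- write_temp_fasta(c(g1 = "ACGT", g2 = "AC-T"))
  aln <- read_aligned_fasta(p)
  expect_s3_class(aln, "seq_alignment")
  expect_length(aln, 2)
  expect_equal(as.character(unclass(aln)), c("ACGT", "AC-T"))
  expect_equal(names(aln), c("g1", "g2"))

  plc <- write_temp_fasta(c(x = "acgt"))
  expect_equal(as.character(unclass(read_aligned_fasta(plc))), "ACGT")

  empty <- tempfile(); file.create(empty)
  expect_error(read_aligned_fasta(empty), "empty")

  ragged <- write_temp_fasta(c(a = "ACGT", b = "ACG"))
  expect_error(read_aligned_fasta(ragged), "ragged")

  dup <- write_temp_fasta(c(a = "ACGT", a = "ACGT"))
  expect_error(read_aligned_fasta(dup), "duplicate")
})

test_that("FASTA round-trip with a header comment is lossless", {
  aln <- alignment(c(g1 = "ACGTN-", g2 = "ACCT-A"))
  p <- tempfile(fileext = ".fasta")
  write_aligned_fasta(aln, p, header = "seed=1")
  back <- read_aligned_fasta(p)
  expect_equal(unclass(back), unclass(aln), ignore_attr = TRUE)
})

test_that("region tables validate overlap, range and nesting rules", {
  tbl <- tibble::tibble(gene_id = "g1", region = "exon2",
                        start = 500, end = 950)
  expect_silent(validate_region_table(tbl))
  expect_equal(tbl$end - tbl$start, 450)

  overlap <- tibble::tibble(gene_id = "g1",
                            region = c("exon2", "intron2"),
                            start = c(500, 900), end = c(950, 1200))
  expect_error(validate_region_table(overlap), "overlap")

  nested <- tibble::tibble(gene_id = "g1",
                           region = c("exon2", "WAP"),
                           start = c(500, 800), end = c(950, 950))
  expect_silent(validate_region_table(nested))

  orphan <- tibble::tibble(gene_id = "g1",
                           region = c("intron1", "WAP"),
                           start = c(0, 100), end = c(400, 250))
  expect_error(validate_region_table(orphan), "nest")

  inverted <- tibble::tibble(gene_id = "g2", region = "exon1",
                             start = 10, end = 10)
  expect_error(validate_region_table(inverted), "g2")
})

test_that("region table file IO works end to end", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tregion\tstart\tend",
               "g1\texon2\t500\t950",
               "g1\tWAP\t800\t950"), p)
  tbl <- read_region_table(p)
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$start, c(500, 800))
})

test_that("slice_region extracts ungapped-coordinate intervals", {
  aln <- alignment(c(g1 = "AAACCCGGG", g2 = "TTTCCCAAA"))
  regions <- tibble::tibble(gene_id = rep(c("g1", "g2"), each = 2),
                            region = rep(c("exon1", "intron1"), 2),
                            start = rep(c(0, 3), 2), end = rep(c(3, 9), 2))
  ex <- slice_region(aln, regions, "exon1")
  expect_equal(as.character(unclass(ex)), c("AAA", "TTT"))

  # a gap column interior to the region is retained (deletion is deferred)
  aln2 <- alignment(c(g1 = "AAC-CG", g2 = "AACTCG"))
  regions2 <- tibble::tibble(gene_id = c("g1", "g2"), region = "exon1",
                             start = 0, end = c(4, 5))
  sl <- slice_region(aln2, regions2, "exon1")
  expect_equal(as.character(unclass(sl))[1], "AAC-C")

  # region missing for one id errors, naming it
  expect_error(slice_region(aln, regions[regions$gene_id == "g1", ],
                            "exon1"), "g2")
})

test_that("complete deletion removes gap and missing-data columns", {
  aln <- alignment(c(a = "AC-T", b = "ACGT"))
  cd <- complete_deletion(aln)
  expect_equal(as.character(unclass(cd)), c("ACT", "ACT"))
  expect_equal(attr(cd, "removed"), 1)

  alnN <- alignment(c(a = "ANGT", b = "ACGT"))
  expect_equal(as.character(unclass(complete_deletion(alnN))),
               c("AGT", "AGT"))

  clean <- alignment(c(a = "ACGT", b = "ACGA"))
  expect_equal(unclass(complete_deletion(clean)), unclass(clean),
               ignore_attr = TRUE)

  pep <- alignment(c(a = "MX-K", b = "MAAK"), type = "aa")
  expect_equal(as.character(unclass(complete_deletion(pep))), c("MK", "MK"))
})

test_that("slicing and complete deletion commute on gapless alignments", {
  set.seed(11)
  for (rep in 1:5) {
    seqs <- stats::setNames(vapply(1:3, function(i) random_dna(60), ""),
                            paste0("g", 1:3))
    aln <- alignment(seqs)
    regions <- tibble::tibble(gene_id = rep(names(seqs), each = 2),
                              region = rep(c("exon1", "intron1"), 3),
                              start = rep(c(0, 20), 3), end = rep(c(20, 60), 3))
    a <- complete_deletion(slice_region(aln, regions, "exon1"))
    b <- slice_region(complete_deletion(aln), regions, "exon1")
    expect_equal(aln_width <- nchar(unclass(a)[[1]]), nchar(unclass(b)[[1]]))
  }
})

test_that("newick round-trip preserves topology, lengths and support", {
  p <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):0.5,C:2);", p)
  tr <- read_newick(p)
  p2 <- tempfile(fileext = ".nwk")
  write_newick(tr, p2)
  tr2 <- read_newick(p2)
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE))
  expect_equal(sort(tr$edge.length), sort(tr2$edge.length))

  p3 <- tempfile(); writeLines("((A:1,B:1)95:0.5,C:2);", p3)
  tr3 <- read_newick(p3)
  expect_true("95" %in% tr3$node.label)

  p4 <- tempfile(); writeLines("((A:1,B:1:0.5,C:2);", p4)
  expect_error(read_newick(p4), "malformed")
})

test_that("global aligner reproduces brute-force optima and conventions", {
  al <- global_pairwise_align("ACGT", "ACGT")
  expect_equal(al$score, 4)
  expect_equal(al$a, al$b)

  al2 <- global_pairwise_align("ACGT", "ACT")
  expect_equal(al2$score, 1)
  expect_equal(al2$a, "ACGT")
  expect_equal(lengths(regmatches(al2$b, gregexpr("-", al2$b))), 1)

  al3 <- global_pairwise_align("A", "G")
  expect_equal(al3$a, "A")
  expect_equal(al3$b, "G")
  expect_equal(al3$score, -1)

  expect_error(global_pairwise_align("", "ACGT"), "empty")

  set.seed(5)
  for (rep in 1:20) {
    a <- random_dna(sample(1:7, 1))
    b <- random_dna(sample(1:7, 1))
    al <- global_pairwise_align(a, b)
    expect_equal(al$score, brute_force_align_score(a, b),
                 info = paste(a, b))
    # gapped outputs restore the inputs
    expect_equal(gsub("-", "", al$a), a)
    expect_equal(gsub("-", "", al$b), b)
  }
})
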