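test_that("read_genome loads, normalises and validates FASTA", {
  p <- write_fasta(list(chr1A = "ATGAAATAGGCATTACCGGTAACCGGTTAA",
                        chr1B = "acgtacgtacgtacgtacgtacgtacgtac"))
  g <- read_genome(p)
  expect_length(g, 2)
  expect_identical(as.character(g[["chr1B"]]),
                   toupper("acgtacgtacgtacgtacgtacgtacgtac"))

  dup <- write_fasta(list(chr1A = "ACGT"))
  cat(">chr1A\nTTTT\n", file = dup, append = TRUE)
  expect_error(read_genome(dup), "duplicate")
})

test_that("read_annotation builds transcript models with strand-aware segment order", {
  p <- write_gff3(c(
    gff_row("chr1", "gene", 100, 211, "+", "ID=gA"),
    gff_row("chr1", "mRNA", 100, 211, "+", "ID=gA.1;Parent=gA"),
    gff_row("chr1", "CDS", 100, 111, "+", "ID=c1;Parent=gA.1"),
    gff_row("chr1", "CDS", 200, 211, "+", "ID=c2;Parent=gA.1"),
    gff_row("chr1", "gene", 100, 211, "-", "ID=gB"),
    gff_row("chr1", "mRNA", 100, 211, "-", "ID=gB.1;Parent=gB"),
    gff_row("chr1", "CDS", 100, 111, "-", "ID=c3;Parent=gB.1"),
    gff_row("chr1", "CDS", 200, 211, "-", "ID=c4;Parent=gB.1")
  ))
  ann <- read_annotation(p)
  expect_setequal(names(ann), c("gA", "gB"))
  segA <- ann$gA[[1]]$cds_segments
  expect_equal(unname(segA[, 1]), c(100, 200))      # ascending on +
  segB <- ann$gB[[1]]$cds_segments
  expect_equal(unname(segB[, 1]), c(200, 100))      # descending (5'->3') on -
})

test_that("CDS with unresolvable Parent is skipped with a warning and logged", {
  p <- write_gff3(c(
    gff_row("chr1", "gene", 1, 30, "+", "ID=gA"),
    gff_row("chr1", "mRNA", 1, 30, "+", "ID=gA.1;Parent=gA"),
    gff_row("chr1", "CDS", 1, 30, "+", "ID=c1;Parent=gA.1"),
    gff_row("chr1", "CDS", 40, 60, "+", "ID=c2;Parent=ghost.1")
  ))
  expect_warning(ann <- read_annotation(p), "unresolvable Parent")
  expect_named(ann, "gA")
  expect_equal(nrow(attr(ann, "rejects")), 1)
  expect_equal(attr(ann, "rejects")$parent, "ghost.1")
})

test_that("primary transcript is first by file rank, ties by transcript id", {
  t1 <- scubr:::transcript_model("g", "g.t2", "chr1", "+",
                                 cbind(1, 9), file_rank = 7)
  t2 <- scubr:::transcript_model("g", "g.t1", "chr1", "+",
                                 cbind(1, 9), file_rank = 3)
  expect_identical(select_primary_transcript(list(t1, t2))$transcript_id, "g.t1")
  expect_identical(select_primary_transcript(list(t1))$transcript_id, "g.t2")

  tied_a <- scubr:::transcript_model("g", "g.b", "chr1", "+", cbind(1, 9), 1)
  tied_b <- scubr:::transcript_model("g", "g.a", "chr1", "+", cbind(1, 9), 1)
  expect_identical(select_primary_transcript(list(tied_a, tied_b))$transcript_id,
                   "g.a")
})

test_that("assemble_cds concatenates segments and reverse-complements on minus", {
  g <- Biostrings::DNAStringSet(c(plus = "ATGAAATAG", minus = "CTATTTCAT",
                                  two = "ATGGCAAATAG"))
  tp <- scubr:::transcript_model("gp", "gp.1", "plus", "+", cbind(1, 9), 1)
  expect_identical(assemble_cds(tp, g)$cds_sequence, "ATGAAATAG")

  tm <- scubr:::transcript_model("gm", "gm.1", "minus", "-", cbind(1, 9), 1)
  expect_identical(assemble_cds(tm, g)$cds_sequence, "ATGAAATAG")

  t2 <- scubr:::transcript_model("g2", "g2.1", "two", "+",
                                 cbind(c(1, 6), c(4, 10)), 1)
  r2 <- assemble_cds(t2, g)
  expect_identical(r2$cds_sequence, "ATGGAAATA")
  expect_equal(r2$segment_lengths, c(4L, 5L))

  oob <- scubr:::transcript_model("g3", "g3.1", "plus", "+", cbind(5, 99), 1)
  r3 <- assemble_cds(oob, g)
  expect_identical(r3$status, "rejected")
  expect_identical(r3$reason, "coords")
})

test_that("strand symmetry: mirrored minus-strand gene assembles to the same CDS", {
  set.seed(11)
  for (i in 1:5) {
    chrom <- paste0(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    segs <- cbind(c(5, 31), c(16, 45))
    g <- Biostrings::DNAStringSet(c(fwd = chrom))
    t_fwd <- scubr:::transcript_model("g", "g.1", "fwd", "+", segs, 1)
    cds_fwd <- assemble_cds(t_fwd, g)$cds_sequence
    # coordinate-mirrored reverse-complement twin
    L <- nchar(chrom)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(chrom)))
    g2 <- Biostrings::DNAStringSet(c(rev = rc))
    segs_m <- cbind(L - segs[, 2] + 1, L - segs[, 1] + 1)
    t_rev <- scubr:::transcript_model("g", "g.1", "rev", "-", segs_m, 1)
    expect_identical(assemble_cds(t_rev, g2)$cds_sequence, cds_fwd)
  }
})

test_that("filter_cds applies the four acceptance rules in order, idempotently", {
  ok <- filter_cds(make_record("ATGGCTTAA", status = NA))
  expect_identical(ok$status, "accepted")

  bad_len <- filter_cds(make_record("ATGGCTTA", status = NA))
  expect_identical(bad_len$reason, "length")

  bad_n <- filter_cds(make_record("ATGGNTTAA", status = NA))
  expect_identical(bad_n$reason, "ambiguous_base_N")

  bad_iupac <- filter_cds(make_record("ATGGRTTAA", status = NA))
  expect_identical(bad_iupac$reason, "ambiguous_base")

  bad_start <- filter_cds(make_record("TTGGCTTAA", status = NA))
  expect_identical(bad_start$reason, "start_codon")

  bad_stop <- filter_cds(make_record("ATGGCTGCA", status = NA))
  expect_identical(bad_stop$reason, "stop_codon")

  # internal stops are not a rejection
  int_stop <- filter_cds(make_record("ATGTAAGCTTAA", status = NA))
  expect_identical(int_stop$status, "accepted")

  expect_identical(filter_cds(filter_cds(bad_n)), filter_cds(bad_n))
  expect_identical(filter_cds(filter_cds(ok)), filter_cds(ok))
})

test_that("split codons follow the upstream/downstream attribution rule", {
  seq12 <- "ATGGCTGCATAA"
  expect_equal(make_record(seq12, seg = c(4, 8))$codon_exon_index,
               c(1, 2, 2, 2))   # split after 1st nt -> downstream
  expect_equal(make_record(seq12, seg = c(5, 7))$codon_exon_index,
               c(1, 1, 2, 2))   # split after 2nd nt -> upstream
  expect_equal(make_record(seq12, seg = c(6, 6))$codon_exon_index,
               c(1, 1, 2, 2))   # clean boundary
})

test_that("exon attribution never alters codon content (random gene models)", {
  set.seed(7)
  for (i in 1:20) {
    n_cod <- sample(5:40, 1)
    seq <- paste0("ATG", paste0(sample(SC59, n_cod, TRUE), collapse = ""), "TAA")
    L <- nchar(seq)
    e <- sample(1:6, 1)
    seg <- if (e == 1) L else diff(c(0, sort(sample(L - 1, e - 1)), L))
    r <- make_record(seq, seg = seg)
    expect_length(r$codon_exon_index, L / 3)
    expect_false(is.unsorted(r$codon_exon_index))
    # pooling codons over exons recovers the full codon sequence
    pooled <- unlist(lapply(sort(unique(r$codon_exon_index)), function(p) {
      codons_of(seq)[r$codon_exon_index == p]
    }))
    expect_identical(pooled, codons_of(seq))
  }
})

test_that("subgenome assignment follows the chr?[1-7][ABD] rule", {
  expect_identical(assign_subgenome("3B"), c("B"))
  expect_identical(assign_subgenome("chr1A"), c("A"))
  expect_identical(assign_subgenome("scaffold_1172"), c("unassigned"))
  expect_identical(unname(assign_subgenome(c("5D", "chr7B", "chrUn"))),
                   c("D", "B", "unassigned"))
})

test_that("extract_cds_records reports a complete filter funnel", {
  # one good gene, one with a non-ATG start
  good <- "ATGGCTGCAAAGTAA"
  bad <- "TTGGCTGCAAAGTAA"
  fa <- write_fasta(list(chr1A = paste0("GGGG", good, "TTTT", bad, "CCCC")))
  gf <- write_gff3(c(
    gff_row("chr1A", "gene", 5, 19, "+", "ID=g1"),
    gff_row("chr1A", "mRNA", 5, 19, "+", "ID=g1.1;Parent=g1"),
    gff_row("chr1A", "CDS", 5, 19, "+", "ID=c1;Parent=g1.1", phase = "0"),
    gff_row("chr1A", "gene", 24, 38, "+", "ID=g2"),
    gff_row("chr1A", "mRNA", 24, 38, "+", "ID=g2.1;Parent=g2"),
    gff_row("chr1A", "CDS", 24, 38, "+", "ID=c2;Parent=g2.1", phase = "0")
  ))
  ex <- extract_cds_records(fa, gf, species_label = "t")
  expect_equal(unname(ex$funnel[["accepted"]]), 1)
  expect_equal(unname(ex$funnel[["start_codon"]]), 1)
  expect_identical(ex$records[[1]]$cds_sequence, good)
  expect_identical(ex$records[[1]]$subgenome, "A")
  tab <- cds_record_table(ex$records)
  expect_equal(tab$cds_length, 15L)
  expect_equal(tab$n_exons, 1L)
})
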