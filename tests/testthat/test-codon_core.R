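test_that("count_codons tallies every in-frame codon, additively", {
  r <- make_record("ATGGCTTAA")
  t1 <- count_codons(r)
  expect_equal(unname(unclass(t1)[c("ATG", "GCT", "TAA")]), c(1L, 1L, 1L))
  expect_equal(sum(t1), 3)
  expect_equal(sc_total(t1), 1)

  t2 <- count_codons(list(r, r))
  expect_equal(unclass(t2), 2L * unclass(t1), ignore_attr = TRUE)

  expect_equal(sum(count_codons(list())), 0)
  expect_error(count_codons(make_record("ATGGCTTAA", status = "rejected")),
               "non-accepted")
})

test_that("count tables over disjoint record sets sum to the union's table", {
  set.seed(3)
  recs <- lapply(1:12, function(i) {
    make_record(paste0("ATG", paste0(sample(SC59, sample(4:20, 1), TRUE),
                                     collapse = ""), "TGA"),
                gene_id = paste0("g", i))
  })
  a <- count_codons(recs[1:5])
  b <- count_codons(recs[6:12])
  expect_equal(unclass(sum_codon_counts(a, b)),
               unclass(count_codons(recs)), ignore_attr = TRUE)
})

test_that("codon frequencies use the universe each mode prescribes", {
  t <- codon_counts(c(ATG = 1, GCT = 1, TAA = 1))
  expect_equal(unname(codon_frequencies(t, "sc59")[["GCT"]]), 1.0)
  f61 <- codon_frequencies(t, "nonstop61")
  expect_equal(unname(f61[["ATG"]]), 1 / 3)   # denominator: all codons
  expect_equal(unname(f61[["GCT"]]), 1 / 3)
  expect_false("TAA" %in% names(f61))
  expect_equal(sum(codon_frequencies(t, "all64")), 1)

  empty <- codon_frequencies(codon_counts(), "sc59")
  expect_true(all(is.na(empty)))
  expect_true(attr(empty, "undefined"))
})

test_that("per-amino-acid C/G : A/T ratios, with undefined on zero denominator", {
  t <- codon_counts(c(GCA = 1, GCT = 1, GCC = 2, GCG = 2,
                      ATT = 2, ATA = 2, ATC = 1))
  r <- per_aa_scub_ratio(t)
  expect_equal(unname(r[["A"]]), 2.0)
  expect_equal(unname(r[["I"]]), 0.25)
  expect_true(is.na(per_aa_scub_ratio(codon_counts(c(GCC = 3)))[["A"]]))
})

test_that("scub_profile ending frequencies and A/T:C/G ratio", {
  t <- codon_counts(c(GCA = 1, GCT = 2, GCC = 3, GCG = 4))
  p <- scub_profile(t)
  expect_equal(unname(p$ending_freq),
               c(0.1, 0.2, 0.3, 0.4))
  expect_equal(p$at_cg_ratio, 3 / 7)
  expect_equal(sum(p$ending_freq), 1, tolerance = 1e-12)

  # degenerate single-codon table
  p2 <- scub_profile(codon_counts(c(GAG = 5)))
  expect_equal(unname(p2$ending_freq[["fNNG"]]), 1)
  expect_equal(p2$at_cg_ratio, 0)
  expect_error(scub_profile(codon_counts()), "SC total is zero")
})

test_that("uniform SC usage reproduces the genetic code's ending composition", {
  # oracle: enumerate the 59-SC set directly from the code table
  t <- codon_counts(setNames(rep(7L, length(SC59)), SC59))
  p <- scub_profile(t)
  third <- substr(SC59, 3, 3)
  for (b in c("A", "T", "C", "G")) {
    expect_equal(unname(p$ending_freq[[paste0("fNN", b)]]),
                 sum(third == b) / length(SC59))
  }
})

test_that("RSCU follows the observed/expected definition with family mean 1", {
  t <- codon_counts(c(GCA = 10, GCT = 20, GCC = 30, GCG = 40))
  r <- rscu(t)
  expect_equal(unname(r[["GCG"]]), 1.6)

  eq <- rscu(codon_counts(c(GCA = 5, GCT = 5, GCC = 5, GCG = 5)))
  expect_equal(unname(eq[c("GCA", "GCT", "GCC", "GCG")]), rep(1, 4))

  z <- rscu(codon_counts(c(GCT = 2, GCC = 2)))
  expect_equal(unname(z[["GCA"]]), 0)

  # family means = 1 for every nonzero family, on random counts
  set.seed(5)
  big <- codon_counts(setNames(sample(0:50, length(SC59), TRUE), SC59))
  rr <- rscu(big)
  fams <- split(SC59, Biostrings::GENETIC_CODE[SC59])
  for (fam in fams) {
    if (sum(unclass(big)[fam]) > 0) {
      expect_equal(mean(rr[fam]), 1, tolerance = 1e-9)
    }
  }
})

test_that("reference weights normalise by the family maximum", {
  t <- codon_counts(c(GCT = 1, GCC = 4))  # family RSCUs (for 4-fold Ala): 0 handled below
  # two-codon family: Lys AAA/AAG with RSCUs 0.4 / 1.6
  t2 <- codon_counts(c(AAA = 1, AAG = 4))
  w <- suppressWarnings(reference_weights(t2, w_floor = NA))
  expect_equal(unname(w[["AAA"]]), 0.25)
  expect_equal(unname(w[["AAG"]]), 1)

  uni <- suppressWarnings(reference_weights(
    codon_counts(c(AAA = 3, AAG = 3)), w_floor = NA))
  expect_equal(unname(uni[c("AAA", "AAG")]), c(1, 1))

  # single observed codon: w = 1, the rest excluded (NA) with a warning
  expect_warning(w1 <- reference_weights(codon_counts(c(GCC = 3)), w_floor = NA),
                 "excluded")
  expect_equal(unname(w1[["GCC"]]), 1)
  expect_true(all(is.na(w1[c("GCA", "GCT", "GCG")])))

  # default flooring policy
  expect_warning(wf <- reference_weights(codon_counts(c(GCC = 3))), "floored")
  expect_equal(unname(wf[["GCA"]]), 0.01)
})

test_that("CAI is the geometric mean of weights, skipping undefined codons", {
  ref <- codon_counts(setNames(rep(10L, length(SC59)), SC59))
  w <- reference_weights(ref)          # all 1 under uniform reference
  g <- codon_counts(c(GCA = 3, AAA = 2))
  expect_equal(cai(g, w)$value, 1)

  w2 <- setNames(rep(NA_real_, length(SC59)), SC59)
  w2[c("AAA", "AAG")] <- c(0.25, 1)
  res <- cai(codon_counts(c(AAA = 1, AAG = 1)), w2)
  expect_equal(res$value, 0.5)
  expect_equal(res$codons_used, 2)

  # gene containing a weight-undefined codon: skipped, reflected in codons_used
  res2 <- cai(codon_counts(c(AAA = 1, AAG = 1, GCA = 5)), w2)
  expect_equal(res2$value, 0.5)
  expect_equal(res2$codons_used, 2)

  expect_error(cai(codon_counts(c(GCA = 5)), w2), "no synonymous codon")

  # scale invariance: duplicating every codon leaves CAI unchanged
  g3 <- codon_counts(c(AAA = 3, AAG = 1))
  g6 <- codon_counts(c(AAA = 6, AAG = 2))
  expect_equal(cai(g3, w2)$value, cai(g6, w2)$value)
})

test_that("Wright's family homozygosity matches the corrected formula", {
  expect_equal(scubr:::family_homozygosity(c(3, 1)),
               (4 * (9 / 16 + 1 / 16) - 1) / 3)  # = 0.5
  expect_equal(scubr:::family_homozygosity(c(3, 1)), 0.5)
  expect_true(is.na(scubr:::family_homozygosity(c(1, 0))))
})

test_that("ENC attains its analytic limits and decreases with bias", {
  uniform <- codon_counts(setNames(rep(100L, length(SC59)), SC59))
  expect_equal(enc(uniform), 61)

  fams <- split(SC59, Biostrings::GENETIC_CODE[SC59])
  one_per_fam <- codon_counts(setNames(
    rep(50L, length(fams)), vapply(fams, `[`, character(1), 1)))
  expect_equal(enc(one_per_fam), 20)

  # tilting the two-fold families monotonically decreases ENC
  base <- setNames(rep(100L, length(SC59)), SC59)
  twofold <- fams[vapply(fams, length, integer(1)) == 2]
  prev <- enc(codon_counts(base))
  for (shift in c(20L, 50L, 80L)) {
    x <- base
    for (fam in twofold) {
      x[fam[1]] <- 100L + shift
      x[fam[2]] <- 100L - shift
    }
    cur <- enc(codon_counts(x))
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("per-aa ratios agree with a brute-force recount over raw CDS strings", {
  set.seed(9)
  recs <- lapply(1:10, function(i) {
    make_record(paste0("ATG", paste0(sample(SC59, 50, TRUE), collapse = ""), "TAA"),
                gene_id = paste0("g", i))
  })
  t <- count_codons(recs)
  r <- per_aa_scub_ratio(t)
  raw <- unlist(lapply(recs, function(x) codons_of(x$cds_sequence)))
  raw_sc <- raw[raw %in% SC59]
  aa <- Biostrings::GENETIC_CODE[raw_sc]
  third <- substr(raw_sc, 3, 3)
  for (a in unique(aa)) {
    cg <- sum(aa == a & third %in% c("C", "G"))
    at <- sum(aa == a & third %in% c("A", "T"))
    if (at > 0) expect_equal(unname(r[[a]]), cg / at)
  }
})

test_that("gc3s is the C/G-ending fraction of synonymous codons", {
  t <- codon_counts(c(GCA = 1, GCT = 2, GCC = 3, GCG = 4))
  expect_equal(gc3s(t), 0.7)
  expect_true(is.na(gc3s(codon_counts())))
})
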