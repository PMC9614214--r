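# Fixture builders shared across test files. Everything is generated in code;
# no stored data files.

ALL64 <- sort(names(Biostrings::GENETIC_CODE))
STOPS <- c("TAA", "TAG", "TGA")
SC59 <- setdiff(ALL64, c("ATG", "TGG", STOPS))

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(id) {
    c(paste0(">", id), seqs[[id]])
  })), path)
  path
}

write_gff3 <- function(rows, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", rows), path)
  path
}

gff_row <- function(seqid, type, start, end, strand, attrs, phase = ".") {
  paste(seqid, "test", type, start, end, ".", strand, phase, attrs, sep = "\t")
}

# A minimal accepted record built directly (bypassing file I/O) for unit
# tests of counting and stratification.
make_record <- function(seq, seg = nchar(seq), gene_id = "g1",
                        status = "accepted") {
  r <- structure(
    list(gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
         species_label = "test", chromosome = "chr1A", strand = "+",
         subgenome = "A", cds_sequence = seq,
         segment_lengths = as.integer(seg), codon_exon_index = NULL,
         status = status, reason = NA_character_),
    class = "cds_record")
  if (identical(status, "accepted")) r <- assign_codons_to_exons(r)
  r
}

# Split a CDS string into codons without using package internals.
codons_of <- function(seq) {
  starts <- seq(1, nchar(seq) - 2, by = 3)
  substring(seq, starts, starts + 2)
}

counts_from_codons <- function(codons) {
  tab <- table(factor(codons, levels = ALL64))
  codon_counts(setNames(as.integer(tab), ALL64))
}

# Independent junction recount: last base T/C of a synonymous codon followed
# by a non-stop codon, keyed by (last base | first base of next).
recount_junctions <- function(codon_list) {
  m <- matrix(0L, 2, 4, dimnames = list(c("NT", "NC"), c("A", "C", "G", "T")))
  for (codons in codon_list) {
    n <- length(codons)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      lb <- substr(codons[i], 3, 3)
      if (!(codons[i] %in% SC59) || !(lb %in% c("T", "C"))) next
      if (codons[i + 1] %in% STOPS) next
      fb <- substr(codons[i + 1], 1, 1)
      row <- if (lb == "T") "NT" else "NC"
      m[row, fb] <- m[row, fb] + 1L
    }
  }
  m
}

# Independent second-position recount over a codon vector.
recount_second_position <- function(codons) {
  sc <- codons[codons %in% SC59]
  m <- matrix(0L, 2, 4, dimnames = list(c("NXA", "NXG"), c("A", "C", "G", "T")))
  for (b in colnames(m)) {
    m["NXA", b] <- sum(substr(sc, 2, 2) == b & substr(sc, 3, 3) == "A")
    m["NXG", b] <- sum(substr(sc, 2, 2) == b & substr(sc, 3, 3) == "G")
  }
  m
}
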