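## Genome and annotation input: FASTA reading, GFF3 transcript models,
## CDS assembly, filtering and codon-to-exon attribution.

#' Read a genome FASTA file
#'
#' Loads all records of a (multi-)FASTA file as a `DNAStringSet`. Sequence
#' identifiers are trimmed at the first whitespace; lowercase bases are
#' normalised to uppercase.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] with unique identifiers.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  dup <- unique(names(genome)[duplicated(names(genome))])
  if (length(dup) > 0) {
    stop("duplicate sequence identifier(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  genome
}

#' A transcript model
#'
#' One mRNA with its CDS segments in 5'-to-3' (transcript) order: ascending
#' genomic coordinates on `+`, descending on `-`. Coordinates are GFF3-style
#' 1-based inclusive.
#'
#' @param gene_id,transcript_id,seq_id,strand,file_rank scalar fields.
#' @param cds_segments two-column matrix (`start`, `end`), one row per segment.
#' @return an object of class `transcript_model`.
#' @keywords internal
transcript_model <- function(gene_id, transcript_id, seq_id, strand,
                             cds_segments, file_rank) {
  stopifnot(strand %in% c("+", "-"))
  o <- order(cds_segments[, 1L], decreasing = (strand == "-"))
  cds_segments <- cds_segments[o, , drop = FALSE]
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, seq_id = seq_id,
         strand = strand, cds_segments = cds_segments, file_rank = file_rank),
    class = "transcript_model"
  )
}

#' Read a GFF3 annotation into transcript models grouped by gene
#'
#' Parses gene/mRNA/CDS features, attaches CDS segments to their transcript
#' via the `Parent` attribute, and groups transcripts by gene. CDS features
#' whose `Parent` points at a gene rather than an mRNA (annotations without
#' explicit transcript features) form a single gene-level transcript. CDS
#' features with an unresolvable `Parent` are skipped with a warning and
#' recorded in the `rejects` attribute.
#'
#' @param path path to a GFF3 file.
#' @return named list (by gene id); each element a list of `transcript_model`s
#'   ordered by file rank. Attribute `rejects` holds a data.frame of skipped
#'   CDS features.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gff))) {
    as.character(gff$ID)
  } else {
    rep(NA_character_, length(gff))
  }

  mrna_rows <- which(type %in% c("mRNA", "transcript"))
  gene_rows <- which(type == "gene")
  cds_rows <- which(type == "CDS")

  mrna_id <- ids[mrna_rows]
  gene_id_of_mrna <- vapply(gff$Parent[mrna_rows], function(p) {
    if (length(p) == 0) NA_character_ else p[[1L]]
  }, character(1))
  mrna_rank <- seq_along(mrna_rows)      # order of first appearance in file
  names(mrna_rank) <- mrna_id
  names(gene_id_of_mrna) <- mrna_id

  gene_ids <- ids[gene_rows]
  gene_rank <- seq_along(gene_rows) + length(mrna_rows) # gene-level CDS after
  names(gene_rank) <- gene_ids

  all_start <- GenomicRanges::start(gff)
  all_end <- GenomicRanges::end(gff)
  all_seqid <- as.character(GenomicRanges::seqnames(gff))
  all_strand <- as.character(GenomicRanges::strand(gff))

  rejects <- data.frame(parent = character(0), reason = character(0))
  seg_parent <- character(0); seg_row <- integer(0)
  if (length(cds_rows) > 0) {
    pl <- as.list(gff$Parent[cds_rows])
    pl[lengths(pl) == 0] <- NA_character_
    parent_vec <- unlist(pl, use.names = FALSE)
    row_vec <- rep(cds_rows, lengths(pl))
    ok <- !is.na(parent_vec) & (parent_vec %in% mrna_id | parent_vec %in% gene_ids)
    if (any(!ok)) {
      bad <- parent_vec[!ok]
      bad[is.na(bad)] <- "<none>"
      rejects <- data.frame(parent = bad, reason = "unresolved_parent")
      warning(sum(!ok), " CDS feature(s) skipped: unresolvable Parent (",
              paste(unique(bad), collapse = ", "), ")")
    }
    seg_parent <- parent_vec[ok]
    seg_row <- row_vec[ok]
  }

  idx_by_parent <- split(seg_row, seg_parent)
  models <- lapply(names(idx_by_parent), function(p) {
    rows <- idx_by_parent[[p]]
    if (p %in% mrna_id) {
      gid <- gene_id_of_mrna[[p]]
      rank <- mrna_rank[[p]]
    } else {
      gid <- p
      rank <- gene_rank[[p]]
      message("gene-level CDS treated as single transcript for gene ", p)
    }
    transcript_model(
      gene_id = gid, transcript_id = p,
      seq_id = all_seqid[rows[1L]], strand = all_strand[rows[1L]],
      cds_segments = cbind(start = all_start[rows], end = all_end[rows]),
      file_rank = rank
    )
  })

  by_gene <- split(models, vapply(models, `[[`, character(1), "gene_id"))
  by_gene <- lapply(by_gene, function(ts) {
    ts[order(vapply(ts, `[[`, numeric(1), "file_rank"))]
  })
  attr(by_gene, "rejects") <- rejects
  by_gene
}

#' Select the primary transcript of a gene
#'
#' The transcript appearing first in the annotation file; ties (which cannot
#' arise from a single well-formed file) broken by lexicographic transcript id
#' for determinism.
#'
#' @param transcripts list of `transcript_model`s for one gene.
#' @return a single `transcript_model`.
#' @export
select_primary_transcript <- function(transcripts) {
  stopifnot(length(transcripts) >= 1)
  ranks <- vapply(transcripts, `[[`, numeric(1), "file_rank")
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  transcripts[[order(ranks, ids)[1L]]]
}

#' Construct a CDS record
#' @keywords internal
cds_record <- function(gene_id, transcript_id, species_label = NA_character_,
                       chromosome = NA_character_, strand = "+",
                       subgenome = "unassigned", cds_sequence = "",
                       segment_lengths = integer(0),
                       codon_exon_index = NULL,
                       status = NA_character_, reason = NA_character_) {
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id,
         species_label = species_label, chromosome = chromosome,
         strand = strand, subgenome = subgenome,
         cds_sequence = cds_sequence, segment_lengths = segment_lengths,
         codon_exon_index = codon_exon_index,
         status = status, reason = reason),
    class = "cds_record"
  )
}

#' @export
print.cds_record <- function(x, ...) {
  cat("<cds_record> ", x$gene_id, " (", x$transcript_id, ") ",
      nchar(x$cds_sequence), " nt, ", length(x$segment_lengths), " exon(s), ",
      "status: ", ifelse(is.na(x$status), "unset", x$status),
      ifelse(is.na(x$reason), "", paste0(" [", x$reason, "]")), "\n", sep = "")
  invisible(x)
}

#' Assemble a transcript's coding sequence from the genome
#'
#' Concatenates the CDS segments in 5'-to-3' order; on the minus strand each
#' segment is reverse-complemented. Segment lengths are recorded in transcript
#' order. A segment outside its chromosome yields a record rejected with
#' reason `"coords"`.
#'
#' @param transcript a `transcript_model`.
#' @param genome a [Biostrings::DNAStringSet] (from [read_genome()]) or a
#'   named character vector of chromosome sequences.
#' @param species_label optional label carried through to outputs.
#' @param subgenome_rule passed to [assign_subgenome()].
#' @return a `cds_record` with `status` unset (or `"rejected"` on bad coords).
#' @export
assemble_cds <- function(transcript, genome, species_label = NA_character_,
                         subgenome_rule = NULL) {
  t <- transcript
  rec <- cds_record(
    gene_id = t$gene_id, transcript_id = t$transcript_id,
    species_label = species_label, chromosome = t$seq_id, strand = t$strand,
    subgenome = assign_subgenome(t$seq_id, subgenome_rule)
  )
  if (!t$seq_id %in% names(genome)) {
    rec$status <- "rejected"; rec$reason <- "coords"
    return(rec)
  }
  segs <- t$cds_segments
  chrom_len <- if (is.character(genome)) {
    nchar(genome[[t$seq_id]])
  } else {
    length(genome[[t$seq_id]])
  }
  if (any(segs[, 1L] < 1L) || any(segs[, 2L] > chrom_len) ||
      any(segs[, 2L] < segs[, 1L])) {
    rec$status <- "rejected"; rec$reason <- "coords"
    return(rec)
  }
  if (is.character(genome)) {
    asc <- segs[order(segs[, 1L]), , drop = FALSE]
    cds <- paste0(substring(genome[[t$seq_id]], asc[, 1L], asc[, 2L]),
                  collapse = "")
    if (t$strand == "-") cds <- revcomp_chr(cds)
    rec$cds_sequence <- toupper(cds)
  } else {
    at <- IRanges::IRanges(start = segs[, 1L], end = segs[, 2L])
    pieces <- Biostrings::extractAt(genome[[t$seq_id]], at)
    if (t$strand == "-") pieces <- Biostrings::reverseComplement(pieces)
    rec$cds_sequence <- toupper(paste0(as.character(pieces), collapse = ""))
  }
  rec$segment_lengths <- as.integer(segs[, 2L] - segs[, 1L] + 1L)
  rec
}

## plain-character reverse complement (IUPAC-aware for the common letters)
revcomp_chr <- function(s) {
  chartr("ACGTRYKMacgtrykm", "TGCAYRMKtgcayrmk",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

#' Apply the CDS acceptance filters
#'
#' A coding sequence is accepted iff its length is a multiple of 3, it
#' contains no ambiguity letter, it starts with ATG and its final codon is one
#' of TAA/TAG/TGA. Rejection records the first failing rule, in that order;
#' the reason distinguishes `N` from other IUPAC ambiguity letters. Internal
#' stop codons are not a rejection: they are simply counted as stop codons
#' downstream (and stops never enter the 59-SC statistics).
#'
#' @param record a `cds_record` from [assemble_cds()].
#' @return the record with `status` (and `reason` if rejected) set. Idempotent.
#' @export
filter_cds <- function(record) {
  r <- record
  if (identical(r$status, "rejected") && identical(r$reason, "coords")) return(r)
  seq <- r$cds_sequence
  n <- nchar(seq)
  reason <- NULL
  if (n == 0L || n %% 3L != 0L) {
    reason <- "length"
  } else if (grepl("[^ACGT]", seq)) {
    reason <- if (grepl("N", seq)) "ambiguous_base_N" else "ambiguous_base"
  } else if (substr(seq, 1L, 3L) != "ATG") {
    reason <- "start_codon"
  } else if (!substr(seq, n - 2L, n) %in% STOP_CODONS) {
    reason <- "stop_codon"
  }
  if (is.null(reason)) {
    r$status <- "accepted"; r$reason <- NA_character_
  } else {
    r$status <- "rejected"; r$reason <- reason
  }
  r
}

#' Attribute each codon of an accepted CDS to an exon
#'
#' Codons wholly inside an exon belong to it. A codon interrupted by an intron
#' after its first nucleotide belongs to the downstream exon; interrupted
#' after its second nucleotide, to the upstream exon. Both cases (and the
#' degenerate codon spread over three exons) reduce to: a codon belongs to the
#' exon carrying its middle nucleotide.
#'
#' @param record an accepted `cds_record`.
#' @return the record with `codon_exon_index` set (one exon index per codon).
#' @export
assign_codons_to_exons <- function(record) {
  r <- record
  if (!identical(r$status, "accepted")) {
    stop("codon-to-exon assignment requires an accepted record (gene ",
         r$gene_id, ")")
  }
  n <- nchar(r$cds_sequence)
  if (sum(r$segment_lengths) != n) {
    stop("internal error: segment lengths inconsistent with CDS length for ",
         r$gene_id)
  }
  exon_of_nt <- rep.int(seq_along(r$segment_lengths), r$segment_lengths)
  r$codon_exon_index <- exon_of_nt[seq.int(2L, n, by = 3L)]
  r
}

#' Map a chromosome name to a subgenome
#'
#' Default rule: the trailing letter of a leading `chr?[1-7][ABD]` token
#' (`"3B"` -> B, `"chr1A"` -> A); anything else is `"unassigned"`.
#'
#' @param chromosome_name chromosome name(s).
#' @param rule optional regular expression with one capture group yielding the
#'   subgenome letter; `NULL` uses the default rule.
#' @return character vector over `{"A","B","D","unassigned"}`.
#' @export
assign_subgenome <- function(chromosome_name, rule = NULL) {
  if (is.null(rule)) rule <- "^(?:chr)?[1-7]([ABD])"
  m <- regmatches(chromosome_name,
                  regexec(rule, chromosome_name, perl = TRUE))
  vapply(m, function(g) {
    if (length(g) >= 2 && g[2L] %in% c("A", "B", "D")) g[2L] else "unassigned"
  }, character(1))
}

#' Extract, filter and exon-annotate all CDS of a genome
#'
#' End-to-end driver for one species: read FASTA + GFF3, pick the primary
#' transcript of every gene, assemble and filter its CDS, and attribute codons
#' to exons for the accepted records.
#'
#' @param fasta,gff3 file paths, or pass `genome=`/`annotation=` directly.
#' @param species_label label stored on every record.
#' @param subgenome_rule passed to [assign_subgenome()].
#' @param genome,annotation optional pre-loaded inputs overriding the paths.
#' @return list with `records` (accepted `cds_record`s, codon-exon index set),
#'   `rejected` (rejected records), and `funnel` (named counts: genes seen,
#'   transcripts selected, accepted, and rejections by reason).
#' @export
extract_cds_records <- function(fasta = NULL, gff3 = NULL,
                                species_label = NA_character_,
                                subgenome_rule = NULL,
                                genome = NULL, annotation = NULL) {
  if (is.null(genome)) genome <- read_genome(fasta)
  if (is.null(annotation)) annotation <- read_annotation(gff3)
  if (!is.character(genome)) genome <- as.character(genome)  # fast slicing
  accepted <- list()
  rejected <- list()
  for (gene in annotation) {
    t <- select_primary_transcript(gene)
    rec <- assemble_cds(t, genome, species_label = species_label,
                        subgenome_rule = subgenome_rule)
    rec <- filter_cds(rec)
    if (identical(rec$status, "accepted")) {
      accepted[[length(accepted) + 1L]] <- assign_codons_to_exons(rec)
    } else {
      rejected[[length(rejected) + 1L]] <- rec
    }
  }
  reasons <- vapply(rejected, `[[`, character(1), "reason")
  funnel <- c(
    genes_seen = length(annotation),
    transcripts_selected = length(annotation),
    accepted = length(accepted),
    table(factor(reasons, levels = c("length", "ambiguous_base_N",
                                     "ambiguous_base", "start_codon",
                                     "stop_codon", "coords")))
  )
  list(records = accepted, rejected = rejected, funnel = funnel)
}

#' Summarise accepted records as a table
#'
#' @param records list of accepted `cds_record`s.
#' @return data.frame: gene_id, transcript_id, chromosome, subgenome, n_exons,
#'   cds_length.
#' @export
cds_record_table <- function(records) {
  data.frame(
    gene_id = vapply(records, `[[`, character(1), "gene_id"),
    transcript_id = vapply(records, `[[`, character(1), "transcript_id"),
    chromosome = vapply(records, `[[`, character(1), "chromosome"),
    subgenome = vapply(records, `[[`, character(1), "subgenome"),
    n_exons = vapply(records, function(r) length(r$segment_lengths), integer(1)),
    cds_length = vapply(records, function(r) nchar(r$cds_sequence), integer(1)),
    row.names = NULL
  )
}
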