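## DNA-methylation context statistics. CpG-type methylation converts
## methylated cytosines to thymines: on the antisense strand this turns NCG
## codons into NCA (third-base G->A on the sense strand), on the sense strand
## it turns the C|G dinucleotide spanning a codon junction into T|G. The
## second-position NXA/NXG ratios and the junction NT|X/NC|X ratios are the
## sequence-level signatures of those two processes.

#' Second-position table of A- and G-ending synonymous codons
#'
#' Counts NXA and NXG (X = second base, over A/C/G/T) across the A-ending and
#' G-ending members of the 59 SCs. ATG and TGG are never included (they are
#' not SCs).
#'
#' @param t a `codon_counts` table.
#' @return object of class `second_position_table`: 2 x 4 integer matrix,
#'   rows `NXA`/`NXG`, columns the second base.
#' @export
second_position_counts <- function(t) {
  x <- unclass(t)
  third <- codon_third_base(SC_CODONS)
  second <- codon_second_base(SC_CODONS)
  m <- matrix(0L, nrow = 2, ncol = 4,
              dimnames = list(c("NXA", "NXG"), c("A", "C", "G", "T")))
  for (b in colnames(m)) {
    m["NXA", b] <- sum(x[SC_CODONS[third == "A" & second == b]])
    m["NXG", b] <- sum(x[SC_CODONS[third == "G" & second == b]])
  }
  structure(m, class = c("second_position_table", "matrix", "array"))
}

#' NXA/NXG ratios by second base
#'
#' @param s a `second_position_table`.
#' @return named numeric vector (X = A, C, G, T); `NA` where NXG = 0.
#' @export
nxa_nxg_ratios <- function(s) {
  vapply(colnames(s), function(b) {
    if (s["NXG", b] == 0) NA_real_ else s["NXA", b] / s["NXG", b]
  }, numeric(1))
}

## Junction tally shared by the genome-wide and per-stratum paths.
## `keep` optionally restricts to pairs whose *previous* codon satisfies it
## (a logical vector aligned with the pairs of one record).
junction_tally <- function(records, keep_fun = NULL) {
  m <- matrix(0L, nrow = 2, ncol = 4,
              dimnames = list(c("NT", "NC"), c("A", "C", "G", "T")))
  for (r in records) {
    codons <- split_codons(r$cds_sequence)
    n <- length(codons)
    if (n < 2) next
    prev <- codons[-n]
    nxt <- codons[-1]
    last_b <- codon_third_base(prev)
    elig <- (prev %in% SC_CODONS) & last_b %in% c("T", "C") &
      !(nxt %in% STOP_CODONS)
    if (!is.null(keep_fun)) elig <- elig & keep_fun(r)
    if (!any(elig)) next
    tab <- table(factor(last_b[elig], levels = c("T", "C")),
                 factor(codon_first_base(nxt)[elig],
                        levels = c("A", "C", "G", "T")))
    m <- m + rbind(NT = tab["T", ], NC = tab["C", ])
  }
  structure(m, class = c("junction_triplet_table", "matrix", "array"))
}

#' Junction triplet table (NT|X and NC|X) over adjacent codon pairs
#'
#' For every within-gene adjacent codon pair, the pair is tallied when the
#' previous codon is one of the 59 SCs ending in T or C and the next codon is
#' not a stop; the key is (last base of previous | first base of next).
#' Junctions are within-CDS: introns are spliced out, so exon boundaries do
#' not interrupt a pair.
#'
#' @param records accepted `cds_record`(s).
#' @return object of class `junction_triplet_table`: 2 x 4 integer matrix,
#'   rows `NT`/`NC`, columns the first base of the next codon.
#' @export
junction_triplet_counts <- function(records) {
  if (inherits(records, "cds_record")) records <- list(records)
  status <- vapply(records, `[[`, character(1), "status")
  if (any(status != "accepted")) stop("junction_triplet_counts: non-accepted record in stream")
  junction_tally(records)
}

#' NT|X / NC|X ratios by first base of the next codon
#'
#' @param j a `junction_triplet_table`.
#' @return named numeric vector (X = A, C, G, T); `NA` where NC|X = 0.
#' @export
ntx_ncx_ratios <- function(j) {
  vapply(colnames(j), function(b) {
    if (j["NC", b] == 0) NA_real_ else j["NT", b] / j["NC", b]
  }, numeric(1))
}

## The A/G-ending same-prefix codon pairs compared across amino acids.
AG_PAIRS <- list(
  Ala = list(A = "GCA", G = "GCG", group = "NCA/NCG"),
  Pro = list(A = "CCA", G = "CCG", group = "NCA/NCG"),
  Ser = list(A = "TCA", G = "TCG", group = "NCA/NCG"),
  Thr = list(A = "ACA", G = "ACG", group = "NCA/NCG"),
  Arg = list(A = c("CGA", "AGA"), G = c("CGG", "AGG"), group = "N(A/G/T)A/G"),
  Glu = list(A = "GAA", G = "GAG", group = "N(A/G/T)A/G"),
  Gly = list(A = "GGA", G = "GGG", group = "N(A/G/T)A/G"),
  Leu = list(A = c("TTA", "CTA"), G = c("TTG", "CTG"), group = "N(A/G/T)A/G"),
  Lys = list(A = "AAA", G = "AAG", group = "N(A/G/T)A/G"),
  Val = list(A = "GTA", G = "GTG", group = "N(A/G/T)A/G")
)

#' Per-amino-acid A-ending : G-ending ratios over same-prefix codon pairs
#'
#' For the ten amino acids with an A-ending and a G-ending codon sharing their
#' first two nucleotides: the ratio of A-ending to G-ending counts (Arg and
#' Leu pool their two such pairs). Amino acids whose second base is C
#' (Ala, Pro, Ser, Thr) form the `NCA/NCG` group — the direct CpG-deamination
#' context — the rest the `N(A/G/T)A/G` control group.
#'
#' @param t a `codon_counts` table.
#' @return data.frame: amino_acid, group, a_count, g_count, ratio (`NA` on
#'   zero G-ending count).
#' @export
per_aa_a_g_ratio <- function(t) {
  x <- unclass(t)
  do.call(rbind, lapply(names(AG_PAIRS), function(aa) {
    p <- AG_PAIRS[[aa]]
    a <- sum(x[p$A]); g <- sum(x[p$G])
    data.frame(amino_acid = aa, group = p$group,
               a_count = a, g_count = g,
               ratio = if (g == 0) NA_real_ else a / g,
               row.names = NULL)
  }))
}

#' Methylation-context tables per exon-count stratum and per exon position
#'
#' Composes the stratifications with the two context counts. A junction pair
#' is attributed to the exon of its *previous* codon for the per-position
#' tables. The `overflow` element (genes with more than `max_exons` exons)
#' completes the partition so stratum sums reproduce genome-wide tables.
#'
#' @param records accepted `cds_record`s with `codon_exon_index` set.
#' @param max_exons cap on stratified exon counts (default 10).
#' @return list with `by_exon_count` (per stratum: `second`, `junction`),
#'   `by_position` (`[[e]][[p]]`: `second`, `junction`), and `overflow`.
#' @export
methylation_by_strata <- function(records, max_exons = 10) {
  n_ex <- vapply(records, function(r) length(r$segment_lengths), integer(1))
  by_exon_count <- lapply(seq_len(max_exons), function(e) {
    recs <- records[n_ex == e]
    list(second = second_position_counts(count_codons(recs)),
         junction = junction_tally(recs))
  })
  names(by_exon_count) <- as.character(seq_len(max_exons))
  pos_matrix <- stratify_by_exon_position(records, max_exons)
  by_position <- lapply(seq_len(max_exons), function(e) {
    recs <- records[n_ex == e]
    lapply(seq_len(e), function(p) {
      list(
        second = second_position_counts(pos_matrix$cells[[e]][[p]]),
        junction = junction_tally(recs, keep_fun = function(r) {
          idx <- r$codon_exon_index
          idx[-length(idx)] == p      # exon of the previous codon
        })
      )
    })
  })
  over <- records[n_ex > max_exons]
  list(by_exon_count = by_exon_count,
       by_position = by_position,
       overflow = list(second = second_position_counts(count_codons(over)),
                       junction = junction_tally(over)))
}
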