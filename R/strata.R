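## Stratified codon counting: by exon count (1..max) and by exon position
## within genes, the tables behind the intron-number and exon-position curves.

#' Stratify codon counts by gene exon count
#'
#' Each gene contributes all of its codons to exactly one stratum, keyed by
#' the number of CDS-bearing exons of its selected transcript. Genes with more
#' than `max_exons` exons go to a separate `overflow` bucket (they remain in
#' genome-wide statistics but are excluded from the exon strata analyses).
#'
#' @param records accepted `cds_record`s with `codon_exon_index` set.
#' @param max_exons cap on the stratified exon counts (default 10).
#' @return object of class `exon_count_strata`: list with `strata` (named list
#'   `"1"`..`"max_exons"` of `codon_counts`) and `overflow` (a `codon_counts`).
#' @export
stratify_by_exon_count <- function(records, max_exons = 10) {
  n_ex <- vapply(records, function(r) length(r$segment_lengths), integer(1))
  strata <- lapply(seq_len(max_exons), function(e) {
    count_codons(records[n_ex == e], scope = paste0("exons=", e))
  })
  names(strata) <- as.character(seq_len(max_exons))
  overflow <- count_codons(records[n_ex > max_exons], scope = "exons>max")
  structure(list(strata = strata, overflow = overflow,
                 max_exons = max_exons),
            class = "exon_count_strata")
}

#' Stratify codon counts by (exon count, exon position)
#'
#' A codon of a gene with e exons (2 <= e <= `max_exons`) is tallied in cell
#' (e, p) where p is its exon index from the split-codon attribution rule.
#' Single-exon genes occupy cell (1, 1).
#'
#' @inheritParams stratify_by_exon_count
#' @return object of class `exon_position_matrix`: nested list
#'   `cells[[e]][[p]]` of `codon_counts` for e in 1..max_exons, p in 1..e.
#' @export
stratify_by_exon_position <- function(records, max_exons = 10) {
  n_ex <- vapply(records, function(r) length(r$segment_lengths), integer(1))
  cells <- lapply(seq_len(max_exons), function(e) {
    recs <- records[n_ex == e]
    codons <- unlist(lapply(recs, function(r) split_codons(r$cds_sequence)),
                     use.names = FALSE)
    idx <- unlist(lapply(recs, `[[`, "codon_exon_index"), use.names = FALSE)
    lapply(seq_len(e), function(p) {
      tab <- table(factor(codons[idx == p], levels = CODONS))
      codon_counts(stats::setNames(as.integer(tab), CODONS),
                   scope = paste0("exons=", e, ",pos=", p))
    })
  })
  structure(list(cells = cells, max_exons = max_exons),
            class = "exon_position_matrix")
}

#' SCUB profiles per stratum or per exon-position cell
#'
#' One row per non-empty cell, with the ending frequencies, pooled A/T and C/G
#' frequencies and both ratio orientations (the NNC/G : NNA/T series drives
#' the exon-position curves). Empty cells are reported with `NA`s.
#'
#' @param s an `exon_count_strata` or `exon_position_matrix`.
#' @return data.frame keyed by `exon_count` (and `position` for the matrix).
#' @export
stratum_profiles <- function(s) {
  profile_row <- function(t) {
    if (sc_total(t) == 0) {
      return(c(fNNA = NA, fNNT = NA, fNNC = NA, fNNG = NA,
               fNNAT = NA, fNNCG = NA, at_cg_ratio = NA, cg_at_ratio = NA,
               sc_total = 0))
    }
    p <- scub_profile(t)
    c(p$ending_freq, p$combined, at_cg_ratio = p$at_cg_ratio,
      cg_at_ratio = p$cg_at_ratio, sc_total = p$sc_total)
  }
  if (inherits(s, "exon_count_strata")) {
    rows <- t(vapply(s$strata, profile_row, numeric(9)))
    out <- data.frame(exon_count = as.integer(names(s$strata)), rows,
                      row.names = NULL)
    return(out)
  }
  if (inherits(s, "exon_position_matrix")) {
    out <- do.call(rbind, lapply(seq_along(s$cells), function(e) {
      do.call(rbind, lapply(seq_len(e), function(p) {
        data.frame(exon_count = e, position = p,
                   t(profile_row(s$cells[[e]][[p]])), row.names = NULL)
      }))
    }))
    return(out)
  }
  stop("stratum_profiles: unsupported input of class ",
       paste(class(s), collapse = "/"))
}

#' Sum all strata (plus overflow) back to a single table
#' @param s an `exon_count_strata` or `exon_position_matrix`.
#' @export
strata_total <- function(s) {
  if (inherits(s, "exon_count_strata")) {
    return(sum_codon_counts(c(s$strata, list(s$overflow)), scope = "total"))
  }
  if (inherits(s, "exon_position_matrix")) {
    return(sum_codon_counts(unlist(s$cells, recursive = FALSE),
                            scope = "total"))
  }
  stop("strata_total: unsupported input")
}
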