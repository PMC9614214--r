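## Codon counting and the SCUB statistics: frequencies, per-amino-acid
## C/G : A/T ending ratios, RSCU, CAI reference weights, CAI and Wright's
## effective number of codons.

#' Create an (empty) codon count table
#'
#' A named integer vector over the 64 codons in canonical alphabetical order,
#' with a `scope` attribute describing what was counted (species, subgenome,
#' stratum, gene, ...).
#'
#' @param counts named integer vector (missing codons filled with 0).
#' @param scope free-form scope descriptor.
#' @return object of class `codon_counts`.
#' @export
codon_counts <- function(counts = integer(0), scope = "") {
  x <- integer(length(CODONS))
  names(x) <- CODONS
  if (length(counts) > 0) {
    bad <- setdiff(names(counts), CODONS)
    if (length(bad) > 0) stop("unknown codon(s): ", paste(bad, collapse = ", "))
    if (any(counts < 0)) stop("codon counts must be non-negative")
    x[names(counts)] <- as.integer(counts)
  }
  structure(x, scope = scope, class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("<codon_counts> scope:", attr(x, "scope"),
      "| total:", sum(x), "| SC total:", sc_total(x), "\n")
  invisible(x)
}

#' Sum of counts over the 59 synonymous codons
#' @param t a `codon_counts` table.
#' @export
sc_total <- function(t) sum(unclass(t)[SC_CODONS])

#' Add codon count tables cell-wise
#' @param ... `codon_counts` tables.
#' @param scope scope of the sum.
#' @export
sum_codon_counts <- function(..., scope = "sum") {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "codon_counts")) tabs <- tabs[[1]]
  out <- integer(length(CODONS))
  for (t in tabs) out <- out + unclass(t)[CODONS]
  codon_counts(stats::setNames(out, CODONS), scope = scope)
}

#' Tally every in-frame codon of a set of accepted CDS records
#'
#' @param records list of accepted `cds_record`s (or a single record).
#' @param scope scope descriptor stored on the table.
#' @return a `codon_counts` table.
#' @export
count_codons <- function(records, scope = "") {
  if (inherits(records, "cds_record")) records <- list(records)
  status <- vapply(records, `[[`, character(1), "status")
  if (any(status != "accepted")) {
    stop("count_codons: stream contains non-accepted record(s): ",
         paste(vapply(records[status != "accepted"], `[[`, character(1),
                      "gene_id"), collapse = ", "))
  }
  if (length(records) == 0) return(codon_counts(scope = scope))
  all_codons <- unlist(lapply(records, function(r) split_codons(r$cds_sequence)),
                       use.names = FALSE)
  tab <- table(factor(all_codons, levels = CODONS))
  codon_counts(stats::setNames(as.integer(tab), CODONS), scope = scope)
}

#' Codon frequencies under a chosen universe
#'
#' `"all64"`: every codon over the grand total. `"nonstop61"`: the 61 non-stop
#' codons, each divided by the number of *all* codons (the denominator used
#' for whole-genome codon frequency). `"sc59"`: the 59 SCs over the SC total.
#'
#' @param t a `codon_counts` table.
#' @param scope_mode one of `"all64"`, `"nonstop61"`, `"sc59"`.
#' @return named numeric vector of frequencies over the selected codons; if
#'   the denominator is zero, a vector of `NA` with attribute
#'   `undefined = TRUE` (never a silent 0).
#' @export
codon_frequencies <- function(t, scope_mode = c("sc59", "nonstop61", "all64")) {
  scope_mode <- match.arg(scope_mode)
  x <- unclass(t)
  sel <- switch(scope_mode,
    all64 = CODONS,
    nonstop61 = setdiff(CODONS, STOP_CODONS),
    sc59 = SC_CODONS
  )
  denom <- switch(scope_mode,
    all64 = sum(x),
    nonstop61 = sum(x),          # "the number of all codons"
    sc59 = sum(x[SC_CODONS])
  )
  if (denom == 0) {
    out <- stats::setNames(rep(NA_real_, length(sel)), sel)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  x[sel] / denom
}

#' Per-amino-acid SCUB ratio (C/G-ending over A/T-ending)
#'
#' For each of the 18 amino acids with synonymous codons: the count of its
#' C/G-ending SCs divided by the count of its A/T-ending SCs. A zero
#' denominator yields `NA` (undefined), never 0.
#'
#' @param t a `codon_counts` table.
#' @return named numeric vector over the 18 amino acids (one-letter codes).
#' @export
per_aa_scub_ratio <- function(t) {
  x <- unclass(t)
  vapply(SC_FAMILIES, function(cods) {
    third <- codon_third_base(cods)
    cg <- sum(x[cods[third %in% c("C", "G")]])
    at <- sum(x[cods[third %in% c("A", "T")]])
    if (at == 0) NA_real_ else cg / at
  }, numeric(1))
}

#' SCUB profile of a count table
#'
#' Third-base ending frequencies of the 59 SCs (fNNA, fNNT, fNNC, fNNG over
#' the SC total), the pooled fNNA/T and fNNC/G, the A/T : C/G ratio and the
#' per-amino-acid C/G : A/T ratios.
#'
#' @param t a `codon_counts` table.
#' @return object of class `scub_profile` (a list).
#' @export
scub_profile <- function(t) {
  x <- unclass(t)
  sct <- sc_total(t)
  if (sct == 0) stop("scub_profile: SC total is zero for scope '",
                     attr(t, "scope"), "'")
  third <- codon_third_base(SC_CODONS)
  f <- vapply(c(A = "A", T = "T", C = "C", G = "G"), function(b) {
    sum(x[SC_CODONS[third == b]]) / sct
  }, numeric(1))
  at <- f[["A"]] + f[["T"]]
  cg <- f[["C"]] + f[["G"]]
  structure(
    list(scope = attr(t, "scope"),
         ending_freq = c(fNNA = f[["A"]], fNNT = f[["T"]],
                         fNNC = f[["C"]], fNNG = f[["G"]]),
         combined = c(fNNAT = at, fNNCG = cg),
         at_cg_ratio = if (cg > 0) at / cg else NA_real_,
         cg_at_ratio = if (at > 0) cg / at else NA_real_,
         per_aa_ratio = per_aa_scub_ratio(t),
         sc_total = sct),
    class = "scub_profile"
  )
}

#' @export
print.scub_profile <- function(x, ...) {
  cat("<scub_profile> scope:", x$scope, "| SC total:", x$sc_total, "\n")
  print(round(c(x$ending_freq, x$combined,
                `NNA/T:NNC/G` = x$at_cg_ratio), 4))
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c = observed count / (family total / family size): the
#' observed frequency over the expected frequency were all codons of the
#' amino acid used equally. Families with zero total get `NA`.
#'
#' @param t a `codon_counts` table.
#' @return named numeric vector over the 59 SCs.
#' @export
rscu <- function(t) {
  x <- unclass(t)
  out <- stats::setNames(rep(NA_real_, length(SC_CODONS)), SC_CODONS)
  for (fam in SC_FAMILIES) {
    tot <- sum(x[fam])
    if (tot > 0) out[fam] <- x[fam] / (tot / length(fam))
  }
  out
}

#' Relative adaptiveness weights for CAI
#'
#' Within each family, w = RSCU / max(RSCU), so the most-used codon of every
#' amino acid has w = 1. Codons unobserved in the reference (RSCU 0) inside a
#' nonzero family receive the floor `w_floor` (default 0.01, standard CAI
#' practice to avoid log(0)); set `w_floor = NA` to exclude them from CAI
#' instead. Families absent from the reference are undefined (`NA`).
#'
#' @param t reference `codon_counts` table.
#' @param w_floor weight assigned to reference-unobserved codons, or `NA`.
#' @return named numeric vector of weights over the 59 SCs.
#' @export
reference_weights <- function(t, w_floor = 0.01) {
  r <- rscu(t)
  w <- stats::setNames(rep(NA_real_, length(SC_CODONS)), SC_CODONS)
  floored <- character(0)
  for (fam in SC_FAMILIES) {
    if (all(is.na(r[fam]))) next
    m <- max(r[fam])
    w[fam] <- r[fam] / m
    zero <- fam[r[fam] == 0]
    if (length(zero) > 0) {
      w[zero] <- w_floor
      floored <- c(floored, zero)
    }
  }
  if (length(floored) > 0) {
    warning(length(floored), " reference-unobserved codon(s) ",
            if (is.na(w_floor)) "excluded from CAI" else
              paste0("floored to w = ", w_floor),
            ": ", paste(floored, collapse = ", "))
  }
  w
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of the relative adaptiveness w over the gene's synonymous
#' codon occurrences (ATG, TGG and stops never contribute). Codons with
#' undefined weight are skipped and reported via `codons_used`.
#'
#' @param gene a `codon_counts` table for one gene.
#' @param w weights from [reference_weights()].
#' @return list with `value` (the CAI) and `codons_used`.
#' @export
cai <- function(gene, w) {
  x <- unclass(gene)[SC_CODONS]
  usable <- !is.na(w[SC_CODONS]) & x > 0
  n_used <- sum(x[usable])
  if (n_used == 0) stop("cai: gene has no synonymous codon with defined weight")
  value <- exp(sum(x[usable] * log(w[SC_CODONS][usable])) / n_used)
  list(value = value, codons_used = n_used)
}

#' Corrected homozygosity of one codon family (Wright's F)
#'
#' F = (n * sum(p_i^2) - 1) / (n - 1) over the family's codon proportions;
#' `NA` when fewer than 2 occurrences.
#'
#' @param counts integer counts of one family's codons.
#' @keywords internal
family_homozygosity <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Wright's effective number of codons
#'
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, with Fk the mean over each
#' k-fold-degenerate family of the corrected homozygosity
#' F = (n * sum(p_i^2) - 1) / (n - 1). Families with fewer than 2 codon
#' occurrences or F <= 0 are excluded from their class mean; a missing 3-fold
#' class mean falls back to the average of the 2- and 4-fold means. The result
#' is capped at 61 so that exactly uniform usage attains the no-bias limit;
#' exclusive use of one codon per family gives 20.
#'
#' @param t a `codon_counts` table.
#' @return ENC value in `[20, 61]` (or `NA` with a warning if a required
#'   degeneracy class is wholly undefined).
#' @export
enc <- function(t) {
  x <- unclass(t)
  fam_F <- vapply(SC_FAMILIES, function(cods) {
    family_homozygosity(x[cods])
  }, numeric(1))
  fam_F[!is.na(fam_F) & fam_F <= 0] <- NA_real_
  deg <- vapply(SC_FAMILIES, length, integer(1))
  class_mean <- vapply(c(`2` = 2L, `3` = 3L, `4` = 4L, `6` = 6L), function(k) {
    v <- fam_F[deg == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (is.na(class_mean[["3"]]) &&
      !is.na(class_mean[["2"]]) && !is.na(class_mean[["4"]])) {
    class_mean[["3"]] <- (class_mean[["2"]] + class_mean[["4"]]) / 2
  }
  if (anyNA(class_mean)) {
    warning("enc: degeneracy class(es) ",
            paste(names(class_mean)[is.na(class_mean)], collapse = ", "),
            " wholly undefined; returning NA")
    return(NA_real_)
  }
  val <- 2 + 9 / class_mean[["2"]] + 1 / class_mean[["3"]] +
    5 / class_mean[["4"]] + 3 / class_mean[["6"]]
  min(val, 61)
}

#' GC content at the third position of synonymous codons
#'
#' @param t a `codon_counts` table.
#' @return fraction of SC occurrences ending in G or C (`NA` if SC total 0).
#' @export
gc3s <- function(t) {
  x <- unclass(t)
  sct <- sc_total(t)
  if (sct == 0) return(NA_real_)
  third <- codon_third_base(SC_CODONS)
  sum(x[SC_CODONS[third %in% c("G", "C")]]) / sct
}
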