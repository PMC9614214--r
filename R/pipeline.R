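## End-to-end orchestration: per-species extraction and counting, strata,
## methylation contexts, cross-species comparative statistics and ordination,
## with optional TSV outputs.

#' Run the full codon-usage pipeline over one or more species
#'
#' Each species entry is either a list with `label`, `fasta`, `gff3` (+
#' optional `subgenome_rule`) or an in-memory `scub_simulation` (written to a
#' temporary directory and read back through the standard file path, so the
#' whole I/O chain is exercised).
#'
#' @param species list of species entries (see above).
#' @param out_dir optional directory for TSV outputs.
#' @param max_exons strata cap (default 10).
#' @param alpha significance level for letter displays (default 0.05).
#' @param ortholog_table optional data.frame (`group_id`, `species_label`,
#'   `gene_id`) restricting counting to complete ortholog groups.
#' @return list of class `scub_report`: per-species `records`, `funnel`,
#'   `counts` (genome-wide `codon_counts`), `by_subgenome`, `profile`,
#'   `strata`, `positions`, `methylation`, `rscu`, `enc`; cross-species
#'   `comparisons` (ending-count partitioning letters, per-codon RSCU CVs,
#'   pairwise Pearson correlations of per-amino-acid ratios) and `ordination`
#'   (clustering + PCA on SC frequencies) when 2+ species are supplied.
#' @export
run_pipeline <- function(species, out_dir = NULL, max_exons = 10,
                         alpha = 0.05, ortholog_table = NULL) {
  per <- list()
  for (sp in species) {
    if (inherits(sp, "scub_simulation")) {
      paths <- write_simulation(sp, tempfile("scubr_sim_"))
      sp <- list(label = sp$label, fasta = paths[["fasta"]],
                 gff3 = paths[["gff3"]])
    }
    ex <- extract_cds_records(sp$fasta, sp$gff3, species_label = sp$label,
                              subgenome_rule = sp$subgenome_rule)
    per[[sp$label]] <- ex
  }
  if (!is.null(ortholog_table)) {
    recs <- restrict_to_orthologs(lapply(per, `[[`, "records"), ortholog_table)
    for (lab in names(per)) per[[lab]]$records <- recs[[lab]]
  }

  species_results <- lapply(names(per), function(lab) {
    recs <- per[[lab]]$records
    counts <- count_codons(recs, scope = lab)
    sub <- vapply(recs, `[[`, character(1), "subgenome")
    grouped <- split(recs, sub)
    by_subgenome <- stats::setNames(
      lapply(names(grouped), function(sg) {
        count_codons(grouped[[sg]], scope = paste0(lab, ":", sg))
      }),
      names(grouped))
    list(label = lab,
         records = recs,
         funnel = per[[lab]]$funnel,
         counts = counts,
         by_subgenome = by_subgenome,
         profile = if (sc_total(counts) > 0) scub_profile(counts) else NULL,
         strata = stratify_by_exon_count(recs, max_exons),
         positions = stratify_by_exon_position(recs, max_exons),
         methylation = list(
           second = second_position_counts(counts),
           junction = junction_triplet_counts(recs),
           by_strata = methylation_by_strata(recs, max_exons)
         ),
         rscu = rscu(counts),
         enc = enc(counts))
  })
  names(species_results) <- names(per)

  comparisons <- NULL
  ordination <- NULL
  if (length(species_results) >= 2) {
    ending <- t(vapply(species_results, function(s) {
      x <- unclass(s$counts)
      third <- codon_third_base(SC_CODONS)
      vapply(c(NNA = "A", NNT = "T", NNC = "C", NNG = "G"), function(b) {
        sum(x[SC_CODONS[third == b]])
      }, numeric(1))
    }, numeric(4)))
    rownames(ending) <- names(species_results)
    partition <- chisq_partition_pairwise(ending, alpha = alpha)

    rscu_mat <- do.call(rbind, lapply(species_results, `[[`, "rscu"))
    cv_per_codon <- apply(rscu_mat, 2, function(v) {
      if (anyNA(v) || mean(v) == 0) NA_real_ else stats::sd(v) / mean(v)
    })

    aa_ratio <- do.call(rbind, lapply(species_results, function(s) {
      per_aa_scub_ratio(s$counts)
    }))
    labs <- names(species_results)
    pearson <- matrix(NA_real_, length(labs), length(labs),
                      dimnames = list(labs, labs))
    diag(pearson) <- 1
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (i < j) {
        ok <- stats::complete.cases(aa_ratio[i, ], aa_ratio[j, ])
        r <- pearson_correlation(aa_ratio[i, ok], aa_ratio[j, ok])$r
        pearson[i, j] <- pearson[j, i] <- r
      }
    }
    comparisons <- list(ending_counts = ending, partition = partition,
                        rscu_cv = cv_per_codon, pearson_aa_ratio = pearson)

    freq_mat <- sc_feature_matrix(lapply(species_results, `[[`, "counts"),
                                  "frequency")
    ordination <- list(
      cluster = hierarchical_cluster(freq_mat),
      pca = tryCatch(pca_ordination(freq_mat),
                     error = function(e) {
                       warning("PCA skipped: ", conditionMessage(e))
                       NULL
                     })
    )
  }

  report <- structure(list(species = species_results,
                           comparisons = comparisons,
                           ordination = ordination,
                           max_exons = max_exons, alpha = alpha),
                      class = "scub_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Restrict records to complete ortholog groups
#'
#' Keeps, per species, only the genes listed in the ortholog table; groups
#' missing any of the supplied species are dropped entirely (with a warning),
#' so every retained group is represented in every species. Unknown gene ids
#' are warned about and skipped.
#'
#' @param records_by_species named list (species label -> list of
#'   `cds_record`s).
#' @param table data.frame with columns `group_id`, `species_label`,
#'   `gene_id`.
#' @return named list of filtered record lists, same names as the input.
#' @export
restrict_to_orthologs <- function(records_by_species, table) {
  stopifnot(all(c("group_id", "species_label", "gene_id") %in% names(table)))
  if (nrow(table) == 0) {
    warning("empty ortholog table: all species restricted to zero genes")
    return(lapply(records_by_species, function(x) list()))
  }
  known <- lapply(records_by_species, function(recs) {
    vapply(recs, `[[`, character(1), "gene_id")
  })
  in_scope <- table$species_label %in% names(records_by_species)
  tab <- table[in_scope, , drop = FALSE]
  unknown <- !mapply(function(sp, gid) gid %in% known[[sp]],
                     tab$species_label, tab$gene_id)
  if (any(unknown)) {
    warning("unknown gene id(s) in ortholog table skipped: ",
            paste(unique(tab$gene_id[unknown]), collapse = ", "))
    tab <- tab[!unknown, , drop = FALSE]
  }
  species_per_group <- tapply(tab$species_label, tab$group_id,
                              function(s) length(unique(s)))
  complete <- names(species_per_group)[
    species_per_group == length(records_by_species)]
  dropped <- setdiff(unique(tab$group_id), complete)
  if (length(dropped) > 0) {
    warning(length(dropped), " ortholog group(s) dropped (missing species): ",
            paste(dropped, collapse = ", "))
  }
  tab <- tab[tab$group_id %in% complete, , drop = FALSE]
  out <- lapply(names(records_by_species), function(sp) {
    keep <- tab$gene_id[tab$species_label == sp]
    recs <- records_by_species[[sp]]
    recs[vapply(recs, `[[`, character(1), "gene_id") %in% keep]
  })
  stats::setNames(out, names(records_by_species))
}

#' Write the pipeline report as TSV files
#'
#' Stable filenames; every table is re-derivable from the emitted codon
#' counts. Called by [run_pipeline()] when `out_dir` is given.
#'
#' @param report a `scub_report`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character(0)
  counts_df <- do.call(rbind, lapply(report$species, function(s) {
    data.frame(species = s$label, codon = CODONS,
               amino_acid = unname(CODON_AA[CODONS]),
               count = as.integer(unclass(s$counts)[CODONS]),
               rscu = unname(s$rscu[match(CODONS, names(s$rscu))]))
  }))
  files <- c(files, tsv(counts_df, "codon_counts.tsv"))

  strata_df <- do.call(rbind, lapply(report$species, function(s) {
    cbind(species = s$label, stratum_profiles(s$strata))
  }))
  files <- c(files, tsv(strata_df, "exon_count_profiles.tsv"))

  pos_df <- do.call(rbind, lapply(report$species, function(s) {
    cbind(species = s$label, stratum_profiles(s$positions))
  }))
  files <- c(files, tsv(pos_df, "exon_position_profiles.tsv"))

  meth_df <- do.call(rbind, lapply(report$species, function(s) {
    sec <- s$methylation$second
    jun <- s$methylation$junction
    data.frame(species = s$label,
               context = rep(c("NXA", "NXG", "NT|X", "NC|X"), each = 4),
               X = rep(colnames(sec), 4),
               count = c(sec["NXA", ], sec["NXG", ], jun["NT", ], jun["NC", ]))
  }))
  files <- c(files, tsv(meth_df, "methylation_contexts.tsv"))

  if (!is.null(report$comparisons)) {
    letters_df <- data.frame(
      species = rownames(report$comparisons$ending_counts),
      report$comparisons$ending_counts,
      letter = report$comparisons$partition$letters,
      row.names = NULL)
    files <- c(files, tsv(letters_df, "species_ending_letters.tsv"))
    files <- c(files, tsv(report$comparisons$partition$pairwise,
                          "species_pairwise_chisq.tsv"))
  }
  if (!is.null(report$ordination)) {
    writeLines(report$ordination$cluster$newick,
               file.path(out_dir, "cluster.nwk"))
    files <- c(files, file.path(out_dir, "cluster.nwk"))
    if (!is.null(report$ordination$pca)) {
      sc <- report$ordination$pca$scores
      files <- c(files, tsv(data.frame(species = rownames(sc), sc,
                                       row.names = NULL),
                            "pca_scores.tsv"))
    }
  }
  invisible(files)
}
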