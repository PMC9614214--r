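# Step 5: cross-species comparison and ordination. Chi-square partitioning
# of the third-base ending counts gives the letter display; per-codon RSCU
# CVs and pairwise Pearson correlations quantify divergence; UPGMA and PCA
# on the 59-SC frequency profiles order the cohort by its built-in bias
# grade (the synthetic analogue of ploidy).

source("analysis/00_cohort.R")
labels <- names(COHORT)
tables <- list()
for (label in labels) {
  recs <- readRDS(need(file.path(RECORD_DIR, paste0(label, ".rds")),
                       "02_extract_count.R"))
  tables[[label]] <- count_codons(recs, scope = label)
}

third <- substr(setdiff(sort(names(Biostrings::GENETIC_CODE)),
                        c("ATG", "TGG", "TAA", "TAG", "TGA")), 3, 3)
sc59 <- setdiff(sort(names(Biostrings::GENETIC_CODE)),
                c("ATG", "TGG", "TAA", "TAG", "TGA"))
ending <- t(vapply(tables, function(t) {
  x <- unclass(t)
  vapply(c(NNA = "A", NNT = "T", NNC = "C", NNG = "G"),
         function(b) sum(x[sc59[third == b]]), numeric(1))
}, numeric(4)))

part <- chisq_partition_pairwise(ending)
letters_df <- data.frame(species = rownames(ending), ending,
                         letter = part$letters, row.names = NULL)
write.table(letters_df, file.path(RESULTS_DIR, "ending_counts_letters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("overall chi-square:", round(part$overall$statistic, 1),
    "df", part$overall$df, "\n")
print(letters_df[, c("species", "letter")])

rscu_mat <- do.call(rbind, lapply(tables, rscu))
cv <- apply(rscu_mat, 2, function(v) sd(v) / mean(v))
write.table(data.frame(codon = colnames(rscu_mat), cv = cv),
            file.path(RESULTS_DIR, "rscu_cv.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("RSCU CV across species: median %.3f, max %.3f (%s)\n",
            median(cv, na.rm = TRUE), max(cv, na.rm = TRUE),
            colnames(rscu_mat)[which.max(cv)]))

aa_ratio <- do.call(rbind, lapply(tables, per_aa_scub_ratio))
cors <- outer(labels, labels, Vectorize(function(a, b) {
  pearson_correlation(aa_ratio[a, ], aa_ratio[b, ])$r
}))
dimnames(cors) <- list(labels, labels)
write.table(data.frame(species = labels, round(cors, 4)),
            file.path(RESULTS_DIR, "per_aa_ratio_pearson.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

fm <- sc_feature_matrix(tables, "frequency")
cl <- hierarchical_cluster(fm)
writeLines(cl$newick, file.path(RESULTS_DIR, "cluster.nwk"))
cat("UPGMA (similarity at merges:",
    paste(round(cl$similarity, 1), collapse = ", "), ")\n")
cat(cl$newick, "\n")

pc <- pca_ordination(fm, n_components = 3)
scores <- data.frame(species = rownames(pc$scores), pc$scores,
                     row.names = NULL)
write.table(scores, file.path(RESULTS_DIR, "pca_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("PC variance proportions:",
    paste(round(pc$proportions[1:3], 3), collapse = ", "), "\n")
print(scores)
cat("wrote ending_counts_letters.tsv, rscu_cv.tsv, per_aa_ratio_pearson.tsv,",
    "cluster.nwk, pca_scores.tsv\n")
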