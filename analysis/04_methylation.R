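# Step 4: CpG-deamination context statistics. The NCA/NCG and NT|G/NC|G
# ratios are the sequence signatures of antisense- and sense-strand
# methylation conversion; the moment estimator inverts NCA/NCG back to the
# generating conversion rate, which the manifest lets us check.

source("analysis/00_cohort.R")
manifest <- read.delim(need(file.path(RESULTS_DIR, "simulation_manifest.tsv"),
                            "01_simulate.R"))

rows <- list(); aa_rows <- list()
for (i in seq_len(nrow(manifest))) {
  label <- manifest$species[i]
  recs <- readRDS(need(file.path(RECORD_DIR, paste0(label, ".rds")),
                       "02_extract_count.R"))
  t <- count_codons(recs, scope = label)
  sec <- second_position_counts(t)
  jun <- junction_triplet_counts(recs)
  m_hat <- suppressWarnings(recover_conversion_rate(sec, cohort_config(label)))
  rows[[label]] <- data.frame(
    species = label,
    X = colnames(sec),
    NXA = sec["NXA", ], NXG = sec["NXG", ],
    nxa_nxg = nxa_nxg_ratios(sec),
    NTX = jun["NT", ], NCX = jun["NC", ],
    ntx_ncx = ntx_ncx_ratios(jun),
    m_anti_true = manifest$m_anti[i], m_anti_hat = m_hat)
  aa_rows[[label]] <- cbind(species = label, per_aa_a_g_ratio(t))
  cat(sprintf("%-18s NCA/NCG %.3f  NT|G/NC|G %.3f  m_anti %.2f -> %.3f\n",
              label, nxa_nxg_ratios(sec)[["C"]], ntx_ncx_ratios(jun)[["G"]],
              manifest$m_anti[i], m_hat))
}
write.table(do.call(rbind, rows),
            file.path(RESULTS_DIR, "methylation_contexts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, aa_rows),
            file.path(RESULTS_DIR, "per_aa_a_g_ratios.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote methylation_contexts.tsv and per_aa_a_g_ratios.tsv\n")
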