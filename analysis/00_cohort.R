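# Shared definition of the synthetic wheat-like cohort used by the numbered
# analysis scripts: five "species" emulating the ploidy series studied with
# real genomes — two diploid progenitors, two tetraploids, one hexaploid.
# The generator parameters encode the qualitative structure the real data
# show: C/G-ending codon bias strengthens with ploidy while the CpG
# deamination signature (NCA/NCG, NT|G/NC|G inflation) weakens, and interior
# exons carry an A/T tilt.
#
# Sourced by scripts 01-05; not a package file.

library(scubr)

chroms <- function(letters_) as.vector(outer(1:7, letters_, paste0))

COHORT <- list(
  urartu_AA = list(seed = 11, cg_odds = 1.30, m_anti = 0.50, m_sense = 0.50,
                   chromosomes = chroms("A")),
  tauschii_DD = list(seed = 12, cg_odds = 1.35, m_anti = 0.45, m_sense = 0.45,
                     chromosomes = chroms("D")),
  dicoccoides_AABB = list(seed = 13, cg_odds = 1.50, m_anti = 0.35,
                          m_sense = 0.35, chromosomes = chroms(c("A", "B"))),
  turgidum_AABB = list(seed = 14, cg_odds = 1.55, m_anti = 0.30,
                       m_sense = 0.30, chromosomes = chroms(c("A", "B"))),
  aestivum_AABBDD = list(seed = 15, cg_odds = 1.70, m_anti = 0.20,
                         m_sense = 0.20, chromosomes = chroms(c("A", "B", "D")))
)

cohort_config <- function(label) {
  p <- COHORT[[label]]
  simulation_config(seed = p$seed, n_genes = 200,
                    cg_odds = p$cg_odds, interior_tilt = 1.3,
                    m_anti = p$m_anti, m_sense = p$m_sense,
                    chromosomes = p$chromosomes, label = label)
}

GENOME_DIR <- "scratch/analysis/genomes"
RECORD_DIR <- "scratch/analysis/records"
RESULTS_DIR <- "results/analysis"

need <- function(path, script) {
  if (!file.exists(path)) {
    stop(path, " not found - run analysis/", script, " first", call. = FALSE)
  }
  path
}
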