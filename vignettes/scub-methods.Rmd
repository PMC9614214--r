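---
title: "Methods: codon usage bias, methylation context statistics and the synthetic-genome oracle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias, methylation context statistics and the synthetic-genome oracle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The statistical model

`scubr` studies synonymous codon usage bias (SCUB): the unequal use of the
59 codons (SCs) belonging to the 18 amino acids with two or more codons.
Because the wobble base of an SC is free of amino-acid constraint, its
composition integrates mutational pressure, selection on translation, and —
the focus here — the mutational footprint of CpG-type DNA methylation.
Methylated cytosine deaminates to thymine. On the antisense strand of a
codon whose second base is C, the CpG sits opposite the codon's third
position, so deamination converts NCG codons to NCA on the sense strand.
On the sense strand, a CpG spanning a codon junction (…C|G…) converts the
C-ending codon to its T-ending synonym. Both substitutions are synonymous
for every codon of the standard code (every XCA/XCG pair and every NNC/NNT
pair is same-family), which is why the two context ratios

* NXA/NXG by second base X (the NCA/NCG channel carries the antisense
  signal; NAA/NAG, NGA/NGG, NTA/NTG are controls), and
* NT|X/NC|X by first base X of the next codon (NT|G/NC|G carries the sense
  signal; X = A, C, T are controls)

isolate the methylation footprint from overall A/T–C/G composition.

## CDS extraction and filters

Coding sequences are assembled from genome FASTA plus GFF3: one transcript
per gene (the first by file order, ties broken by transcript id), CDS
segments concatenated 5′→3′ with reverse-complementation on the minus
strand. A CDS is accepted iff its length is a multiple of 3, it contains no
ambiguity letter, it starts with ATG and ends with TAA/TAG/TGA; the first
failing rule is recorded. Two deliberate choices:

* *All* IUPAC ambiguity letters reject, not only N, since any non-ACGT base
  makes codon classification undefined; the reason code distinguishes the
  two so the N-only accounting can still be reported.
* Internal stop codons do **not** reject. They are counted as stop codons
  and are outside the 59-SC universe, so they never contaminate the SCUB
  statistics; rejecting them would silently change the gene set under a
  filter the acceptance rules do not state.
* The GFF3 phase column is ignored; frame errors surface through the
  start/stop/length filters.

## The split-codon rule and exon strata

A codon interrupted by an intron after its first nucleotide belongs to the
downstream exon; after its second, to the upstream exon. Both cases, and
the degenerate codon cut by *two* introns (one nucleotide per exon, which a
uniform intron-placement model does produce), reduce to one rule used
throughout: **a codon belongs to the exon carrying its middle nucleotide**.

Genes are stratified by the number of CDS-bearing exons of the selected
transcript (UTR-only exons are invisible to a CDS-based analysis). Strata
run 1–10; genes with more exons stay in genome-wide statistics but go to an
overflow bucket excluded from the exon analyses, and both stratifications
conserve counts exactly (stratum sums equal the genome-wide table). For
position curves, "interior" means positions 2…e−1; junction pairs are
attributed to the exon of the previous codon.

## Indices

* **RSCU**: count / (family total / family size). Zero-total families are
  undefined (`NA`), never 0. Family means equal 1 by construction (checked
  to 1e−9).
* **CAI**: geometric mean of w = RSCU / family max over a gene's SC
  occurrences. No expression data are bundled, so the default reference is
  the whole-genome table; any user gene set can serve as the
  highly-expressed reference. Reference-unobserved codons get a floor
  w = 0.01 (standard practice to avoid log 0); `w_floor = NA` excludes them
  instead, and `codons_used` always reports the basis of the mean.
* **ENC**: 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆ with
  F = (n·Σp² − 1)/(n − 1) per family. Families with n < 2 or F ≤ 0 are
  excluded from their class mean; a wholly missing 3-fold class falls back
  to (F̄₂ + F̄₄)/2. The result is capped at 61: the corrected F̄ lies below
  its asymptotic 1/k under exactly uniform finite counts, and the cap makes
  the no-bias limit exact (maximal bias gives exactly 20 without any
  adjustment).
* Codon frequencies come in three universes: all 64 codons, the 61
  non-stop codons over the *total* codon count (the whole-genome frequency
  convention), and the 59 SCs over the SC total. Zero denominators
  propagate as explicit undefined values — silent zeros would bias CVs and
  correlations downstream.

## Comparative statistics

Pearson χ² without continuity correction for contingency tables; group
comparisons use χ² partitioning — every 2×k pairwise sub-table tested at a
single α (0.05 default, Bonferroni optional but off, matching how
partitioning letters are conventionally reported) — and a compact letter
display built by insert-and-absorb with groups processed in label order, so
letters are a deterministic function of the p-matrix. The t-test defaults
to Welch (it reduces to Student's exactly when variances and sizes are
equal); CV is sample sd over mean; Pearson r comes with its two-sided test.

## Ordination

Clustering is UPGMA over Euclidean distances on the 59-SC feature matrix
(frequencies or RSCU), with merge heights also expressed as similarities
100·(1 − d/d_max) and Newick serialisation. PCA is an eigendecomposition of
the correlation matrix by default — the original analyses sat behind
proprietary software defaults, and the correlation matrix is the scale-free
choice — with covariance available. Factor score coefficients are
eigenvectors scaled by 1/√λ (the weights taking standardised features to
unit-variance scores); the sign convention makes the largest-magnitude
loading of each component positive so output is backend-independent.

# The synthetic-genome generator

The generator is the package's ground-truth oracle: genes are built as
ATG + drawn SCs + stop, split across exons, placed on named chromosomes on
random strands, and written as standard FASTA + GFF3 alongside the pre- and
post-conversion truth. Its parameters, defaults chosen once as a realistic
desk-scale study condition:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 200 | genes per genome |
| `exon_count_probs` | uniform 1–10 | exon-count distribution |
| `codon_range` | 80–200 | body codons per gene (uniform) |
| `aa_probs` | uniform over 18 | amino-acid composition |
| `cg_odds` | 1 | within-family odds multiplier on C/G-ending codons |
| `interior_tilt` | 1 | A/T-ending odds multiplier in interior exons |
| `m_anti` | 0 | P(NCG → NCA), antisense CpG deamination |
| `m_sense` | 0 | P(C|G junction → T|G), sense CpG deamination |
| `intron_range` | 60–150 nt | intron lengths (uniform) |
| `spacer` | 80 nt | intergenic spacer |

Intron insertion points are uniform over inter-nucleotide positions of the
CDS, so both split-codon types (and the rare double cut) arise naturally.
Synonymy of every conversion is asserted at run time, not assumed. A single
stream is keyed by the seed with per-gene counter-derived substreams, so
gene i is byte-identical whatever `n_genes` is.

`expected_ratios()` gives the closed-form per-draw expectations — e.g.
E(NCA) = p(NCA) + m·p(NCG), E(NCG) = (1 − m)·p(NCG) — and
`recover_conversion_rate()` inverts them: with R the observed NCA/NCG and
R₀ the baseline, m̂ = (R − R₀)/(1 + R), clamped to [0, 1].

**What the generator does not emulate.** Codons are drawn i.i.d. given the
amino acid: there is no autocorrelation along genes, no GC landscape, no
gene-length/GC covariation, and no expression structure — real wheat
genomes have all of these. Passing the oracle tests therefore demonstrates
that the *counting machinery* is exact and the *estimators* consistent
under the stated model, not that the biological conclusions transfer; on
real data the context ratios remain descriptive statistics.

**A known estimator caveat.** The moment estimator's baseline R₀ comes from
the untilted family distributions. Under a positional A/T tilt
(`interior_tilt` > 1) the realised pre-conversion NCA/NCG already exceeds
R₀, so m̂ is biased upward (visible in the workflow's cohort, where tilted
genomes recover e.g. 0.35 for a true 0.30). Calibration runs therefore use
tilt-free configurations; estimates from tilted or real data should be read
as upper bounds under this baseline.

# Numerical conventions and degenerate inputs

* Undefined ratios (zero denominators) are `NA` with an explicit guard or
  warning, never 0; zero SC totals raise errors where a profile would be
  meaningless.
* Ending frequencies must sum to 1 within 1e−12; RSCU family means to 1
  within 1e−9; ordination eigen-solutions are checked against an
  independent SVD route at 1e−9.
* Ties: transcript selection falls back to lexicographic transcript id;
  letter display processes groups in label order; eigenvector signs follow
  the max-|loading| convention; UPGMA inherits `hclust`'s deterministic
  merge order.
* Junction pairs require the previous codon to be an SC ending T or C and
  the next codon to be a non-stop, keeping both junction rows inside the
  SC universe used everywhere else.

# Problem sizes

The test suite and verification script run entirely on generated data:
20 genomes of 200 genes for the exact pipeline-versus-truth recounts,
3 × 20 replicates of 2×10⁵ codon draws for rate recovery across
m ∈ {0, 0.2, 0.4} (recovery within ±0.02), 200-gene genomes with exon
counts 3–8 for the positional-tilt contrast (tilt 1.5 against a flat
control), and three 50-gene genomes with C/G odds 1, 1.5, 3 for the
ordination check. These sizes were chosen so every check rests on a few
thousand to a few million draws — enough that the stochastic checks are
decisively powered under the generator's known parameters.

# Limitations

* Ortholog detection (collinearity/BLAST) is external; the pipeline only
  consumes a precomputed group table and enforces group completeness.
* No tRNA adaptation index, codon-pair bias, Fop/CBI; no bisulfite data —
  methylation enters only through its sequence-context proxies.
* CAI without an expression-defined reference set measures adaptation
  toward the genome-wide consensus, which compresses its dynamic range
  relative to a highly-expressed reference.
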