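## Synthetic genomes with known codon-usage structure.
##
## Genes are built as ATG + drawn synonymous codons + stop, split across exons
## by uniformly drawn intron insertion points (so intron-interrupted codons of
## both split types arise naturally), with three controllable distortions:
##   * a within-family C/G-ending odds multiplier (`cg_odds`),
##   * an interior-exon A/T-ending odds multiplier (`interior_tilt`),
##   * CpG-deamination conversions: NCG -> NCA at rate `m_anti` (antisense
##     methylation) and C|G codon junctions -> T|G at rate `m_sense` (sense
##     methylation).
## Both conversions are synonymous for every codon of the standard code
## (XCA ~ XCG and NNC ~ NNT are always same-family), which is asserted at run
## time. A per-gene counter-derived seed keeps earlier genes stable when
## `n_genes` changes.

NCG_SET <- c("ACG", "CCG", "GCG", "TCG")

#' Configuration of the synthetic-genome generator
#'
#' @param seed integer seed (mandatory).
#' @param n_genes number of genes (default 200).
#' @param exon_count_probs probability vector over exon counts 1..E_max
#'   (default uniform over 1..10).
#' @param codon_range inclusive range of body codons per gene (default
#'   80..200, drawn uniformly).
#' @param aa_probs named probabilities over the 18 SC-bearing amino acids
#'   (default uniform).
#' @param cg_odds multiplier on the within-family odds of C/G-ending codons
#'   (default 1 = uniform within family).
#' @param family_probs optional explicit list (amino acid -> named codon
#'   probability vector) overriding `cg_odds`.
#' @param interior_tilt multiplier g on the A/T-ending odds of codons whose
#'   exon is interior (positions 2..e-1); default 1 (no tilt).
#' @param m_anti probability that an NCG codon is converted to NCA.
#' @param m_sense probability that a C-ending codon followed by a G-starting
#'   codon is converted to T-ending.
#' @param intron_range inclusive intron length range (default 60..150 nt).
#' @param spacer intergenic spacer length (default 80 nt).
#' @param chromosomes chromosome names to distribute genes over, round-robin
#'   (default `"chr1A"`; name pattern drives [assign_subgenome()]).
#' @param label species label written on outputs.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed, n_genes = 200,
                              exon_count_probs = rep(1 / 10, 10),
                              codon_range = c(80, 200),
                              aa_probs = NULL,
                              cg_odds = 1,
                              family_probs = NULL,
                              interior_tilt = 1,
                              m_anti = 0, m_sense = 0,
                              intron_range = c(60, 150),
                              spacer = 80,
                              chromosomes = "chr1A",
                              label = "sim") {
  if (missing(seed)) stop("simulation_config: seed is mandatory")
  if (is.null(aa_probs)) {
    aa_probs <- stats::setNames(rep(1, length(SC_FAMILIES)), names(SC_FAMILIES))
  }
  aa_probs <- aa_probs / sum(aa_probs)
  if (!setequal(names(aa_probs), names(SC_FAMILIES))) {
    stop("aa_probs must cover exactly the 18 SC-bearing amino acids")
  }
  stopifnot(all(exon_count_probs >= 0), sum(exon_count_probs) > 0,
            m_anti >= 0, m_anti <= 1, m_sense >= 0, m_sense <= 1,
            interior_tilt >= 0, cg_odds >= 0,
            codon_range[1] >= 2, codon_range[2] >= codon_range[1],
            intron_range[1] >= 1, intron_range[2] >= intron_range[1])
  cfg <- structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         exon_count_probs = exon_count_probs / sum(exon_count_probs),
         codon_range = as.integer(codon_range), aa_probs = aa_probs,
         cg_odds = cg_odds, family_probs = family_probs,
         interior_tilt = interior_tilt,
         m_anti = m_anti, m_sense = m_sense,
         intron_range = as.integer(intron_range), spacer = as.integer(spacer),
         chromosomes = chromosomes, label = label),
    class = "simulation_config"
  )
  # fail early on impossible family distributions
  fp <- sim_family_probs(cfg)
  if (any(vapply(fp, function(p) sum(p) <= 0, logical(1)))) {
    stop("simulation_config: a codon family has zero total probability")
  }
  cfg
}

## Per-family codon distributions implied by the config (no tilt applied).
sim_family_probs <- function(config) {
  if (!is.null(config$family_probs)) {
    fp <- lapply(names(SC_FAMILIES), function(aa) {
      p <- config$family_probs[[aa]]
      if (is.null(p)) stop("family_probs missing amino acid ", aa)
      p <- p[SC_FAMILIES[[aa]]]
      if (anyNA(p)) stop("family_probs for ", aa, " must name every family codon")
      p / sum(p)
    })
    names(fp) <- names(SC_FAMILIES)
    return(fp)
  }
  fp <- lapply(SC_FAMILIES, function(cods) {
    w <- ifelse(codon_third_base(cods) %in% c("C", "G"), config$cg_odds, 1)
    stats::setNames(w / sum(w), cods)
  })
  fp
}

## Marginal per-draw codon probabilities (baseline, no tilt): aa draw times
## within-family draw.
sim_codon_probs <- function(config, tilt = 1) {
  fp <- sim_family_probs(config)
  p <- stats::setNames(numeric(length(SC_CODONS)), SC_CODONS)
  for (aa in names(fp)) {
    q <- fp[[aa]]
    if (tilt != 1) {
      w <- ifelse(codon_third_base(names(q)) %in% c("A", "T"), tilt, 1)
      q <- q * w / sum(q * w)
    }
    p[names(q)] <- p[names(q)] + config$aa_probs[[aa]] * q
  }
  p
}

gene_seed <- function(seed, i) {
  (as.numeric(seed) + i * 1000003) %% 2147483629
}

## Draw body codons: amino acids from aa_probs, codons from the family
## distribution, with interior codons' A/T odds multiplied by the tilt.
draw_body_codons <- function(config, n, interior) {
  fp <- sim_family_probs(config)
  aa <- sample(names(fp), n, replace = TRUE, prob = unname(config$aa_probs[names(fp)]))
  out <- character(n)
  for (a in unique(aa)) {
    q <- fp[[a]]
    for (flag in unique(interior[aa == a])) {
      sel <- aa == a & interior == flag
      qq <- q
      if (flag && config$interior_tilt != 1) {
        w <- ifelse(codon_third_base(names(q)) %in% c("A", "T"),
                    config$interior_tilt, 1)
        qq <- q * w / sum(q * w)
      }
      out[sel] <- sample(names(qq), sum(sel), replace = TRUE, prob = qq)
    }
  }
  out
}

## Apply the two CpG-deamination conversions to a codon vector. Returns the
## converted vector plus event counts. Conversions target disjoint codon
## classes (third base G vs third base C), so order is immaterial.
apply_conversions <- function(codons, m_anti, m_sense) {
  post <- codons
  n_anti <- 0L; n_sense <- 0L
  if (m_anti > 0) {
    cand <- which(post %in% NCG_SET)
    hit <- cand[stats::runif(length(cand)) < m_anti]
    if (length(hit) > 0) {
      substr(post[hit], 3L, 3L) <- "A"
      n_anti <- length(hit)
    }
  }
  if (m_sense > 0 && length(post) >= 2) {
    ends_c <- codon_third_base(post) == "C"
    next_g <- c(codon_first_base(post)[-1] == "G", FALSE)
    cand <- which(ends_c & next_g)
    hit <- cand[stats::runif(length(cand)) < m_sense]
    if (length(hit) > 0) {
      substr(post[hit], 3L, 3L) <- "T"
      n_sense <- length(hit)
    }
  }
  if (!identical(translate_codons(codons), translate_codons(post))) {
    stop("internal error: a conversion was not synonymous")
  }
  list(post = post, n_anti = n_anti, n_sense = n_sense)
}

random_bases <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with known codon-usage structure
#'
#' Generates genes under `config`, splits them across exons with drawn intron
#' lengths, applies the CpG-deamination conversions, places the genes on
#' chromosomes (both strands) and returns the genome, a GFF3 annotation table
#' and the per-gene ground truth. Deterministic given the seed; per-gene
#' substreams mean gene i is identical whatever `n_genes` is.
#'
#' @param config a [simulation_config()].
#' @return object of class `scub_simulation`: `genome`
#'   ([Biostrings::DNAStringSet]), `gff` (data.frame of GFF3 columns),
#'   `truth` (per-gene list: pre/post codons, exon index, segment lengths,
#'   conversion counts), `config`, `label`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  e_max <- length(config$exon_count_probs)
  genes <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    set.seed(gene_seed(config$seed, i))
    e <- sample.int(e_max, 1, prob = config$exon_count_probs)
    n_body <- sample.int(config$codon_range[2] - config$codon_range[1] + 1L, 1) +
      config$codon_range[1] - 1L
    L <- 3L * (n_body + 2L)
    seg <- if (e > 1) {
      bp <- sort(sample.int(L - 1L, e - 1L))
      diff(c(0L, bp, L))
    } else L
    exon_of_nt <- rep.int(seq_len(e), seg)
    idx <- exon_of_nt[seq.int(2L, L, by = 3L)]
    body_idx <- idx[seq.int(2L, n_body + 1L)]
    interior <- body_idx >= 2L & body_idx <= e - 1L
    body <- draw_body_codons(config, n_body, interior)
    pre <- c("ATG", body, sample(STOP_CODONS, 1))
    conv <- apply_conversions(pre, config$m_anti, config$m_sense)
    introns <- if (e > 1) {
      vapply(seq_len(e - 1L), function(k) {
        random_bases(sample.int(config$intron_range[2] -
                                  config$intron_range[1] + 1L, 1) +
                       config$intron_range[1] - 1L)
      }, character(1))
    } else character(0)
    genes[[i]] <- list(
      gene_id = sprintf("%s_g%04d", config$label, i),
      exon_count = e, segment_lengths = seg,
      codon_exon_index = idx,
      pre_codons = pre, post_codons = conv$post,
      n_anti = conv$n_anti, n_sense = conv$n_sense,
      introns = introns,
      strand = sample(c("+", "-"), 1)
    )
  }

  # assemble chromosomes: spacer + gene + spacer + gene + ...
  set.seed(gene_seed(config$seed, 0L))
  chrom_of_gene <- rep_len(config$chromosomes, config$n_genes)
  chrom_seq <- stats::setNames(vector("list", length(config$chromosomes)),
                               config$chromosomes)
  for (ch in config$chromosomes) chrom_seq[[ch]] <- random_bases(config$spacer)
  gff <- list()
  truth <- list()
  for (i in seq_len(config$n_genes)) {
    g <- genes[[i]]
    ch <- chrom_of_gene[i]
    cds <- paste0(g$post_codons, collapse = "")
    # interleave exon segments and introns (sense orientation)
    seg_end <- cumsum(g$segment_lengths)
    seg_start <- seg_end - g$segment_lengths + 1L
    parts <- character(0)
    sense_pos <- matrix(0L, nrow = g$exon_count, ncol = 2)
    at <- 0L
    for (k in seq_len(g$exon_count)) {
      exon_seq <- substr(cds, seg_start[k], seg_end[k])
      sense_pos[k, ] <- c(at + 1L, at + nchar(exon_seq))
      parts <- c(parts, exon_seq)
      at <- at + nchar(exon_seq)
      if (k < g$exon_count) {
        parts <- c(parts, g$introns[k])
        at <- at + nchar(g$introns[k])
      }
    }
    pre_mrna <- paste0(parts, collapse = "")
    Lg <- nchar(pre_mrna)
    s <- nchar(chrom_seq[[ch]]) + 1L
    placed <- if (g$strand == "-") revcomp(pre_mrna) else pre_mrna
    chrom_seq[[ch]] <- paste0(chrom_seq[[ch]], placed, random_bases(config$spacer))
    genomic <- if (g$strand == "+") {
      cbind(s + sense_pos[, 1] - 1L, s + sense_pos[, 2] - 1L)
    } else {
      cbind(s + Lg - sense_pos[, 2], s + Lg - sense_pos[, 1])
    }
    tid <- paste0(g$gene_id, ".1")
    phase <- (3L - (c(0L, seg_end[-g$exon_count]) %% 3L)) %% 3L
    o <- order(genomic[, 1])
    gff[[length(gff) + 1L]] <- data.frame(
      seqid = ch, source = "scubr_sim",
      type = c("gene", "mRNA", rep("CDS", g$exon_count)),
      start = c(min(genomic), min(genomic), genomic[o, 1]),
      end = c(max(genomic), max(genomic), genomic[o, 2]),
      score = ".", strand = g$strand,
      phase = c(".", ".", as.character(phase[o])),
      attributes = c(
        paste0("ID=", g$gene_id),
        paste0("ID=", tid, ";Parent=", g$gene_id),
        paste0("ID=", tid, ".cds", seq_len(g$exon_count), ";Parent=", tid)[o]
      )
    )
    truth[[i]] <- c(g[c("gene_id", "exon_count", "segment_lengths",
                        "codon_exon_index", "pre_codons", "post_codons",
                        "n_anti", "n_sense", "strand")],
                    list(chromosome = ch))
  }
  genome <- Biostrings::DNAStringSet(vapply(chrom_seq, identity, character(1)))
  structure(list(genome = genome, gff = do.call(rbind, gff),
                 truth = truth, config = config, label = config$label),
            class = "scub_simulation")
}

#' Write a simulated genome as FASTA + GFF3
#'
#' @param sim a `scub_simulation`.
#' @param dir output directory (created if needed).
#' @param prefix file prefix (defaults to the simulation label).
#' @return named character vector: `fasta`, `gff3` paths.
#' @export
write_simulation <- function(sim, dir, prefix = sim$label) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  gff3 <- file.path(dir, paste0(prefix, ".gff3"))
  Biostrings::writeXStringSet(sim$genome, fasta)
  g <- sim$gff
  lines <- c("##gff-version 3",
             paste(g$seqid, g$source, g$type, g$start, g$end, g$score,
                   g$strand, g$phase, g$attributes, sep = "\t"))
  writeLines(lines, gff3)
  c(fasta = fasta, gff3 = gff3)
}

#' Draw a flat pool of synonymous codons under a config
#'
#' The gene-free simulator core: `n` body codons drawn from the config's
#' amino-acid and family distributions (no positional tilt), conversions
#' applied along the linear codon sequence. Used for calibration and rate
#' recovery at large n.
#'
#' @param config a [simulation_config()].
#' @param n number of codon draws.
#' @param seed seed (defaults to the config seed).
#' @return a `codon_counts` table of the post-conversion draws; attributes
#'   `n_anti`/`n_sense` record realised conversion events.
#' @export
simulate_codon_pool <- function(config, n, seed = config$seed) {
  set.seed(seed)
  p <- sim_codon_probs(config)
  pre <- sample(names(p), n, replace = TRUE, prob = p)
  conv <- apply_conversions(pre, config$m_anti, config$m_sense)
  tab <- table(factor(conv$post, levels = CODONS))
  out <- codon_counts(stats::setNames(as.integer(tab), CODONS),
                      scope = paste0("pool_n", n))
  attr(out, "n_anti") <- conv$n_anti
  attr(out, "n_sense") <- conv$n_sense
  out
}

#' Closed-form expected context ratios under a config
#'
#' Per-draw expectations for the baseline (untilted) codon distribution:
#' E(NCA) = p(NCA) + m_anti p(NCG) and E(NCG) = (1 - m_anti) p(NCG) per draw;
#' junction expectations compose codon-pair probabilities with the sense
#' conversion applied when the next codon starts with G.
#'
#' @param config a [simulation_config()].
#' @return list: `nxa_nxg` and `ntx_ncx` (named expected ratios over X =
#'   A/C/G/T), `ending_freq` (expected post-conversion fNNA..fNNG), and the
#'   baseline `p_nca`, `p_ncg`, `r0_nca_ncg`.
#' @export
expected_ratios <- function(config) {
  p <- sim_codon_probs(config)
  m_a <- config$m_anti; m_s <- config$m_sense
  second <- codon_second_base(SC_CODONS)
  third <- codon_third_base(SC_CODONS)
  first <- codon_first_base(SC_CODONS)
  p_g1 <- sum(p[SC_CODONS[first == "G"]])   # P(next codon starts G)

  # post-conversion per-draw probabilities at third position
  post <- p
  for (c_g in NCG_SET) {
    c_a <- sub("G$", "A", c_g)
    post[c_a] <- post[c_a] + m_a * p[c_g]
    post[c_g] <- (1 - m_a) * p[c_g]
  }
  # sense conversion shifts C-ending mass to T-ending, conditional on a
  # G-starting successor (per-draw marginal)
  if (m_s > 0) {
    for (c_c in SC_CODONS[third == "C"]) {
      c_t <- sub("C$", "T", c_c)
      moved <- m_s * p_g1 * p[c_c]
      post[c_t] <- post[c_t] + moved
      post[c_c] <- post[c_c] - moved
    }
  }

  nxa_nxg <- vapply(c(A = "A", C = "C", G = "G", T = "T"), function(b) {
    num <- sum(post[SC_CODONS[second == b & third == "A"]])
    den <- sum(post[SC_CODONS[second == b & third == "G"]])
    if (den == 0) NA_real_ else num / den
  }, numeric(1))

  p_end_t <- sum(p[SC_CODONS[third == "T"]])
  p_end_c <- sum(p[SC_CODONS[third == "C"]])
  p_first <- vapply(c(A = "A", C = "C", G = "G", T = "T"), function(b) {
    sum(p[SC_CODONS[first == b]])
  }, numeric(1))
  ntx_ncx <- vapply(names(p_first), function(b) {
    if (b == "G") {
      num <- (p_end_t + m_s * p_end_c) * p_first[[b]]
      den <- (1 - m_s) * p_end_c * p_first[[b]]
    } else {
      num <- p_end_t * p_first[[b]]
      den <- p_end_c * p_first[[b]]
    }
    if (den == 0) NA_real_ else num / den
  }, numeric(1))

  ending <- vapply(c(A = "A", T = "T", C = "C", G = "G"), function(b) {
    sum(post[SC_CODONS[third == b]])
  }, numeric(1))
  p_nca <- sum(p[SC_CODONS[second == "C" & third == "A"]])
  p_ncg <- sum(p[SC_CODONS[second == "C" & third == "G"]])
  list(nxa_nxg = nxa_nxg, ntx_ncx = ntx_ncx,
       ending_freq = ending / sum(ending),
       p_nca = p_nca, p_ncg = p_ncg,
       r0_nca_ncg = p_nca / p_ncg)
}

#' Recover the antisense conversion rate from an observed NCA/NCG ratio
#'
#' Moment estimator inverting the per-draw expectation
#' E(NCA)/E(NCG) = (p_NCA + m p_NCG) / ((1 - m) p_NCG): with R the observed
#' ratio and R0 = p_NCA/p_NCG the baseline ratio,
#' m-hat = (R - R0) / (1 + R). Consistent as the number of draws grows.
#'
#' @param observed a `second_position_table` (or the pair `c(NCA, NCG)`).
#' @param config the generating [simulation_config()] (supplies the baseline).
#' @return estimated rate in `[0, 1]`; an observed ratio below baseline is
#'   clamped to 0 with a warning.
#' @export
recover_conversion_rate <- function(observed, config) {
  if (inherits(observed, "second_position_table")) {
    nca <- observed["NXA", "C"]; ncg <- observed["NXG", "C"]
  } else {
    nca <- observed[1]; ncg <- observed[2]
  }
  if (ncg == 0) stop("recover_conversion_rate: observed NCG count is zero")
  r_obs <- nca / ncg
  r0 <- expected_ratios(config)$r0_nca_ncg
  m_hat <- (r_obs - r0) / (1 + r_obs)
  if (m_hat < 0) {
    warning("observed NCA/NCG ratio below baseline; clamping estimate to 0")
    m_hat <- 0
  }
  min(m_hat, 1)
}
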