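---
title: "Methods: eQTL mapping, hotspot detection and regulatory-network extraction"
author: "eqtlNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL mapping, hotspot detection and regulatory-network extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlNet)
```

# Scope and model

`eqtlNet` implements a complete expression-QTL analysis for an outbred F1
mapping population: the kind of design used to dissect wood-formation gene
regulation in shrub willow, where ~10^5 biallelic markers from reduced-
representation sequencing are tested against young-stem RNA-seq expression
of ~120 full-sib offspring.

The statistical core is deliberately simple and standard. For each SNP
*s* and gene *g* the additive linear model

$$ y_{gi} = \beta_0 + \beta \, d_{si} + \varepsilon_i $$

is fit by ordinary least squares, where $d_{si} \in \{0,1,2\}$ is the ALT
allele count of individual *i* and $y_{gi}$ is the gene's rank-based
inverse-normal score. The per-pair t statistic has $n-2$ degrees of freedom
and yields the two-sided p-value $2\,(1 - F_t(|t|;\,n-2))$. The
implementation evaluates the whole SNP × gene grid with one centered
cross-product (the fast-matrix-association approach) and is tested to agree
with per-pair `lm()` fits to 1e-10 relative tolerance on *t*.

Assumptions worth keeping in mind:

* **Additivity, no covariates.** No dominance coding, no kinship or mixed
  model, no expression PCs. The target design is a single full-sib family
  measured in one tissue and batch, where these corrections are weaker
  concerns than in diversity panels; the module boundary makes it clear
  where covariates would enter if needed.
* **Missing dosages are mean-imputed per SNP** rather than dropped
  pairwise. This keeps `n_used` constant per SNP, matches the behaviour of
  the fast matrix association tools used in practice, and biases mildly
  toward the null (an acceptable direction for a screen gated at a
  family-wise threshold).
* **Inverse-normal scores.** Each gene is transformed with the Blom formula
  $\Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$, average ranks on ties,
  constant genes mapped to zero with a warning. The transform makes the
  association invariant to any monotone rescaling of expression — which is
  also why the synthetic generator's choice of acting on log-FPKM is
  immaterial downstream.

# Pipeline stages and their parameters

All thresholds live in one place, `pipelineConfig()`, with these defaults:

| parameter | default | meaning |
|---|---|---|
| `fpkm_min`, `frac_min` | 1, 0.20 | expressed iff FPKM > 1 in **more than** 20% of individuals (both strict) |
| `qual_min`, `maf_min`, `miss_max` | 50, 0.05, 0.10 | SNP gates: quality ≥ 50, MAF > 5%, missing < 10% (strictness follows the stated rules verbatim) |
| `alpha` | 0.05 | family-wise level; the gate is `alpha / (n_SNPs × n_genes)` |
| `p_threshold` | `NULL` | optional fixed "suggestive" cutoff replacing the Bonferroni gate (the practice of applying a pre-computed threshold as a constant); required for toy datasets where the minimal attainable p exceeds the Bonferroni gate |
| `max_gap_bp`, `min_snps` | 10 kb, 3 | block chaining: consecutive significant SNPs join while gaps ≤ 10 kb; blocks need ≥ 3 members |
| `cis_window_bp` | 10 kb | cis iff the lead SNP is within [gene start − w, gene end + w], inclusive |
| `win_bp`, `step_bp` | 1 Mb, 10 kb | hotspot sliding-window geometry |
| `n_perm`, `hotspot_alpha` | 1000, 0.01 | permutations and family-wise level for the hotspot threshold |
| `merge_gap_bp` | 0 | hotspots merge when overlapping or touching |
| `bin_bp`, `min_targets` | 100 kb, 2 | network bins must control ≥ 2 distinct WFRGs |
| `proximity_bp` | 100 kb | "near the eQTL": gene overlaps the bin or is within 100 kb of a member lead SNP |
| `pcc_min` | 0.4 | \|Pearson r\| must be **strictly** greater |
| `reg_fc`, `tgt_fc` | 1.2, 1.5 | fold-change gates (inclusive ≥), simultaneous in the same dataset |
| `min_component` | 5 | smallest reportable network component |
| `flank_bp` | 5 kb | upstream/downstream annotation window |

Design decisions where the procedure was genuinely open:

* **Gap vs diameter.** "Clusters within a maximum distance of 10 kb" is read
  as an inter-SNP gap rule (single-linkage chaining), not a cluster
  diameter. Chaining is the standard interval-merge reading, is invariant
  to input order, and is what the oracle tests encode.
* **Cis window anchor.** The 10 kb cis window is anchored to the gene body
  (start − 10 kb, end + 10 kb), boundaries inclusive, rather than the TSS;
  "surrounding each gene" names a region around the gene, not a point.
* **Permutation scheme.** The hotspot threshold is underdetermined by
  "1000 permutations, p < 0.01" alone. We re-place the observed number of
  trans lead SNPs uniformly over the concatenated genome (chromosome drawn
  proportionally to length), recompute all window counts, record the
  genome-wide maximum, and take one more than the ⌈(1 − α)·n⌉-th order
  statistic of those maxima. Using the maximum gives family-wise control
  over all windows, which is what a "declare hotspots at p < 0.01" rule
  needs; a per-window quantile would be anti-conservative under multiplicity.
  Window counts at or above the returned integer are called (the
  "at least" convention), which is equivalent to being strictly above the
  null quantile.
* **Counts are trans blocks, not distinct genes.** Windows count lead SNPs
  of trans blocks; distinct target-gene counts are carried alongside for
  inspection.
* **Lead-SNP ties** break by genomic position, making all outputs
  deterministic. The significance gate is inclusive (`p ≤ threshold`).
* **Fold-change pseudocount.** The gates compare
  `max(meanA/meanB, meanB/meanA)`; a +0.5 pseudocount is applied only when
  a mean is zero, so (3, 2) is exactly 1.5 and (0, 0) is exactly 1.
* **DEG stand-in.** Parental DEGs are called by a Welch t-test on
  log2(library-size-normalized count + 0.5) with Benjamini–Hochberg
  correction, not a negative-binomial shrinkage model. Only the binary DEG
  flags feed the downstream screens, and the tests show ≥ 90% power at
  |log2 FC| = 3 with five replicates and dispersion 0.1, with the null
  controlled — sufficient fidelity for that role.
* **Coordinates.** Everything internal is 1-based inclusive (VCF/GFF3
  convention); conversion to 0-based half-open happens only when writing
  BED.
* **Variant annotation.** One category per SNP with most-severe-wins
  precedence (coding > intron/UTR > flanking > intergenic), so categories
  partition the SNP set and shares sum to 100%. Coding substitutions are
  classified by rebuilding the reference codon from the spliced CDS
  sequence, strand-aware; `large_effect` marks stop-gain/loss, start-loss,
  frameshift-length indels, and the 2 bp splice dinucleotides. The 5 kb
  flanking window is the conventional annotator default; the upstream/
  downstream share of a SNP set constrains but does not determine this
  choice, so it is exposed as `flank_bp`.
* **Multi-allelic records are skipped, not split** (no defensible dosage
  rule without phasing); phased and unphased separators are equivalent
  because only the additive dosage is consumed. Biallelic indels and MNPs
  are accepted as dosage-bearing records.

# The synthetic-data generator

`simulateDataset()` is the package's test bed and defines the conditions
under which the pipeline's operating characteristics are demonstrated:

* 120 offspring; 5 chromosomes × 5 Mb; 500 genes; 5,000 background SNPs
  with per-site MAF ~ U(0.05, 0.5) and Hardy–Weinberg dosages; 5% missing
  genotypes; ~2% of sites below the quality gate.
* Baseline log expression Normal(gene mean, 0.5); every planted effect adds
  β·dosage with β chosen so the genotype explains the requested fraction of
  variance (r² = 0.5 by default); FPKM = exp(log expression).
* Planted effects are **fully linked 5-SNP clusters** (gaps ≤ 2 kb, within
  10 kb of the gene for cis, on another chromosome for trans). Five rather
  than the minimal three, because the missingness filter removes a member
  site occasionally and the block rule needs three survivors; real causal
  loci likewise carry several linked markers.
* Each hotspot is one such cluster whose dosage feeds 30 distant genes
  (≥ 1 Mb away or on another chromosome), plus three regulator genes
  relocated to within 100 kb of the locus, driven by the same dosage at
  r² = 0.8 and forced to be parentally differentially expressed (|log2 FC|
  1.2 for regulators, 1.5 for targets) so the three screening criteria are
  satisfiable by construction. Real hotspots sit in gene-bearing regions;
  the relocation makes that true of the simulated ones.
* Parent counts are Negative-Binomial with dispersion 0.1 around means
  separated by the planted log2 fold changes, five replicates per parent.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: pedigree linkage disequilibrium (offspring are
i.i.d. Hardy–Weinberg draws; the pipeline consumes only dosage–expression
covariance, but real F1 segregation produces long-range LD that widens
blocks and can alias trans signals), polygenic and shared-environment
expression covariance, expression outliers and batch structure, reference/
mapping bias in dosages, and multi-allelic or structural variation. The
worked example (`makeWorkedExample()`) is a separate fixed 6-sample fixture
built from deterministic arithmetic, small enough to verify by hand; its
companion `workedExampleConfig()` substitutes a fixed suggestive p cutoff
and 2 kb windows because at n = 6 the smallest attainable rank-normal
association p (~0.005) can never pass a genome-wide Bonferroni gate.

# Numerical choices and degenerate inputs

* Correlations are clipped to [−1, 1] before the t transform; a perfect fit
  yields a finite large t and an underflowing p rather than NaN.
* Zero-variance dosages (after imputation) and constant expression rows are
  skipped and counted, never silently dropped.
* Sites with every dosage missing are removed with a warning (MAF
  undefined).
* Empty result sets propagate as zero-row tables end to end; writers emit
  header-only files.
* The Wilcoxon comparison of cis vs trans lead p-values uses the normal
  approximation with tie correction on −log10 p; tests check the rank-sum
  statistic against exact enumeration on small inputs.
* Permutation and simulation randomness is fully seeded; a single pipeline
  seed fans out to the permutation stage by a fixed offset so stages are
  reproducible standalone. Identical config + seed gives byte-identical
  output files.

# Test-suite problem sizes

The suite exercises recovery at the study's sample size (n = 120) but
scaled-down marker/gene counts chosen for a deterministic, fast run: 50
replicates of 3 chromosomes × 3 Mb, 60 genes, 400 background SNPs, 5 cis +
3 trans effects and one 12-target hotspot, with 150 permutations per
replicate; null calibration uses one 28,300-pair dataset and 200 null
hotspot genomes. Across those conditions the suite requires ≥ 90% cis
recovery, ≥ 95% hotspot recovery, ≥ 90% motif recovery, pairwise-OLS
agreement to 1e-10, and null rates within Monte-Carlo error of nominal.

# Known limitations

* Bonferroni across all pairs is intentionally rigorous; with correlated
  markers it is conservative, and no FDR alternative is provided.
* Cis/trans classification depends on the lead SNP only; a wide block
  straddling the window boundary is labelled by its lead.
* The hotspot permutation null assumes exchangeable lead positions; marker
  density variation along real genomes (e.g. RAD-tag clustering) is not
  modelled and would inflate counts in dense regions.
* The regulator screen is correlational; "regulator" labels candidate
  genes near the locus, not directed causal claims.
* The DEG stand-in is less powerful than a negative-binomial model at low
  counts; its role here is limited to fold-change gating.
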