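# eqtlNet

Genome-wide eQTL mapping, trans-eQTL hotspot detection and regulatory-network
extraction for outbred F1 mapping populations, written for the kind of study
that motivated it: dissecting the genetic regulation of wood-formation genes
in a 120-offspring full-sib family of the shrub willow *Salix suchowensis*,
from RAD-seq genotypes and young-stem RNA-seq expression.

## What it computes

Given biallelic SNP genotypes (VCF), gene models (GFF3), a gene × sample FPKM
table and raw counts for the two parents, the pipeline runs four stages:

1. **Preprocess** — keep genes with FPKM > 1 in more than 20% of individuals
   and rank-normalize each gene with the Blom inverse-normal transform
   Φ⁻¹((r − 3/8)/(n + 1/4)); keep SNPs with site quality ≥ 50, minor allele
   frequency > 5% and missing rate < 10%; classify every SNP's functional
   context (coding synonymous/nonsynonymous, intron, UTR, 5 kb
   upstream/downstream, intergenic) with a most-severe-wins precedence;
   call parental DEGs (|log2 FC| > 1, BH q < 0.05).
2. **Map** — test every SNP–gene pair with the additive linear model
   y = β₀ + β·dosage + ε (missing dosages mean-imputed per SNP), gate at the
   Bonferroni threshold α/(n_SNPs · n_genes), chain significant SNPs within
   10 kb gaps into eQTL blocks of ≥ 3 SNPs, represent each block by its
   minimum-p lead SNP, and classify a block *cis* when the lead SNP lies
   within 10 kb of the target gene body, *trans* otherwise.
3. **Hotspots** — count trans-eQTL lead SNPs in 1 Mb windows sliding by
   10 kb, derive the hotspot count threshold from 1000 permutations of lead
   positions (family-wise p < 0.01 on the genome-wide maximum), call windows
   at or above threshold, and merge overlapping/adjacent calls.
4. **Network** — tile the genome in 100 kb bins, keep bins whose trans
   blocks target ≥ 2 wood-formation-related genes (WFRGs), collect candidate
   regulator genes near those loci, and keep regulator → target pairs with
   |Pearson r| > 0.4 across the population that are simultaneously
   differentially expressed in at least one dataset (regulator ≥ 1.2×,
   target ≥ 1.5×); report connected components with ≥ 5 nodes.

A first-class synthetic-data generator (`simulateDataset()`) emulates the
study design — 120 offspring, Hardy–Weinberg dosages at realistic MAFs,
planted cis/trans effects of known r², hotspot loci feeding dozens of
distant genes, regulator genes beside each hotspot, and parental
differential expression — and returns a truth table so every stage is
testable end to end.

## Worked example

A fixed 6-sample, 2-chromosome, 8-gene, 30-SNP dataset ships with the
package (`inst/extdata/worked_example/`, regenerated by
`makeWorkedExample()`), with one cis effect 1,354 bp upstream of its target,
one trans effect, and a 3-target mini-hotspot:

```r
library(eqtlNet)
we  <- makeWorkedExample()
res <- runPipeline(we, workedExampleConfig())
res$blocks[, c("gene_id", "chrom", "lead_snp", "lead_pos", "lead_p", "cls")]
#>   gene_id chrom lead_snp lead_pos      lead_p   cls
#> 1      g1  chr1    cis_1    18646 0.005306199   cis
#> 2      g2  chr2  trans_1    70000 0.005306199 trans
#> 3      g3  chr2    hot_1    50000 0.005306199 trans
#> 4      g4  chr2    hot_1    50000 0.005306199 trans
#> 5      g6  chr2    hot_1    50000 0.005306199 trans
#> 6      g7  chr2    hot_1    50000 0.005306199   cis
res$hotspots[, c("chrom", "start", "end", "n_trans_eqtls")]
#>   chrom start   end n_trans_eqtls
#> 1  chr2 48001 51500             3
res$pairs[, c("regulator", "target", "pcc", "de_datasets")]
#>   regulator target       pcc de_datasets
#> 1        g7     g3 1.0000000     parents
#> 2        g7     g4 0.7668944     parents
```

Reading the output: the planted cis SNP (`cis_1`, 1,354 bp upstream of `g1`)
is recovered as a cis block; the trans cluster on chr2 maps to `g2` on chr1;
the three hotspot-driven genes (`g3`, `g4`, `g6`) share the lead SNP
`hot_1`, whose window count (3) meets the permutation threshold and becomes
the merged hotspot chr2:48,001–51,500; and the regulator gene `g7` sitting
beside the hotspot passes the correlation and differential-expression
screens against two of its WFRG targets. (`g7`'s own block is cis because it
lies within 10 kb of the hotspot locus that also drives it.)

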