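# shared in-code fixtures for the test suite

# a small GenotypeData from a dosage matrix and positions
makeGeno <- function(dosages, chrom = "chr1", pos = NULL, qual = 99,
                     ids = NULL, ref = "A", alt = "G") {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(ids))
    ids <- if (!is.null(rownames(dosages))) rownames(dosages)
           else sprintf("s%03d", seq_len(n))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("I%02d", seq_len(ncol(dosages)))
  gr <- GenomicRanges::GRanges(rep(chrom, length.out = n),
                               IRanges::IRanges(pos, width = 1L),
                               ref = rep(ref, length.out = n),
                               alt = rep(alt, length.out = n),
                               qual = rep(qual, length.out = n))
  names(gr) <- ids
  GenotypeData(dosages, gr)
}

# a GeneModels with a single-CDS gene whose spliced sequence is given
makeCodingGene <- function(id = "gx", chrom = "chr1", start = 1000L,
                           cds_len = 900L, strand = "+", seq = NULL,
                           cds = NULL) {
  end <- start + cds_len - 1L
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand)
  names(g) <- id
  if (is.null(cds))
    cds <- GenomicRanges::GRangesList(list(
      GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                             strand = strand)))
  if (is.null(seq)) {
    n_codons <- cds_len / 3
    seq <- paste0("ATG", strrep("GCT", n_codons - 2), "TAA")
  }
  seqs <- Biostrings::DNAStringSet(seq)
  names(seqs) <- id
  GeneModels(g, cds, cdsSeqs = seqs)
}

# tiny recovery-scale simulation config (n = 120 kept at study scale)
recoveryConfig <- function(seed, ...) {
  simulationConfig(n_samples = 120, n_chromosomes = 3, chrom_length_bp = 3e6,
                   n_genes = 60, n_snps = 400, n_cis_effects = 5,
                   n_trans_effects = 3, cis_r2 = 0.5, trans_r2 = 0.5,
                   hotspot_spec = list(list(chrom = "chr1", pos = 1500000,
                                            n_target_genes = 12,
                                            effect_r2 = 0.5)),
                   seed = seed, ...)
}
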